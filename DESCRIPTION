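Package: dmriqc
Title: Real-Time Quality Control and Re-Acquisition Planning for Fetal
    Diffusion MRI
Version: 0.1.0
Authors@R:
    person("dmriqc", "developers", email = "dmriqc@example.org",
           role = c("aut", "cre"))
Description: Per-volume quality assessment for 4D diffusion-weighted MRI
    series of the fetal brain: geometric motion features (brain volume,
    centre of mass, field-of-view boundary contact) derived from per-volume
    brain masks, intra-volume dropout-slice detection, a b-value-dependent
    volume-change threshold, prioritized re-acquisition planning with an
    iteration cap and volume merge-back, a synthetic multi-b-value phantom
    generator with injectable artifacts and Rician noise, and voxel-wise
    ADC and segmented IVIM model fitting with region-of-interest
    statistics. Includes a minimal NIfTI-1 reader/writer and FSL-style
    bval/bvec table support so the whole pipeline runs from the command
    line without scanner infrastructure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
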