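# Fixture builders shared across test files. All fixtures are generated
# in code; nothing is read from disk except files the tests write first.

# A minimal hand-built series: constant background intensity inside a
# box mask, `t` volumes on an isotropic grid.
toy_series <- function(grid = c(8L, 8L, 6L), t = 4L, voxel = 2,
                       bvals = rep(0, t), intensity = 100) {
  data <- array(intensity, dim = c(grid, t))
  bt <- btable(bvals, matrix(rep(c(1, 0, 0), t), nrow = 3) *
                 rep(ifelse(bvals > 0, 1, 0), each = 3))
  diffusion_series(data, rep(voxel, 3), diag(c(rep(voxel, 3), 1)), bt)
}

# Box mask occupying [i0..i1, j0..j1, k0..k1] in every volume.
box_masks <- function(series, i = 3:6, j = 3:6, k = 2:5) {
  m <- array(0, dim = dim(series$data))
  m[i, j, k, ] <- 1
  mask_series(m, series)
}

# Small quick phantom configuration used across tests.
small_phantom_config <- function(seed, artifacts = list(), noise_sigma = 0,
                                 bt = default_btable()) {
  phantom_config(grid = c(26L, 26L, 14L), voxel_size = c(3, 3, 3),
                 bt = bt, semi_axes_mm = c(22, 26, 12), csf_rim_mm = 3,
                 noise_sigma = noise_sigma, artifacts = artifacts, seed = seed)
}

# Random small series + masks for oracle-equivalence testing: random
# blob masks, random intensities, occasional planted artifacts so both
# flag outcomes are exercised.
random_small_case <- function(seed) {
  set.seed(seed)
  g <- sample(6:12, 3, replace = TRUE)
  t <- sample(3:8, 1)
  voxel <- runif(1, 1, 3)
  bvals <- sample(c(0, 10, 200, 1000), t, replace = TRUE)
  bvals[1] <- 0
  bvecs <- matrix(0, 3, t)
  for (i in seq_len(t)) if (bvals[i] > 0) {
    v <- rnorm(3); bvecs[, i] <- v / sqrt(sum(v^2))
  }
  data <- array(runif(prod(g) * t, 80, 120), dim = c(g, t))
  m <- array(0, dim = c(g, t))
  ctr <- g / 2
  base_r <- min(g) / 2 - 1.2
  for (i in seq_len(t)) {
    r <- base_r * runif(1, 0.85, 1.15)
    for (k in seq_len(g[3])) {
      dz2 <- ((k - ctr[3]) / r)^2
      if (dz2 <= 1) {
        sl <- outer(((seq_len(g[1]) - ctr[1]) / r)^2,
                    ((seq_len(g[2]) - ctr[2]) / r)^2, `+`) + dz2
        m[, , k, i] <- as.double(sl <= 1)
      }
    }
    # occasionally attenuate one slice or shift the mask to the boundary
    if (runif(1) < 0.4) {
      ks <- sample(seq_len(g[3]), 1)
      data[, , ks, i] <- data[, , ks, i] * runif(1, 0.1, 0.9)
    }
    if (runif(1) < 0.15) {
      m[, , , i] <- 0
      m[1:2, 1:2, 1:2, i] <- 1      # tiny blob touching the boundary
    }
  }
  bt <- btable(bvals, bvecs)
  series <- diffusion_series(data, rep(voxel, 3), diag(c(rep(voxel, 3), 1)), bt)
  list(series = series, masks = mask_series(m, series))
}
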