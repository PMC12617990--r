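case,region,adc_conv,adc_conv_sd,adc_qc,adc_qc_sd,ivim_conv,ivim_conv_sd,ivim_qc,ivim_qc_sd,n_corrupted
1,WM,0.00202,0.00030,0.00159,0.00031,0.470,0.26,0.239,0.12,7
1,GM,0.00158,0.00031,0.00115,0.00025,0.379,0.26,0.114,0.07,7
2,WM,0.00149,0.00019,0.00145,0.00021,0.124,0.07,0.097,0.08,5
2,GM,0.00105,0.00021,0.00106,0.00019,0.088,0.05,0.093,0.10,5
3,WM,0.00120,0.00012,0.00113,0.00013,0.107,0.13,0.026,0.03,4
3,GM,0.00109,0.00062,0.00106,0.00051,0.091,0.10,0.084,0.12,4
4,WM,0.00138,0.00020,0.00136,0.00020,0.112,0.13,0.097,0.12,3
4,GM,0.00119,0.00018,0.00115,0.00016,0.114,0.08,0.081,0.05,3
5,WM,0.00152,0.00020,0.00131,0.00019,0.307,0.24,0.127,0.10,5
5,GM,0.00122,0.00031,0.00111,0.00017,0.220,0.22,0.061,0.03,5
6,WM,0.00141,0.00019,0.00140,0.00019,0.055,0.07,0.056,0.07,1
6,GM,0.00110,0.00021,0.00110,0.00021,0.062,0.09,0.063,0.09,1
7,WM,0.00131,0.00020,0.00123,0.00015,0.028,0.04,0.054,0.08,1
7,GM,0.00093,0.00019,0.00094,0.00019,0.025,0.03,0.037,0.05,1
8,WM,0.00126,0.00017,0.00127,0.00017,0.054,0.06,0.053,0.04,3
8,GM,0.00098,0.00033,0.00096,0.00030,0.036,0.06,0.033,0.05,3
9,WM,0.00160,0.00019,0.00160,0.00017,0.127,0.12,0.120,0.11,3
9,GM,0.00131,0.00018,0.00131,0.00020,0.105,0.09,0.103,0.08,3
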