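# Example analysis configuration: keys map 1:1 onto nc_thresholds()
rpmm_min: 1
local_frac: 0.10
rho_cut: 0.5
n_tissues_global: 5
min_reads_sample: 2000000
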