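# small virtual trial used by examples and tests
n_patients: 4
D_median: 25
rho_median: 16
D_sdlog: 0.5
rho_sdlog: 0.5
noise_sd_mm: 1
initial_radius_mm: 12
seed: 11
fatal_radius_mm: 30
horizon_days: 900
dg_scan_day: 91
arms:
  biopsy: {type: resection, extent: biopsy}
  gtr: {type: resection, extent: GTR}
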