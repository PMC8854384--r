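cohort:
  n_control: 8.0
  n_dlb: 8.0
  n_regions: 60.0
  n_timepoints: 200.0
  sampling_interval: 3.0
  dwell_jitter_sd: 0.25
analysis:
  window: 15.0
  band:
  - 0.071
  - 0.125
  filter: yes
  similarity_mode: connectivity
  gamma: 1.0
  louvain_restarts: 10.0
  b_bins: 100.0
  z_bins: 100.0
  n_perm: 2000.0
  region_n_perm: 500.0
  fdr_q: 0.05
  region_q: 0.1
  gene_q: 0.1
behavior:
  drift0: 0.2
  drift_slope: 0.2
  drift_noise: 0.25
  boundary: 0.12
  nondecision: 0.3
  n_trials: 200.0
  max_rt: 10.0
  noise_scale: 0.1
expression:
  n_genes: 20.0
  planted_rho: 0.6
  planted_name: PLANTED
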