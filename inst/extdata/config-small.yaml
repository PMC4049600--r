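# Packaged small simulation: 6 subjects per group on a 12 x 12 x 8 grid
# with 8 planted sources and 8 estimated components.
seed: 20
simulation:
  grid_dims: [12, 12, 8]
  n_sources: 8
  n_subjects_per_group: 6
  tr_seconds: 2
  scans_per_condition: 200
  noise_sd: 0.02
  drift_amplitude: 0.01
  hrf_delay_jitter_sd: 0.25
  coupling_strength: 0.06
  blob_sigma: 1.2
ica:
  n_components: 8
  n_runs: 10
hrf:
  step: 0.5
  convolve_motion: true
behavior:
  rt_min: 200
  rt_max: 1500
  exclusion_rule: either
stats:
  alpha: 0.05
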