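# Demo pipeline: two motility conditions (autoinhibited baseline vs
# Lis1+Nde1-activated, 16-fold landing-rate contrast), a dwell section at
# the Nde1 residence-time scale, and a two-population mass histogram.
seed: 42
output: pipeline_demo_out
imaging:
  field_size_um: [40.0, 40.0]
  pixel_size_nm: 160.0
  frame_interval_s: 0.6
  n_frames: 500
analysis:
  min_run_length_nm: 500.0
  min_duration_s: 2.0
  end_exclusion_nm: 1000.0
conditions:
  - label: baseline
    reference: true
    f_true: 2.0e-4
    n_microtubules: 6
    velocity_mean_nms: 450.0
  - label: lis1_nde1
    f_true: 3.2e-3
    n_microtubules: 6
    velocity_mean_nms: 550.0
dwell:
  tau_s: 21.0
  n_baits: 40
  gap_mean_s: 60.0
  method: mle
massphot:
  n_samples: 3000
  shape_fixed: 0.0
  components:
    - {location: 170.0, scale: 12.0, shape: 0.0, weight: 0.55}
    - {location: 260.0, scale: 15.0, shape: 0.0, weight: 0.45}
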