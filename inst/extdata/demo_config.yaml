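seed: 1.0
landscape:
  n_rows: 60.0
  n_cols: 100.0
  cell_size_m: 1000.0
  n_layers: 6.0
  smoothness: 3.0
  intercept: -0.5
  coefficients:
    env01: 2.0
    env02: -1.0
  n_occ_A: 500.0
  n_occ_B: 80.0
  n_effort_points: 8000.0
cu_thresholds:
  A: 1000.0
  B: 15000.0
pa:
  n_sets: 3.0
  mode:
    A: cell
    B: buffer
cv:
  train_frac: 0.7
  n_reps: 2.0
algorithms:
  RF:
    ntree: 200.0
  CTA: []
ensemble_schemes:
- EMmean
- EMca
- EMwmean
boyce:
  window_width: 0.1
  n_windows: 101.0
importance:
  n_shuffles: 9.0
independent:
  n_points: 120.0
overlap:
  species:
    focal1: 40.0
    focal2: 25.0
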