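simulation:
  n_participants: 25.0
  n_trials: 605.0
  sfreq_hz: 1000.0
  dt_shift_ms: 200.0
  dt_lognorm_mu: 6.17
  dt_lognorm_sigma: 0.55
  onset_ms: 50.0
  bound_uv:
    selection_required: 10.0
  decay_tau_ms: 300.0
  topo_center:
  - 0.0
  - -0.335
  topo_width: 0.3
  pink_rms_uv: 10.0
  white_rms_uv: 5.0
  alpha_rms_uv: 4.0
  common_mode_rms_uv: 2.0
  cue_evoked_amp_uv: 3.0
  p_condition: 1.0
  error_kappa:
    selection_required: 3.1637782
  dt_condition_shift_ms:
    selection_required: 0.0
  onset_jitter_sd_ms: 0.0
  montage: full
  seed: 2.0240327e+07
preprocess:
  ref_channels:
  - M1
  - M2
  target_sfreq_hz: 250.0
  cue_window_ms:
  - -250.0
  - 1500.0
  resp_window_ms:
  - -1500.0
  - 500.0
  cue_baseline_ms:
  - -250.0
  - 0.0
  resp_baseline_ms:
  - 0.0
  - 250.0
  smooth_sigma_ms: 30.0
  dt_bounds_ms:
  - 200.0
  - 2000.0
  variance_z_threshold: 3.5
analysis:
  cluster_channels:
  - Pz
  - CPz
  - POz
  - P1
  - P2
  n_bins_fine: 100.0
  n_bins_coarse: 4.0
  slope_window_ms:
  - -500.0
  - -50.0
  sweep_starts_ms:
  - -1000.0
  - -200.0
  - 50.0
  sweep_ends_ms:
  - -400.0
  - 0.0
  - 50.0
  min_window_ms: 100.0
  topo_windows_ms:
    cue:
    - 300.0
    - 600.0
    resp:
    - -300.0
    - 0.0
    contrast:
    - -600.0
    - -300.0
inference:
  cluster_alpha: 0.05
  n_permutations: 10000.0
  seed: 1.0
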