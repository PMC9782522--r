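# Replica field-trial configuration: three 0.5 m x 10 m broadcast-seeded
# rows, walking-pace pass with per-frame speed jitter, detector emulated
# at its 68% per-frame recall operating point. Any field omitted here
# falls back to the package defaults (see ?default_config).
rows:
  - {length: 10, width: 0.5, weed_density: 6.6}
  - {length: 10, width: 0.5, weed_density: 17.8}
  - {length: 10, width: 0.5, weed_density: 11.8}
soy_density: 39.5
exact_counts: true
camera:
  fps: 19
  ground_window: [0.95, 0.53]
nozzle:
  flow_rate_lpm: 1.6
  open_time_s: 0.2
  height_m: 0.45
  pattern_width_m: 1.08
  offset_m: 0.30
noise:
  miss: {weed: 0.32, soybean: 0.32}
  misclass: 0.0
  clutter_rate: 0.2
  center_jitter_px: 3
  size_jitter: 0.05
trajectory:
  v: 0.69
  v_range: [0.53, 0.83]
n_trials: 3
n_weed_samples: 30
n_soy_samples: 30
adjacency_radius: 0.15
seed: 1
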