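experiment: shepp_horizontal
phantom: shepp_logan
grid:
  nx: 128
detector:
  line_length_mm: 76.0
  distance_mm: 38.0
  orientation: horizontal
time:
  fs_hz: 2.0e+08
  duration_s: 2.0e-05
  t_offset_s: 0.0
  c_mps: 1500.0
sampling_points: [50, 20, 10]
solvers: [patch_tv, patch_re, tv_gd]
params:
  alpha: 0.50
  beta: 0.42
  T: 0.65
  max_iters: 10
signal_supersample: 2
seed: 1
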