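experiment: forbild_noise
phantom: forbild
grid:
  nx: 128
detector:
  line_length_mm: 76.0
  distance_mm: 38.0
  orientation: vertical
time:
  fs_hz: 2.0e+08
  duration_s: 2.0e-05
  t_offset_s: 0.0
  c_mps: 1500.0
sampling_points: [20]
solvers: [patch_tv, tv_gd]
params:
  alpha: 0.73
  beta: 0.60
  T: 0.54
  max_iters: 10
noise_snr_db: [10.0, 5.0, 0.0]
signal_supersample: 2
seed: 1
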