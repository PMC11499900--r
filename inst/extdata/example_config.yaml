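geometry:
  d_mm: 20.0
  aspect_ratio: 2.9
  dilation_ratio: 1.9
  total_length_mm: 250.0
  wall_thickness_mm: 1.8
fluid:
  kinematic_viscosity_mm2s: 3.82
  density_kgm3: 1060.0
flow:
  case: FH
  period_s: 0.8
  n_harmonics: 12.0
loop:
  n_cycles: 6.0
  fs_hz: 5000.0
  delay_s: 0.023
  noise_q_m3s: 0.0
  noise_p_pa: 0.0
camera:
  width_px: 1920.0
  height_px: 1200.0
  bit_depth: 12.0
  scale_px_mm: 24.6
  exposure_us: 13000.0
  min_interframe_us: 80.0
illumination:
  label: C4
roi:
  x0_mm: -118.0
  x1_mm: -96.0
  width_px: 540.0
  height_px: 560.0
seeding:
  density_mm2: 7.0
  sheet_thickness_mm: 1.5
acquisition:
  phases: 25.0
  n_cycles: 1.0
  jitter: 0.0
piv:
  passes:
  - 128.0
  - 64.0
  - 32.0
  overlap: 0.5
  snr_min: 1.25
  global_k: 5.0
  median_k: 3.0
seed: 1.0
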