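# Desk-scale SVR 4D flow experiment: scanner reconstruction protocol
# (996/332-arm windows, 0.005 mm/TR SWEEP, TTV 0.08 x 30, SVR 0.01 x 10)
# on a 64 x 64 x 48 phantom with a 25 mm sweep.
seed: 1
segmentation: labels
phantom:
  grid_shape: [64, 64, 48]
  voxel_size_mm: 1.2
  cardiac_period_ms: 800
  rr_jitter_frac: 0.03
  t1_blood_ms: 1600
  t1_tissue_ms: 900
  background_phase_coeffs: [0.06, 0.0015, -0.001, 2.0e-5, -1.0e-5, 1.5e-5]
  vessels:
    - id: MPA
      centerline: [[-14, -8, -28.8], [-14, -8, 0]]
      radius_mm: 6
      peak_velocity_cm_s: 90
      waveform: {name: raised_cosine, peak_phase: 0.18, width: 0.4, base: 0.15}
    - id: RPA
      centerline: [[-14, -8, 0], [-24, -8, 4.8], [-24, -8, 28.8]]
      radius_mm: 4.5
      branch_of: {parent: MPA, fraction: 0.55}
    - id: LPA
      centerline: [[-14, -8, 0], [-4, -8, 4.8], [-4, -8, 28.8]]
      radius_mm: 4.2
      branch_of: {parent: MPA, fraction: 0.45}
    - id: AAo
      centerline: [[10, -12, -28.8], [10, -12, 28.8]]
      radius_mm: 5.5
      peak_velocity_cm_s: 100
      waveform: {name: raised_cosine, peak_phase: 0.15, width: 0.35, base: 0.2}
    - id: DAo
      centerline: [[24, 8, -28.8], [24, 8, 28.8]]
      radius_mm: 4.2
      peak_velocity_cm_s: 75
      waveform: {name: raised_cosine, peak_phase: 0.22, width: 0.45, base: 0.15}
    - id: SVC
      centerline: [[2, 14, -28.8], [2, 14, 28.8]]
      radius_mm: 4.8
      peak_velocity_cm_s: 45
      waveform: {name: raised_cosine, peak_phase: 0.35, width: 0.6, base: 0.35}
acquisition:
  tr_ms: 7.5
  te_ms: 3
  flip_deg: 15
  venc_cm_s: 150
  slice_thickness_mm: 4
  in_plane_resolution_mm: 1.2
  fov_mm: 76.8
  shift_per_tr_mm: 0.005
  duration_s: 37.35            # 4980 TR, 24.9 mm sweep
  z_start_mm: -12
  noise_sd: 0.02
  n_arm_samples: 128
  seed: 1
comparator:
  tr_ms: 5.3
  te_ms: 3
  flip_deg: 20
  venc_cm_s: 150
  slice_thickness_mm: 5
  in_plane_resolution_mm: 1.2
  fov_mm: 76.8
  shift_per_tr_mm: 0
  duration_s: 80
  noise_sd: 0.02
  seed: 8
cs:
  n_iterations: 30
  ttv_weight: 0.08
  n_cardiac_phases: 16
  arms_per_window: 996
  overlap_arms: 332
svr:
  n_iterations: 10
  reg_weight: 0.01
  target_voxel_mm: 1.2
  psf_fwhm_mm: 4
measure:
  - {vessel_id: MPA, z_mm: -7}
  - {vessel_id: RPA, z_mm: 7}
  - {vessel_id: LPA, z_mm: 7}
  - {vessel_id: AAo, z_mm: -2}
  - {vessel_id: DAo, z_mm: 3}
  - {vessel_id: SVC, z_mm: -4}
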