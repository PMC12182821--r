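# Scanner-scale protocol for reference: 5-minute SWEEP acquisition covering a
# 200 mm volume (40 000 TR at 0.005 mm/TR). Running this profile end to end
# takes hours; use desk.yaml for an interactive run. The phantom grid here is
# a full pediatric-thorax extent at acquisition resolution.
seed: 1
segmentation: labels
phantom:
  grid_shape: [256, 256, 192]
  voxel_size_mm: 1.2
  cardiac_period_ms: 800
  rr_jitter_frac: 0.03
  t1_blood_ms: 1600
  t1_tissue_ms: 900
  background_phase_coeffs: [0.06, 0.0015, -0.001, 2.0e-5, -1.0e-5, 1.5e-5]
  vessels:
    - id: AAo
      centerline: [[40, -48, -115.2], [40, -48, 115.2]]
      radius_mm: 11
      peak_velocity_cm_s: 100
      waveform: {name: raised_cosine, peak_phase: 0.15, width: 0.35, base: 0.2}
    - id: DAo
      centerline: [[96, 32, -115.2], [96, 32, 115.2]]
      radius_mm: 8.4
      peak_velocity_cm_s: 75
      waveform: {name: raised_cosine, peak_phase: 0.22, width: 0.45, base: 0.15}
acquisition:
  tr_ms: 7.5
  te_ms: 3
  flip_deg: 15
  venc_cm_s: 150
  slice_thickness_mm: 4
  in_plane_resolution_mm: 1.2
  fov_mm: 307.2
  shift_per_tr_mm: 0.005
  duration_s: 300
  z_start_mm: -100
  noise_sd: 0.02
  n_arm_samples: 512
  seed: 1
comparator:
  tr_ms: 5.3
  te_ms: 3
  flip_deg: 20
  venc_cm_s: 150
  slice_thickness_mm: 5
  in_plane_resolution_mm: 1.2
  fov_mm: 307.2
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
  - {vessel_id: AAo, z_mm: 0}
  - {vessel_id: DAo, z_mm: 0}
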