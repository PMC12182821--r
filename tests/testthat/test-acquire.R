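test_that("separable NDFT agrees with the brute-force oracle and its adjoint", {
  set.seed(11)
  x <- svrflow:::axis_coords(11, 1.5)
  y <- svrflow:::axis_coords(9, 1.5)
  img <- matrix(complex(real = rnorm(99), imaginary = rnorm(99)), 11, 9)
  k <- cbind(runif(40, -0.33, 0.33), runif(40, -0.33, 0.33))
  s <- ndft_forward(img, k, x, y)
  expect_equal(s, ndft_bruteforce(img, k, x, y), tolerance = 1e-10)
  v <- complex(real = rnorm(40), imaginary = rnorm(40))
  lhs <- sum(Conj(v) * ndft_forward(img, k, x, y))
  rhs <- sum(Conj(ndft_adjoint(v, k, x, y)) * img)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-12)
})

test_that("velocity encoding maps speed to phase by pi/VENC per axis", {
  expect_equal(encode_phase(c(0, 0, 150), 1, 150), pi)   # V_TP at VENC
  expect_equal(encode_phase(c(70, 10, 150), 0, 150), 0)  # flow-compensated
  expect_equal(encode_phase(c(75, 0, 0), 2, 150), pi / 2)  # V_X
  expect_equal(encode_phase(c(0, -75, 0), 3, 150), -pi / 2)  # V_Y
  # beyond VENC the phase exceeds pi and wraps in the complex signal
  ph <- encode_phase(c(0, 0, 200), 1, 150)
  expect_equal(ph, 4.18879, tolerance = 1e-5)
  wrapped <- Arg(exp(1i * ph))
  expect_equal(wrapped, -2.0944, tolerance = 1e-4)
  expect_equal(150 * wrapped / pi, -100, tolerance = 1e-3)
})

test_that("sweep simulation is linear in magnitude and deterministic", {
  cfg <- tube_phantom_config(grid = c(16, 16, 12), voxel = 1.5, radius = 4,
                             peak = 60)
  ph <- build_phantom(cfg, 2)
  acq <- acquisition_config(fov_mm = 24, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 0.01,
                            duration_s = 0.12, z_start_mm = 0, noise_sd = 0,
                            n_arm_samples = 64, seed = 4)
  tt <- sample_triggers(cfg, 2000, seed = 4)
  k1 <- simulate_sweep(ph, tt, acq)
  k1b <- simulate_sweep(ph, tt, acq)
  expect_identical(k1$data, k1b$data)            # bit-for-bit without noise
  ph2 <- ph
  ph2$magnitude <- 2 * ph$magnitude
  k2 <- simulate_sweep(ph2, tt, acq)
  expect_equal(k2$data, 2 * k1$data, tolerance = 1e-12)
})

test_that("a radially symmetric static object gives rotation-invariant arms", {
  cfg <- phantom_config(c(24, 24, 12), 1.5, vessels = list())
  ph <- build_phantom(cfg, 2)
  # replace the scene by a smooth centred Gaussian blob (a voxelised
  # hard-edged disc is not rotation invariant at high k)
  crd <- phantom_grid(cfg)
  blob <- exp(-outer(crd$x^2, crd$y^2, "+") / (2 * 6^2))
  for (p in 1:2) for (z in 1:12)
    ph$magnitude[, , z, p] <- 0.6 * blob
  acq <- acquisition_config(fov_mm = 36, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 0.001,
                            duration_s = 0.24, z_start_mm = 0, noise_sd = 0,
                            n_arm_samples = 64, seed = 1)
  tt <- sample_triggers(cfg, 2000, seed = 1)
  ks <- simulate_sweep(ph, tt, acq)
  vo <- which(ks$schedule$encoding_index == 0)
  mags <- abs(ks$data[vo, ])
  spread <- apply(mags, 2, function(cc) diff(range(cc)))
  expect_lt(max(spread) / max(mags), 0.02)
})

test_that("a single bright voxel produces the analytic Fourier phase ramp", {
  cfg <- phantom_config(c(16, 16, 10), 1.5, vessels = list())
  ph <- build_phantom(cfg, 2)
  ph$magnitude[] <- 0
  ph$magnitude[5, 9, 5, ] <- 1                  # one bright voxel, in tissue
  ph$labels[] <- 1L
  acq <- acquisition_config(fov_mm = 24, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 3, shift_per_tr_mm = 1e-4,
                            duration_s = 0.03, z_start_mm = 0, noise_sd = 0,
                            n_arm_samples = 64, seed = 1)
  tt <- sample_triggers(cfg, 2000, seed = 1)
  ks <- simulate_sweep(ph, tt, acq)
  crd <- phantom_grid(cfg)
  sp <- svrflow:::slice_profile_weights(crd$z, 0, 3)
  amp <- sp$w[sp$idx == 5] * inflow_signal(0, 3, 7.5, 15, 900)
  kr <- rotate_arm(ks$arm, ks$schedule$rotation_deg[1])
  pred <- amp * exp(-2i * pi * (kr[, 1] * crd$x[5] + kr[, 2] * crd$y[9])) /
    sqrt(16 * 16)
  expect_equal(ks$data[1, ], pred, tolerance = 1e-6)
})

test_that("the sweep must stay inside the phantom", {
  cfg <- tube_phantom_config(grid = c(16, 16, 12), voxel = 1.5)
  ph <- build_phantom(cfg, 2)
  acq <- acquisition_config(fov_mm = 24, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 0.5,
                            duration_s = 0.6, z_start_mm = 0, noise_sd = 0,
                            n_arm_samples = 64)
  tt <- sample_triggers(cfg, 3000, seed = 1)
  expect_error(simulate_sweep(ph, tt, acq), "exceeds phantom z-extent by")
})

test_that("sweep keeps the mean signal in a steady state across TRs", {
  cfg <- tube_phantom_config(grid = c(24, 24, 24), voxel = 1.5, radius = 5,
                             peak = 80)
  ph <- build_phantom(cfg, 2)
  acq <- acquisition_config(fov_mm = 36, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 0.02,
                            duration_s = 3, z_start_mm = -10, noise_sd = 0,
                            n_arm_samples = 64, seed = 1)
  tt <- sample_triggers(cfg, 5000, seed = 1)
  ks <- simulate_sweep(ph, tt, acq)
  vo <- which(ks$schedule$encoding_index == 0)
  dc <- abs(ks$data[vo, 1])                     # k = 0 sample per V_o arm
  expect_lt(max(abs(diff(dc))), 0.05 * mean(dc))
})

test_that("the fully sampled comparator reproduces slab magnitude and phase", {
  cfg <- tube_phantom_config(grid = c(32, 32, 16), voxel = 1.2, radius = 5,
                             peak = 60)
  ph <- build_phantom(cfg, 2)
  acq <- acquisition_config(venc_cm_s = 150, fov_mm = 38.4,
                            in_plane_resolution_mm = 1.2,
                            slice_thickness_mm = 4, shift_per_tr_mm = 0,
                            duration_s = 1, noise_sd = 0, seed = 1)
  c2d <- simulate_2d_pcmri(ph, list(z_mm = 0), acq, 2)
  crd <- phantom_grid(cfg)
  sp <- svrflow:::slice_profile_weights(crd$z, 0, 4)
  lm <- lumen_mask_at(ph, 0)
  # V_o magnitude equals the slice-profile-weighted, inflow-scaled magnitude
  ref <- svrflow:::slab_signal(ph, 0, sp$idx, sp$w, 0, acq,
                               matrix(0, 32, 32))
  expect_equal(c2d$images[, , 1, 1], ref, tolerance = 1e-12)
  # phase difference V_TP - V_o is uniform pi v / VENC inside the lumen core
  dphi <- Arg(c2d$images[, , 2, 1] * Conj(c2d$images[, , 1, 1]))
  vtrue <- ph$velocity[, , lm$zi, 3, 1]
  core <- lm$mask & vtrue > 20
  expect_equal(dphi[core], pi * vtrue[core] / 150, tolerance = 1e-6)
  # lumen flow within 5% of the analytic value
  q <- sum(150 * dphi[lm$mask] / pi) * 1.44 / 1000
  expect_equal(q, analytic_tube_flow(5, 60), tolerance = 0.05)
  expect_error(simulate_2d_pcmri(ph, list(z_mm = 99), acq, 2), "outside")
})

test_that("k-space sets round-trip through the archive", {
  cfg <- tube_phantom_config(grid = c(16, 16, 12), voxel = 1.5)
  ph <- build_phantom(cfg, 2)
  acq <- acquisition_config(fov_mm = 24, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 0.01,
                            duration_s = 0.12, z_start_mm = 0, noise_sd = 0.01,
                            n_arm_samples = 64, seed = 2)
  tt <- sample_triggers(cfg, 2000, seed = 2)
  ks <- simulate_sweep(ph, tt, acq)
  f <- tempfile(fileext = ".rds")
  write_kspace(ks, f)
  ks2 <- read_kspace(f)
  expect_identical(ks2$data, ks$data)
  expect_identical(as.data.frame(ks2$schedule), as.data.frame(ks$schedule))
})
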