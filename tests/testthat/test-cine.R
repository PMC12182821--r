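test_that("window bookkeeping reproduces the reconstruction protocol", {
  s <- build_schedule(5000, 7.5, -10, 0.005)
  cs <- cs_config(arms_per_window = 996, overlap_arms = 332)
  w <- make_windows(s, cs)
  # hop 996 - 332 = 664 TRs; 996 arms split 4 ways = 249 per encoding
  expect_equal(w[[2]]$tr_indices[1] - w[[1]]$tr_indices[1], 664)
  expect_equal(length(intersect(w[[1]]$tr_indices, w[[2]]$tr_indices)), 332)
  expect_equal(w[[1]]$arms_per_encoding, 249)
  expect_equal(length(w), 7)                     # trailing 16 TRs dropped
  expect_equal(w[[2]]$center_z_mm - w[[1]]$center_z_mm, 664 * 0.005)
  s1 <- build_schedule(996, 7.5, 0, 0.005)
  expect_length(make_windows(s1, cs), 1)
})

test_that("cardiac phase assignment matches a brute-force interval search", {
  cfg <- tube_phantom_config(jitter = 0.08)
  tt <- sample_triggers(cfg, 30000, seed = 7)
  pk <- tt$r_peak_times_ms
  expect_equal(assign_cardiac_phase(pk[3], tt), 0)
  expect_equal(assign_cardiac_phase((pk[3] + pk[4]) / 2, tt), 0.5)
  t <- seq(pk[1], pk[length(pk)], length.out = 500)
  brute <- vapply(t, function(ti) {
    i <- max(which(pk <= ti))
    if (i == length(pk)) return(0)
    (ti - pk[i]) / (pk[i + 1] - pk[i])
  }, 0)
  expect_equal(assign_cardiac_phase(t, tt), brute, tolerance = 1e-12)
  expect_error(assign_cardiac_phase(-1, tt), "outside the trigger span")
})

test_that("unregularised recon on a full Cartesian grid inverts exactly", {
  n <- 12
  d <- 1.5
  x <- svrflow:::axis_coords(n, d)
  kax <- (seq_len(n) - n / 2 - 1) / (n * d)
  kk <- as.matrix(expand.grid(kx = kax, ky = kax))
  set.seed(21)
  truth <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  y <- ndft_forward(truth, kk, x, x)
  sol <- cs_temporal_tv(list(kk), list(y), list(rep(1, nrow(kk))), x, x,
                        n_iterations = 5, ttv_weight = 0)
  expect_equal(matrix(sol$x[, , 1], n, n), truth, tolerance = 1e-8)
})

test_that("a static scene reconstructs with equal cardiac phases", {
  cfg <- phantom_config(c(24, 24, 12), 1.5, vessels = list())
  ph <- build_phantom(cfg, 4)
  acq <- acquisition_config(fov_mm = 36, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 1e-3,
                            duration_s = 4.8, z_start_mm = 0, noise_sd = 0,
                            n_arm_samples = 64, seed = 5)
  tt <- sample_triggers(cfg, 7000, seed = 5)
  ks <- simulate_sweep(ph, tt, acq)
  cs <- cs_config(n_iterations = 15, ttv_weight = 0.08, n_cardiac_phases = 4,
                  arms_per_window = 640, overlap_arms = 0)
  cn <- reconstruct_cine(ks, make_windows(ks$schedule, cs)[[1]], cs)
  m <- abs(cn$images[, , 1, ])
  scale <- max(m)
  for (p in 2:4)
    expect_lt(max(abs(m[, , p] - m[, , 1])) / scale, 0.01)
  # objective non-increasing for every encoding
  for (e in 1:4)
    expect_true(all(diff(cn$objective[e, ]) <= 1e-8 * cn$objective[e, 1]))
  # purity: same window, same result
  cn2 <- reconstruct_cine(ks, make_windows(ks$schedule, cs)[[1]], cs)
  expect_identical(cn$images, cn2$images)
})

test_that("an empty cardiac bin is reported with window, encoding and bin", {
  cfg <- tube_phantom_config(grid = c(16, 16, 12), voxel = 1.5)
  ph <- build_phantom(cfg, 2)
  acq <- acquisition_config(fov_mm = 24, in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4, shift_per_tr_mm = 1e-3,
                            duration_s = 0.24, z_start_mm = 0, noise_sd = 0,
                            n_arm_samples = 64, seed = 1)
  tt <- sample_triggers(cfg, 2500, seed = 1)
  ks <- simulate_sweep(ph, tt, acq)
  # 32 TRs cover 240 ms; with many bins over an 800 ms cycle most stay empty
  cs <- cs_config(n_iterations = 2, ttv_weight = 0.08, n_cardiac_phases = 16,
                  arms_per_window = 32, overlap_arms = 0)
  expect_error(reconstruct_cine(ks, make_windows(ks$schedule, cs)[[1]], cs),
               "empty cardiac bin.*encoding.*bin")
})

test_that("dense noiseless sampling reproduces the encoding phase in the lumen", {
  cfg <- tube_phantom_config(grid = c(24, 24, 16), voxel = 1.5, radius = 5,
                             peak = 70)
  ph <- build_phantom(cfg, 2)
  n_arms <- ceiling(pi * 24)
  apw <- n_arms * 2 * 4
  acq <- acquisition_config(venc_cm_s = 150, fov_mm = 36,
                            in_plane_resolution_mm = 1.5,
                            slice_thickness_mm = 4,
                            shift_per_tr_mm = 1e-4,
                            duration_s = apw * 7.5 / 1000, z_start_mm = 0,
                            noise_sd = 0, n_arm_samples = 96, seed = 3)
  tt <- sample_triggers(cfg, acq$duration_s * 1000 + 1700, seed = 3)
  ks <- simulate_sweep(ph, tt, acq)
  cs <- cs_config(n_iterations = 30, ttv_weight = 0.08, n_cardiac_phases = 2,
                  arms_per_window = apw, overlap_arms = 0)
  cn <- reconstruct_cine(ks, make_windows(ks$schedule, cs)[[1]], cs)
  lm <- lumen_mask_at(ph, 0)
  core <- lm$mask & ph$velocity[, , lm$zi, 3, 1] > 30
  dphi <- Arg(cn$images[, , 2, 1] * Conj(cn$images[, , 1, 1]))
  want <- pi * ph$velocity[, , lm$zi, 3, 1] / 150
  expect_lt(max(abs(dphi[core] - want[core])), 0.05)
})
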