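test_that("phase-difference decoding is linear in phase and wraps at VENC", {
  mk <- function(ph) array(exp(1i * ph), c(4, 4, 1, 1))
  enc <- array(0i, c(4, 4, 4, 1))
  enc[, , 1, 1] <- 1
  enc[, , 2, 1] <- exp(1i * pi / 2)              # V_TP
  enc[, , 3, 1] <- 1                             # V_X
  enc[, , 4, 1] <- exp(-1i * pi / 4)             # V_Y
  v <- decode_velocity(enc, 150, enc_dim = 3)
  expect_equal(unique(as.vector(v[, , 3, 1])), 75)      # z from V_TP
  expect_equal(unique(as.vector(v[, , 1, 1])), 0)
  expect_equal(unique(as.vector(v[, , 2, 1])), -37.5)
  # identical encodings decode to zero
  same <- array(exp(1i * 0.7), c(4, 4, 4, 1))
  expect_true(all(decode_velocity(same, 150, enc_dim = 3) == 0))
  # 200 cm/s at VENC 150 aliases to -100
  enc[, , 2, 1] <- exp(1i * pi * 200 / 150)
  v <- decode_velocity(enc, 150, enc_dim = 3)
  expect_equal(unique(as.vector(v[, , 3, 1])), -100, tolerance = 1e-10)
})

test_that("second-order background phase is recovered and removed", {
  nx <- 40; ny <- 40
  x <- svrflow:::axis_coords(nx, 1.2)
  y <- svrflow:::axis_coords(ny, 1.2)
  coeffs <- c(2, 0.08, -0.05, 1.5e-3, -8e-4, 1e-3)  # cm/s units
  bg <- svrflow:::background_phase_field(coeffs * pi / 150, x, y) * 150 / pi
  set.seed(41)
  truth_lumen <- matrix(0, nx, ny)
  truth_lumen[18:22, 18:22] <- 80
  vel <- array(rep(bg + truth_lumen, 3), c(nx, ny, 3))
  static <- truth_lumen == 0
  res <- correct_background_phase(vel, static, x, y)
  expect_equal(unname(res$coefficients), coeffs, tolerance = 0.01)
  expect_lt(abs(res$residual_static_cm_s), 0.5)
  expect_equal(res$velocity[20, 20, 2], 80, tolerance = 0.01)
  # nothing to remove: the field changes by < 0.1 cm/s
  vel0 <- array(rnorm(nx * ny * 2, sd = 0.01), c(nx, ny, 2))
  res0 <- correct_background_phase(vel0, matrix(TRUE, nx, ny), x, y)
  expect_lt(max(abs(res0$velocity - vel0)), 0.1)
  expect_error(correct_background_phase(vel[1:5, 1:5, , drop = FALSE],
                                        matrix(TRUE, 5, 5), x[1:5], y[1:5]),
               "too small")
})

test_that("neighbourhood-median unwrapping restores a wrapped tube core", {
  cfg <- tube_phantom_config(grid = c(40, 40, 12), voxel = 1.2, radius = 8,
                             peak = 200)
  ph <- build_phantom(cfg, 2)
  venc <- 150
  truth <- ph$velocity[, , , 3, 1]
  wrapped <- truth - 2 * venc * round(truth / (2 * venc))
  expect_lt(max(wrapped), venc + 1e-9)           # core maps near -100
  uw <- unwrap_aliasing(wrapped, venc)
  expect_true(uw$converged)
  core <- truth > 160
  expect_true(all(abs(uw$velocity[core] - truth[core]) < 3))
  expect_equal(uw$velocity, truth, tolerance = 1e-8)
  # smooth field within (-venc, venc): untouched
  sm <- array(50 * sin(seq(0, 3, length.out = 30)), c(30, 5, 4))
  uw2 <- unwrap_aliasing(sm, venc)
  expect_identical(uw2$velocity, sm)
  expect_equal(uw2$n_unresolved, 0L)
})

test_that("an adversarial checkerboard reports unresolved voxels", {
  n <- 16
  cb <- 149 * (-1)^(outer(1:n, 1:n, "+"))
  uw <- unwrap_aliasing(matrix(cb, n, n), 100)
  expect_gt(uw$n_unresolved, 0)
  expect_false(uw$converged)
})

test_that("lumen segmentation: oracle masks, threshold quality, connectivity", {
  # two fast tubes against an air background with a thin slice: high contrast
  # across the whole lumen (with thick slices the no-slip rim stays dim and
  # no threshold can reach Dice 0.9 against the geometric cross-section)
  vessels <- list(
    vessel_spec("a", rbind(c(-8, 0, -10), c(-8, 0, 10)), 5, 200),
    vessel_spec("b", rbind(c(9, 0, -10), c(9, 0, 10)), 4, 150))
  cfg <- phantom_config(c(32, 32, 16), 1.2, vessels = vessels)
  ph <- build_phantom(cfg, 2)
  ph$magnitude[array(ph$labels <= 2L, dim(ph$magnitude))] <- 0
  acq <- acquisition_config(tr_ms = 5.3, flip_deg = 20, fov_mm = 38.4,
                            in_plane_resolution_mm = 1.2,
                            slice_thickness_mm = 1.5, shift_per_tr_mm = 0,
                            duration_s = 1, noise_sd = 0, seed = 1)
  c2d <- simulate_2d_pcmri(ph, list(z_mm = 0), acq, 2)
  mag <- abs(c2d$images[, , 1, ])
  crd <- phantom_grid(cfg)
  seed_a <- c(which.min(abs(crd$x + 8)), which.min(abs(crd$y)))
  lm <- lumen_mask_at(ph, 0, 1)
  # oracle mode returns the exact label cross-section
  m_or <- segment_lumen(mag, seed_a, labels = ph$labels[, , lm$zi])
  expect_identical(m_or, lm$mask)
  # threshold mode: Dice > 0.9 on the noiseless high-contrast tube
  m_th <- segment_lumen(mag, seed_a)
  dice <- 2 * sum(m_th & lm$mask) / (sum(m_th) + sum(lm$mask))
  expect_gt(dice, 0.9)
  # connectivity: only the component under the seed is returned
  lmb <- lumen_mask_at(ph, 0, 2)
  expect_equal(sum(m_th & lmb$mask), 0)
  expect_error(segment_lumen(mag, c(1, 1), labels = ph$labels[, , lm$zi]),
               "seed")
})

test_that("mean flow integrates velocity times pixel area", {
  v <- array(100, c(10, 10, 3))
  mask <- matrix(TRUE, 10, 10)
  m <- mean_flow(v, mask, pixel_area_mm2 = 1)
  expect_equal(m$mean_flow_ml_s, 10)             # 100 cm/s x 100 mm^2
  expect_equal(m$per_phase_flow_ml_s, rep(10, 3))
  expect_equal(mean_flow(array(0, c(4, 4, 2)), matrix(TRUE, 4, 4), 2)$mean_flow_ml_s, 0)
  expect_error(mean_flow(v, matrix(FALSE, 10, 10), 1), "empty")
  # parabolic tube against the analytic oracle
  cfg <- tube_phantom_config(grid = c(40, 40, 12), voxel = 1.2, radius = 6,
                             peak = 100)
  ph <- build_phantom(cfg, 2)
  lm <- lumen_mask_at(ph, 0)
  m2 <- mean_flow(ph$velocity[, , lm$zi, 3, ], lm$mask, 1.44)
  expect_equal(m2$mean_flow_ml_s, analytic_tube_flow(6, 100), tolerance = 0.05)
})

test_that("SNR and CNR use the Rayleigh-corrected air noise", {
  set.seed(42)
  n_air <- 12000
  sigma <- 0.05
  mag <- c(sqrt(rnorm(n_air, sd = sigma)^2 + rnorm(n_air, sd = sigma)^2),
           rep(1, 500), rep(0.2, 500))
  arr <- array(mag, c(length(mag), 1))
  air <- arr * 0 == 0 & seq_along(mag) <= n_air
  lum <- seq_along(mag) > n_air & seq_along(mag) <= n_air + 500
  lng <- seq_along(mag) > n_air + 500
  res <- snr_cnr(arr, array(lum), array(lng), array(air))
  # corrected air SD estimates the complex-channel sigma within 5%
  expect_equal(res$noise_sd, sigma, tolerance = 0.05)
  expect_equal(res$snr, 1 / res$noise_sd, tolerance = 1e-6)
  expect_equal(res$cnr, 0.8 / res$noise_sd, tolerance = 1e-6)
  # lung signal equal to lumen signal: CNR 0
  arr_eq <- arr
  arr_eq[lng] <- 1
  res2 <- snr_cnr(arr_eq, array(lum), array(lng), array(air))
  expect_equal(res2$cnr, 0)
  expect_error(snr_cnr(arr, array(lum), array(lum), array(air)), "disjoint")
  # noiseless: infinite flag, no division
  m0 <- array(c(rep(0, 100), rep(1, 10), rep(0.5, 10)), c(120, 1))
  r0 <- snr_cnr(m0, array(seq_len(120) > 100 & seq_len(120) <= 110),
                array(seq_len(120) > 110), array(seq_len(120) <= 100))
  expect_false(r0$finite)
  expect_identical(r0$snr, Inf)
})
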