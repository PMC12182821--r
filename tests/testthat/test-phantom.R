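test_that("laminar profile peaks at the centreline and vanishes at the wall", {
  cfg <- tube_phantom_config(grid = c(24, 24, 16), voxel = 1, radius = 6,
                             peak = 100)
  ph <- build_phantom(cfg, 2)
  crd <- phantom_grid(cfg)
  ic <- which.min(abs(crd$x))                    # centreline voxel (x = y = 0.5 off-centre)
  vz <- ph$velocity[, , 8, 3, 1]
  r2 <- outer(crd$x^2, crd$y^2, "+")
  expect_equal(max(vz), 100 * (1 - min(r2) / 36), tolerance = 1e-10)
  expect_true(all(vz[r2 > 36] == 0))             # no slip outside the lumen
  expect_equal(vz[r2 <= 36], 100 * (1 - r2[r2 <= 36] / 36), tolerance = 1e-10)
})

test_that("voxelised lumen flow matches the analytic pi R^2 v/2 within 3%", {
  # >= 4 voxels per radius: R = 6 mm at 1.2 mm voxels gives 5
  cfg <- tube_phantom_config(grid = c(40, 40, 16), voxel = 1.2, radius = 6,
                             peak = 100)
  ph <- build_phantom(cfg, 2)
  lm <- lumen_mask_at(ph, 0)
  q_vox <- sum(ph$velocity[, , lm$zi, 3, 1][lm$mask]) * 1.2^2 / 1000
  expect_equal(q_vox, analytic_tube_flow(6, 100), tolerance = 0.03)
})

test_that("bifurcation children carry the prescribed flow split", {
  wf <- waveform_spec("raised_cosine", 0.2, 0.4, 0.2)
  vessels <- list(
    vessel_spec("P", rbind(c(0, 0, -24), c(0, 0, 0)), 6, 90, waveform = wf),
    vessel_spec("L", rbind(c(0, 0, 0), c(-10, 0, 5), c(-10, 0, 24)), 4.6,
                waveform = NULL, branch_of = list(parent = "P", fraction = 0.6)),
    vessel_spec("R", rbind(c(0, 0, 0), c(10, 0, 5), c(10, 0, 24)), 4.6,
                waveform = NULL, branch_of = list(parent = "P", fraction = 0.4)))
  cfg <- phantom_config(c(40, 40, 40), 1.2, vessels = vessels)
  ph <- build_phantom(cfg, 4)
  crd <- phantom_grid(cfg)
  zi_p <- which.min(abs(crd$z + 10))
  zi_c <- which.min(abs(crd$z - 10))
  q <- function(zi, lab) sum(ph$velocity[, , zi, 3, 1][ph$labels[, , zi] == lab]) *
    1.44 / 1000
  qp <- q(zi_p, 3L); ql <- q(zi_c, 4L); qr <- q(zi_c, 5L)
  expect_equal(ql / qp, 0.6, tolerance = 0.03)
  expect_equal(qr / qp, 0.4, tolerance = 0.03)
  expect_equal(ql + qr, qp, tolerance = 0.03)
})

test_that("overlapping unrelated vessels with different velocities error", {
  vessels <- list(
    vessel_spec("a", rbind(c(0, 0, -10), c(0, 0, 10)), 5, 100),
    vessel_spec("b", rbind(c(-10, 0, 0), c(10, 0, 0)), 5, 50))
  cfg <- phantom_config(c(24, 24, 24), 1.2, vessels = vessels)
  expect_error(build_phantom(cfg, 2), "overlap.*inconsistent velocities")
})

test_that("phantom fields are periodic in cardiac phase", {
  wf <- waveform_spec("raised_cosine", 0.18, 0.4, 0.15)
  expect_equal(waveform_factor(wf, 0), waveform_factor(wf, 1))
  cfg <- tube_phantom_config(grid = c(16, 16, 12), voxel = 1.5, radius = 4,
                             peak = 80, waveform = wf)
  ph <- build_phantom(cfg, 6)
  at0 <- phantom_at_phase(ph, 0)
  at1 <- phantom_at_phase(ph, 1)
  expect_equal(at0$velocity, at1$velocity, tolerance = 1e-12)
  expect_equal(at0$magnitude, at1$magnitude, tolerance = 1e-12)
})

test_that("air carries no signal and velocity is confined to lumens", {
  cfg <- tube_phantom_config(grid = c(24, 24, 16), voxel = 1.2)
  ph <- build_phantom(cfg, 3)
  expect_true(all(ph$magnitude[array(ph$labels == 0L, dim(ph$magnitude))] == 0))
  spd <- sqrt(ph$velocity[, , , 1, 2]^2 + ph$velocity[, , , 2, 2]^2 +
                ph$velocity[, , , 3, 2]^2)
  expect_true(all(spd[ph$labels <= 2L] == 0))
  expect_true(all(ph$magnitude >= 0))
})

test_that("inflow signal spans the static and fully-replaced limits", {
  a <- 15 * pi / 180
  e1 <- exp(-7.5 / 1600)
  s_static <- sin(a) * (1 - e1) / (1 - cos(a) * e1)
  expect_equal(inflow_signal(0, 4, 7.5, 15, 1600), s_static)
  # full replacement: speed >= thickness/TR = 4 mm / 7.5 ms = 53.3 cm/s
  expect_equal(inflow_signal(4 / 7.5 * 100, 4, 7.5, 15, 1600), sin(a))
  expect_equal(inflow_signal(500, 4, 7.5, 15, 1600), sin(a))
  # 50% replacement sits at the midpoint of the two limits
  v_half <- 0.5 * 4 / 7.5 * 100
  expect_equal(inflow_signal(v_half, 4, 7.5, 15, 1600),
               (s_static + sin(a)) / 2)
})

test_that("inflow signal is non-decreasing in speed for varied sequences", {
  v <- seq(0, 200, by = 2)
  for (p in list(c(10, 5, 1200), c(20, 7.5, 1600), c(30, 12, 900))) {
    s <- inflow_signal(v, 4, p[2], p[1], p[3])
    expect_true(all(diff(s) >= -1e-14))
  }
})

test_that("trigger trains are exact without jitter and reproducible with it", {
  cfg <- tube_phantom_config()
  tt <- sample_triggers(cfg, 4000, seed = 5)
  expect_equal(tt$r_peak_times_ms, seq(0, 4000, by = 800))
  cfg$rr_jitter_frac <- 0.05
  t1 <- sample_triggers(cfg, 20000, seed = 9)
  t2 <- sample_triggers(cfg, 20000, seed = 9)
  expect_identical(t1$r_peak_times_ms, t2$r_peak_times_ms)
  dd <- diff(t1$r_peak_times_ms)
  expect_true(all(dd > 800 * (1 - 4 * 0.05) & dd < 800 * (1 + 4 * 0.05)))
})

test_that("sampled R-R jitter matches the generating dispersion", {
  cfg <- tube_phantom_config(jitter = 0.05)
  tt <- sample_triggers(cfg, 10000 * 800, seed = 3)
  dd <- diff(tt$r_peak_times_ms)
  expect_gt(length(dd), 9000)
  expect_equal(sd(dd), 0.05 * 800, tolerance = 0.15)
})
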