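#' Acquisition configuration
#'
#' Sequence parameters for the SWEEP spiral phase-contrast acquisition and for
#' the simulated fully sampled 2D Cartesian comparator. Scanner-scale defaults:
#' TE/TR 3.0/7.5 ms, flip 15 degrees, VENC 150 cm/s, 1.2 mm in-plane, 4 mm
#' slice, 0.005 mm/TR slice shift.
#'
#' @param tr_ms,te_ms repetition and echo time (ms).
#' @param flip_deg excitation flip angle (degrees).
#' @param venc_cm_s velocity encoding sensitivity (cm/s; speed mapped to phase
#'   pi).
#' @param slice_thickness_mm excited slice thickness / through-slice PSF FWHM
#'   (mm); must exceed the in-plane resolution.
#' @param in_plane_resolution_mm reconstructed in-plane voxel (mm).
#' @param fov_mm in-plane field of view (mm).
#' @param shift_per_tr_mm SWEEP slice advance per TR (mm).
#' @param duration_s total acquisition duration (s).
#' @param z_start_mm slice centre of the first TR; `NA` centres the sweep on
#'   z = 0.
#' @param noise_sd complex-noise SD per channel, relative to the static tissue
#'   signal level (>= 0).
#' @param n_arm_samples samples per spiral readout.
#' @param n_turns spiral revolutions per arm.
#' @param seed integer seed for the receiver noise.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(tr_ms = 7.5, te_ms = 3, flip_deg = 15,
                               venc_cm_s = 150, slice_thickness_mm = 4,
                               in_plane_resolution_mm = 1.2, fov_mm = 76.8,
                               shift_per_tr_mm = 0.005, duration_s = 300,
                               z_start_mm = NA, noise_sd = 0.02,
                               n_arm_samples = 128, n_turns = 1, seed = 1) {
  stopifnot(venc_cm_s > 0, slice_thickness_mm > in_plane_resolution_mm,
            noise_sd >= 0, tr_ms > 0, duration_s > 0, fov_mm > 0)
  structure(list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 venc_cm_s = venc_cm_s, slice_thickness_mm = slice_thickness_mm,
                 in_plane_resolution_mm = in_plane_resolution_mm,
                 fov_mm = fov_mm, shift_per_tr_mm = shift_per_tr_mm,
                 duration_s = duration_s, z_start_mm = z_start_mm,
                 noise_sd = noise_sd, n_arm_samples = n_arm_samples,
                 n_turns = n_turns, seed = seed),
            class = "acquisition_config")
}

#' Velocity-encoding phase
#'
#' Phase imparted by the bipolar velocity-encoding gradients: 0 for the
#' flow-compensated reference (encoding 0), and `pi * v_k / venc` for the
#' through-plane (encoding 1, slice axis z), in-plane x (encoding 2) and
#' in-plane y (encoding 3) directions. No wrapping is applied here; aliasing
#' emerges downstream from the complex-exponential signal representation.
#'
#' @param velocity numeric length-3 vector `(vx, vy, vz)` in cm/s, or an
#'   `n x 3` matrix.
#' @param encoding_index integer in `0:3` (order V_o, V_TP, V_X, V_Y).
#' @param venc_cm_s velocity encoding sensitivity (> 0).
#' @return phase in radians (vector of n).
#' @export
encode_phase <- function(velocity, encoding_index, venc_cm_s) {
  stopifnot(venc_cm_s > 0, encoding_index %in% 0:3)
  if (is.null(dim(velocity))) velocity <- matrix(velocity, ncol = 3)
  if (encoding_index == 0) return(rep(0, nrow(velocity)))
  comp <- c(3L, 1L, 2L)[encoding_index]   # V_TP -> z, V_X -> x, V_Y -> y
  pi * velocity[, comp] / venc_cm_s
}

# gaussian slice profile weights over slice z-coordinates, normalised to sum 1;
# returns indices and weights of the supported slab (|z - zc| <= 2.5 sigma)
slice_profile_weights <- function(z, center_mm, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  idx <- which(abs(z - center_mm) <= 2.5 * sigma)
  if (!length(idx)) return(list(idx = integer(), w = numeric()))
  w <- exp(-0.5 * ((z[idx] - center_mm) / sigma)^2)
  list(idx = idx, w = w / sum(w))
}

# complex transverse signal of a phantom slab at one cardiac phase and
# encoding: magnitude x inflow scale x exp(i (encoding phase + background
# phase)), collapsed along z with the slice profile. `bg` is the in-plane
# background phase map (radians), applied to velocity-sensitive encodings only.
slab_signal <- function(phantom, phase, zidx, zw, encoding_index, config, bg) {
  g <- dim(phantom$labels)
  nx <- g[1]; ny <- g[2]; nzi <- length(zidx)
  P <- phantom$n_phases
  u <- (phase %% 1) * P
  i0 <- (floor(u) %% P) + 1
  i1 <- (i0 %% P) + 1
  wt <- u - floor(u)

  mag <- (1 - wt) * phantom$magnitude[, , zidx, i0, drop = FALSE] +
    wt * phantom$magnitude[, , zidx, i1, drop = FALSE]
  vel <- (1 - wt) * phantom$velocity[, , zidx, , i0, drop = FALSE] +
    wt * phantom$velocity[, , zidx, , i1, drop = FALSE]
  dim(mag) <- c(nx, ny, nzi)
  dim(vel) <- c(nx, ny, nzi, 3)

  lum <- array(phantom$labels[, , zidx] > 2L, c(nx, ny, nzi))
  scale <- array(inflow_signal(0, config$slice_thickness_mm, config$tr_ms,
                               config$flip_deg,
                               phantom$config$t1_tissue_ms), c(nx, ny, nzi))
  if (any(lum))
    scale[lum] <- inflow_signal(abs(vel[, , , 3][lum]),
                                config$slice_thickness_mm, config$tr_ms,
                                config$flip_deg, phantom$config$t1_blood_ms)

  ph <- array(0, c(nx, ny, nzi))
  if (encoding_index > 0) {
    comp <- c(3L, 1L, 2L)[encoding_index]
    ph <- pi * vel[, , , comp] / config$venc_cm_s + array(bg, c(nx, ny, nzi))
    dim(ph) <- c(nx, ny, nzi)
  }
  sig <- mag * scale * exp(1i * ph)
  img <- matrix(0i, nx, ny)
  for (j in seq_len(nzi)) img <- img + zw[j] * sig[, , j]
  img
}

# static tissue signal level used as the reference for noise_sd
tissue_signal_level <- function(phantom, config)
  0.6 * inflow_signal(0, config$slice_thickness_mm, config$tr_ms,
                      config$flip_deg, phantom$config$t1_tissue_ms)

#' Simulate the SWEEP golden-angle spiral phase-contrast acquisition
#'
#' For every TR of the schedule: evaluate the phantom at the cardiac phase
#' given by the trigger train, weight voxels by a Gaussian slice profile
#' centred at the TR's slice position, apply inflow enhancement from the
#' through-plane speed, multiply by the complex exponential of the
#' velocity-encoding phase plus the background phase (velocity-sensitive
#' encodings only), sample the golden-angle-rotated spiral arm by exact
#' non-uniform Fourier evaluation, and add seeded complex Gaussian noise.
#'
#' @param phantom a [build_phantom()] object.
#' @param triggers a [sample_triggers()] object covering the acquisition.
#' @param config an [acquisition_config()].
#' @param schedule optional [build_schedule()]; built from `config` if `NULL`.
#' @param arm optional [design_spiral()]; built from `config` if `NULL`.
#' @param progress print progress every 2000 TRs.
#' @return object of class `kspace_set`: `data` (`n_tr x n_samples` complex
#'   matrix), `schedule`, `arm`, `triggers`, `config`.
#' @export
simulate_sweep <- function(phantom, triggers, config, schedule = NULL,
                           arm = NULL, progress = FALSE) {
  if (is.null(arm))
    arm <- design_spiral(config$fov_mm, config$in_plane_resolution_mm,
                         config$n_arm_samples, config$te_ms,
                         n_turns = config$n_turns)
  if (is.null(schedule)) {
    n_tr <- floor(config$duration_s * 1000 / config$tr_ms)
    z0 <- if (is.na(config$z_start_mm))
      -sweep_extent_mm(n_tr, config$shift_per_tr_mm) / 2 else config$z_start_mm
    schedule <- build_schedule(n_tr, config$tr_ms, z0, config$shift_per_tr_mm)
  }
  crd <- phantom_grid(phantom$config)
  half_vox <- phantom$voxel_size_mm / 2
  zr <- range(schedule$slice_z_mm)
  over <- max(0, crd$z[1] - half_vox - zr[1], zr[2] - crd$z[length(crd$z)] - half_vox)
  if (over > 0)
    stop(sprintf("SWEEP range [%.2f, %.2f] mm exceeds phantom z-extent by %.2f mm",
                 zr[1], zr[2], over))

  n_tr <- nrow(schedule)
  ns <- nrow(arm$k)
  bg <- background_phase_field(phantom$config$background_phase_coeffs,
                               crd$x, crd$y)
  phases <- assign_cardiac_phase(schedule$time_ms + config$te_ms, triggers)
  data <- matrix(0i, n_tr, ns)
  for (i in seq_len(n_tr)) {
    sp <- slice_profile_weights(crd$z, schedule$slice_z_mm[i],
                                config$slice_thickness_mm)
    if (!length(sp$idx)) next
    img <- slab_signal(phantom, phases[i], sp$idx, sp$w,
                       schedule$encoding_index[i], config, bg)
    kr <- rotate_arm(arm, schedule$rotation_deg[i])
    data[i, ] <- ndft_forward(img, kr, crd$x, crd$y)
    if (progress && i %% 2000 == 0)
      message("  TR ", i, " / ", n_tr)
  }
  if (config$noise_sd > 0) {
    sigma <- config$noise_sd * tissue_signal_level(phantom, config)
    noise <- local_seed(config$seed + 101L, {
      matrix(stats::rnorm(n_tr * ns, sd = sigma), n_tr, ns) +
        1i * matrix(stats::rnorm(n_tr * ns, sd = sigma), n_tr, ns)
    })
    data <- data + noise
  }
  structure(list(data = data, schedule = schedule, arm = arm,
                 triggers = triggers, config = config),
            class = "kspace_set")
}

#' Simulate the fully sampled 2D Cartesian phase-contrast comparator
#'
#' One axial slice, reconstructed per cardiac phase and velocity encoding with
#' the same signal physics as the SWEEP acquisition (Gaussian slice profile,
#' inflow enhancement, encoding phase, background phase) but fully sampled, so
#' the image is evaluated directly on the grid; seeded complex Gaussian noise
#' is added in the image domain (the unitary transform of white k-space noise).
#' Retrospective gating is emulated by averaging the complex signal over
#' `n_gate_subsamples` time points spanning each cardiac bin, as a segmented
#' gated acquisition does; brighter (faster, inflow-enhanced) moments within a
#' bin therefore dominate the bin average, exactly as in the SWEEP arm.
#'
#' @param phantom a [build_phantom()] object.
#' @param plane list with `z_mm`, the axial slice position.
#' @param config an [acquisition_config()] for the comparator (its own TR,
#'   flip, VENC, slice thickness).
#' @param n_phases cardiac phases to reconstruct.
#' @param n_gate_subsamples complex time-averaging points per cardiac bin.
#' @return object of class `pc_cine_2d`: `images` (`nx x ny x 4 x n_phases`
#'   complex), `z_mm`, `phases`, `config`.
#' @export
simulate_2d_pcmri <- function(phantom, plane, config, n_phases,
                              n_gate_subsamples = 5) {
  crd <- phantom_grid(phantom$config)
  half_vox <- phantom$voxel_size_mm / 2
  if (plane$z_mm < crd$z[1] - half_vox ||
      plane$z_mm > crd$z[length(crd$z)] + half_vox)
    stop(sprintf("comparator plane z = %.2f mm lies outside the phantom", plane$z_mm))
  sp <- slice_profile_weights(crd$z, plane$z_mm, config$slice_thickness_mm)
  if (!length(sp$idx)) stop("comparator plane does not intersect the phantom")
  bg <- background_phase_field(phantom$config$background_phase_coeffs,
                               crd$x, crd$y)
  nx <- length(crd$x); ny <- length(crd$y)
  phases <- (seq_len(n_phases) - 1) / n_phases
  K <- max(1L, n_gate_subsamples)
  images <- array(0i, c(nx, ny, 4, n_phases))
  for (p in seq_len(n_phases))
    for (e in 0:3) {
      acc <- matrix(0i, nx, ny)
      for (j in seq_len(K))
        acc <- acc + slab_signal(phantom,
                                 (p - 1 + (j - 0.5) / K) / n_phases,
                                 sp$idx, sp$w, e, config, bg)
      images[, , e + 1, p] <- acc / K
    }
  if (config$noise_sd > 0) {
    sigma <- config$noise_sd * tissue_signal_level(phantom, config)
    n <- length(images)
    images <- images + local_seed(config$seed + 202L, {
      array(stats::rnorm(n, sd = sigma) + 1i * stats::rnorm(n, sd = sigma),
            dim(images))
    })
  }
  structure(list(images = images, z_mm = plane$z_mm, phases = phases,
                 config = config), class = "pc_cine_2d")
}

#' Persist / load a k-space set
#'
#' Single-archive binary (RDS) holding the complex data, schedule, arm,
#' triggers and configuration, loadable by the CINE reconstruction without the
#' phantom.
#'
#' @param kspace a [simulate_sweep()] object.
#' @param path file path.
#' @return `path` (write) or the `kspace_set` (read).
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "kspace_set"))
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  k <- readRDS(path)
  stopifnot(inherits(k, "kspace_set"))
  k
}
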