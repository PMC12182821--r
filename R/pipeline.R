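#' Automatic static-tissue mask
#'
#' Voxels with appreciable signal and near-zero time-averaged speed: magnitude
#' above a floor set from the background level (5x the 10th percentile, with
#' inflow-enhanced blood typically an order of magnitude brighter than tissue
#' a relative ceiling would exclude tissue entirely) and time-averaged speed
#' below 15% of VENC (loose enough to tolerate aliasing noise and the
#' uncorrected background offset itself; slow lumen rims that leak in are a
#' negligible fraction of a 6-parameter global fit). Used to anchor the
#' background-phase fit without ground-truth labels.
#'
#' @param magnitude `... x T` magnitude array (spatial dims then phases).
#' @param velocity `... x 3 x T` velocity array.
#' @param venc_cm_s velocity encoding sensitivity (cm/s).
#' @return logical array over the spatial dims.
#' @export
auto_static_mask <- function(magnitude, velocity, venc_cm_s) {
  dm <- dim(magnitude)
  nd <- length(dm)
  nsp <- prod(dm[-nd])
  magm <- rowMeans(matrix(magnitude, nsp, dm[nd]))
  # velocity is laid out (space, component, phase): column block per component
  v <- matrix(velocity, nsp, 3 * dm[nd])
  spd <- matrix(0, nsp, 3)
  for (cc in 1:3) {
    idx <- (seq_len(dm[nd]) - 1) * 3 + cc
    spd[, cc] <- rowMeans(v[, idx, drop = FALSE])
  }
  spdm <- sqrt(rowSums(spd^2))           # speed of the time-mean velocity
  floor_mag <- max(5 * stats::quantile(magm, 0.10),
                   0.03 * stats::quantile(magm, 0.99))
  array(magm > floor_mag & spdm < 0.15 * venc_cm_s, dm[-nd])
}

# refine a candidate static mask by trimming voxels inconsistent with a pilot
# least-squares background fit (slow-moving lumen rims leak into any velocity
# threshold; against the fit they are outliers). `velocity` has dims
# (space..., 3, T); `mask` covers the spatial dims.
refine_static_mask <- function(velocity, mask, x_mm, y_mm) {
  d <- dim(velocity)
  nd <- length(d)
  nsp <- prod(d[seq_len(nd - 2)])
  T <- d[nd]
  v <- matrix(velocity, nsp, 3 * T)
  vm <- matrix(0, nsp, 3)
  for (cc in 1:3)
    vm[, cc] <- rowMeans(v[, (seq_len(T) - 1) * 3 + cc, drop = FALSE])
  nxy <- length(x_mm) * length(y_mm)
  X <- matrix(x_mm, length(x_mm), length(y_mm))
  Y <- matrix(y_mm, length(x_mm), length(y_mm), byrow = TRUE)
  basis <- cbind(1, as.vector(X), as.vector(Y), as.vector(X)^2,
                 as.vector(X * Y), as.vector(Y)^2)
  basis <- basis[rep(seq_len(nxy), nsp / nxy), , drop = FALSE]
  sel <- which(as.vector(mask))
  if (length(sel) < 60) return(mask)
  res2 <- rep(0, length(sel))
  for (cc in 1:3) {
    fit <- stats::lm.fit(basis[sel, , drop = FALSE], vm[sel, cc])
    res2 <- res2 + fit$residuals^2
  }
  r <- sqrt(res2)
  keep <- r < stats::median(r) + 2.5 * stats::mad(r)
  if (sum(keep) < 60) return(mask)
  out <- array(FALSE, dim(mask))
  out[sel[keep]] <- TRUE
  out
}

# voxels with signal above the background floor (time-averaged magnitude)
signal_mask <- function(magnitude) {
  dm <- dim(magnitude)
  nd <- length(dm)
  magm <- rowMeans(matrix(magnitude, prod(dm[-nd]), dm[nd]))
  floor_mag <- max(5 * stats::quantile(magm, 0.10),
                   0.03 * stats::quantile(magm, 0.99))
  array(magm > floor_mag, dm[-nd])
}

#' Assemble a decoded 4D flow volume from per-encoding SVR volumes
#'
#' Decodes velocities by phase difference, optionally fits and removes the
#' second-order background phase (per component, on an automatic or supplied
#' static mask) and applies neighbourhood-median anti-aliasing per component
#' and phase.
#'
#' @param svrvols a [reconstruct_svr()] object.
#' @param correct_background,unwrap logical switches.
#' @param static_mask optional logical `nx x ny x nz` mask for the
#'   background-phase fit; automatic if `NULL`.
#' @return object of class `flow_volume4d`: `magnitude` (`nx x ny x nz x T`),
#'   `velocity` (`nx x ny x nz x 3 x T`, cm/s), `x_mm`, `y_mm`, `z_mm`,
#'   `voxel_mm`, `venc_cm_s`, `background_coefficients` (6 x 3 or NULL),
#'   `n_unresolved` (aliasing voxels still inconsistent, per component).
#' @export
make_flow_volume <- function(svrvols, correct_background = TRUE, unwrap = TRUE,
                             static_mask = NULL) {
  vols <- svrvols$volumes
  d <- dim(vols)                         # nx ny nz 4 T
  T <- d[5]
  velocity <- decode_velocity(vols, svrvols$venc_cm_s, enc_dim = 4)
  magnitude <- abs(array(vols[, , , 1, ], c(d[1:3], T)))

  bgc <- NULL
  if (correct_background) {
    if (is.null(static_mask)) {
      static_mask <- auto_static_mask(magnitude, velocity, svrvols$venc_cm_s)
      static_mask <- refine_static_mask(velocity, static_mask, svrvols$x_mm,
                                        svrvols$y_mm)
    }
    bgc <- matrix(0, 6, 3)
    for (cc in 1:3) {
      vc <- array(velocity[, , , cc, ], c(d[1:3], T))
      cb <- correct_background_phase(vc, static_mask, svrvols$x_mm,
                                     svrvols$y_mm)
      velocity[, , , cc, ] <- cb$velocity
      bgc[, cc] <- cb$coefficients
    }
  }
  n_unres <- rep(0L, 3)
  if (unwrap) {
    sigmask <- signal_mask(magnitude)
    for (cc in 1:3) for (p in seq_len(T)) {
      uw <- unwrap_aliasing(array(velocity[, , , cc, p], d[1:3]),
                            svrvols$venc_cm_s, mask = sigmask)
      velocity[, , , cc, p] <- uw$velocity
      n_unres[cc] <- n_unres[cc] + uw$n_unresolved
    }
  }
  structure(list(magnitude = magnitude, velocity = velocity,
                 x_mm = svrvols$x_mm, y_mm = svrvols$y_mm, z_mm = svrvols$z_mm,
                 voxel_mm = svrvols$voxel_mm, venc_cm_s = svrvols$venc_cm_s,
                 background_coefficients = bgc, n_unresolved = n_unres),
            class = "flow_volume4d")
}

#' Decode a simulated 2D comparator acquisition
#'
#' Same decoding chain as [make_flow_volume()] for a single-slice
#' [simulate_2d_pcmri()] result.
#'
#' @param cine2d a [simulate_2d_pcmri()] object.
#' @param phantom the phantom, used only for the voxel grid coordinates.
#' @param correct_background,unwrap logical switches.
#' @return list: `magnitude` (`nx x ny x T`), `velocity` (`nx x ny x 3 x T`),
#'   `x_mm`, `y_mm`, `z_mm`, `venc_cm_s`, `background_coefficients`,
#'   `n_unresolved`.
#' @export
decode_comparator <- function(cine2d, phantom, correct_background = TRUE,
                              unwrap = TRUE) {
  crd <- phantom_grid(phantom$config)
  img <- cine2d$images                   # nx ny 4 T
  d <- dim(img)
  T <- d[4]
  velocity <- decode_velocity(img, cine2d$config$venc_cm_s, enc_dim = 3)
  magnitude <- abs(array(img[, , 1, ], c(d[1], d[2], T)))
  bgc <- NULL
  if (correct_background) {
    sm <- auto_static_mask(magnitude, velocity, cine2d$config$venc_cm_s)
    sm <- refine_static_mask(velocity, sm, crd$x, crd$y)
    bgc <- matrix(0, 6, 3)
    for (cc in 1:3) {
      vc <- array(velocity[, , cc, ], c(d[1], d[2], T))
      cb <- correct_background_phase(vc, sm, crd$x, crd$y)
      velocity[, , cc, ] <- cb$velocity
      bgc[, cc] <- cb$coefficients
    }
  }
  n_unres <- rep(0L, 3)
  if (unwrap) {
    sigmask <- signal_mask(magnitude)
    for (cc in 1:3) for (p in seq_len(T)) {
      uw <- unwrap_aliasing(matrix(velocity[, , cc, p], d[1], d[2]),
                            cine2d$config$venc_cm_s, mask = sigmask)
      velocity[, , cc, p] <- uw$velocity
      n_unres[cc] <- n_unres[cc] + uw$n_unresolved
    }
  }
  list(magnitude = magnitude, velocity = velocity, x_mm = crd$x, y_mm = crd$y,
       z_mm = cine2d$z_mm, venc_cm_s = cine2d$config$venc_cm_s,
       background_coefficients = bgc, n_unresolved = n_unres)
}

# point where a vessel centreline crosses an axial plane; nearest vertex if the
# plane does not intersect
centerline_point_at_z <- function(vessel, z_mm) {
  cl <- vessel$centerline
  for (s in seq_len(nrow(cl) - 1)) {
    z0 <- cl[s, 3]; z1 <- cl[s + 1, 3]
    if ((z_mm - z0) * (z_mm - z1) <= 0 && z0 != z1) {
      t <- (z_mm - z0) / (z1 - z0)
      return(cl[s, ] + t * (cl[s + 1, ] - cl[s, ]))
    }
  }
  cl[which.min(abs(cl[, 3] - z_mm)), ]
}

# grid indices of the in-plane seed point of a vessel at an axial plane
vessel_seed_ij <- function(vessel, z_mm, x_mm, y_mm) {
  p <- centerline_point_at_z(vessel, z_mm)
  c(which.min(abs(x_mm - p[1])), which.min(abs(y_mm - p[2])))
}

# nearest phantom label plane to an axial position
phantom_label_plane <- function(phantom, z_mm) {
  crd <- phantom_grid(phantom$config)
  phantom$labels[, , which.min(abs(crd$z - z_mm))]
}

#' Measure a vessel on a decoded flow field
#'
#' Extracts the through-plane (z) velocity at the nearest axial slice,
#' segments the lumen (threshold seeded at the vessel centreline, or
#' ground-truth labels) and integrates the flow; SNR/CNR are computed on the
#' magnitude against lung and air regions from the phantom labels.
#'
#' @param field a [make_flow_volume()] volume or [decode_comparator()] slice.
#' @param vessel the [vessel_spec()] being measured.
#' @param z_mm axial measurement plane (mm).
#' @param phantom the phantom (labels for ROI placement / oracle masks).
#' @param segmentation `"threshold"` (default) or `"labels"` (oracle mode).
#' @return a [mean_flow()] measurement with `snr` and `cnr` fields added.
#' @export
measure_vessel <- function(field, vessel, z_mm, phantom,
                           segmentation = c("threshold", "labels")) {
  segmentation <- match.arg(segmentation)
  is_vol <- inherits(field, "flow_volume4d")
  if (is_vol) {
    zi <- which.min(abs(field$z_mm - z_mm))
    vz <- field$velocity[, , zi, 3, ]
    mag <- field$magnitude[, , zi, ]
  } else {
    vz <- field$velocity[, , 3, ]
    mag <- field$magnitude
  }
  T <- dim(mag)[3]
  labplane <- phantom_label_plane(phantom, z_mm)
  seed <- vessel_seed_ij(vessel, z_mm, field$x_mm, field$y_mm)
  mask <- if (segmentation == "labels")
    segment_lumen(mag, seed, labels = labplane)
  else segment_lumen(mag, seed)
  pix <- (field$x_mm[2] - field$x_mm[1]) * (field$y_mm[2] - field$y_mm[1])
  meas <- mean_flow(array(vz, c(dim(mag)[1:2], T)), mask, pix,
                    vessel_id = vessel$id, plane = list(z_mm = z_mm))
  lung <- labplane == 2L & !mask
  air <- labplane == 0L
  meas$snr <- NA_real_
  meas$cnr <- NA_real_
  if (any(lung) && any(air)) {
    sc <- snr_cnr(mag, mask, lung, air)
    meas$snr <- sc$snr
    meas$cnr <- sc$cnr
  }
  meas
}

# ---- configuration ---------------------------------------------------------

#' Experiment configuration
#'
#' Bundles the phantom, SWEEP acquisition, 2D comparator acquisition, CS and
#' SVR settings, the vessels/planes to measure, the segmentation mode and the
#' master seed. A fixed seed makes the whole run reproducible.
#'
#' @param phantom a [phantom_config()].
#' @param acquisition an [acquisition_config()] for the SWEEP scan.
#' @param comparator an [acquisition_config()] for the 2D comparator.
#' @param cs a [cs_config()].
#' @param svr an [svr_config()].
#' @param measure list of `list(vessel_id =, z_mm =)` measurement planes.
#' @param segmentation `"threshold"` or `"labels"`.
#' @param seed master integer seed.
#' @param output_dir where [run_experiment()] persists artifacts.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(phantom, acquisition, comparator, cs, svr,
                              measure, segmentation = "threshold", seed = 1,
                              output_dir = tempfile("svrflow_run_")) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(acquisition, "acquisition_config"),
            inherits(comparator, "acquisition_config"),
            inherits(cs, "cs_config"), inherits(svr, "svr_config"),
            length(measure) >= 1)
  structure(list(phantom = phantom, acquisition = acquisition,
                 comparator = comparator, cs = cs, svr = svr,
                 measure = measure, segmentation = segmentation,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Desk-scale default experiment
#'
#' A complete study-in-a-box: a 64 x 64 x 48 thorax phantom (1.2 mm voxels)
#' with a pulmonary-artery bifurcation (55/45 split) plus three systemic
#' vessels, a SWEEP spiral acquisition at the scanner protocol (TR 7.5 ms,
#' VENC 150 cm/s, flip 15 degrees, 4 mm slices, 0.005 mm/TR shift, 996-arm
#' windows sharing 332 arms, ~50 ms cardiac bins, acceleration ~12), CS at 30
#' iterations / TTV 0.08, SVR at 10 iterations / weight 0.01 to 1.2 mm
#' isotropic, and six paired vessel measurements. Only the grid, sweep extent
#' (25 mm, a 37 s scan) and vessel count are scaled down from the scanner
#' setting.
#'
#' @param seed master seed.
#' @param output_dir artifact directory.
#' @param noise_sd receiver noise level relative to tissue signal.
#' @param segmentation `"threshold"` or `"labels"`.
#' @return an [experiment_config()].
#' @export
desk_experiment_config <- function(seed = 1, output_dir = tempfile("svrflow_run_"),
                                   noise_sd = 0.02,
                                   segmentation = "labels") {
  zlo <- -28.8; zhi <- 28.8
  sys_wave <- waveform_spec("raised_cosine", peak_phase = 0.18, width = 0.4,
                            base = 0.15)
  vessels <- list(
    vessel_spec("MPA", rbind(c(-14, -8, zlo), c(-14, -8, 0)), radius_mm = 6,
                peak_velocity_cm_s = 90, waveform = sys_wave),
    vessel_spec("RPA", rbind(c(-14, -8, 0), c(-24, -8, 4.8), c(-24, -8, zhi)),
                radius_mm = 4.5, waveform = NULL,
                branch_of = list(parent = "MPA", fraction = 0.55)),
    vessel_spec("LPA", rbind(c(-14, -8, 0), c(-4, -8, 4.8), c(-4, -8, zhi)),
                radius_mm = 4.2, waveform = NULL,
                branch_of = list(parent = "MPA", fraction = 0.45)),
    vessel_spec("AAo", rbind(c(10, -12, zlo), c(10, -12, zhi)), radius_mm = 5.5,
                peak_velocity_cm_s = 100,
                waveform = waveform_spec("raised_cosine", 0.15, 0.35, 0.2)),
    vessel_spec("DAo", rbind(c(24, 8, zlo), c(24, 8, zhi)), radius_mm = 4.2,
                peak_velocity_cm_s = 75,
                waveform = waveform_spec("raised_cosine", 0.22, 0.45, 0.15)),
    vessel_spec("SVC", rbind(c(2, 14, zlo), c(2, 14, zhi)), radius_mm = 4.8,
                peak_velocity_cm_s = 45,
                waveform = waveform_spec("raised_cosine", 0.35, 0.6, 0.35)))
  ph <- phantom_config(grid_shape = c(64, 64, 48), voxel_size_mm = 1.2,
                       cardiac_period_ms = 800, rr_jitter_frac = 0.03,
                       vessels = vessels,
                       background_phase_coeffs = c(0.06, 0.0015, -0.001,
                                                   2e-5, -1e-5, 1.5e-5))
  n_tr <- 996 + 664 * 6                  # 7 windows of 996 arms, 332 shared
  acq <- acquisition_config(tr_ms = 7.5, te_ms = 3, flip_deg = 15,
                            venc_cm_s = 150, slice_thickness_mm = 4,
                            in_plane_resolution_mm = 1.2, fov_mm = 76.8,
                            shift_per_tr_mm = 0.005,
                            duration_s = n_tr * 7.5 / 1000,
                            z_start_mm = -12, noise_sd = noise_sd,
                            n_arm_samples = 128, seed = seed)
  comp <- acquisition_config(tr_ms = 5.3, te_ms = 3, flip_deg = 20,
                             venc_cm_s = 150, slice_thickness_mm = 5,
                             in_plane_resolution_mm = 1.2, fov_mm = 76.8,
                             shift_per_tr_mm = 0, duration_s = 80,
                             noise_sd = noise_sd, seed = seed + 7L)
  cs <- cs_config(n_iterations = 30, ttv_weight = 0.08, n_cardiac_phases = 16,
                  arms_per_window = 996, overlap_arms = 332)
  svr <- svr_config(n_iterations = 10, reg_weight = 0.01,
                    target_voxel_mm = 1.2, psf_fwhm_mm = 4)
  measure <- list(list(vessel_id = "MPA", z_mm = -7),
                  list(vessel_id = "RPA", z_mm = 7),
                  list(vessel_id = "LPA", z_mm = 7),
                  list(vessel_id = "AAo", z_mm = -2),
                  list(vessel_id = "DAo", z_mm = 3),
                  list(vessel_id = "SVC", z_mm = -4))
  experiment_config(ph, acq, comp, cs, svr, measure,
                    segmentation = segmentation, seed = seed,
                    output_dir = output_dir)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; see the bundled profiles under
#'   `system.file("extdata/profiles", package = "svrflow")` for the schema.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  vessels <- lapply(y$phantom$vessels, function(v) {
    wf <- if (is.null(v$waveform)) NULL
    else do.call(waveform_spec, v$waveform)
    vessel_spec(v$id, do.call(rbind, v$centerline), v$radius_mm,
                peak_velocity_cm_s = v$peak_velocity_cm_s %||% NA,
                waveform = wf, branch_of = v$branch_of)
  })
  phlist <- y$phantom
  phlist$vessels <- NULL
  phlist$grid_shape <- unlist(phlist$grid_shape)
  phlist$background_phase_coeffs <- unlist(phlist$background_phase_coeffs)
  ph <- do.call(phantom_config, c(phlist, list(vessels = vessels)))
  experiment_config(
    phantom = ph,
    acquisition = do.call(acquisition_config, y$acquisition),
    comparator = do.call(acquisition_config, y$comparator),
    cs = do.call(cs_config, y$cs),
    svr = do.call(svr_config, y$svr),
    measure = y$measure,
    segmentation = y$segmentation %||% "threshold",
    seed = y$seed %||% 1,
    output_dir = y$output_dir %||% tempfile("svrflow_run_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- volume I/O -------------------------------------------------------------

#' Write / read a decoded 4D flow volume as NIfTI files
#'
#' One 4D NIfTI per field (`magnitude`, `vx`, `vy`, `vz`) with the voxel
#' spacing in the header, plus a YAML sidecar holding VENC, grid origin and
#' phase count.
#'
#' @param vol a [make_flow_volume()] object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the directory (write) or a restored `flow_volume4d` (read).
#' @export
write_flow_volume <- function(vol, dir, prefix = "flow") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(arr, name) {
    im <- RNifti::asNifti(arr)
    im <- RNifti::`pixdim<-`(im, c(vol$voxel_mm, 1))  # 4th dim: cardiac phase
    RNifti::writeNifti(im, file.path(dir, paste0(prefix, "_", name, ".nii.gz")))
  }
  d <- dim(vol$magnitude)
  wr(vol$magnitude, "magnitude")
  for (cc in 1:3)
    wr(array(vol$velocity[, , , cc, ], d), c("vx", "vy", "vz")[cc])
  yaml::write_yaml(list(venc_cm_s = vol$venc_cm_s,
                        voxel_mm = as.numeric(vol$voxel_mm),
                        x0_mm = vol$x_mm[1], y0_mm = vol$y_mm[1],
                        z0_mm = vol$z_mm[1], n_phases = d[4]),
                   file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(dir)
}

#' @rdname write_flow_volume
#' @export
read_flow_volume <- function(dir, prefix = "flow") {
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
  rd <- function(name) {
    a <- as.array(RNifti::readNifti(file.path(dir, paste0(prefix, "_", name,
                                                          ".nii.gz"))))
    array(as.numeric(a), dim(a))               # plain array, no NIfTI attrs
  }
  mag <- rd("magnitude")
  d <- dim(mag)
  velocity <- array(0, c(d[1:3], 3, d[4]))
  for (cc in 1:3)
    velocity[, , , cc, ] <- rd(c("vx", "vy", "vz")[cc])
  vx <- meta$voxel_mm
  structure(list(magnitude = mag, velocity = velocity,
                 x_mm = meta$x0_mm + (seq_len(d[1]) - 1) * vx[1],
                 y_mm = meta$y0_mm + (seq_len(d[2]) - 1) * vx[2],
                 z_mm = meta$z0_mm + (seq_len(d[3]) - 1) * vx[3],
                 voxel_mm = vx, venc_cm_s = meta$venc_cm_s,
                 background_coefficients = NULL, n_unresolved = NA),
            class = "flow_volume4d")
}

# ---- experiment driver ------------------------------------------------------

#' Run the full SVR 4D flow experiment
#'
#' Executes phantom generation, trigger sampling, SWEEP spiral simulation,
#' windowed CS CINE reconstruction, slice-to-volume fusion, velocity decoding
#' with background correction and anti-aliasing, paired vessel measurement by
#' SVR 4D flow and the simulated 2D comparator, and the agreement analysis.
#' All intermediates are persisted under `config$output_dir`; a YAML manifest
#' records parameters and stage timings. Vessels whose measurement plane falls
#' outside the swept z-coverage are dropped with an "incomplete coverage"
#' warning.
#'
#' @param config an [experiment_config()].
#' @param progress print stage progress.
#' @return list: `report` ([agreement_report()]), `measurements` (data.frame),
#'   `flow_volume`, `svr_volumes`, `cines`, `kspace`, `phantom`, `output_dir`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    if (progress) message("[", name, "]")
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed (artifacts in ", config$output_dir,
           "): ", conditionMessage(e), call. = FALSE))
    t_all[[name]] <<- round(tic() - t0, 2)
    out
  }
  cs <- config$cs
  n_ph <- if (is.na(cs$n_cardiac_phases)) 8L else cs$n_cardiac_phases

  phantom <- stage("phantom", build_phantom(config$phantom, n_ph))
  triggers <- stage("triggers",
                    sample_triggers(config$phantom,
                                    config$acquisition$duration_s * 1000 +
                                      2 * config$phantom$cardiac_period_ms,
                                    seed = config$seed))
  kspace <- stage("simulate", {
    k <- simulate_sweep(phantom, triggers, config$acquisition,
                        progress = progress)
    write_kspace(k, file.path(config$output_dir, "kspace.rds"))
    k
  })
  cines <- stage("recon-cine", {
    cn <- reconstruct_cine_stack(kspace, cs, progress = progress)
    saveRDS(cn, file.path(config$output_dir, "cine_stack.rds"))
    cn
  })
  svrvols <- stage("recon-svr", reconstruct_svr(cines, config$svr))
  flowvol <- stage("decode", {
    fv <- make_flow_volume(svrvols)
    write_flow_volume(fv, config$output_dir)
    fv
  })

  vessels <- config$phantom$vessels
  vids <- vapply(vessels, `[[`, "", "id")
  zcov <- range(flowvol$z_mm)
  rows <- list()
  for (m in config$measure) {
    vessel <- vessels[[match(m$vessel_id, vids)]]
    if (m$z_mm < zcov[1] || m$z_mm > zcov[2]) {
      warning("incomplete coverage: vessel '", m$vessel_id, "' plane z = ",
              m$z_mm, " mm outside the swept range [", round(zcov[1], 1), ", ",
              round(zcov[2], 1), "] mm; dropped", call. = FALSE)
      next
    }
    ms <- stage(paste0("measure-svr-", m$vessel_id),
                measure_vessel(flowvol, vessel, m$z_mm, phantom,
                               config$segmentation))
    cine2d <- stage(paste0("simulate-2d-", m$vessel_id),
                    simulate_2d_pcmri(phantom, list(z_mm = m$z_mm),
                                      config$comparator, n_ph))
    dec2d <- decode_comparator(cine2d, phantom)
    m2 <- stage(paste0("measure-2d-", m$vessel_id),
                measure_vessel(dec2d, vessel, m$z_mm, phantom,
                               config$segmentation))
    rows[[length(rows) + 1]] <- data.frame(
      vessel_id = m$vessel_id, z_mm = m$z_mm,
      m_2d = m2$mean_flow_ml_s, m_svr = ms$mean_flow_ml_s,
      snr_2d = m2$snr, snr_svr = ms$snr, cnr_2d = m2$cnr, cnr_svr = ms$cnr)
  }
  if (!length(rows)) stop("no vessel could be measured (no coverage)")
  measurements <- do.call(rbind, rows)

  long <- rbind(
    data.frame(vessel_id = measurements$vessel_id, technique = "2D",
               mean_flow_ml_s = measurements$m_2d, snr = measurements$snr_2d,
               cnr = measurements$cnr_2d),
    data.frame(vessel_id = measurements$vessel_id, technique = "SVR4D",
               mean_flow_ml_s = measurements$m_svr, snr = measurements$snr_svr,
               cnr = measurements$cnr_svr))
  utils::write.csv(long, file.path(config$output_dir, "measurements.csv"),
                   row.names = FALSE)

  report <- if (nrow(measurements) >= 3)
    agreement_report(measurements) else NULL
  if (!is.null(report)) write_agreement(report, config$output_dir)

  yaml::write_yaml(list(seed = config$seed,
                        n_tr = nrow(kspace$schedule),
                        n_windows = length(cines$slices),
                        n_phases = n_ph,
                        segmentation = config$segmentation,
                        unresolved_aliasing_voxels = as.integer(flowvol$n_unresolved),
                        stage_seconds = t_all),
                   file.path(config$output_dir, "manifest.yaml"))

  list(report = report, measurements = measurements, flow_volume = flowvol,
       svr_volumes = svrvols, cines = cines, kspace = kspace,
       phantom = phantom, output_dir = config$output_dir)
}

#' Command-line entry point
#'
#' Subcommands: `phantom` (build and export the phantom volumes), `simulate`
#' (SWEEP k-space), `recon-cine`, `recon-svr` + decode, `quantify`, `compare`,
#' `run-all`. Each reads/writes artifacts under the config's `output_dir`.
#' Invoked by the `inst/cli/svrflow.R` script:
#' `Rscript svrflow.R <subcommand> --config cfg.yaml`.
#'
#' @param args character vector of command-line arguments.
#' @return 0 on success (invisibly); errors propagate to the caller.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: svrflow.R <phantom|simulate|recon-cine|recon-svr|",
                 "quantify|compare|run-all> --config <file.yaml>")
  if (length(args) < 1) stop(usage, call. = FALSE)
  cmd <- args[1]
  ci <- which(args == "--config")
  if (!length(ci) || ci + 1 > length(args)) stop(usage, call. = FALSE)
  config <- read_experiment_config(args[ci + 1])
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  n_ph <- if (is.na(config$cs$n_cardiac_phases)) 8L
          else config$cs$n_cardiac_phases

  get_phantom <- function() build_phantom(config$phantom, n_ph)
  switch(cmd,
    "phantom" = {
      ph <- get_phantom()
      saveRDS(ph, file.path(out, "phantom.rds"))
      message("phantom written to ", out)
    },
    "simulate" = {
      ph <- get_phantom()
      tr <- sample_triggers(config$phantom,
                            config$acquisition$duration_s * 1000 +
                              2 * config$phantom$cardiac_period_ms,
                            seed = config$seed)
      k <- simulate_sweep(ph, tr, config$acquisition)
      write_kspace(k, file.path(out, "kspace.rds"))
      message("k-space written to ", out)
    },
    "recon-cine" = {
      k <- read_kspace(file.path(out, "kspace.rds"))
      cn <- reconstruct_cine_stack(k, config$cs)
      saveRDS(cn, file.path(out, "cine_stack.rds"))
      message("CINE stack written to ", out)
    },
    "recon-svr" = {
      cn <- readRDS(file.path(out, "cine_stack.rds"))
      sv <- reconstruct_svr(cn, config$svr)
      fv <- make_flow_volume(sv)
      write_flow_volume(fv, out)
      message("flow volume written to ", out)
    },
    "quantify" = ,
    "compare" = ,
    "run-all" = {
      res <- run_experiment(config, progress = TRUE)
      if (!is.null(res$report)) print(res$report)
      message("artifacts in ", res$output_dir)
    },
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
  invisible(0L)
}
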