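#' Periodic vessel waveform
#'
#' Velocity scale factor as a function of cardiac phase in `[0, 1)`. Two
#' families: `"steady"` (factor identically 1) and `"raised_cosine"`, a
#' raised-cosine systolic pulse of given width centred at `peak_phase` on top
#' of a diastolic `base` level, normalised so the systolic peak is 1.
#'
#' @param name `"steady"` or `"raised_cosine"`.
#' @param peak_phase cardiac phase of peak systole, in `[0, 1)`.
#' @param width full width of the systolic pulse in phase units, in `(0, 1]`.
#' @param base diastolic factor, in `(0, 1]`.
#' @return object of class `waveform_spec`.
#' @export
waveform_spec <- function(name = c("raised_cosine", "steady"),
                          peak_phase = 0.18, width = 0.4, base = 0.15) {
  name <- match.arg(name)
  if (name == "raised_cosine")
    stopifnot(peak_phase >= 0, peak_phase < 1, width > 0, width <= 1,
              base > 0, base <= 1)
  structure(list(name = name, peak_phase = peak_phase, width = width,
                 base = base), class = "waveform_spec")
}

#' Evaluate a waveform at cardiac phases
#' @param wf a [waveform_spec()].
#' @param phase numeric vector of cardiac phases (any real; interpreted mod 1).
#' @return velocity scale factors, same length as `phase`; in `[base, 1]`.
#' @export
waveform_factor <- function(wf, phase) {
  if (wf$name == "steady") return(rep(1, length(phase)))
  d <- (phase - wf$peak_phase) %% 1
  d <- ifelse(d > 0.5, d - 1, d)            # cyclic distance in [-0.5, 0.5)
  f <- rep(wf$base, length(phase))
  inside <- abs(d) < wf$width / 2
  f[inside] <- wf$base + (1 - wf$base) * 0.5 * (1 + cos(2 * pi * d[inside] / wf$width))
  f
}

#' Cycle-mean of a waveform factor
#' @param wf a [waveform_spec()].
#' @param n quadrature points over one cycle.
#' @return mean factor over the cardiac cycle.
#' @export
waveform_mean <- function(wf, n = 4096) mean(waveform_factor(wf, (seq_len(n) - 1) / n))

#' Vessel specification
#'
#' A tubular vessel defined by a centreline polyline, lumen radius and a
#' laminar (parabolic) velocity profile whose centreline peak is
#' `peak_velocity_cm_s`, modulated over the cardiac cycle by `waveform`.
#' A child vessel declares `branch_of = list(parent = <id>, fraction = f)`;
#' its peak velocity is then derived from the parent so that the child carries
#' exactly the fraction `f` of the parent's flow, and it inherits the parent's
#' waveform unless one is given.
#'
#' @param id character vessel identifier.
#' @param centerline `n x 3` matrix of points (mm), n >= 2.
#' @param radius_mm lumen radius (mm).
#' @param peak_velocity_cm_s systolic centreline speed (cm/s); ignored (derived)
#'   for branch children.
#' @param waveform a [waveform_spec()] or `NULL` (steady; children inherit).
#' @param branch_of `NULL` or `list(parent =, fraction =)`.
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(id, centerline, radius_mm, peak_velocity_cm_s = NA,
                        waveform = waveform_spec("steady"), branch_of = NULL) {
  centerline <- as.matrix(centerline)
  stopifnot(is.character(id), ncol(centerline) == 3, nrow(centerline) >= 2,
            radius_mm > 0)
  if (is.null(branch_of)) stopifnot(is.finite(peak_velocity_cm_s))
  structure(list(id = id, centerline = centerline, radius_mm = radius_mm,
                 peak_velocity_cm_s = peak_velocity_cm_s, waveform = waveform,
                 branch_of = branch_of), class = "vessel_spec")
}

#' Phantom configuration
#'
#' Geometry and physiology of the digital thorax phantom: grid, isotropic voxel
#' size, cardiac period and R-R variability, vessels, blood/tissue T1 and the
#' coefficients of a second-order in-plane background phase field
#' `b1 + b2*x + b3*y + b4*x^2 + b5*x*y + b6*y^2` (radians; x, y in mm from the
#' field-of-view centre) applied to the velocity-sensitive encodings.
#'
#' @param grid_shape integer vector of 3 (all >= 8).
#' @param voxel_size_mm isotropic voxel size (> 0).
#' @param cardiac_period_ms mean R-R interval (> 0).
#' @param rr_jitter_frac fractional SD of R-R intervals, in `[0, 0.2]`.
#' @param vessels list of [vessel_spec()].
#' @param t1_blood_ms,t1_tissue_ms longitudinal relaxation times (ms).
#' @param background_phase_coeffs numeric length 6 (radians; see above).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape, voxel_size_mm, cardiac_period_ms = 800,
                           rr_jitter_frac = 0.03, vessels = list(),
                           t1_blood_ms = 1600, t1_tissue_ms = 900,
                           background_phase_coeffs = rep(0, 6)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8), voxel_size_mm > 0,
            cardiac_period_ms > 0, rr_jitter_frac >= 0, rr_jitter_frac <= 0.2,
            length(background_phase_coeffs) == 6,
            t1_blood_ms > 0, t1_tissue_ms > 0)
  for (v in vessels) {
    stopifnot(inherits(v, "vessel_spec"))
    if (v$radius_mm < 2 * voxel_size_mm)
      stop("vessel '", v$id, "': radius must be >= 2 voxel sizes")
  }
  # children of one parent must split all of its flow
  parents <- vapply(vessels, function(v)
    if (is.null(v$branch_of)) NA_character_ else v$branch_of$parent, "")
  for (p in unique(stats::na.omit(parents))) {
    fr <- sum(vapply(vessels[which(parents == p)],
                     function(v) v$branch_of$fraction, 0))
    if (abs(fr - 1) > 1e-8)
      stop("flow split fractions of children of '", p, "' sum to ", fr,
           ", not 1")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 cardiac_period_ms = cardiac_period_ms,
                 rr_jitter_frac = rr_jitter_frac, vessels = vessels,
                 t1_blood_ms = t1_blood_ms, t1_tissue_ms = t1_tissue_ms,
                 background_phase_coeffs = background_phase_coeffs),
            class = "phantom_config")
}

# centred voxel coordinates along one axis (mm)
axis_coords <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

#' Voxel-centre coordinates of a phantom grid
#' @param config a [phantom_config()].
#' @return list of numeric vectors `x`, `y`, `z` (mm, centred on the FOV).
#' @export
phantom_grid <- function(config) {
  list(x = axis_coords(config$grid_shape[1], config$voxel_size_mm),
       y = axis_coords(config$grid_shape[2], config$voxel_size_mm),
       z = axis_coords(config$grid_shape[3], config$voxel_size_mm))
}

# background phase field over an in-plane grid (radians)
background_phase_field <- function(coeffs, x, y) {
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  coeffs[1] + coeffs[2] * X + coeffs[3] * Y +
    coeffs[4] * X^2 + coeffs[5] * X * Y + coeffs[6] * Y^2
}

# follow branch_of chain to the root vessel id
vessel_root <- function(vessels, id) {
  ids <- vapply(vessels, `[[`, "", "id")
  repeat {
    v <- vessels[[match(id, ids)]]
    if (is.null(v$branch_of)) return(id)
    id <- v$branch_of$parent
  }
}

# effective peak centreline velocity, deriving children from parent flow split
effective_peak_velocity <- function(vessels, id) {
  ids <- vapply(vessels, `[[`, "", "id")
  v <- vessels[[match(id, ids)]]
  if (is.null(v$branch_of)) return(v$peak_velocity_cm_s)
  p <- vessels[[match(v$branch_of$parent, ids)]]
  vp <- effective_peak_velocity(vessels, p$id)
  # Q = pi R^2 v/2 (parabolic); child carries fraction f of parent flow
  v$branch_of$fraction * vp * (p$radius_mm / v$radius_mm)^2
}

# inherited waveform (children default to the parent's)
effective_waveform <- function(vessels, id) {
  ids <- vapply(vessels, `[[`, "", "id")
  v <- vessels[[match(id, ids)]]
  if (!is.null(v$waveform)) return(v$waveform)
  if (is.null(v$branch_of)) return(waveform_spec("steady"))
  effective_waveform(vessels, v$branch_of$parent)
}

#' Analytic mean flow of a laminar tube
#'
#' For a parabolic (Poiseuille) profile with centreline peak speed `v_c` the
#' lumen-integrated flow is `pi R^2 v_c / 2`; the cycle mean scales by the
#' waveform mean. Returned in mL/s (`cm/s * mm^2 / 1000`).
#'
#' @param radius_mm lumen radius (mm).
#' @param peak_velocity_cm_s centreline peak speed (cm/s).
#' @param waveform optional [waveform_spec()]; `NULL` means steady.
#' @return mean flow over the cardiac cycle, mL/s.
#' @export
analytic_tube_flow <- function(radius_mm, peak_velocity_cm_s, waveform = NULL) {
  wmean <- if (is.null(waveform)) 1 else waveform_mean(waveform)
  pi * radius_mm^2 * peak_velocity_cm_s / 2 * wmean / 1000
}

#' Build the dynamic flow phantom
#'
#' Rasterises vessels (parabolic axial velocity profile, no-slip walls) into a
#' thorax-like scene: an elliptical tissue body, two low-signal lung regions,
#' air outside. Velocities are zero outside lumens; air has zero magnitude.
#' Cardiac phases are uniform in `[0, 1)`; the field is periodic (phase 1 wraps
#' to phase 0).
#'
#' @param config a [phantom_config()].
#' @param n_phases number of cardiac phases (>= 2).
#' @return object of class `flow_phantom`: `magnitude` (`x,y,z,phase` array,
#'   arbitrary units), `velocity` (`x,y,z,3,phase` array, cm/s, component order
#'   x/y/z), `labels` (`x,y,z` integer array: 0 air, 1 tissue, 2 lung,
#'   `2 + i` lumen of vessel i), `voxel_size_mm`, `phases`, `config`.
#' @export
build_phantom <- function(config, n_phases) {
  stopifnot(inherits(config, "phantom_config"), n_phases >= 2)
  g <- config$grid_shape
  crd <- phantom_grid(config)
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  X <- array(crd$x, g)
  Y <- array(rep(crd$y, each = nx), g)
  Z <- array(rep(crd$z, each = nx * ny), g)

  fov <- g * config$voxel_size_mm
  labels <- array(0L, g)
  body <- (X / (0.45 * fov[1]))^2 + (Y / (0.45 * fov[2]))^2 <= 1
  labels[body] <- 1L
  for (sx in c(-1, 1)) {
    lung <- ((X - sx * 0.24 * fov[1]) / (0.14 * fov[1]))^2 +
      ((Y - 0.08 * fov[2]) / (0.26 * fov[2]))^2 <= 1
    labels[lung & body] <- 2L
  }

  vessels <- config$vessels
  ids <- vapply(vessels, `[[`, "", "id")
  vel_base <- array(0, c(g, 3))            # velocity at waveform factor 1
  owner <- array(0L, g)                    # claiming vessel index
  n_vox <- prod(g)
  P <- cbind(as.vector(X), as.vector(Y), as.vector(Z))

  for (vi in seq_along(vessels)) {
    v <- vessels[[vi]]
    vpk <- effective_peak_velocity(vessels, v$id)
    cl <- v$centerline
    best_d2 <- rep(Inf, n_vox)
    best_seg <- rep(0L, n_vox)
    for (s in seq_len(nrow(cl) - 1)) {
      p0 <- cl[s, ]; d <- cl[s + 1, ] - p0
      len2 <- sum(d^2)
      if (len2 == 0) next
      t <- pmin(1, pmax(0, ((P[, 1] - p0[1]) * d[1] + (P[, 2] - p0[2]) * d[2] +
                              (P[, 3] - p0[3]) * d[3]) / len2))
      d2 <- (P[, 1] - (p0[1] + t * d[1]))^2 + (P[, 2] - (p0[2] + t * d[2]))^2 +
        (P[, 3] - (p0[3] + t * d[3]))^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_seg[upd] <- s
    }
    inl <- which(best_d2 <= v$radius_mm^2)
    if (!length(inl)) next
    prof <- vpk * (1 - best_d2[inl] / v$radius_mm^2)
    tangents <- cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]
    tn <- tangents / sqrt(rowSums(tangents^2))
    vvec <- tn[best_seg[inl], , drop = FALSE] * prof

    clash <- inl[owner[inl] != 0L]
    if (length(clash)) {
      other <- unique(owner[clash])
      for (o in other) {
        same_family <- vessel_root(vessels, ids[o]) == vessel_root(vessels, v$id)
        if (!same_family) {
          sel <- clash[owner[clash] == o]
          old <- cbind(vel_base[sel], vel_base[sel + n_vox],
                       vel_base[sel + 2 * n_vox])
          new <- vvec[match(sel, inl), , drop = FALSE]
          if (max(abs(old - new)) > 0.1)
            stop("vessels '", ids[o], "' and '", v$id,
                 "' overlap with inconsistent velocities")
        }
      }
      keep <- owner[inl] == 0L           # first claim wins within a family
      inl <- inl[keep]; vvec <- vvec[keep, , drop = FALSE]
    }
    if (!length(inl)) next
    owner[inl] <- vi
    vel_base[inl] <- vvec[, 1]
    vel_base[inl + n_vox] <- vvec[, 2]
    vel_base[inl + 2 * n_vox] <- vvec[, 3]
    labels[inl] <- 2L + vi
  }

  mag_levels <- c(0, 0.6, 0.09)           # air, tissue, lung
  mag3 <- array(mag_levels[pmin(labels, 2L) + 1L], g)
  mag3[labels > 2L] <- 1                  # blood

  phases <- (seq_len(n_phases) - 1) / n_phases
  scale_tab <- matrix(1, nrow = max(1, length(vessels)), ncol = n_phases)
  for (vi in seq_along(vessels))
    scale_tab[vi, ] <- waveform_factor(effective_waveform(vessels, ids[vi]),
                                       phases)
  velocity <- array(0, c(g, 3, n_phases))
  scal <- array(0, g)
  for (p in seq_len(n_phases)) {
    if (length(vessels)) {
      scal[] <- 0
      nz0 <- owner != 0L
      scal[nz0] <- scale_tab[owner[nz0], p]
      for (cc in 1:3)
        velocity[, , , cc, p] <- vel_base[, , , cc] * scal
    }
  }
  magnitude <- array(mag3, c(g, n_phases))

  structure(list(magnitude = magnitude, velocity = velocity, labels = labels,
                 voxel_size_mm = config$voxel_size_mm, phases = phases,
                 n_phases = n_phases, config = config),
            class = "flow_phantom")
}

#' Inflow (time-of-flight) signal enhancement
#'
#' Steady-state spoiled gradient-echo signal for partially replaced spins.
#' Static spins give `sin(a) (1 - E1) / (1 - cos(a) E1)` with
#' `E1 = exp(-TR/T1)`; spins fully replaced each TR give the fully relaxed
#' `sin(a)`. The signal is linearly interpolated between the two with the
#' fraction of the slice replaced per TR, `min(1, speed * TR / thickness)`, so
#' it is non-decreasing in speed.
#'
#' @param through_plane_speed_cm_s speed of blood through the slice (cm/s, >= 0);
#'   vectorised.
#' @param slice_thickness_mm excited slice thickness (mm).
#' @param tr_ms repetition time (ms).
#' @param flip_deg excitation flip angle (degrees).
#' @param t1_ms longitudinal relaxation time (ms).
#' @return relative signal scale in `[0, sin(flip)]`.
#' @export
inflow_signal <- function(through_plane_speed_cm_s, slice_thickness_mm, tr_ms,
                          flip_deg, t1_ms) {
  stopifnot(slice_thickness_mm > 0, tr_ms > 0, flip_deg > 0, t1_ms > 0,
            all(through_plane_speed_cm_s >= 0))
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  s_static <- sin(a) * (1 - e1) / (1 - cos(a) * e1)
  # speed in cm/s -> mm per TR: * 0.01 mm/ms * tr_ms
  frac <- pmin(1, through_plane_speed_cm_s * 0.01 * tr_ms / slice_thickness_mm)
  s_static + frac * (sin(a) - s_static)
}

#' Sample a quasi-periodic cardiac trigger train
#'
#' R-peak times with independent Gaussian R-R jitter (SD =
#' `rr_jitter_frac * cardiac_period_ms`, truncated at +/- 3.9 SD so successive
#' differences stay within `period * (1 +/- 4 * rr_jitter_frac)`), starting at
#' 0 and extended until the full acquisition duration is covered.
#'
#' @param config a [phantom_config()].
#' @param duration_ms acquisition duration (> 2 cardiac periods).
#' @param seed integer seed; fixed seed gives an identical train.
#' @return object of class `trigger_train`: list with `r_peak_times_ms`.
#' @export
sample_triggers <- function(config, duration_ms, seed = 1) {
  stopifnot(duration_ms > 2 * config$cardiac_period_ms)
  period <- config$cardiac_period_ms
  jit <- config$rr_jitter_frac
  n_guess <- ceiling(duration_ms / period * 1.5) + 8
  intervals <- local_seed(seed, {
    z <- pmin(3.9, pmax(-3.9, stats::rnorm(n_guess)))
    period * (1 + jit * z)
  })
  peaks <- cumsum(c(0, intervals))
  stopifnot(peaks[length(peaks)] >= duration_ms)
  peaks <- peaks[seq_len(which(peaks >= duration_ms)[1])]
  structure(list(r_peak_times_ms = peaks, cardiac_period_ms = period,
                 rr_jitter_frac = jit), class = "trigger_train")
}

# evaluate an expression under a temporary RNG seed, restoring global state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Cyclic linear interpolation of phantom fields at an arbitrary cardiac phase
#'
#' @param phantom a [build_phantom()] object.
#' @param phase cardiac phase in `[0, 1)` (scalar).
#' @return list with `magnitude` (`x,y,z`) and `velocity` (`x,y,z,3`) arrays.
#' @export
phantom_at_phase <- function(phantom, phase) {
  P <- phantom$n_phases
  u <- (phase %% 1) * P
  i0 <- floor(u) %% P
  i1 <- (i0 + 1) %% P
  w <- u - floor(u)
  g <- dim(phantom$labels)
  m <- (1 - w) * phantom$magnitude[, , , i0 + 1] +
    w * phantom$magnitude[, , , i1 + 1]
  v <- (1 - w) * phantom$velocity[, , , , i0 + 1] +
    w * phantom$velocity[, , , , i1 + 1]
  list(magnitude = array(m, g), velocity = array(v, c(g, 3)))
}
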