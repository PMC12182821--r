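#' Decode velocities from the four encoded complex fields
#'
#' Phase-difference decoding: `v_k = venc * Arg(x_k * conj(x_0)) / pi` for each
#' velocity-sensitive encoding against the flow-compensated reference, giving
#' velocities in `(-venc, venc]`; speeds beyond VENC alias (wrap by multiples
#' of `2 venc`).
#'
#' @param encoded complex array whose second-to-last (or chosen) dimension of
#'   size 4 indexes the encodings in acquisition order (V_o, V_TP, V_X, V_Y);
#'   e.g. `nx x ny x 4 x T` or `nx x ny x nz x 4 x T`.
#' @param venc_cm_s velocity encoding sensitivity (cm/s).
#' @param enc_dim which dimension indexes the encodings; default the
#'   second-to-last.
#' @return array with the encoding dimension replaced by 3 velocity components
#'   in x, y, z order (cm/s).
#' @export
decode_velocity <- function(encoded, venc_cm_s, enc_dim = length(dim(encoded)) - 1) {
  d <- dim(encoded)
  stopifnot(d[enc_dim] == 4)
  ref <- slice_dim(encoded, enc_dim, 1)
  out_d <- d; out_d[enc_dim] <- 3
  v <- array(0, out_d)
  # acquisition order V_TP (z), V_X (x), V_Y (y) -> component slots z=3, x=1, y=2
  slots <- c(3L, 1L, 2L)
  for (k in 1:3) {
    xk <- slice_dim(encoded, enc_dim, k + 1)
    v <- assign_dim(v, enc_dim, slots[k], venc_cm_s * Arg(xk * Conj(ref)) / pi)
  }
  v
}

# extract / assign index i along dimension `dm` of array a, keeping other dims
slice_dim <- function(a, dm, i) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[dm]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

assign_dim <- function(a, dm, i, value) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[dm]] <- i
  do.call(`[<-`, c(list(a), idx, list(value = value)))
}

#' Fit and remove a second-order background phase from a velocity field
#'
#' Fits `b1 + b2 x + b3 y + b4 x^2 + b5 x y + b6 y^2` by least squares to the
#' time-averaged velocity of static-tissue voxels and subtracts the fitted
#' in-plane field from every z-slice and phase (eddy-current offsets are
#' static in time and, here, in z).
#'
#' @param velocity velocity array: `nx x ny [x nz] x T` (one component), cm/s.
#' @param static_mask logical `nx x ny [x nz]` mask of static tissue; must hold
#'   at least 10 voxels per fitted coefficient (60).
#' @param x_mm,y_mm in-plane voxel coordinates (mm).
#' @return list: `velocity` (corrected, same shape), `coefficients` (length 6,
#'   cm/s units), `residual_static_cm_s` (mean corrected static velocity).
#' @export
correct_background_phase <- function(velocity, static_mask, x_mm, y_mm) {
  d <- dim(velocity)
  nd <- length(d)
  nz <- if (nd == 4) d[3] else 1L
  T <- d[nd]
  stopifnot(length(static_mask) == d[1] * d[2] * nz)
  if (sum(static_mask) < 60) stop("static mask too small for a 6-coefficient fit")

  vmean <- rowMeans(matrix(velocity, length(static_mask), T))
  X <- matrix(x_mm, d[1], d[2])
  Y <- matrix(y_mm, d[1], d[2], byrow = TRUE)
  basis2d <- cbind(1, as.vector(X), as.vector(Y), as.vector(X)^2,
                   as.vector(X * Y), as.vector(Y)^2)
  basis <- basis2d[rep(seq_len(d[1] * d[2]), nz), , drop = FALSE]
  sel <- as.vector(static_mask)
  qrA <- qr(basis[sel, , drop = FALSE])
  if (qrA$rank < 6) stop("rank-deficient background-phase fit")
  coef <- qr.coef(qrA, vmean[sel])
  fit <- as.vector(basis %*% coef)
  corrected <- velocity - array(rep(fit, T), d)
  cm <- rowMeans(matrix(corrected, length(static_mask), T))
  list(velocity = corrected, coefficients = coef,
       residual_static_cm_s = mean(cm[sel]))
}

# row-wise median of a fixed small number of columns via a sorting network
sort_net <- function(cols, pairs) {
  for (pr in pairs) {
    a <- cols[[pr[1]]]; b <- cols[[pr[2]]]
    cols[[pr[1]]] <- pmin(a, b)
    cols[[pr[2]]] <- pmax(a, b)
  }
  cols
}

median4 <- function(cols) {
  cols <- sort_net(cols, list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(2, 3)))
  (cols[[2]] + cols[[3]]) / 2
}

median6 <- function(cols) {
  cols <- sort_net(cols, list(c(1, 2), c(3, 4), c(5, 6), c(1, 3), c(4, 6),
                              c(2, 5), c(1, 2), c(3, 4), c(5, 6), c(2, 3),
                              c(4, 5), c(3, 4)))
  (cols[[3]] + cols[[4]]) / 2
}

# edge-replicated neighbour arrays along each axis
shift_arr <- function(a, axis, by) {
  d <- dim(a)
  i <- seq_len(d[axis]) - by
  i <- pmin(pmax(i, 1L), d[axis])
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# median of the face neighbours (4 in 2D, 6 in 3D), edges replicated
neighbour_median <- function(v) {
  d <- dim(v)
  nd <- length(d)
  cols <- list()
  for (ax in seq_len(nd))
    for (by in c(-1L, 1L))
      cols[[length(cols) + 1]] <- as.vector(shift_arr(v, ax, by))
  m <- if (nd == 2) median4(cols) else median6(cols)
  array(m, d)
}

# zero-filled shift along one axis (logical arrays shift FALSE in)
shift0 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  n <- d[axis]
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  is <- id <- rep(list(quote(expr = )), length(d))
  is[[axis]] <- src; id[[axis]] <- dst
  do.call(`[<-`, c(list(out), id,
                   list(value = do.call(`[`, c(list(a), is, list(drop = FALSE))))))
}

#' Automatic velocity anti-aliasing
#'
#' Region-growing unwrapping against the face neighbourhood (6 neighbours in
#' 3D, 4 in 2D). Voxels with `|v| <= VENC/2` are unambiguous (a wrap maps an
#' in-range speed to an apparent speed of at least VENC) and seed the trusted
#' region; each pass then resolves every untrusted voxel adjacent to the
#' trusted region by shifting it by the multiple of `2 VENC` closest to the
#' mean of its trusted neighbours, so wrapped regions are peeled from their
#' rim inward. At most `max_passes` passes are run. Non-convergence is a
#' reported condition, not an error: voxels never reached plus voxels still
#' differing from their neighbourhood median by more than VENC are counted
#' as unresolved (as with vendor anti-aliasing, severe aliasing can be
#' uncorrectable).
#'
#' @param velocity 2D or 3D numeric array of one velocity component (cm/s).
#' @param venc_cm_s velocity encoding sensitivity (cm/s).
#' @param max_passes maximum growth passes (default 10).
#' @param mask optional logical array: only these voxels are unwrapped and
#'   audited (air carries uniformly random phase, so unwrapping it is
#'   meaningless churn); `NULL` processes every voxel.
#' @return list: `velocity` (unwrapped), `n_unresolved`, `converged`,
#'   `passes`.
#' @export
unwrap_aliasing <- function(velocity, venc_cm_s, max_passes = 10, mask = NULL) {
  v <- velocity
  d <- dim(v)
  if (is.null(mask)) mask <- array(TRUE, d)
  visited <- mask & abs(v) <= venc_cm_s / 2
  passes <- 0L
  while (passes < max_passes) {
    sumn <- array(0, d)
    cnt <- array(0, d)
    for (ax in seq_along(d)) for (by in c(-1L, 1L)) {
      sumn <- sumn + shift0(ifelse(visited, v, 0), ax, by)
      cnt <- cnt + shift0(visited, ax, by)
    }
    frontier <- mask & !visited & cnt > 0
    if (!any(frontier)) break
    ref <- sumn[frontier] / cnt[frontier]
    k <- round((v[frontier] - ref) / (2 * venc_cm_s))
    v[frontier] <- v[frontier] - 2 * venc_cm_s * k
    visited[frontier] <- TRUE
    passes <- passes + 1L
  }
  bad <- (abs(v - neighbour_median(v)) > venc_cm_s | !visited) & mask
  n_bad <- sum(bad)
  list(velocity = v, n_unresolved = n_bad, converged = n_bad == 0L,
       passes = passes)
}

#' Segment a vessel lumen on a magnitude plane
#'
#' Automatic threshold (Otsu on the plane's magnitude, time-averaged)
#' seeded by a known in-lumen point: the mask is the single connected
#' component of the supra-threshold region containing the seed, and is
#' propagated unchanged to all cardiac phases. Alternatively, with
#' ground-truth `labels`, returns the exact lumen cross-section of the vessel
#' under the seed.
#'
#' @param magnitude `nx x ny` or `nx x ny x T` magnitude image(s).
#' @param seed_ij integer length-2 voxel index of a point inside the lumen.
#' @param labels optional `nx x ny` ground-truth label plane (values > 2 are
#'   lumens); if given, oracle mode is used.
#' @return logical `nx x ny` mask.
#' @export
segment_lumen <- function(magnitude, seed_ij, labels = NULL) {
  if (!is.null(labels)) {
    lab <- labels[seed_ij[1], seed_ij[2]]
    if (lab <= 2) stop("seed does not lie in a lumen of the label image")
    mask <- labels == lab
    if (!any(mask)) stop("empty lumen mask")
    return(mask)
  }
  m <- if (length(dim(magnitude)) == 3) apply(magnitude, c(1, 2), mean)
       else magnitude
  rng <- range(m)
  if (rng[2] <= rng[1]) stop("flat magnitude plane; cannot threshold")
  mn <- (m - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(mn), range = c(0, 1))
  bw <- mn > th
  cc <- EBImage::bwlabel(EBImage::Image(bw))
  cc <- EBImage::imageData(cc)
  lab <- cc[seed_ij[1], seed_ij[2]]
  if (lab == 0) stop("seed falls outside the thresholded region; empty mask")
  cc == lab
}

#' Volumetric flow through a plane
#'
#' Per-phase flow is the masked sum of through-plane velocity times pixel
#' area, `sum(v_perp) * area / 1000` (cm/s * mm^2 -> mL/s); the mean flow is
#' the cycle average.
#'
#' @param v_through `nx x ny x T` through-plane velocity at the measurement
#'   plane (cm/s).
#' @param mask logical `nx x ny` lumen mask (propagated to all phases).
#' @param pixel_area_mm2 in-plane pixel area (mm^2).
#' @param vessel_id optional identifier.
#' @param plane optional plane description (kept in the result).
#' @return object of class `vessel_measurement`: `vessel_id`,
#'   `per_phase_flow_ml_s`, `mean_flow_ml_s`, `n_pixels`, `plane`.
#' @export
mean_flow <- function(v_through, mask, pixel_area_mm2, vessel_id = NA_character_,
                      plane = NULL) {
  d <- dim(v_through)
  if (length(d) == 2) v_through <- array(v_through, c(d, 1))
  T <- dim(v_through)[3]
  if (!any(mask)) stop("empty lumen mask")
  per_phase <- vapply(seq_len(T), function(p)
    sum(v_through[, , p][mask]) * pixel_area_mm2 / 1000, 0)
  structure(list(vessel_id = vessel_id, per_phase_flow_ml_s = per_phase,
                 mean_flow_ml_s = mean(per_phase), n_pixels = sum(mask),
                 plane = plane), class = "vessel_measurement")
}

#' Signal- and contrast-to-noise ratio
#'
#' SNR is the mean lumen magnitude divided by the background-noise SD measured
#' in air and corrected for the Rayleigh (magnitude) bias by dividing by
#' `sqrt(2 - pi/2)` (~0.655), which converts the air magnitude SD to the
#' underlying complex-noise SD. CNR replaces the numerator by the absolute
#' lumen-lung difference.
#'
#' @param magnitude numeric array.
#' @param lumen_mask,lung_mask,air_mask disjoint non-empty logical masks.
#' @return object of class `snr_cnr_result`: `snr`, `cnr`, `noise_sd`
#'   (corrected complex-noise SD), `air_sd_raw`, `finite` (FALSE when the air
#'   SD is zero, in which case SNR/CNR are `Inf` flags, not ratios).
#' @export
snr_cnr <- function(magnitude, lumen_mask, lung_mask, air_mask) {
  stopifnot(any(lumen_mask), any(lung_mask), any(air_mask))
  if (any((lumen_mask & lung_mask) | (lumen_mask & air_mask) |
          (lung_mask & air_mask)))
    stop("lumen, lung and air masks must be disjoint")
  rep_mask <- function(mk) {             # recycle a spatial mask over phases
    if (length(mk) == length(magnitude)) mk
    else array(mk, dim(magnitude))
  }
  lum <- mean(magnitude[rep_mask(lumen_mask)])
  lng <- mean(magnitude[rep_mask(lung_mask)])
  air_sd <- stats::sd(magnitude[rep_mask(air_mask)])
  if (air_sd == 0)
    return(structure(list(snr = Inf, cnr = Inf, noise_sd = 0, air_sd_raw = 0,
                          finite = FALSE), class = "snr_cnr_result"))
  noise <- air_sd / sqrt(2 - pi / 2)
  structure(list(snr = lum / noise, cnr = abs(lum - lng) / noise,
                 noise_sd = noise, air_sd_raw = air_sd, finite = TRUE),
            class = "snr_cnr_result")
}
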