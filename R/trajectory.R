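#' Golden angle (degrees)
#'
#' Irrational rotation increment `360 / phi^2` with `phi` the golden ratio,
#' giving near-uniform angular coverage of k-space for any contiguous block of
#' spiral arms.
#'
#' @export
golden_angle_deg <- function() 360 * (1 - 2 / (1 + sqrt(5)))

#' Design a single Archimedean spiral arm
#'
#' Builds a uniform-pitch (Archimedean) spiral readout starting at the k-space
#' origin and reaching `k_max = 1 / (2 * resolution_mm)` cycles/mm, the Nyquist
#' radius for the requested in-plane resolution. The radius grows linearly with
#' sample index, so `|k|` is monotonically non-decreasing along the readout.
#'
#' @param fov_mm in-plane field of view (mm).
#' @param resolution_mm in-plane resolution (mm); must be smaller than the FOV.
#' @param n_samples number of complex samples along the arm (>= 64).
#' @param readout_ms duration of the readout; sample times are uniform over it.
#' @param n_turns number of revolutions from centre to edge.
#' @return An object of class `spiral_arm`: list with `k` (`n_samples` x 2
#'   matrix, cycles/mm), `sample_times_ms`, `k_max`, `fov_mm`, `resolution_mm`.
#' @export
design_spiral <- function(fov_mm, resolution_mm, n_samples = 128,
                          readout_ms = 3, n_turns = 1) {
  stopifnot(resolution_mm < fov_mm, n_samples >= 64, readout_ms > 0,
            n_turns > 0)
  k_max <- 1 / (2 * resolution_mm)
  tau <- seq(0, 1, length.out = n_samples)
  r <- k_max * tau
  theta <- 2 * pi * n_turns * tau
  arm <- list(
    k = cbind(kx = r * cos(theta), ky = r * sin(theta)),
    sample_times_ms = tau * readout_ms,
    k_max = k_max,
    fov_mm = fov_mm,
    resolution_mm = resolution_mm,
    n_turns = n_turns
  )
  class(arm) <- "spiral_arm"
  arm
}

#' Rotate a spiral arm in-plane
#'
#' @param arm a [design_spiral()] object.
#' @param angle_deg rotation angle, degrees counter-clockwise.
#' @return `n x 2` matrix of rotated k-space coordinates (cycles/mm).
#' @export
rotate_arm <- function(arm, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  arm$k %*% R
}

#' Radial density-compensation weights for a spiral arm
#'
#' Ramp weights proportional to `|k|` (floored near the origin), normalised to
#' unit mean. Used as diagonal weights in the least-squares data term so the
#' density-compensated adjoint is a good starting image.
#'
#' @param arm a [design_spiral()] object.
#' @return numeric vector, one weight per sample, mean 1.
#' @export
arm_density_weights <- function(arm) {
  r <- sqrt(rowSums(arm$k^2))
  w <- pmax(r, arm$k_max / length(r))
  w / mean(w)
}

#' Build the SWEEP TR schedule
#'
#' One record per TR: accumulated golden-angle rotation, slice excitation
#' centre (advancing by a constant small shift each TR), velocity-encoding
#' index cycling with period 4 in the order flow-compensated (V_o),
#' through-plane (V_TP), in-plane x (V_X), in-plane y (V_Y), and excitation
#' time. Rotation accumulates every TR, not per 4-TR encoding group.
#'
#' @param n_tr number of TRs (>= 4).
#' @param tr_ms repetition time (ms).
#' @param z_start_mm slice centre of the first TR (mm).
#' @param shift_per_tr_mm slice advance per TR (mm); 0.005 mm/TR at scanner
#'   scale.
#' @param golden_deg rotation increment per TR (degrees).
#' @return An object of class `tr_schedule`: data.frame with columns `index`
#'   (0-based), `time_ms`, `rotation_deg`, `slice_z_mm`, `encoding_index`.
#' @export
build_schedule <- function(n_tr, tr_ms, z_start_mm, shift_per_tr_mm,
                           golden_deg = golden_angle_deg()) {
  stopifnot(n_tr >= 4, tr_ms > 0)
  i <- seq_len(n_tr) - 1
  sched <- data.frame(
    index = i,
    time_ms = i * tr_ms,
    rotation_deg = (i * golden_deg) %% 360,
    slice_z_mm = z_start_mm + i * shift_per_tr_mm,
    encoding_index = i %% 4L
  )
  attr(sched, "tr_ms") <- tr_ms
  attr(sched, "shift_per_tr_mm") <- shift_per_tr_mm
  class(sched) <- c("tr_schedule", "data.frame")
  sched
}

#' Total slice-direction extent swept by a schedule
#'
#' @param n_tr number of TRs.
#' @param shift_per_tr_mm slice advance per TR (mm).
#' @return swept extent in mm (`n_tr * shift_per_tr_mm`).
#' @export
sweep_extent_mm <- function(n_tr, shift_per_tr_mm) n_tr * shift_per_tr_mm

#' Encoding labels in acquisition order
#' @return character vector `c("V_o", "V_TP", "V_X", "V_Y")`.
#' @export
encoding_labels <- function() c("V_o", "V_TP", "V_X", "V_Y")

#' Write a TR schedule as a delimited table
#' @param schedule a [build_schedule()] object.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
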