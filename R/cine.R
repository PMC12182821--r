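#' Compressed-sensing CINE configuration
#'
#' Scanner-scale defaults follow the reconstruction protocol: 996 spiral arms
#' per slice window with 332 arms shared between adjacent windows, 30
#' iterations with a temporal-total-variation weight of 0.08 (relative to
#' normalised data). `n_cardiac_phases = NA` derives the bin count as
#' `round(mean R-R / 50 ms)` at reconstruction time (about 50 ms temporal
#' resolution).
#'
#' @param n_iterations proximal-gradient iterations (>= 1).
#' @param ttv_weight temporal-TV weight, relative to the maximum of the
#'   density-compensated adjoint image `max |A^H W y|` (>= 0).
#' @param n_cardiac_phases cardiac bins, or `NA` to derive from the R-R.
#' @param arms_per_window spiral arms per slice window (all encodings pooled).
#' @param overlap_arms arms shared between adjacent windows
#'   (< `arms_per_window`).
#' @return object of class `cs_config`.
#' @export
cs_config <- function(n_iterations = 30, ttv_weight = 0.08,
                      n_cardiac_phases = NA, arms_per_window = 996,
                      overlap_arms = 332) {
  stopifnot(n_iterations >= 1, ttv_weight >= 0,
            overlap_arms < arms_per_window, arms_per_window >= 4)
  structure(list(n_iterations = n_iterations, ttv_weight = ttv_weight,
                 n_cardiac_phases = n_cardiac_phases,
                 arms_per_window = arms_per_window,
                 overlap_arms = overlap_arms), class = "cs_config")
}

#' Group TRs into overlapping slice windows
#'
#' Consecutive blocks of `arms_per_window` TRs, advancing by
#' `arms_per_window - overlap_arms` TRs (the hop), so adjacent windows share
#' exactly `overlap_arms` TRs; trailing TRs that do not fill a window are
#' dropped.
#'
#' @param schedule a [build_schedule()] object.
#' @param cs a [cs_config()].
#' @return list of `slice_window` objects: `tr_indices` (1-based rows into the
#'   schedule), `center_z_mm`, `arms_per_encoding`.
#' @export
make_windows <- function(schedule, cs) {
  apw <- cs$arms_per_window
  stopifnot(nrow(schedule) >= apw)
  hop <- apw - cs$overlap_arms
  starts <- seq(1L, nrow(schedule) - apw + 1L, by = hop)
  lapply(starts, function(s) {
    idx <- s:(s + apw - 1L)
    structure(list(tr_indices = idx,
                   center_z_mm = mean(schedule$slice_z_mm[idx]),
                   arms_per_encoding = apw / 4),
              class = "slice_window")
  })
}

#' Cardiac phase of a time point under retrospective gating
#'
#' Fraction of the enclosing R-R interval elapsed, in `[0, 1)`.
#'
#' @param time_ms numeric vector of times; must lie within the trigger span.
#' @param triggers a [sample_triggers()] object.
#' @return numeric vector of phases in `[0, 1)`.
#' @export
assign_cardiac_phase <- function(time_ms, triggers) {
  pk <- triggers$r_peak_times_ms
  n <- length(pk)
  if (any(time_ms < pk[1] | time_ms > pk[n]))
    stop("time outside the trigger span [", pk[1], ", ", pk[n], "] ms")
  i <- pmin(findInterval(time_ms, pk), n - 1L)
  ph <- (time_ms - pk[i]) / (pk[i + 1] - pk[i])
  ph %% 1                               # the final R peak wraps to phase 0
}

# default cardiac bin count: ~50 ms temporal resolution
derive_n_phases <- function(triggers, target_ms = 50) {
  rr <- mean(diff(triggers$r_peak_times_ms))
  max(2L, as.integer(round(rr / target_ms)))
}

# ---- cyclic temporal total-variation proximal operator ---------------------

# prox_{tau * sum_t |x_t - x_{t-1}|} (cyclic) for complex V (n_pix x T),
# via projected gradient ascent on the dual; p0 warm-starts the dual variable.
prox_ttv_cyclic <- function(V, tau, p0 = NULL, n_inner = 40) {
  T <- ncol(V)
  if (tau <= 0 || T < 2) return(list(x = V, p = p0))
  prv <- c(T, seq_len(T - 1))
  nxt <- c(seq_len(T - 1) + 1, 1)
  p <- if (is.null(p0)) matrix(0i, nrow(V), T) else p0
  for (it in seq_len(n_inner)) {
    x <- V - (p - p[, nxt, drop = FALSE])          # x = V - D^T p
    g <- x - x[, prv, drop = FALSE]                # D x
    p <- p + 0.25 * g
    m <- abs(p)
    shrink <- m > tau
    p[shrink] <- p[shrink] * (tau / m[shrink])
  }
  list(x = V - (p - p[, nxt, drop = FALSE]), p = p)
}

# cyclic temporal TV value of x (n_pix x T)
ttv_value <- function(x) {
  T <- ncol(x)
  if (T < 2) return(0)
  sum(abs(x - x[, c(T, seq_len(T - 1)), drop = FALSE]))
}

#' Low-level gated compressed-sensing solver with cyclic temporal TV
#'
#' Solves `argmin_x 0.5 * sum_b ||W_b^(1/2) (A_b x_b - y_b)||^2 +
#' lambda * sum |x(t) - x(t-1)|` (temporal differences cyclic over the cardiac
#' cycle) by proximal gradient with a fixed step from a power-method estimate
#' of the operator norm; `A_b` is the non-uniform Fourier operator of cardiac
#' bin `b` and `W_b` holds radial density-compensation weights. `lambda =
#' ttv_weight * max |A^H W y|`. Runs exactly `n_iterations`; deterministic.
#'
#' @param ks list of `n_k x 2` k-coordinate matrices, one per cardiac bin.
#' @param ys list of complex sample vectors, one per bin.
#' @param ws list of density-compensation weight vectors, one per bin.
#' @param x_mm,y_mm image voxel-centre coordinates (mm).
#' @param n_iterations,ttv_weight see [cs_config()].
#' @return list: `x` (`nx x ny x T` complex array), `objective`
#'   (per-iteration), `lambda`, `step`.
#' @export
cs_temporal_tv <- function(ks, ys, ws, x_mm, y_mm, n_iterations, ttv_weight) {
  T <- length(ks)
  nx <- length(x_mm); ny <- length(y_mm)
  npix <- nx * ny
  nrm <- sqrt(npix)

  # cache the separable complex-exponential factors of each bin's operator
  ops <- lapply(seq_len(T), function(b)
    list(Bx = exp(-2i * pi * outer(ks[[b]][, 1], x_mm)),
         By = exp(-2i * pi * outer(ks[[b]][, 2], y_mm))))
  fwd <- function(b, xb) rowSums((ops[[b]]$Bx %*% xb) * ops[[b]]$By) / nrm
  adjt <- function(b, s)
    crossprod(Conj(ops[[b]]$Bx), s * Conj(ops[[b]]$By)) / nrm

  adj <- vapply(seq_len(T), function(b) adjt(b, ys[[b]] * ws[[b]]),
                matrix(0i, nx, ny))
  lambda <- ttv_weight * max(abs(adj))

  # power method for L = max_b ||A_b^H W_b A_b||
  L <- 0
  for (b in seq_len(T)) {
    v <- matrix(adj[, , b], nx, ny)
    if (max(abs(v)) == 0) v <- matrix(1 + 0i, nx, ny)
    lam <- 1
    for (i in 1:6) {
      v <- v / sqrt(sum(abs(v)^2))
      Gv <- adjt(b, ws[[b]] * fwd(b, v))
      lam <- Re(sum(Conj(v) * Gv))
      v <- Gv
    }
    L <- max(L, lam)
  }
  L <- L * 1.05

  # initial image: density-compensated adjoint, scaled by the 1-D least-squares
  # fit of its forward projection onto the data
  num <- 0; den <- 0
  for (b in seq_len(T)) {
    f <- fwd(b, matrix(adj[, , b], nx, ny))
    num <- num + Re(sum(Conj(f) * ws[[b]] * ys[[b]]))
    den <- den + sum(ws[[b]] * abs(f)^2)
  }
  alpha <- if (den > 0) num / den else 0
  x <- matrix(as.vector(adj) * alpha, npix, T)

  p_dual <- NULL
  objective <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    grad <- matrix(0i, npix, T)
    fid <- 0
    for (b in seq_len(T)) {
      r <- fwd(b, matrix(x[, b], nx, ny)) - ys[[b]]
      fid <- fid + 0.5 * sum(ws[[b]] * abs(r)^2)
      grad[, b] <- as.vector(adjt(b, ws[[b]] * r))
    }
    objective[it] <- fid + lambda * ttv_value(x)
    pr <- prox_ttv_cyclic(x - grad / L, lambda / L, p0 = p_dual)
    x <- pr$x
    p_dual <- pr$p
  }
  list(x = array(x, c(nx, ny, T)), objective = objective, lambda = lambda,
       step = 1 / L)
}

#' Reconstruct per-encoding CINEs for one slice window
#'
#' Splits the window's TRs by velocity encoding, gates each arm into a cardiac
#' bin (uniform bins in normalised phase, nearest-bin assignment, cyclic), and
#' solves the temporal-TV compressed-sensing problem per encoding.
#'
#' @param kspace a [simulate_sweep()] k-space set.
#' @param window one element of [make_windows()].
#' @param cs a [cs_config()].
#' @return object of class `cine_slice`: `images` (`nx x ny x 4 x T` complex),
#'   `center_z_mm`, `phase_edges`, `objective` (4 x n_iterations), `lambda`.
#' @export
reconstruct_cine <- function(kspace, window, cs) {
  sched <- kspace$schedule
  stopifnot(max(window$tr_indices) <= nrow(sched))
  cfg <- kspace$config
  T <- if (is.na(cs$n_cardiac_phases)) derive_n_phases(kspace$triggers)
       else cs$n_cardiac_phases
  crd_n <- round(cfg$fov_mm / cfg$in_plane_resolution_mm)
  x_mm <- axis_coords(crd_n, cfg$in_plane_resolution_mm)
  y_mm <- x_mm

  sub <- sched[window$tr_indices, ]
  ph <- assign_cardiac_phase(sub$time_ms + cfg$te_ms, kspace$triggers)
  bin <- pmin(T, floor(ph * T) + 1L)
  w_arm <- arm_density_weights(kspace$arm)

  images <- array(0i, c(crd_n, crd_n, 4, T))
  objective <- matrix(NA_real_, 4, cs$n_iterations)
  lambda <- numeric(4)
  for (e in 0:3) {
    rows <- which(sub$encoding_index == e)
    ks <- ys <- ws <- vector("list", T)
    for (b in seq_len(T)) {
      rb <- rows[bin[rows] == b]
      if (!length(rb))
        stop(sprintf("empty cardiac bin: window centred %.2f mm, encoding %s, bin %d",
                     window$center_z_mm, encoding_labels()[e + 1], b))
      ks[[b]] <- do.call(rbind, lapply(rb, function(r)
        rotate_arm(kspace$arm, sub$rotation_deg[r])))
      ys[[b]] <- as.vector(t(kspace$data[window$tr_indices[rb], , drop = FALSE]))
      ws[[b]] <- rep(w_arm, length(rb))
    }
    sol <- cs_temporal_tv(ks, ys, ws, x_mm, y_mm, cs$n_iterations,
                          cs$ttv_weight)
    images[, , e + 1, ] <- sol$x
    objective[e + 1, ] <- sol$objective
    lambda[e + 1] <- sol$lambda
  }
  structure(list(images = images, center_z_mm = window$center_z_mm,
                 phase_edges = (0:T) / T, objective = objective,
                 lambda = lambda, x_mm = x_mm, y_mm = y_mm),
            class = "cine_slice")
}

#' Reconstruct all slice windows into a CINE stack
#'
#' @param kspace a [simulate_sweep()] k-space set.
#' @param cs a [cs_config()].
#' @param progress print one line per window.
#' @return object of class `cine_stack`: `slices` (list of `cine_slice`),
#'   `center_z_mm`, `n_phases`, `x_mm`, `y_mm`, `config`, `cs`.
#' @export
reconstruct_cine_stack <- function(kspace, cs, progress = FALSE) {
  wins <- make_windows(kspace$schedule, cs)
  slices <- vector("list", length(wins))
  for (i in seq_along(wins)) {
    if (progress)
      message("window ", i, " / ", length(wins), " (z = ",
              round(wins[[i]]$center_z_mm, 2), " mm)")
    slices[[i]] <- reconstruct_cine(kspace, wins[[i]], cs)
  }
  structure(list(slices = slices,
                 center_z_mm = vapply(slices, `[[`, 0, "center_z_mm"),
                 n_phases = dim(slices[[1]]$images)[4],
                 x_mm = slices[[1]]$x_mm, y_mm = slices[[1]]$y_mm,
                 config = kspace$config, cs = cs),
            class = "cine_stack")
}
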