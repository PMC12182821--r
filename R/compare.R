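#' Linear agreement between paired flow measurements
#'
#' Ordinary least squares of the SVR 4D flow measurement on the 2D comparator
#' measurement, with 95% confidence intervals from the t distribution on
#' `n - 2` degrees of freedom.
#'
#' @param pairs data.frame with columns `m_2d` and `m_svr` (mL/s) and
#'   optionally `vessel_id`; at least 3 rows.
#' @return list: `slope`, `intercept_ml_s`, `slope_ci95`, `intercept_ci95`,
#'   `r_squared`, `n`.
#' @export
linear_agreement <- function(pairs) {
  stopifnot(nrow(pairs) >= 3)
  if (stats::var(pairs$m_2d) == 0)
    stop("degenerate comparator measurements: zero variance in m_2d")
  fit <- stats::lm(m_svr ~ m_2d, data = pairs)
  ci <- stats::confint(fit, level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept_ml_s = unname(stats::coef(fit)[1]),
       slope_ci95 = unname(ci[2, ]),
       intercept_ci95 = unname(ci[1, ]),
       r_squared = summary(fit)$r.squared,
       n = nrow(pairs))
}

#' Bland-Altman agreement
#'
#' Differences are taken as `m_2d - m_svr` by default (configurable); bias is
#' the mean difference and the limits of agreement are
#' `bias +/- 1.96 * SD(differences)` with the sample (n-1) SD.
#'
#' @param pairs data.frame with columns `m_2d` and `m_svr` (mL/s); >= 2 rows.
#' @param direction `"2d_minus_svr"` (default) or `"svr_minus_2d"`.
#' @return list: `bias_ml_s`, `loa_low_ml_s`, `loa_high_ml_s`, `sd_diff_ml_s`,
#'   `means`, `differences`, `direction`, `n`.
#' @export
bland_altman <- function(pairs, direction = c("2d_minus_svr", "svr_minus_2d")) {
  direction <- match.arg(direction)
  stopifnot(nrow(pairs) >= 2)
  d <- if (direction == "2d_minus_svr") pairs$m_2d - pairs$m_svr
       else pairs$m_svr - pairs$m_2d
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias_ml_s = bias, loa_low_ml_s = bias - 1.96 * s,
       loa_high_ml_s = bias + 1.96 * s, sd_diff_ml_s = s,
       means = (pairs$m_2d + pairs$m_svr) / 2, differences = d,
       direction = direction, n = nrow(pairs))
}

#' Full agreement report for paired vessel flows
#'
#' @param pairs data.frame with `vessel_id`, `m_2d`, `m_svr` (mL/s).
#' @param direction Bland-Altman difference convention; see [bland_altman()].
#' @return object of class `agreement_report` combining [linear_agreement()]
#'   and [bland_altman()] with the pairs.
#' @export
agreement_report <- function(pairs, direction = "2d_minus_svr") {
  reg <- linear_agreement(pairs)
  ba <- bland_altman(pairs, direction)
  structure(list(pairs = pairs, regression = reg, bland_altman = ba),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  r <- x$regression; b <- x$bland_altman
  cat(sprintf("Agreement over %d vessel pairs (mL/s)\n", r$n))
  cat(sprintf("  regression: slope = %.3f [%.3f, %.3f], intercept = %.2f [%.2f, %.2f], r^2 = %.3f\n",
              r$slope, r$slope_ci95[1], r$slope_ci95[2], r$intercept_ml_s,
              r$intercept_ci95[1], r$intercept_ci95[2], r$r_squared))
  cat(sprintf("  Bland-Altman (%s): bias = %.2f, LoA [%.2f, %.2f]\n",
              b$direction, b$bias_ml_s, b$loa_low_ml_s, b$loa_high_ml_s))
  invisible(x)
}

#' Regression and Bland-Altman plots
#'
#' Scatter of SVR 4D flow against the 2D comparator with the fitted and
#' identity lines, and a Bland-Altman plot with bias and limits of agreement.
#'
#' @param report an [agreement_report()].
#' @return list of two ggplot objects: `regression`, `bland_altman`.
#' @export
plot_agreement <- function(report) {
  p <- report$pairs
  r <- report$regression
  b <- report$bland_altman
  df <- data.frame(m_2d = p$m_2d, m_svr = p$m_svr,
                   mean = b$means, diff = b$differences)
  g1 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m_2d, y = .data$m_svr)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "blue") +
    ggplot2::geom_abline(slope = r$slope, intercept = r$intercept_ml_s,
                         colour = "red") +
    ggplot2::labs(x = "2D PCMRI mean flow (mL/s)",
                  y = "SVR 4D flow mean flow (mL/s)",
                  title = sprintf("slope %.2f, r² = %.2f", r$slope,
                                  r$r_squared)) +
    ggplot2::theme_minimal()
  g2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = b$bias_ml_s, colour = "red") +
    ggplot2::geom_hline(yintercept = c(b$loa_low_ml_s, b$loa_high_ml_s),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "mean of techniques (mL/s)",
                  y = sprintf("difference, %s (mL/s)", b$direction),
                  title = sprintf("bias %.2f, LoA [%.2f, %.2f]", b$bias_ml_s,
                                  b$loa_low_ml_s, b$loa_high_ml_s)) +
    ggplot2::theme_minimal()
  list(regression = g1, bland_altman = g2)
}

#' Write an agreement report as delimited tables
#'
#' @param report an [agreement_report()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_agreement <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs_path <- file.path(dir, "flow_pairs.csv")
  utils::write.csv(report$pairs, pairs_path, row.names = FALSE)
  r <- report$regression; b <- report$bland_altman
  stats_path <- file.path(dir, "agreement_stats.csv")
  utils::write.csv(data.frame(
    quantity = c("slope", "slope_ci_low", "slope_ci_high", "intercept_ml_s",
                 "intercept_ci_low", "intercept_ci_high", "r_squared",
                 "bias_ml_s", "loa_low_ml_s", "loa_high_ml_s", "n_pairs"),
    value = c(r$slope, r$slope_ci95, r$intercept_ml_s, r$intercept_ci95,
              r$r_squared, b$bias_ml_s, b$loa_low_ml_s, b$loa_high_ml_s, r$n)),
    stats_path, row.names = FALSE)
  invisible(c(pairs_path, stats_path))
}
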