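#' Maximal PSII quantum yield Fv/Fm
#'
#' Photosynthetic efficiency from dark-acclimated fluorescence yields:
#' `(Fm - Fo) / Fm`, bounded in [0, 1].
#'
#' @param fm Maximal fluorescence yield (> 0).
#' @param fo Minimal (dark-acclimated) fluorescence yield, `0 <= fo <= fm`.
#' @return Fv/Fm ratio(s) in [0, 1].
#' @export
compute_fvfm <- function(fm, fo) {
  if (any(fm <= 0)) stop_ss("Fm must be > 0")
  if (any(fo < 0) || any(fo > fm)) stop_ss("need 0 <= Fo <= Fm")
  (fm - fo) / fm
}

#' Specific growth rate from a cell-count series
#'
#' Ordinary least-squares slope of ln(cell concentration) versus time
#' (days) over the exponential phase, i.e. the specific growth rate mu in
#' 1/day. The window defaults to the whole series; `auto` restricts it to
#' the steepest `window_points`-point run of the log-linear fit (a
#' heuristic for picking the exponential phase).
#'
#' @param counts Data.frame with `time` (days) and `value` (cells/mL,
#'   > 0), or two vectors via `time`.
#' @param window Optional numeric length-2 time interval `c(t0, t1)`.
#' @param auto If TRUE and no window given, auto-detect the steepest
#'   `window_points`-point run.
#' @param window_points Run length for auto-detection.
#' @return A list with `mu` (1/day), `r_squared`, `window`, `n`.
#' @export
specific_growth_rate <- function(counts, window = NULL, auto = FALSE,
                                 window_points = 4L) {
  t <- counts$time; y <- counts$value
  if (any(y <= 0)) stop_ss("cell counts must be > 0")
  if (!is.null(window)) {
    keep <- t >= window[1L] & t <= window[2L]
    t <- t[keep]; y <- y[keep]
  } else if (auto && length(t) > window_points) {
    slopes <- vapply(seq_len(length(t) - window_points + 1L), function(i) {
      idx <- i:(i + window_points - 1L)
      stats::coef(stats::lm(log(y[idx]) ~ t[idx]))[2L]
    }, numeric(1L))
    i <- which.max(slopes)
    idx <- i:(i + window_points - 1L)
    t <- t[idx]; y <- y[idx]
  }
  if (length(t) < 3L) stop_ss("need >= 3 points in the window")
  fit <- stats::lm(log(y) ~ t)
  list(mu = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       window = range(t), n = length(t))
}

#' Fit a logistic-with-lag growth model to a cell-count series
#'
#' Least-squares fit on ln(count) — a multiplicative noise model,
#' consistent with the log-linear definition of mu — of the explicit-lag
#' logistic curve [logistic_lag_curve()]: density `n0` during the lag,
#' then logistic growth at rate `mu` toward carrying capacity `K`.
#' Initial values are seeded from the data: `n0` from the first count,
#' `K` from the maximum, `mu` and `lag` from the steepest log-linear
#' segment and its intercept. Non-convergence is flagged, never silent.
#'
#' @param counts Data.frame with `time` (days) and `value` (cells/mL).
#' @param min_points Minimum number of points (default 6, enough to span
#'   lag, exponential and plateau phases).
#' @return A list of class `growth_fit`: `K`, `mu`, `lag`, `n0`,
#'   `residual_sd` (on ln counts), `converged`, `boundary_K` (TRUE when
#'   the fitted K is not identified by a plateau), and `fitted`.
#' @export
fit_logistic_with_lag <- function(counts, min_points = 6L) {
  t <- counts$time; y <- counts$value
  if (length(t) < min_points)
    stop_ss("need >= ", min_points, " points")
  if (any(y <= 0)) stop_ss("cell counts must be > 0")
  if (max(y) <= y[1L]) stop_ss("no growth: max count <= initial count")
  ly <- log(y)

  # seed estimates
  n0_0 <- y[1L]; K_0 <- max(y)
  np <- min(4L, length(t) - 1L)
  slopes <- vapply(seq_len(length(t) - np + 1L), function(i) {
    idx <- i:(i + np - 1L)
    stats::coef(stats::lm(ly[idx] ~ t[idx]))
  }, numeric(2L))
  i_max <- which.max(slopes[2L, ])
  mu_0 <- max(slopes[2L, i_max], 1e-3)
  # lag: where the steepest segment's back-extrapolation meets ln(n0)
  lag_0 <- max((log(n0_0) - slopes[1L, i_max]) / mu_0, 0)

  df <- data.frame(t = t, ly = ly)
  form <- ly ~ log(logistic_lag_curve(t, K, mu, lag, n0))
  start <- list(K = K_0, mu = mu_0, lag = lag_0, n0 = n0_0)
  lower <- c(K = y[1L] * 1.0001, mu = 1e-6, lag = 0, n0 = min(y) * 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    fit <- tryCatch(stats::nls(form, data = df, start = start,
                               control = stats::nls.control(
                                 maxiter = 500, warnOnly = TRUE)),
                    error = function(e) e)
  }
  if (inherits(fit, "error")) {
    out <- list(K = NA_real_, mu = NA_real_, lag = NA_real_,
                n0 = NA_real_, residual_sd = NA_real_, converged = FALSE,
                boundary_K = NA, message = conditionMessage(fit),
                fitted = NULL)
    class(out) <- "growth_fit"
    return(out)
  }
  cf <- as.list(stats::coef(fit))
  conv <- isTRUE(fit$convInfo$isConv %||% TRUE)
  # K unidentified when the series never flattens: fitted K escapes past
  # the observed maximum without a plateau (no late point within 20% of K)
  boundary_K <- cf$K > 1.5 * max(y) || max(y) < 0.8 * cf$K
  if (boundary_K)
    warning("carrying capacity not identified by a plateau; ",
            "K estimate is a boundary extrapolation", call. = FALSE)
  out <- list(K = cf$K, mu = cf$mu, lag = cf$lag, n0 = cf$n0,
              residual_sd = stats::sd(stats::residuals(fit)),
              converged = conv && !boundary_K, boundary_K = boundary_K,
              fitted = exp(stats::fitted(fit)))
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "logistic-with-lag fit: K = %.4g cells/mL, mu = %.4g /day, lag = %.4g d, n0 = %.4g (%s)\n",
    x$K, x$mu, x$lag, x$n0,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}
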