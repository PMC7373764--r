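# Specific-rate estimation by log-linear regression.
#
# Growth: mu is the least-squares slope of ln(X) vs t, i.e. the slope of the
# semilog plot ln(X/X0) vs time, positive during exponential growth.
# Degradation: q is the slope of -ln(S/S0) vs t, positive during first-order
# depletion. Both follow directly from dX/dt = mu*X and dS/dt = -q*S.

# slope + r2 of a simple linear regression; r2 reported as 0 when the
# response is constant (undefined variance)
loglinear_fit <- function(t, y) {
  n <- length(t)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  slope <- sxy / sxx
  syy <- sum((y - ym)^2)
  r2 <- if (syy <= 0) 0 else {
    ss_res <- syy - slope * sxy
    max(0, min(1, 1 - ss_res / syy))
  }
  list(slope = slope, r2 = r2, n = n)
}

rate_estimate <- function(s0, rate, r2, window, n_points, branch, replicate,
                          low_quality = FALSE) {
  structure(
    list(s0 = s0, rate = rate, r2_loglinear = r2,
         window = window, n_points = n_points, branch = branch,
         replicate = replicate, low_quality = low_quality),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "%s rate at s0 = %.4g mg/L: %.5g 1/h (r2 = %.3f, %d points, window %g-%g h)%s\n",
    x$branch, x$s0, x$rate, x$r2_loglinear, x$n_points,
    x$window[1], x$window[2],
    if (isTRUE(x$low_quality)) " [low quality]" else ""))
  invisible(x)
}

#' @export
as.data.frame.rate_estimate <- function(x, ...) {
  data.frame(s0 = x$s0, branch = x$branch, rate = x$rate,
             r2 = x$r2_loglinear, window_start = x$window[1],
             window_end = x$window[2], n_points = x$n_points,
             replicate = x$replicate)
}

# default analysis window: drop a leading flat (lag) segment, and for the
# growth branch stop once substrate is exhausted (biomass plateaus there, so
# later points no longer reflect exponential growth)
default_window_idx <- function(curve, branch, detection_frac) {
  series <- if (branch == "growth") curve$biomass else curve$substrate
  idx <- seq_along(curve$times)
  # leading observations indistinguishable from the first (noiseless lag)
  flat <- abs(series - series[1]) <= 1e-9 * abs(series[1])
  n_flat <- match(FALSE, flat, nomatch = length(flat) + 1L) - 1L
  if (n_flat >= 2L && n_flat < length(idx))
    idx <- idx[-seq_len(n_flat - 1L)]   # keep last flat point as t0
  if (branch == "growth" && !is.null(curve$substrate)) {
    alive <- curve$substrate[idx] > detection_frac * curve$s0
    if (any(alive) && !all(alive)) {
      last <- max(which(alive)) + 1L    # include the exhaustion sample
      last <- max(last, 3L)             # never fewer than 3 points
      idx <- idx[seq_len(min(last, length(idx)))]
    }
  }
  idx
}

extract_rate <- function(curve, branch, window, detection_frac) {
  series <- if (branch == "growth") curve$biomass else curve$substrate
  what <- if (branch == "growth") "biomass" else "substrate"
  if (is.null(series))
    stop(sprintf("curve has no %s series", what), call. = FALSE)
  if (is.null(window)) {
    idx <- default_window_idx(curve, branch, detection_frac)
  } else {
    if (!is.numeric(window) || length(window) != 2L || window[1] >= window[2])
      stop("'window' must be c(t_start, t_end) with t_start < t_end",
           call. = FALSE)
    idx <- which(curve$times >= window[1] & curve$times <= window[2])
  }
  t <- curve$times[idx]
  y <- series[idx]
  if (branch == "degradation") {
    keep <- y > detection_frac * curve$s0   # points at/below detection excluded
    t <- t[keep]; y <- y[keep]
  } else if (any(y <= 0)) {
    stop("non-positive biomass in the analysis window; cannot take logs",
         call. = FALSE)
  }
  if (length(t) < 3L)
    stop(sprintf("fewer than 3 usable %s points in the analysis window", what),
         call. = FALSE)
  fit <- loglinear_fit(t, log(y))
  rate <- if (branch == "growth") fit$slope else -fit$slope
  rate_estimate(
    s0 = curve$s0, rate = rate, r2 = fit$r2,
    window = c(t[1], t[length(t)]), n_points = fit$n,
    branch = branch, replicate = curve$replicate)
}

#' Specific growth rate from a batch curve
#'
#' Estimates mu (1/h) as the least-squares slope of `ln(biomass)` against
#' time. By default the window runs from the end of any flat lag segment to
#' the sample after substrate exhaustion (when a substrate series is
#' available); pass `window = c(t_start, t_end)` to restrict the fit, e.g.
#' to the early exponential phase, or use [select_exponential_window()] to
#' pick the best log-linear stretch automatically.
#'
#' @param curve A [batch_curve()] with a biomass series.
#' @param window Optional time interval `c(t_start, t_end)`, h.
#' @param detection_frac Fraction of `s0` below which substrate is
#'   considered exhausted when delimiting the default window (default 0.01).
#' @return A `rate_estimate` with fields `s0`, `rate`, `r2_loglinear`,
#'   `window`, `n_points`, `branch`, `replicate`.
#' @export
specific_growth_rate <- function(curve, window = NULL, detection_frac = 0.01) {
  stopifnot(inherits(curve, "batch_curve"))
  extract_rate(curve, "growth", window, detection_frac)
}

#' Specific degradation rate from a batch curve
#'
#' Estimates q (1/h) as the least-squares slope of `-ln(S/S0)` against time
#' (equivalently, minus the slope of `ln(S)` vs t). Substrate observations
#' at or below the detection floor (`detection_frac * s0`, default 1%) are
#' excluded from the log fit.
#'
#' @inheritParams specific_growth_rate
#' @param curve A [batch_curve()] with a substrate series.
#' @return A `rate_estimate`, as for [specific_growth_rate()].
#' @export
specific_degradation_rate <- function(curve, window = NULL,
                                      detection_frac = 0.01) {
  stopifnot(inherits(curve, "batch_curve"))
  extract_rate(curve, "degradation", window, detection_frac)
}

#' Automatically delimit the exponential phase
#'
#' Scans every contiguous window of at least `min_points` samples and
#' returns the one maximising the log-linear r-squared, breaking ties
#' (within `1e-9`) in favour of more points, then of an earlier start. A
#' window is flagged `low_quality` when even the best r-squared falls below
#' `r2_threshold`, which on batch data usually means the curve never settled
#' into a single exponential stretch.
#'
#' @param curve A [batch_curve()].
#' @param branch `"growth"` or `"degradation"`.
#' @param min_points Minimum window size (default 3).
#' @param r2_threshold Quality floor for the returned window (default 0.90).
#' @param detection_frac Substrate detection floor as for
#'   [specific_degradation_rate()].
#' @return A list with `window` (`c(t_start, t_end)`), `r2`, `n_points`,
#'   and `low_quality`.
#' @export
select_exponential_window <- function(curve,
                                      branch = c("growth", "degradation"),
                                      min_points = 3L, r2_threshold = 0.90,
                                      detection_frac = 0.01) {
  stopifnot(inherits(curve, "batch_curve"))
  branch <- match.arg(branch)
  series <- if (branch == "growth") curve$biomass else curve$substrate
  if (is.null(series))
    stop(sprintf("curve has no %s series", branch), call. = FALSE)
  keep <- if (branch == "degradation")
    series > detection_frac * curve$s0 else series > 0
  t <- curve$times[keep]
  y <- log(series[keep])
  n <- length(t)
  if (n < 4L)
    stop("window selection needs at least 4 usable points", call. = FALSE)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      fit <- loglinear_fit(t[i:j], y[i:j])
      cand <- list(i = i, j = j, r2 = fit$r2, n = j - i + 1L)
      if (is.null(best)) { best <- cand; next }
      d <- cand$r2 - best$r2
      if (d > 1e-9 ||
          (abs(d) <= 1e-9 && (cand$n > best$n ||
                              (cand$n == best$n && cand$i < best$i))))
        best <- cand
    }
  }
  list(window = c(t[best$i], t[best$j]), r2 = best$r2, n_points = best$n,
       low_quality = best$r2 < r2_threshold)
}
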