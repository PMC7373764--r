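#' Fit the Haldane model to (S0, rate) points
#'
#' Nonlinear least squares of observed specific rates against
#' `haldane_rate(s0, p)` over the parameter triple `(rate_star, ks, ki)`.
#' The optimisation runs in log-parameter space (which enforces positivity
#' and conditions the very different scales of the three constants) with
#' box bounds of `[1e-6, 1e8]` on each parameter (the upper bound sits far
#' above any physically plausible constant so that near-Monod data, whose
#' `ki` is effectively infinite, are not truncated into a biased fit), using
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). Because the Haldane
#' objective is multimodal for sparse rate data, the fit is restarted from
#' `n_starts` initial points: a data-driven guess (`rate_star` at twice the
#' largest observed rate, `ks` at the substrate level of half-maximal rate,
#' `ki` at the largest tested `s0`) plus seeded log-uniform perturbations
#' of it by factors in `[0.1, 10]`. The best start by residual sum of
#' squares wins; exact ties go to the smaller `ks`.
#'
#' @param points A data.frame with columns `s0` and `rate` (a list of
#'   `rate_estimate` objects is coerced). At least 4 distinct `s0` values
#'   are required (3 free parameters plus one residual degree of freedom);
#'   replicate rates at the same `s0` all enter the loss.
#' @param branch `"growth"` or `"degradation"`, recorded on the fitted
#'   parameters.
#' @param init Optional named list overriding the data-driven start
#'   (`rate_star`, `ks`, `ki`).
#' @param n_starts Number of multistart restarts (default 10).
#' @param seed Seed for the restart perturbations (default 1; restarts are
#'   deterministic given the seed).
#' @param weights `"none"` (unweighted, the default) or `"inv_rate2"`
#'   (residuals scaled by 1/rate, i.e. squared loss weighted by 1/rate^2,
#'   down-weighting the large fast-growth residuals).
#' @return An object of class `haldane_fit`: `params`
#'   ([haldane_params()]), `derived` ([derived_kinetics()]), `r2`
#'   (1 - SSres/SStot), `r2_pearson` (squared Pearson correlation of
#'   observed and fitted, reported alongside since conventions differ),
#'   `residuals`, `fitted`, `ssr`, `n_points`, `converged`,
#'   `n_starts_used`.
#' @examples
#' p <- haldane_params(0.574, 20.29, 268.1)
#' s0 <- c(25, 50, 75, 100, 150, 250, 400, 600, 800, 1100)
#' fit <- fit_haldane(data.frame(s0 = s0, rate = haldane_rate(s0, p)))
#' fit$params$ks
#' @export
fit_haldane <- function(points, branch = c("growth", "degradation"),
                        init = NULL, n_starts = 10L, seed = 1L,
                        weights = c("none", "inv_rate2")) {
  branch <- match.arg(branch)
  weights <- match.arg(weights)
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, TRUE, "rate_estimate")))
    points <- do.call(rbind, lapply(points, as.data.frame))
  if (!is.data.frame(points) || !all(c("s0", "rate") %in% names(points)))
    stop("'points' must be a data.frame with columns 's0' and 'rate'",
         call. = FALSE)
  s0 <- points$s0
  rate <- points$rate
  if (any(!is.finite(s0)) || any(!is.finite(rate)))
    stop("non-finite values in 'points'", call. = FALSE)
  if (any(rate < 0))
    stop("negative rates cannot arise from the Haldane law", call. = FALSE)
  if (length(unique(s0)) < 4L)
    stop("insufficient data: need >= 4 distinct s0 values to fit 3 parameters",
         call. = FALSE)
  if (all(rate == 0))
    stop("degenerate data: all rates are zero", call. = FALSE)

  w <- if (weights == "inv_rate2") 1 / pmax(rate, 1e-8 * max(rate)) else
    rep(1, length(rate))

  resid_fn <- function(theta) {
    p <- exp(theta)
    w * (rate - p[1] * s0 / (p[2] + s0 + s0^2 / p[3]))
  }

  init <- init %||% default_haldane_init(s0, rate)
  theta0 <- log(c(init$rate_star, init$ks, init$ki))
  lb <- rep(log(1e-6), 3)
  ub <- rep(log(1e8), 3)
  theta0 <- pmin(pmax(theta0, lb), ub)
  starts <- with_seed(seed, {
    pert <- matrix(log(stats::runif(3 * max(n_starts - 1L, 0L), 0.1, 10)),
                   ncol = 3)
    rbind(rep(0, 3), pert)
  })
  starts <- sweep(starts, 2, theta0, `+`)
  starts <- pmin(pmax(starts, matrix(lb, nrow(starts), 3, byrow = TRUE)),
                 matrix(ub, nrow(starts), 3, byrow = TRUE))

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, gtol = 1e-8,
                                     maxfev = 2000, maxiter = 500)
  best <- NULL
  any_converged <- FALSE
  for (k in seq_len(nrow(starts))) {
    sol <- tryCatch(
      minpack.lm::nls.lm(par = starts[k, ], lower = lb, upper = ub,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(sol)) next
    ssr <- sum(sol$fvec^2)
    conv <- sol$info %in% 1:4
    any_converged <- any_converged || conv
    if (is.null(best) || ssr < best$ssr * (1 - 1e-12) ||
        (abs(ssr - best$ssr) <= 1e-12 * max(best$ssr, 1e-300) &&
         sol$par[2] < best$sol$par[2]))
      best <- list(sol = sol, ssr = ssr)
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)

  p_hat <- exp(best$sol$par)
  params <- haldane_params(p_hat[1], p_hat[2], p_hat[3], branch = branch)
  fitted <- haldane_rate(s0, params)
  res <- rate - fitted
  ss_tot <- sum((rate - mean(rate))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  r2p <- if (stats::sd(fitted) > 0 && stats::sd(rate) > 0)
    stats::cor(rate, fitted)^2 else NA_real_
  structure(
    list(params = params, derived = derived_kinetics(params),
         r2 = r2, r2_pearson = r2p, residuals = res, fitted = fitted,
         ssr = sum(res^2), n_points = length(rate),
         converged = any_converged, n_starts_used = nrow(starts),
         data = data.frame(s0 = s0, rate = rate)),
    class = "haldane_fit"
  )
}

# data-driven start: the observed rate maximum bounds rate_star from below
# (true max < rate_star), ks is read off the ascending limb at half-max,
# ki is at the scale of the largest tested substrate level
default_haldane_init <- function(s0, rate) {
  o <- order(s0)
  s0 <- s0[o]; rate <- rate[o]
  rmax <- max(rate)
  imax <- which.max(rate)
  half <- rmax / 2
  asc_s <- s0[seq_len(imax)]
  asc_r <- rate[seq_len(imax)]
  ks <- if (imax >= 2L && any(asc_r <= half)) {
    stats::approx(asc_r, asc_s, xout = half, ties = "ordered")$y
  } else NA_real_
  if (!is.finite(ks) || ks <= 0) ks <- max(min(s0[s0 > 0], na.rm = TRUE), 1)
  list(rate_star = 2 * rmax, ks = ks, ki = max(s0))
}

#' @export
print.haldane_fit <- function(x, ...) {
  lab <- if (x$params$branch == "growth")
    c("mu*", "Ks", "Ki", "Sm", "mu_max") else
    c("q*", "Ks'", "Ki'", "Sm'", "q_max")
  cat(sprintf("Haldane %s fit (%d points, %d starts%s):\n",
              x$params$branch, x$n_points, x$n_starts_used,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  %s = %.4g 1/h, %s = %.4g mg/L, %s = %.4g mg/L\n",
              lab[1], x$params$rate_star, lab[2], x$params$ks,
              lab[3], x$params$ki))
  cat(sprintf("  %s = %.4g mg/L, %s = %.4g 1/h, R2 = %.4f\n",
              lab[4], x$derived$s_m, lab[5], x$derived$true_max_rate, x$r2))
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` with the total sum of squares taken about the mean of
#' the observations. This is the regression R-squared; the squared Pearson
#' correlation (which some kinetics reports quote instead) coincides with
#' it only for linear fits with intercept, so [fit_haldane()] reports both.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return R-squared (can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) != length(predicted) || length(observed) < 2L)
    stop("'observed' and 'predicted' must be numeric, equal length >= 2",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0)
    stop("observed values have zero variance; R-squared is undefined",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}
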