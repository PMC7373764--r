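# Independent oracles, deliberately naive: these re-derive expected values
# by brute force so the package code paths they check are never reused.

# fine-step explicit Euler integration of dX/dt = mu(S) X, dS/dt = -q(S) S
# (haldane_rate is the shared rate law under test elsewhere; the dynamics
# assembly and integration here are independent of simulate_batch)
euler_batch <- function(pg, pd, x0, s0, times, dt = 1e-3) {
  hal <- function(s, p) p$rate_star * s / (p$ks + s + s^2 / p$ki)
  t_end <- max(times)
  n <- ceiling(t_end / dt)
  tgrid <- seq(0, by = dt, length.out = n + 1)
  x <- numeric(n + 1); s <- numeric(n + 1)
  x[1] <- x0; s[1] <- s0
  for (i in seq_len(n)) {
    x[i + 1] <- x[i] + dt * hal(s[i], pg) * x[i]
    s[i + 1] <- max(s[i] - dt * hal(s[i], pd) * s[i], 0)
  }
  list(X = stats::approx(tgrid, x, xout = times)$y,
       S = stats::approx(tgrid, s, xout = times)$y)
}

# exhaustive search over contiguous windows: best r2, then more points,
# then earlier start (lm() is the slope/r2 oracle)
brute_force_window <- function(t, y, min_points = 3L) {
  n <- length(t)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      fit <- suppressWarnings(summary(stats::lm(y[i:j] ~ t[i:j])))
      r2 <- if (is.nan(fit$r.squared)) 0 else fit$r.squared
      cand <- list(i = i, j = j, r2 = r2, n = j - i + 1L)
      better <- is.null(best) ||
        cand$r2 - best$r2 > 1e-9 ||
        (abs(cand$r2 - best$r2) <= 1e-9 &&
         (cand$n > best$n || (cand$n == best$n && cand$i < best$i)))
      if (better) best <- cand
    }
  }
  c(t[best$i], t[best$j])
}

# random valid Haldane parameter sets spanning realistic kinetic scales
random_haldane <- function(n, seed, branch = "growth") {
  with_seed_local(seed, {
    lapply(seq_len(n), function(i)
      haldane_params(
        rate_star = exp(stats::runif(1, log(0.05), log(2))),
        ks = exp(stats::runif(1, log(1), log(500))),
        ki = exp(stats::runif(1, log(50), log(5000))),
        branch = branch))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

phenol_cal <- function() linear_calibration(0.002447, 0.1423)

published_growth <- function() haldane_params(0.574, 20.29, 268.1)
published_degradation <- function()
  haldane_params(1.244, 9.152, 517.5, branch = "degradation")
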