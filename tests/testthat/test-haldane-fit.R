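fit_grid <- c(25, 50, 75, 100, 150, 250, 400, 600, 800, 1100)

test_that("noise-free rates are fitted back to the generating parameters", {
  p <- published_growth()
  pts <- data.frame(s0 = fit_grid, rate = haldane_rate(fit_grid, p))
  fit <- fit_haldane(pts)
  expect_equal(fit$params$rate_star, p$rate_star, tolerance = 1e-6)
  expect_equal(fit$params$ks, p$ks, tolerance = 1e-6)
  expect_equal(fit$params$ki, p$ki, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_length(fit$residuals, nrow(pts))
  # derived quantities flow from the fitted parameters
  expect_equal(fit$derived$s_m, critical_substrate(fit$params))
})

test_that("Monod-generated rates drive the fitted ki to the uninhibited regime", {
  p <- haldane_params(0.4, 15, Inf)
  pts <- data.frame(s0 = fit_grid, rate = haldane_rate(fit_grid, p))
  fit <- fit_haldane(pts)
  expect_gt(fit$params$ki, 1e4 * fit$params$ks)
  expect_equal(haldane_rate(fit_grid, fit$params),
               0.4 * fit_grid / (15 + fit_grid), tolerance = 1e-4)
})

test_that("degenerate inputs are rejected with specific errors", {
  expect_error(fit_haldane(data.frame(s0 = c(10, 20, 30),
                                      rate = c(0.1, 0.2, 0.15))),
               "insufficient data")
  # replicates do not count toward distinct substrate levels
  expect_error(fit_haldane(data.frame(s0 = rep(c(10, 20), 4),
                                      rate = runif(8))),
               "insufficient data")
  expect_error(fit_haldane(data.frame(s0 = c(10, 20, 30, 40),
                                      rate = rep(0, 4))),
               "degenerate")
  expect_error(fit_haldane(data.frame(s0 = c(10, 20, 30, 40),
                                      rate = c(0.1, -0.2, 0.3, 0.2))),
               "negative")
})

test_that("r_squared follows 1 - SSres/SStot", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(r_squared(1, 1), "equal length")
})

test_that("fit is scale-equivariant in the rates", {
  p <- published_degradation()
  pts <- data.frame(s0 = fit_grid, rate = haldane_rate(fit_grid, p))
  f1 <- fit_haldane(pts, branch = "degradation")
  pts$rate <- pts$rate * 3.7
  f2 <- fit_haldane(pts, branch = "degradation")
  expect_equal(f2$params$rate_star, 3.7 * f1$params$rate_star,
               tolerance = 1e-5)
  expect_equal(f2$params$ks, f1$params$ks, tolerance = 1e-5)
  expect_equal(f2$params$ki, f1$params$ki, tolerance = 1e-5)
})

test_that("multistart recovery holds across random parameter sets", {
  for (p in random_haldane(20, seed = 7)) {
    pts <- data.frame(s0 = fit_grid, rate = haldane_rate(fit_grid, p))
    fit <- fit_haldane(pts)
    expect_equal(fit$params$rate_star, p$rate_star, tolerance = 1e-5)
    expect_equal(fit$params$ks, p$ks, tolerance = 1e-5)
    expect_equal(fit$params$ki, p$ki, tolerance = 1e-5)
  }
})

test_that("a list of rate estimates is accepted as input", {
  p <- published_growth()
  scn <- simulation_scenario(p, published_degradation(), s0_grid = fit_grid,
                             replicates = 1L, noise_cv = 0, seed = 2)
  pts <- generate_rate_points(scn, noise_sd = 0)
  fit <- fit_haldane(pts)
  expect_equal(fit$params$ks, p$ks, tolerance = 1e-6)
})
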