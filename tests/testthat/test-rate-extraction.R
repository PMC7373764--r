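test_that("exact exponential series recover the generating rate", {
  t <- seq(0, 48, by = 12)
  cv <- batch_curve(t, s0 = 100, biomass = 50 * exp(0.2 * t))
  est <- specific_growth_rate(cv)
  expect_equal(est$rate, 0.2, tolerance = 1e-10)
  expect_equal(est$r2_loglinear, 1, tolerance = 1e-10)
  # invariant to the window chosen
  est_w <- specific_growth_rate(cv, window = c(12, 48))
  expect_equal(est_w$rate, 0.2, tolerance = 1e-10)
  expect_equal(est_w$n_points, 4L)

  cs <- batch_curve(t, s0 = 1000, substrate = 1000 * exp(-0.05 * t))
  est_d <- specific_degradation_rate(cs)
  expect_equal(est_d$rate, 0.05, tolerance = 1e-10)
})

test_that("flat series yield zero rate with r2 reported as 0", {
  t <- seq(0, 60, by = 12)
  cv <- batch_curve(t, s0 = 100, biomass = rep(80, length(t)),
                    substrate = rep(100, length(t)))
  g <- specific_growth_rate(cv)
  expect_equal(g$rate, 0)
  expect_equal(g$r2_loglinear, 0)
  d <- specific_degradation_rate(cv)
  expect_equal(d$rate, 0)
})

test_that("sign conventions: growth and depletion both give positive rates", {
  t <- seq(0, 72, by = 12)
  cv <- batch_curve(t, s0 = 500, biomass = 30 * exp(0.1 * t),
                    substrate = 500 * exp(-0.08 * t))
  expect_gt(specific_growth_rate(cv)$rate, 0)
  expect_gt(specific_degradation_rate(cv)$rate, 0)
})

test_that("degradation fit excludes points below the detection floor", {
  t <- seq(0, 72, by = 12)
  s <- 1000 * exp(-0.15 * t)   # drops below 1% of s0 after ~31 h
  cv <- batch_curve(t, s0 = 1000, substrate = s)
  est <- specific_degradation_rate(cv)
  expect_true(all(s[t <= est$window[2]] > 10))
  expect_equal(est$rate, 0.15, tolerance = 1e-10)
  # a series entirely at the floor cannot be fitted
  dead <- suppressWarnings(
    batch_curve(t, s0 = 1000, substrate = rep(0.5, length(t))))
  expect_error(specific_degradation_rate(dead), "fewer than 3")
})

test_that("non-positive biomass in the window is an error", {
  t <- seq(0, 48, by = 12)
  cv <- batch_curve(t, s0 = 100, biomass = c(0, 10, 20, 40, 80))
  expect_error(specific_growth_rate(cv, window = c(0, 48)), "non-positive")
})

test_that("window selection matches exhaustive search", {
  t <- seq(0, 96, by = 12)
  # 12 h lag then clean exponential: the lag points must be excluded
  x_lag <- c(50, 50, 50 * exp(0.15 * (t[3:9] - 12)))
  cv <- batch_curve(t, s0 = 500, biomass = x_lag)
  sel <- select_exponential_window(cv, "growth")
  expect_equal(sel$window, brute_force_window(t, log(x_lag)))
  expect_false(sel$low_quality)
  expect_equal(sel$window[1], 12)  # lag excluded, exponential origin kept

  # no lag: the full series is the best window
  x <- 50 * exp(0.15 * t)
  sel2 <- select_exponential_window(batch_curve(t, 500, biomass = x), "growth")
  expect_equal(sel2$window, c(0, 96))

  # noise: the chosen window still matches the exhaustive search
  y <- with_seed_local(5, exp(stats::rnorm(length(t), 3, 0.5)))
  sel3 <- select_exponential_window(batch_curve(t, 500, biomass = y), "growth")
  expect_equal(sel3$window, brute_force_window(t, log(y)))

  # a sawtooth admits no log-linear window at all: flagged low quality
  saw <- exp(rep(c(2, 4), length.out = length(t)))
  sel4 <- select_exponential_window(batch_curve(t, 500, biomass = saw), "growth")
  expect_true(sel4$low_quality)
  expect_equal(sel4$window, brute_force_window(t, log(saw)))
})

test_that("windowed estimates approach the instantaneous Haldane rate", {
  # fine sampling so that early windows see substrate still near s0
  scn <- simulation_scenario(published_growth(), published_degradation(),
                             sampling_interval = 0.25, horizon = 12,
                             noise_cv = 0, seed = 1)
  cv <- simulate_batch(scn, 100)[[1]]
  mu_true <- haldane_rate(100, published_growth())
  est <- specific_growth_rate(cv, window = c(0, 0.75))
  expect_equal(est$rate, mu_true, tolerance = 0.02)
  # shrinking the window moves the estimate closer still
  est_wide <- specific_growth_rate(cv, window = c(0, 3))
  expect_lt(abs(est$rate - mu_true), abs(est_wide$rate - mu_true))

  scn_d <- simulation_scenario(published_growth(), published_degradation(),
                               sampling_interval = 0.05, horizon = 2,
                               noise_cv = 0, seed = 1)
  cd <- simulate_batch(scn_d, 60)[[1]]
  q_true <- haldane_rate(60, published_degradation())
  est_d <- specific_degradation_rate(cd, window = c(0, 0.15))
  expect_equal(est_d$rate, q_true, tolerance = 0.02)
})

test_that("batch curves validate their structure", {
  expect_error(batch_curve(c(0, 12, 12), 100, biomass = c(1, 2, 3)),
               "strictly increasing")
  expect_error(batch_curve(c(0, 12, 24), 100), "at least one")
  expect_error(batch_curve(c(0, 12, 24), 100, biomass = c(1, -2, 3)),
               "negative")
  expect_warning(batch_curve(c(0, 12, 24), 100,
                             substrate = c(80, 50, 20)),
                 "differs from nominal")
})
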