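test_that("degradation switched off leaves substrate constant and growth exponential", {
  pg <- haldane_params(0.574, 20.29, 268.1)
  pd_off <- haldane_params(1e-6, 9.152, 517.5, branch = "degradation")
  scn <- simulation_scenario(pg, pd_off, noise_cv = 0, seed = 1,
                             replicates = 1L, horizon = 48)
  cv <- simulate_batch(scn, 100)[[1]]
  expect_equal(cv$substrate, rep(100, length(cv$times)), tolerance = 1e-3)
  # with S pinned at s0, growth is exponential at mu(s0)
  mu <- haldane_rate(100, pg)
  expect_equal(cv$biomass, scn$x0 * exp(mu * cv$times), tolerance = 1e-4)
})

test_that("sampled trajectories agree with a fine-step independent integration", {
  scn <- simulation_scenario(published_growth(), published_degradation(),
                             noise_cv = 0, seed = 1, replicates = 1L)
  cv <- simulate_batch(scn, 1000)[[1]]
  oracle <- euler_batch(published_growth(), published_degradation(),
                        x0 = scn$x0, s0 = 1000, times = cv$times, dt = 1e-3)
  expect_equal(cv$biomass, oracle$X, tolerance = 2e-3)
  expect_equal(cv$substrate, oracle$S, tolerance = 2e-3)
  # monotone while substrate remains, exhausted within the horizon
  expect_true(all(diff(cv$substrate) <= 0))
  alive <- cv$substrate > 0.1
  expect_true(all(diff(cv$biomass[alive]) > 0))
  expect_lt(cv$substrate[length(cv$substrate)], 1)
})

test_that("mass monotonicity holds for random parameters with noise off", {
  pars <- random_haldane(10, seed = 9)
  for (k in seq_along(pars)) {
    pg <- pars[[k]]
    pd <- haldane_params(pars[[k]]$rate_star * 1.5, pars[[k]]$ks,
                         pars[[k]]$ki, branch = "degradation")
    scn <- simulation_scenario(pg, pd, noise_cv = 0, seed = k,
                               replicates = 1L)
    cv <- simulate_batch(scn, 500)[[1]]
    expect_true(all(diff(cv$substrate) <= 1e-12))
    expect_true(all(diff(cv$biomass) >= -1e-12))
  }
})

test_that("halving the integrator step leaves sampled values unchanged", {
  scn <- simulation_scenario(published_growth(), published_degradation(),
                             noise_cv = 0, seed = 1, replicates = 1L)
  h <- scn$sampling_interval / 100
  a <- simulate_batch(scn, 800, internal_step = h)[[1]]
  b <- simulate_batch(scn, 800, internal_step = h / 2)[[1]]
  expect_equal(a$biomass, b$biomass, tolerance = 1e-6)
  expect_equal(a$substrate, b$substrate, tolerance = 1e-6)
})

test_that("the lag rule freezes the state at high substrate", {
  scn <- simulation_scenario(published_growth(), published_degradation(),
                             noise_cv = 0, seed = 1, replicates = 1L)
  cv <- simulate_batch(scn, 1117)[[1]]   # above the 1000 mg/L threshold
  expect_equal(cv$biomass[cv$times <= 12], rep(scn$x0, 2))
  expect_equal(cv$substrate[cv$times <= 12], rep(1117, 2))
  expect_gt(cv$biomass[3], scn$x0)
  # below the threshold: no lag
  cv2 <- simulate_batch(scn, 800)[[1]]
  expect_gt(cv2$biomass[2], scn$x0)
})

test_that("seeded runs are bit-reproducible and seeds differ", {
  scn <- simulation_scenario(published_growth(), published_degradation(), seed = 42)
  a <- simulate_batch(scn, 400)
  b <- simulate_batch(scn, 400)
  expect_identical(a, b)
  scn2 <- simulation_scenario(published_growth(), published_degradation(), seed = 43)
  c <- simulate_batch(scn2, 400)
  expect_false(identical(a[[1]]$biomass, c[[1]]$biomass))
  # replicates within a run carry independent noise
  expect_false(identical(a[[1]]$biomass, a[[2]]$biomass))
})

test_that("multiplicative noise is mean-one", {
  scn <- simulation_scenario(published_growth(), published_degradation(),
                             s0_grid = 100, noise_cv = 0.05,
                             replicates = 1L, seed = 6)
  n <- 1e4
  true_value <- 123.4
  obs <- with_seed_local(6, haldane:::apply_mult_noise(rep(true_value, n), 0.05))
  expect_equal(mean(obs), true_value, tolerance = 3 * 0.05 / sqrt(n))
  expect_true(all(obs >= 0))
  expect_equal(stats::sd(obs) / mean(obs), 0.05, tolerance = 0.05)
})

test_that("direct rate generation matches the law and responds to noise", {
  scn <- simulation_scenario(published_growth(), published_degradation(),
                             replicates = 2L, seed = 4)
  pts <- generate_rate_points(scn, noise_sd = 0)
  expect_equal(pts$rate,
               haldane_rate(pts$s0, published_growth()))
  fit <- fit_haldane(pts)
  expect_equal(fit$params$ki, 268.1, tolerance = 1e-5)
  # heavy noise degrades the fit quality visibly
  noisy <- generate_rate_points(scn, noise_sd = 0.5)
  fit_noisy <- fit_haldane(noisy)
  expect_lt(fit_noisy$r2, 0.9)
  expect_true(all(noisy$rate >= 0))
})
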