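test_that("transition moments honour the continuity and stationary limits", {
  tm0 <- transition_moments(0.5, 0.8, 1e-10)
  expect_lt(abs(tm0$f_vv - 1), 1e-9)
  expect_lt(abs(tm0$f_xv), 1e-9)
  expect_lt(max(tm0$q_xx, abs(tm0$q_xv), tm0$q_vv), 1e-9)
  # long interval: velocity variance at stationarity, autocorrelation gone
  tml <- transition_moments(0.5, 0.8, 500)
  expect_equal(tml$q_vv, 0.8^2 / (2 * 0.5), tolerance = 1e-12)
  expect_lt(tml$f_vv, 1e-100)
  # just below the series switch point the expansion matches the closed
  # forms evaluated directly (cancellation is still mild at x ~ 1e-4)
  beta <- 2; sigma <- 1.3; delta <- 0.49e-4   # x = 0.98e-4, series branch
  tm <- transition_moments(beta, sigma, delta)
  e1 <- exp(-beta * delta); e2 <- exp(-2 * beta * delta)
  expect_equal(tm$f_xv, (1 - e1) / beta, tolerance = 1e-9)
  expect_equal(tm$q_vv, sigma^2 / (2 * beta) * (1 - e2), tolerance = 1e-9)
  expect_equal(tm$q_xv, sigma^2 / (2 * beta^2) * (1 - e1)^2, tolerance = 1e-7)
  expect_equal(tm$q_xx,
               sigma^2 / beta^2 * (delta - 2 * (1 - e1) / beta +
                                     (1 - e2) / (2 * beta)),
               tolerance = 1e-4)  # closed form itself cancels ~8 digits here
  expect_error(transition_moments(-1, 1, 1), "positive")
})

test_that("transition moments agree with Euler-Maruyama SDE simulation", {
  set.seed(21)
  beta <- 0.6; sigma <- 1.1; delta <- 1.5; v0 <- 2
  em <- simulate_ou_em(beta, sigma, delta, v0 = v0, dt = 1e-3, nrep = 4e4)
  tm <- transition_moments(beta, sigma, delta)
  n <- nrow(em)
  # means against f_xv, f_vv within 3 Monte-Carlo SEs
  expect_lt(abs(mean(em[, 1]) - v0 * tm$f_xv), 3 * sd(em[, 1]) / sqrt(n))
  expect_lt(abs(mean(em[, 2]) - v0 * tm$f_vv), 3 * sd(em[, 2]) / sqrt(n))
  # second moments within 3 SEs (variance SE ~ var * sqrt(2/n))
  expect_lt(abs(var(em[, 1]) - tm$q_xx), 3 * var(em[, 1]) * sqrt(2 / n))
  expect_lt(abs(var(em[, 2]) - tm$q_vv), 3 * var(em[, 2]) * sqrt(2 / n))
  expect_lt(abs(cov(em[, 1], em[, 2]) - tm$q_xv),
            3 * sqrt((var(em[, 1]) * var(em[, 2]) +
                        cov(em[, 1], em[, 2])^2) / n))
})

test_that("Kalman marginal likelihood equals the joint-Gaussian oracle", {
  for (seed in 1:8) {
    trk <- random_track(n = sample(3:12, 1), seed = 100 + seed)
    a <- ctcrw_loglik(trk$times, trk$obs, trk$sd_x, trk$sd_y,
                      trk$sigma, trk$beta)
    b <- joint_gaussian_loglik(trk$times, trk$obs, trk$sd_x, trk$sd_y,
                               trk$sigma, trk$beta)
    expect_lt(abs(a - b), 1e-8)
  }
})

test_that("likelihood is translation invariant and penalises inflated errors", {
  trk <- random_track(10, seed = 42)
  a <- ctcrw_loglik(trk$times, trk$obs, trk$sd_x, trk$sd_y, trk$sigma, trk$beta)
  b <- ctcrw_loglik(trk$times, trk$obs + 100, trk$sd_x, trk$sd_y,
                    trk$sigma, trk$beta)
  expect_lt(abs(a - b), 1e-6)
  # doubling observation SDs lowers the likelihood of a well-fit track
  set.seed(43)
  times <- cumsum(c(0, runif(199, 0.5, 2)))
  sig <- rep(0.5, 199); bet <- rep(0.3, 199)
  sdv <- rep(0.5, 200)
  sim <- simulate_states(times, sig, bet, sdv, sdv)
  l1 <- ctcrw_loglik(times, sim$obs, sdv, sdv, sig, bet)
  l2 <- ctcrw_loglik(times, sim$obs, 2 * sdv, 2 * sdv, sig, bet)
  expect_gt(l1, l2)
  expect_error(ctcrw_loglik(times, sim$obs, sdv * 0, sdv, sig, bet), "positive")
})

test_that("RTS smoothing contracts towards the truth with proper variances", {
  set.seed(44)
  n <- 250
  times <- cumsum(c(0, runif(n - 1, 0.5, 2)))
  sig <- rep(0.5, n - 1); bet <- rep(0.25, n - 1)
  sdv <- rep(2, n)
  sim <- simulate_states(times, sig, bet, sdv, sdv, start = c(50, -30))
  sm <- smooth_states(times, sim$obs, sdv, sdv, sig, bet)
  # smoothed positions beat raw observations against the simulated truth
  rmse_obs <- sqrt(mean((sim$obs[, 1] - sim$states$x)^2 +
                          (sim$obs[, 2] - sim$states$y)^2))
  rmse_sm <- sqrt(mean((sm$x - sim$states$x)^2 + (sm$y - sim$states$y)^2))
  expect_lt(rmse_sm, rmse_obs)
  # smoothing never inflates the filtered position variance
  expect_true(all(sm$var_x <= sm$fvar_x + 1e-9))
  expect_true(all(sm$var_y <= sm$fvar_y + 1e-9))
  expect_true(all(sm$var_x > -1e-10))
  # zero observation error: smoothed positions equal the observations
  tiny <- rep(1e-8, n)
  sm0 <- smooth_states(times, sim$obs, tiny, tiny, sig, bet)
  expect_equal(sm0$x, sim$obs[, 1], tolerance = 1e-6)
  expect_equal(sm0$y, sim$obs[, 2], tolerance = 1e-6)
})

test_that("state simulation is seed-reproducible with the right autocorrelation", {
  times <- seq(0, 400, by = 2)
  n <- length(times)
  sig <- rep(0.6, n - 1); bet <- rep(0.15, n - 1)
  sdv <- rep(1, n)
  a <- simulate_states(times, sig, bet, sdv, sdv, seed = 9)
  b <- simulate_states(times, sig, bet, sdv, sdv, seed = 9)
  expect_identical(a, b)
  # pooled lag-one velocity autocorrelation across replicates ~ e^(-beta*dt);
  # the band allows the O(1/n) small-sample bias of the correlation
  # estimator on top of Monte-Carlo error
  set.seed(45)
  acs <- replicate(60, {
    s <- simulate_states(times, sig, bet, sdv, sdv)$states
    cor(s$vx[-n], s$vx[-1])
  })
  expect_lt(abs(mean(acs) - exp(-0.15 * 2)),
            3 * sd(acs) / sqrt(60) + 2 / n)
})

test_that("likelihood at the generating parameters beats a perturbed alternative", {
  set.seed(46)
  diffs <- replicate(150, {
    times <- cumsum(c(0, runif(29, 0.5, 3)))
    sig <- rep(0.5, 29); bet <- rep(0.3, 29)
    sdv <- rep(0.8, 30)
    sim <- simulate_states(times, sig, bet, sdv, sdv)
    ctcrw_loglik(times, sim$obs, sdv, sdv, sig, bet) -
      ctcrw_loglik(times, sim$obs, sdv, sdv, 1.2 * sig, bet)
  })
  expect_gt(mean(diffs), 0)
})
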