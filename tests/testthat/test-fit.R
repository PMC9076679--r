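test_that("link evaluation follows the log-linear algebra", {
  X <- matrix(c(2, 0, -1), ncol = 1, dimnames = list(NULL, "SST"))
  th0 <- c(A0 = 0, A_SST = 0, B0 = 0, B_SST = 0)
  lp <- linear_predictors(th0, X, covariates = "SST")
  expect_equal(lp$sigma, c(1, 1))
  expect_equal(lp$beta, c(1, 1))
  expect_equal(lp$p, c(3, 3))
  th <- c(A0 = 0, A_SST = 0.5, B0 = 0, B_SST = 0)
  expect_equal(linear_predictors(th, X, covariates = "SST")$sigma[1], exp(1))
  # group offset multiplies sigma by e^a0 at X = 0
  thg <- c(A0 = 0.2, A_SST = 0, B0 = 0, B_SST = 0,
           a0 = 0.7, a_SST = 0, b0 = 0, b_SST = 0)
  X0 <- matrix(0, 2, 1, dimnames = list(NULL, "SST"))
  s0 <- linear_predictors(thg, X0, G = 0, covariates = "SST")$sigma[1]
  s1 <- linear_predictors(thg, X0, G = 1, covariates = "SST")$sigma[1]
  expect_equal(s1 / s0, exp(0.7))
  # p = 3 / beta wherever parameters are materialised
  sim <- small_regional_sim()
  for (pr in sim$truth$params) expect_equal(pr$p, 3 / pr$beta)
})

test_that("pooled likelihood is the sum of per-animal likelihoods and is
           invariant to covariate reordering", {
  sim <- small_regional_sim()
  fit <- ctcrw_fit(~ SST + ICE08, sim$fleet)
  by_hand <- sum(vapply(fit$data, function(d) {
    lp <- linear_predictors(coef(fit), d$X, d$G, fit$covariates)
    n <- length(d$times_h)
    ctcrw_loglik(d$times_h, d$y, d$sd_x, d$sd_y,
                 lp$sigma[seq_len(n - 1)], lp$beta[seq_len(n - 1)])
  }, numeric(1)))
  expect_equal(fit$logLik, by_hand, tolerance = 1e-8)
  # reordered covariates, permuted coefficients: same likelihood
  dat2 <- crwlink:::.fit_data(sim$fleet, c("ICE08", "SST"), "none")
  th2 <- coef(fit)[c("A0", "A_ICE08", "A_SST", "B0", "B_ICE08", "B_SST")]
  ll2 <- -crwlink:::.fleet_negloglik(th2, dat2, c("ICE08", "SST"), FALSE, 1e6)
  expect_equal(ll2, fit$logLik, tolerance = 1e-10)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik)
  expect_equal(unname(AIC(fit)), fit$AIC)
})

test_that("an intercept-only individual fit recovers its movement scales", {
  set.seed(55)
  n <- 400
  times <- cumsum(c(0, runif(n - 1, 1, 3)))
  sig_t <- 0.6; bet_t <- 0.12
  sdv <- rep(0.8, n)
  sim <- simulate_states(times, rep(sig_t, n - 1), rep(bet_t, n - 1), sdv, sdv)
  fx <- data.frame(time = as.POSIXct("2020-01-01", tz = "UTC") + times * 3600,
                   lon = 0, lat = 0, x = sim$obs[, 1], y = sim$obs[, 2],
                   sd_x = sdv, sd_y = sdv)
  fleet <- ctcrw_fleet(list(ctcrw_track("w1", fx)), covariates = character(0))
  fit <- ctcrw_fit(~1, fleet)
  expect_true(fit$convergence)
  expect_lt(abs(coef(fit)[["A0"]] - log(sig_t)), 3 * fit$se[["A0"]])
  expect_lt(abs(coef(fit)[["B0"]] - log(bet_t)), 3 * fit$se[["B0"]])
  # methods on the fitted object stay coherent
  expect_equal(attr(logLik(fit), "df"), 2)
  expect_equal(nrow(fitted(fit)), n - 1)
  r <- residuals(fit)
  expect_equal(nrow(r), n)
  expect_lt(abs(sd(r$rx[-1]) - 1), 0.2)  # innovations near-standardised
  pr <- predict(fit, data.frame(G = 0))
  expect_equal(pr$p, 3 / pr$beta)
})

test_that("individual fits drop invariant covariates with a warning", {
  sim <- small_regional_sim()
  fleet <- sim$fleet
  fleet$tracks[[1]]$fixes$ICE08 <- 0   # this whale never met ice
  sub <- ctcrw_fleet(fleet$tracks[1], std = fleet$std,
                     covariates = fleet$covariates)
  expect_warning(ctcrw_fit(~ SST + ICE08, sub, mode = "I"), "invariant")
  fits <- suppressWarnings(ctcrw_fit(~ SST + ICE08, fleet, mode = "I"))
  expect_s3_class(fits, "ctcrw_fit_list")
  expect_length(fits, length(fleet$tracks))
  expect_false("A_ICE08" %in% names(coef(fits[[1]])))
  expect_true(all(c("A_SST", "B_SST") %in% names(coef(fits[[1]]))))
})

test_that("model enumeration respects forbidden pairs and groupings", {
  expect_length(enumerate_models(c("A", "B", "C")), 7)
  specs <- enumerate_models(c("SST", "CHL"), forbidden = list(c("SST", "CHL")))
  expect_setequal(vapply(specs, function(s) paste(s$covariates, collapse = "+"),
                         character(1)), c("SST", "CHL"))
  # the humpback pools: SST/CHL/DSB mutually exclusive, ICE08/ICE10 exclusive
  pool <- c("DEPTH", "SST", "SSTA", "CHL", "CURL", "DSB", "ICE08", "ICE10")
  forb <- list(c("SST", "CHL"), c("SST", "DSB"), c("CHL", "DSB"),
               c("ICE08", "ICE10"))
  specs <- enumerate_models(pool, forb, groupings = c("none", "sex", "period"))
  keys <- names(specs)
  expect_true("DEPTH+SST+SSTA+CURL+ICE08|sex" %in% keys)
  has <- function(v) vapply(specs, function(s) v %in% s$covariates, logical(1))
  expect_false(any(has("SST") & has("CHL")))
  expect_false(any(has("SST") & has("DSB")))
  expect_false(any(has("ICE08") & has("ICE10")))
})

test_that("AIC ranking is stable, ties resolved by name", {
  mk <- function(ll, k, covs, nm) {
    structure(list(logLik = ll, k = k, AIC = 2 * k - 2 * ll,
                   covariates = covs, grouping = "none", convergence = TRUE),
              class = "ctcrw_fit")
  }
  fits <- list(b = mk(-100, 4, "X", "b"), a = mk(-100, 4, "Y", "a"),
               c = mk(-90, 6, "Z", "c"))
  tab <- aic_table(fits)
  expect_equal(tab$AIC[tab$model == "b"], 208)
  expect_equal(tab$dAIC[1], 0)
  expect_equal(tab$model[1], "c")
  expect_equal(tab$model[2:3], c("a", "b"))   # equal AIC: alphabetical
})

test_that("ice-effect ratios follow the displayed closed forms", {
  th <- c(A0 = 1, A_ICE08 = -0.5, B0 = 0, B_ICE08 = 0.3,
          a0 = 0, a_ICE08 = -0.2, b0 = 0, b_ICE08 = 1.1)
  expect_equal(ice_effect_ratio(th, "sigma", "reference"), exp(0.5))
  expect_equal(ice_effect_ratio(th, "sigma", "deviated"), exp(0.7))
  expect_equal(ice_effect_ratio(th, "beta", "deviated"), exp(-1.4))
  expect_equal(ice_effect_ratio(c(A0 = 1, A_ICE08 = 0, B0 = 0, B_ICE08 = 0),
                                "sigma"), 1)
  expect_error(ice_effect_ratio(c(A0 = 1, B0 = 0), "sigma"), "ICE08")
})

test_that("a grouped pooled fit detects a strong group deviation", {
  cfg <- sim_config(migratory = FALSE, n_animals = 8L, n_mothers = 4L,
                    n_fixes = 80L, grouping = "sex",
                    theta = c(A0 = -1.0, A_SST = 0.3, B0 = -2.8, B_SST = -0.5,
                              a0 = -0.8, a_SST = 0, b0 = 0.9, b_SST = 0))
  cfg$covariates <- "SST"
  sim <- sim_fleet(cfg, seed = 77)
  fit <- ctcrw_fit(~SST, sim$fleet, grouping = "sex")
  expect_true(all(c("a0", "b0") %in% names(coef(fit))))
  expect_lt(abs(coef(fit)[["a0"]] + 0.8), 3 * fit$se[["a0"]])
  expect_lt(abs(coef(fit)[["b0"]] - 0.9), 3 * fit$se[["b0"]])
  expect_error(ctcrw_fit(~SST, sim$fleet, grouping = "period"), "both groups")
})
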