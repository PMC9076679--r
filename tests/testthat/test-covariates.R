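test_that("grid sampling is bilinear, masked-aware, and extent-checked", {
  g <- lonlat_grid(0:10, 0:10, matrix(7, 11, 11))
  expect_equal(unname(sample_grid(g, c(0.5, 3.7, 10), c(2.2, 9.9, 0))[1:3]),
               rep(7, 3))
  # exact on a linear plane: v = 2 lon - 3 lat + 1
  lon <- seq(0, 10, 0.5); lat <- seq(0, 10, 0.5)
  pl <- outer(lon, lat, function(a, b) 2 * a - 3 * b + 1)
  gp <- lonlat_grid(lon, lat, pl)
  set.seed(2)
  qlon <- runif(50, 0, 10); qlat <- runif(50, 0, 10)
  expect_equal(unname(sample_grid(gp, qlon, qlat)[1:50]),
               2 * qlon - 3 * qlat + 1, tolerance = 1e-6)
  # masked (land) corner makes the sample missing
  pl[5, 5] <- NA
  gm <- lonlat_grid(lon, lat, pl)
  expect_true(is.na(suppressWarnings(
    sample_grid(gm, lon[5] + 0.1, lat[5] + 0.1))))
  # outside the extent: missing + warning
  expect_warning(out <- sample_grid(g, 40, 5), "outside")
  expect_true(is.na(out[1]))
})

test_that("grids and stacks round-trip and match nearest-not-after in time", {
  g1 <- lonlat_grid(0:3, 0:2, matrix(1, 4, 3),
                    time = as.POSIXct("2020-01-01", tz = "UTC"))
  g2 <- lonlat_grid(0:3, 0:2, matrix(2, 4, 3),
                    time = as.POSIXct("2020-02-01", tz = "UTC"))
  st <- grid_stack(list(g1, g2), c(g1$time, g2$time))
  t_q <- as.POSIXct(c("2019-12-15", "2020-01-15", "2020-02-15"), tz = "UTC")
  expect_equal(sample_stack(st, rep(1, 3), rep(1, 3), t_q), c(1, 1, 2))
  f <- tempfile(fileext = ".csv")
  write_grid(g1, f)
  g1b <- read_grid(f)
  expect_equal(g1b$values, g1$values)
  expect_equal(g1b$lon, g1$lon)
})

test_that("forward fill follows the previous-value convention", {
  expect_equal(forward_fill(c(2, NA, NA, 5)), c(2, 2, 2, 5))
  expect_equal(forward_fill(c(NA, 3)), c(3, 3))
  expect_identical(forward_fill(c(1, 2, 3)), c(1, 2, 3))
  expect_error(forward_fill(c(NA_real_, NA_real_), "CHL"), "CHL")
})

test_that("ten-day ice rule samples days 1, 4, ..., 28 of a 31-day month", {
  mk_daily <- function(ice_days) {
    lapply(1:31, function(d) {
      lonlat_grid(0:2, 0:2, matrix(ifelse(d %in% ice_days, 1, 0), 3, 3))
    })
  }
  expect_equal(build_ice_binary(mk_daily(integer(0)), 1, 1), 0L)
  expect_equal(build_ice_binary(mk_daily(1:31), 1, 1), 1L)
  # ice only on day 4 (sampled) vs only on day 5 (not sampled)
  expect_equal(build_ice_binary(mk_daily(4), 1, 1), 1L)
  expect_equal(build_ice_binary(mk_daily(5), 1, 1), 0L)
  # exhaustive check of the day set: single-day ice flags exactly the
  # arithmetic sequence 1, 4, ..., 28
  flagged <- vapply(1:31, function(d) build_ice_binary(mk_daily(d), 1, 1),
                    integer(1))
  expect_equal(which(flagged == 1L), seq(1, 28, by = 3))
  expect_error(build_ice_binary(mk_daily(1)[1:5], 1, 1), "10")
})

test_that("distance to a front polyline matches closed forms and converges", {
  line <- cbind(seq(-40, -20, by = 1), -60)   # zonal line at 60S
  expect_equal(distance_to_front(-30, -60, line), 0, tolerance = 1)
  # one degree due north of the line: meridian arc of ~111.2 km
  d <- distance_to_front(-30, -59, line)
  expect_equal(d / 1000, 111.2, tolerance = 0.01)
  # densification refinement changes the result by < 0.1%
  wig <- cbind(seq(-40, -20, 2), -60 + sin(seq(-40, -20, 2) / 3))
  d1 <- distance_to_front(-31.3, -57.2, wig, max_chord_km = 2)
  d2 <- distance_to_front(-31.3, -57.2, wig, max_chord_km = 1)
  expect_lt(abs(d1 - d2) / d2, 0.001)
  # symmetric under polyline reversal
  d3 <- distance_to_front(-31.3, -57.2, wig[rev(seq_len(nrow(wig))), ],
                          max_chord_km = 1)
  expect_equal(d2, d3, tolerance = 1e-9)
})

test_that("pooled standardization centres, scales, and inverts exactly", {
  set.seed(12)
  df <- data.frame(SST = rnorm(500, 10, 4), DEPTH = runif(500, 100, 4000),
                   ICE08 = rbinom(500, 1, 0.3))
  out <- standardize_covariates(df)
  expect_lt(abs(mean(out$data$SST)), 1e-10)
  expect_equal(sd(out$data$SST), 1, tolerance = 1e-10)
  expect_identical(out$data$ICE08, df$ICE08)   # binaries pass through
  back <- apply_standardization(out$data, out$spec, invert = TRUE)
  expect_equal(back$DEPTH, df$DEPTH, tolerance = 1e-12)
  # reusing the pooled spec commutes with subsetting
  sub <- apply_standardization(df[1:100, ], out$spec)
  expect_equal(sub$SST, out$data$SST[1:100])
})

test_that("correlation screening flags exactly the over-correlated pairs", {
  set.seed(13)
  n <- 1000
  x <- rnorm(n)
  df <- data.frame(a = x, b = rnorm(n), c = x + rnorm(n, 0, 0.01), d = x)
  sc <- correlation_screen(df)
  get <- function(p, q) sc$forbidden[(sc$var_a == p & sc$var_b == q) |
                                       (sc$var_a == q & sc$var_b == p)]
  expect_false(get("a", "b"))       # independent columns pass
  expect_true(get("a", "c"))        # x plus tiny noise
  expect_true(get("a", "d"))        # duplicated column, r = 1
  # false-positive rate near alpha for independent columns
  set.seed(14)
  hits <- mean(replicate(200, {
    s <- correlation_screen(data.frame(u = rnorm(300), v = rnorm(300)))
    s$forbidden[1]
  }))
  expect_lt(hits, 0.05)
})
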