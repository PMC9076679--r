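write_toy_csvs <- function(tel_rows, meta_rows = NULL) {
  tf <- tempfile(fileext = ".csv")
  mf <- tempfile(fileext = ".csv")
  writeLines(tel_rows, tf)
  writeLines(meta_rows %||% c("id,sex,calf,role,period", "w1,F,TRUE,Mo,1"), mf)
  list(tel = tf, meta = mf)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("read_tracks sorts shuffled fixes and keeps the better class on duplicates", {
  p <- write_toy_csvs(c(
    "id,date,lc,lon,lat",
    "w1,2020-01-03T00:00:00,1,-40,-30",
    "w1,2020-01-01T00:00:00,B,-40,-28",
    "w1,2020-01-02T00:00:00,2,-40,-29",
    "w1,2020-01-02T00:00:00,B,-41,-29.5"))
  tr <- read_tracks(p$tel, p$meta)[[1]]
  expect_false(is.unsorted(tr$fixes$time))
  expect_equal(nrow(tr$fixes), 3)
  dup <- tr$fixes[tr$fixes$time == as.POSIXct("2020-01-02", tz = "UTC"), ]
  expect_equal(dup$lc, "2")   # class 2 beats B
  expect_equal(dup$lon, -40)
})

test_that("read_tracks reports schema problems precisely", {
  p <- write_toy_csvs(c("id,date,lc,lat", "w1,2020-01-01,3,-30"))
  expect_error(read_tracks(p$tel, p$meta), "lon")
  p2 <- write_toy_csvs(c("id,date,lc,lon,lat", "w1,not-a-date,3,-40,-30"))
  expect_error(read_tracks(p2$tel, p2$meta), "row")
})

test_that("a simulated fleet round-trips through the CSV dialect", {
  sim <- small_migratory_sim()
  dir <- tempfile()
  write_fleet(sim, dir)
  tracks <- read_tracks(file.path(dir, "telemetry.csv"),
                        file.path(dir, "meta.csv"),
                        proj = sim$truth$config$proj)
  expect_length(tracks, length(sim$fleet$tracks))
  ids <- vapply(tracks, `[[`, character(1), "id")
  for (tr0 in sim$fleet$tracks) {
    tr <- tracks[[match(tr0$id, ids)]]
    expect_equal(tr$fixes$time, tr0$fixes$time)
    expect_equal(tr$fixes$lon, round(tr0$fixes$lon, 6))
    expect_equal(tr$fixes$lat, round(tr0$fixes$lat, 6))
    expect_equal(tr$fixes$lc, tr0$fixes$lc)
    expect_equal(tr$meta, tr0$meta)
  }
})

test_that("azimuthal equidistant projection is centred, invertible, and metric", {
  p <- aeqd_projection()
  expect_equal(unname(project_lonlat(-40, -45, p)[1, ]), c(0, 0))
  set.seed(1)
  lon <- runif(200, -60, 10); lat <- runif(200, -65, -15)
  xy <- project_lonlat(lon, lat, p)
  back <- unproject_xy(xy[, 1], xy[, 2], p)
  expect_lt(max(abs(back[, 1] - lon), abs(back[, 2] - lat)), 1e-6)
  # planar distances at 55S against the haversine oracle: near-radial pairs
  # are essentially exact; arbitrary (tangential) pairs carry the azimuthal
  # equidistant scale distortion c^2/6 ~ 0.8% at 10-14 degrees from centre
  a <- cbind(runif(50, -45, -20), runif(50, -57, -53))
  b <- cbind(runif(50, -45, -20), runif(50, -57, -53))
  d_proj <- sqrt(rowSums((project_lonlat(a[, 1], a[, 2], p) -
                            project_lonlat(b[, 1], b[, 2], p))^2))
  d_gc <- geosphere::distHaversine(a, b) / 1000
  expect_lt(max(abs(d_proj - d_gc) / pmax(d_gc, 1)), 0.01)
  ar <- cbind(runif(50, -41, -39), runif(50, -57, -53))
  br <- cbind(ar[, 1] + runif(50, -0.2, 0.2), ar[, 2] + runif(50, 1, 3))
  dr_proj <- sqrt(rowSums((project_lonlat(ar[, 1], ar[, 2], p) -
                             project_lonlat(br[, 1], br[, 2], p))^2))
  dr_gc <- geosphere::distHaversine(ar, br) / 1000
  expect_lt(max(abs(dr_proj - dr_gc) / dr_gc), 0.002)
})

make_track <- function(lon, lat, gap_h = 1, t0 = "2020-01-01", ...) {
  tm <- as.POSIXct(t0, tz = "UTC") + seq_along(lon) * gap_h * 3600
  xy <- project_lonlat(lon, lat)
  ctcrw_track("w1", data.frame(time = tm, lon = lon, lat = lat,
                               lc = "3", smaj = NA_real_, smin = NA_real_,
                               eor = NA_real_, x = xy[, 1], y = xy[, 2]), ...)
}

test_that("speed filter removes spikes iteratively and only spikes", {
  # straight 1 m/s track untouched (3.6 km/h over 1 h gaps)
  lat <- -30 - cumsum(rep(3.6 / 111.2, 10))
  tr <- make_track(rep(-40, 10), lat)
  expect_identical(speed_filter(tr)$fixes, tr$fixes)
  # single 500 km spike between neighbours 1 h apart is removed
  lat2 <- lat; lon2 <- rep(-40, 10); lon2[5] <- -40 + 500 / 96.3 # ~500 km at -30
  sp <- make_track(lon2, lat2)
  out <- speed_filter(sp)
  expect_equal(nrow(out$fixes), 9)
  expect_false(any(out$fixes$lon != -40))
  # plausible tracks with injected spikes: every retained consecutive pair
  # below the ceiling, output a subsequence, first fix kept, spikes gone
  set.seed(99)
  for (r in 1:5) {
    lon <- -40 + cumsum(rnorm(40, 0, 0.05))
    lat <- -30 - cumsum(abs(rnorm(40, 0.05, 0.03)))
    spikes <- sample(5:35, 3)
    lon[spikes] <- lon[spikes] + sample(c(-3, 3), 3, replace = TRUE)
    tr <- make_track(lon, lat)
    out <- speed_filter(tr)
    fx <- out$fixes
    v <- sqrt(diff(fx$x)^2 + diff(fx$y)^2) /
      as.numeric(diff(fx$time), units = "hours")
    expect_true(all(v <= 5 * 3.6 + 1e-9))
    expect_true(all(paste(fx$time) %in% paste(tr$fixes$time)))
    expect_equal(fx$time[1], tr$fixes$time[1])
    expect_false(any(format(fx$time) %in% format(tr$fixes$time[spikes])))
  }
})

test_that("censoring drops pre-departure fixes, rejects shelf-bound tracks, and is idempotent", {
  shelf <- brazil_shelf_polygon()
  # track that never leaves the shelf
  on_shelf <- make_track(rep(-39, 5), seq(-20, -21, length.out = 5))
  rej <- censor_track(on_shelf, shelf)
  expect_s3_class(rej, "ctcrw_rejection")
  expect_match(rej$reason, "never departed")
  # migrating track: pre-departure fixes removed, retained because it reaches -55
  lat <- seq(-20, -55, length.out = 40)
  lon <- rep(-38, 40)
  tr <- make_track(lon, lat, gap_h = 24)
  cen <- censor_track(tr, shelf)
  expect_s3_class(cen, "ctcrw_track")
  expect_lt(nrow(cen$fixes), nrow(tr$fixes))
  expect_false(point_in_polygon(cen$fixes$lon[1], cen$fixes$lat[1], shelf))
  # ceased before the Polar Front
  early <- make_track(lon[1:20], lat[1:20], gap_h = 24)
  expect_s3_class(censor_track(early, shelf), "ctcrw_rejection")
  # idempotent
  expect_identical(censor_track(cen, shelf)$fixes, cen$fixes)
})

test_that("crossing date interpolates the Polar Front passage in whole days", {
  # deployment starting 2003-12-28, heading south at a steady rate that puts
  # the interpolated -50 passage 36.5 days in: first fix at -50 is on
  # 2004-02-03 but the crossing date lands on 2004-02-02 and the migratory
  # duration on 36 whole days
  tm <- as.POSIXct("2003-12-28", tz = "UTC") + (0:59) * 86400
  lat <- -45 - 5 * (0:59) / 36.5
  tr <- ctcrw_track("w", data.frame(time = tm, lon = -40, lat = lat))
  cr <- crossing_date(tr)
  expect_equal(as.Date(cr$date), as.Date("2004-02-02"))
  expect_equal(cr$duration_days, 36L)
  # track already south of the cut: both fields NA
  s <- ctcrw_track("s", data.frame(
    time = as.POSIXct("2013-01-20", tz = "UTC") + (0:5) * 86400,
    lon = -40, lat = seq(-60, -61, length.out = 6)))
  cs <- crossing_date(s)
  expect_true(is.na(cs$date) && is.na(cs$duration_days))
  # synthetic truth: generator crossing time matches crossing_date on the
  # true positions to within one fix interval
  sim <- small_migratory_sim()
  for (i in seq_along(sim$truth$states)) {
    st <- sim$truth$states[[i]]
    if (!sim$truth$reached_50S[i]) next
    tr <- ctcrw_track("t", data.frame(
      time = as.POSIXct("2020-01-01", tz = "UTC") + st$time_h * 3600,
      lon = st$lon, lat = st$lat))
    cr <- crossing_date(tr)
    k <- which(st$lat <= -50)[1]
    expect_lt(abs(as.numeric(difftime(cr$date,
                                      as.POSIXct("2020-01-01", tz = "UTC"),
                                      units = "hours")) - st$time_h[k]),
              max(diff(st$time_h)) + 1e-9)
  }
})

test_that("deployment summary footer follows the single-animal convention", {
  lat <- seq(-45, -55, length.out = 20)
  tr <- make_track(rep(-40, 20), lat, gap_h = 24)
  s <- summarize_tracks(list(tr))
  expect_equal(s$footer["mean", "locs"], 20)
  expect_equal(s$footer["median", "td"], s$animals$td[1])
  expect_equal(s$footer["sd", "locs"], 0)
})
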