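#' Configuration of the synthetic study system
#'
#' Bundles every knob of the synthetic-data generator: fleet composition,
#' sampling cadence, the true link coefficients, covariate-field geometry,
#' and Argos-class error mixtures.  The default `migratory` configuration
#' echoes the tagged SWA humpback fleet: 22 retained whales (12 mothers, 10
#' males+) over two tagging periods, roughly a thousand fixes per animal at
#' a ~2 h cadence, departing the Brazilian shelf with persistent southward
#' velocity and shifting to slow, tortuous movement in cold, ice-influenced
#' water.  `migratory = FALSE` gives the regional configuration used for
#' parameter-recovery experiments: animals scattered over the feeding
#' grounds under a compact SST + ICE08 link.
#'
#' @param migratory logical; see above.
#' @param ... overrides for any configuration element.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(migratory = TRUE, ...) {
  base <- list(
    migratory = migratory,
    n_animals = 22L, n_mothers = 12L, n_period1 = 8L,
    n_short = 0L, short_frac = 0.25,
    n_fixes = 1049L, gap_mean_h = 2, gap_shape = 2,
    years = c(2012L, 2018L),  # tag year per period
    start_month_day = "11-01",
    covariates = c("SST", "ICE08"),
    extra_covariates = c("DEPTH", "SSTA", "CURL", "CHL", "DSB", "ICE10"),
    grouping = "sex",
    theta = c(A0 = -2.4, A_SST = -0.95, A_ICE08 = -0.4,
              B0 = -6.1, B_SST = -2.0, B_ICE08 = 1.8,
              a0 = 0, a_SST = 0, a_ICE08 = -0.5,
              b0 = 0, b_SST = 0, b_ICE08 = 0.8),
    start_lon = c(-41, -36), start_lat = c(-23, -19),
    v0_mean = c(0, -5.5), v0_sd = 0.4,
    grid_res = 0.5, lon_range = c(-60, 10), lat_range = c(-70, -8),
    sst_base = -2, sst_lat_slope = 0.48, sst_noise = 0.6,
    ssta_amp = 1.0, curl_amp = 0.12, chl_slope = 0.08, chl_noise = 0.15,
    chl_gap_band = c(-20, -12),  # lon band masked to exercise forward-fill
    depth_base = 3800, depth_ridge_amp = 2500, depth_ridge_lat = -57,
    depth_noise = 150,
    ice_boundary_lat = -54, ice_wiggle_amp = 2, ice_wiggle_period = 40,
    ice_oct_offset = 2,  # October boundary sits this much further south
    front_lat = -55, front_amp = 1.5,
    class_probs = c(`3` = 0.10, `2` = 0.15, `1` = 0.20, `0` = 0.20,
                    A = 0.20, B = 0.15),
    ellipse_smaj_mean = c(`3` = 250, `2` = 500, `1` = 1500, `0` = 4000,
                          A = 6000, B = 10000),
    ellipse_shape = 4,
    withhold_ellipses_period1 = migratory,
    proj = aeqd_projection())
  if (!migratory) {
    base$n_animals <- 20L; base$n_mothers <- 10L; base$n_period1 <- 0L
    base$n_fixes <- 150L; base$gap_mean_h <- 3
    base$years <- c(2018L, 2018L)
    base$grouping <- "none"
    base$theta <- c(A0 = -1.0, A_SST = 0.3, A_ICE08 = -0.4,
                    B0 = -2.8, B_SST = -0.5, B_ICE08 = 0.8)
    base$extra_covariates <- c("DEPTH", "SSTA", "CURL")
    base$start_lon <- c(-45, -5); base$start_lat <- c(-64, -50)
    base$v0_mean <- c(0, 0); base$v0_sd <- NA  # stationary draw
    base$withhold_ellipses_period1 <- FALSE
  }
  ov <- list(...)
  cfg <- utils::modifyList(base, ov)
  # a resized fleet keeps its composition unless told otherwise
  if ("n_animals" %in% names(ov) && !"n_mothers" %in% names(ov)) {
    cfg$n_mothers <- min(cfg$n_mothers, cfg$n_animals %/% 2)
  }
  if ("n_animals" %in% names(ov) && !"n_period1" %in% names(ov)) {
    cfg$n_period1 <- min(cfg$n_period1, cfg$n_animals %/% 2)
  }
  stopifnot(cfg$n_mothers <= cfg$n_animals, cfg$n_fixes >= 2,
            cfg$gap_mean_h > 0, abs(sum(cfg$class_probs) - 1) < 1e-8)
  structure(cfg, class = c("sim_config", "list"))
}

#' Save / load a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$proj <- unclass(cfg$proj)
  for (nm in c("theta", "class_probs", "ellipse_smaj_mean")) {
    cfg[[nm]] <- as.list(cfg[[nm]])   # keep names through the YAML map
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("theta", "class_probs", "ellipse_smaj_mean")) {
    cfg[[nm]] <- unlist(cfg[[nm]])
  }
  cfg$proj <- structure(cfg$proj, class = "aeqd_projection")
  structure(cfg, class = c("sim_config", "list"))
}

# Smooth random field: sum of low-frequency sinusoids, deterministic given
# the RNG stream.
.smooth_noise <- function(lon_m, lat_m, amp, k = 6) {
  z <- matrix(0, nrow(lon_m), ncol(lon_m))
  for (i in seq_len(k)) {
    a <- runif(1, 0.02, 0.10); b <- runif(1, 0.02, 0.10)
    ph <- runif(1, 0, 2 * pi)
    z <- z + sin(2 * pi * (a * lon_m + b * lat_m) + ph)
  }
  amp * z / sqrt(k / 2)
}

.ice_boundary <- function(cfg, lon, day = 15, month = 8, year = 2018) {
  # year/day wiggle keeps interannual and within-month variation in the edge
  ph <- (year %% 7) * 0.9 + month
  cfg$ice_boundary_lat - (month == 10) * cfg$ice_oct_offset +
    cfg$ice_wiggle_amp * sin(2 * pi * lon / cfg$ice_wiggle_period + ph) +
    0.03 * (day - 15)
}

#' Generate the synthetic covariate fields
#'
#' Builds the raster stack the synthetic fleet moves through: SST with a
#' latitudinal gradient plus smooth noise, zero-mean SSTA patches, a depth
#' ramp with a mid-latitude ridge, a sign-structured wind-stress-curl
#' field, chlorophyll constructed to correlate strongly with SST (so the
#' correlation screen has something to catch) with a masked longitude band
#' (so forward-filling is exercised), daily August and October ice-fraction
#' layers south of a wiggly interannual boundary, and a zonal front
#' polyline.  Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of class `sim_fields`: static [lonlat_grid()] layers
#'   (`DEPTH`, `SST`, `SSTA`, `CURL`, `CHL`), per-year daily ice stacks
#'   (`ice_aug`, `ice_oct`), the `front` polyline, and the grid-moment
#'   `standardization_spec` (`std`) defining the truth scale.
#' @export
gen_covariate_fields <- function(config, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  cfg <- config
  lon <- seq(cfg$lon_range[1], cfg$lon_range[2], by = cfg$grid_res)
  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], by = cfg$grid_res)
  lon_m <- matrix(lon, length(lon), length(lat))
  lat_m <- matrix(lat, length(lon), length(lat), byrow = TRUE)
  sst <- cfg$sst_base + cfg$sst_lat_slope * (lat_m - cfg$lat_range[1]) +
    .smooth_noise(lon_m, lat_m, cfg$sst_noise)
  ssta <- .smooth_noise(lon_m, lat_m, cfg$ssta_amp)
  ssta <- ssta - mean(ssta)
  curl <- -cfg$curl_amp * tanh((lat_m + 45) / 5) +
    .smooth_noise(lon_m, lat_m, cfg$curl_amp / 4)
  chl <- pmax(0.5 + cfg$chl_slope * sst +
                .smooth_noise(lon_m, lat_m, cfg$chl_noise), 0.02)
  chl[lon_m >= cfg$chl_gap_band[1] & lon_m <= cfg$chl_gap_band[2]] <- NA
  depth <- cfg$depth_base -
    cfg$depth_ridge_amp * exp(-((lat_m - cfg$depth_ridge_lat) / 4)^2) +
    .smooth_noise(lon_m, lat_m, cfg$depth_noise)
  front_lon <- seq(cfg$lon_range[1], cfg$lon_range[2], by = 1)
  front <- cbind(lon = front_lon,
                 lat = cfg$front_lat + cfg$front_amp *
                   sin(2 * pi * front_lon / 50))
  years <- sort(unique(cfg$years))
  mk_ice <- function(month, year) {
    lapply(seq_len(31), function(day) {
      b <- .ice_boundary(cfg, lon_m, day, month, year)
      lonlat_grid(lon, lat, ifelse(lat_m < b, 1, 0),
                  name = sprintf("ice_%d_%02d_%02d", year, month, day))
    })
  }
  ice_aug <- setNames(lapply(years, function(y) mk_ice(8, y)), years)
  ice_oct <- setNames(lapply(years, function(y) mk_ice(10, y)), years)
  collapse_ice <- function(stacks) {
    lapply(stacks, function(daily) {
      step <- max(1L, floor((length(daily) - 1) / 9))
      days <- seq(1L, by = step, length.out = 10L)
      v <- Reduce(function(acc, d) acc | (daily[[d]]$values > 0), days,
                  init = matrix(FALSE, length(lon), length(lat)))
      lonlat_grid(lon, lat, v + 0)
    })
  }
  # grid-moment standardization defines the scale on which the true link acts
  raw <- data.frame(DEPTH = as.vector(depth), SST = as.vector(sst),
                    SSTA = as.vector(ssta), CURL = as.vector(curl),
                    CHL = as.vector(chl))
  dsb_probe <- distance_to_front(runif(200, cfg$lon_range[1], cfg$lon_range[2]),
                                 runif(200, cfg$lat_range[1], cfg$lat_range[2]),
                                 front, max_chord_km = 25)
  center <- c(vapply(raw, mean, numeric(1), na.rm = TRUE), DSB = mean(dsb_probe))
  scale <- c(vapply(raw, sd, numeric(1), na.rm = TRUE), DSB = sd(dsb_probe))
  std <- structure(list(center = center, scale = scale,
                        binary = c("ICE08", "ICE10")),
                   class = "standardization_spec")
  structure(list(
    DEPTH = lonlat_grid(lon, lat, depth, name = "DEPTH"),
    SST = lonlat_grid(lon, lat, sst, name = "SST"),
    SSTA = lonlat_grid(lon, lat, ssta, name = "SSTA"),
    CURL = lonlat_grid(lon, lat, curl, name = "CURL"),
    CHL = lonlat_grid(lon, lat, chl, name = "CHL"),
    ice_aug = ice_aug, ice_oct = ice_oct,
    ice08_presence = collapse_ice(ice_aug),
    ice10_presence = collapse_ice(ice_oct),
    front = front, std = std, config = cfg), class = "sim_fields")
}

# Raw covariate values at point locations (ice as 0/1 for the tag year).
# The collapsed ice-presence grids are used when available: bilinear
# sampling of the cell-wise any-sampled-day maximum is positive exactly when
# the day-by-day rule of build_ice_binary() is (both reduce to "any corner
# cell iced on a sampled day").
.sample_raw_covariates <- function(fields, lon, lat, year, vars,
                                   front_chord_km = 10) {
  out <- list()
  yr <- as.character(year)
  ice <- function(presence, daily) {
    if (!is.null(presence)) {
      as.integer(suppressWarnings(sample_grid(presence, lon, lat)) > 0)
    } else build_ice_binary(daily, lon, lat)
  }
  for (v in vars) {
    out[[v]] <- switch(v,
      DEPTH = , SST = , SSTA = , CURL = , CHL =
        suppressWarnings(sample_grid(fields[[v]], lon, lat)),
      DSB = distance_to_front(lon, lat, fields$front,
                              max_chord_km = front_chord_km),
      ICE08 = ice(fields$ice08_presence[[yr]], fields$ice_aug[[yr]]),
      ICE10 = ice(fields$ice10_presence[[yr]], fields$ice_oct[[yr]]),
      stop("unknown covariate ", v))
  }
  as.data.frame(out)
}

#' Simulate a telemetry fleet with known truth
#'
#' Generates every input the analysis pipeline consumes.  For each animal:
#' irregular gamma-distributed fix gaps; the true state advanced with the
#' exact CTCRW transition sampled interval by interval, with `(sigma_t,
#' beta_t)` evaluated from the true link coefficients and the covariates at
#' the current true position; observations corrupted with anisotropic
#' Gaussian error drawn from an Argos-class ellipse mixture.  Tracks that
#' exit the covariate-field extent are truncated and flagged.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed (full determinism: same config + seed
#'   gives identical output).
#' @param fields optional pre-built [gen_covariate_fields()] output.
#' @return list of class `sim_fleet`: `fleet` (a ready-to-fit
#'   [ctcrw_fleet()] whose fixes carry standardized covariates and
#'   observation SDs), `telemetry` and `meta` (the CSV-dialect data frames),
#'   and `truth` (true states, per-interval `sigma`/`beta`, the true
#'   coefficients and standardization spec, per-animal Polar Front crossing
#'   info, and truncation flags).
#' @export
sim_fleet <- function(config = sim_config(), seed = 1L, fields = NULL) {
  cfg <- config
  old <- .save_rng(); on.exit(.restore_rng(old))
  if (is.null(fields)) fields <- gen_covariate_fields(cfg, seed)
  set.seed(as.integer(seed) + 1L)
  k_main <- cfg$covariates
  all_vars <- union(k_main, cfg$extra_covariates)
  grouped <- cfg$grouping != "none"
  tracks <- vector("list", cfg$n_animals)
  truth_states <- truth_params <- vector("list", cfg$n_animals)
  truncated <- logical(cfg$n_animals)
  tel_rows <- meta_rows <- vector("list", cfg$n_animals)
  for (i in seq_len(cfg$n_animals)) {
    is_mother <- i <= cfg$n_mothers
    period <- if (i <= cfg$n_period1) 1L else 2L
    meta <- list(sex = if (is_mother) "F" else sample(c("M", "U"), 1, prob = c(0.8, 0.2)),
                 calf = is_mother,
                 role = if (is_mother) "Mo" else sample(c("Ad", "Es", "Un"), 1),
                 period = period)
    G <- group_indicator(meta, cfg$grouping)
    year <- cfg$years[period]
    id <- sprintf("%d-%03d", year, i)
    n <- cfg$n_fixes
    if (i > cfg$n_animals - cfg$n_short) n <- max(10L, as.integer(n * cfg$short_frac))
    n <- max(10L, as.integer(round(n * runif(1, 0.85, 1.15))))
    gaps <- pmax(0.05, rgamma(n - 1, shape = cfg$gap_shape,
                              rate = cfg$gap_shape / cfg$gap_mean_h))
    times_h <- c(0, cumsum(gaps))
    t0 <- as.POSIXct(sprintf("%d-%s 00:00:00", year, cfg$start_month_day),
                     tz = "UTC") + runif(1, 0, 20) * 86400
    lon0 <- runif(1, cfg$start_lon[1], cfg$start_lon[2])
    lat0 <- runif(1, cfg$start_lat[1], cfg$start_lat[2])
    xy0 <- project_lonlat(lon0, lat0, cfg$proj)
    st <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("x", "y", "vx", "vy")))
    Xs <- matrix(NA_real_, n, length(k_main), dimnames = list(NULL, k_main))
    raw_link <- matrix(NA_real_, n, length(k_main),
                       dimnames = list(NULL, k_main))
    sig <- bet <- rep(NA_real_, n - 1)
    ctr <- fields$std$center; scl <- fields$std$scale
    std1 <- function(raw) {
      out <- raw
      for (v in k_main) {
        if (!v %in% fields$std$binary) out[v] <- (raw[v] - ctr[[v]]) / scl[[v]]
      }
      out
    }
    link1 <- function(lonp, latp) {
      vapply(k_main, function(v) {
        val <- switch(v,
          ICE08 = suppressWarnings(
            sample_grid(fields$ice08_presence[[as.character(year)]], lonp, latp)) > 0,
          ICE10 = suppressWarnings(
            sample_grid(fields$ice10_presence[[as.character(year)]], lonp, latp)) > 0,
          DSB = distance_to_front(lonp, latp, fields$front, max_chord_km = 10),
          suppressWarnings(sample_grid(fields[[v]], lonp, latp)))
        as.numeric(val)
      }, numeric(1))
    }
    if (any(is.na(cfg$v0_sd))) {
      v0 <- c(NA, NA) # filled from the stationary distribution below
    } else {
      v0 <- rnorm(2, cfg$v0_mean, cfg$v0_sd)
    }
    st[1, ] <- c(xy0, if (anyNA(v0)) c(0, 0) else v0)
    n_used <- n
    for (j in seq_len(n - 1)) {
      ll <- unproject_xy(st[j, 1], st[j, 2], cfg$proj)
      raw_link[j, ] <- link1(ll[1], ll[2])
      if (anyNA(raw_link[j, ])) {
        stop("link covariate sampled as missing at (", round(ll[1], 2), ", ",
             round(ll[2], 2), "); keep link covariates gap-free")
      }
      Xs[j, ] <- std1(raw_link[j, ])
      lp <- .link_params(cfg$theta, Xs[j, , drop = FALSE], G, k_main, grouped)
      sig[j] <- lp$sigma[1]; bet[j] <- lp$beta[1]
      if (j == 1 && anyNA(v0)) {
        st[1, 3:4] <- rnorm(2, 0, sig[1] / sqrt(2 * bet[1]))
      }
      tm <- transition_moments(bet[j], sig[j], gaps[j])
      a <- sqrt(tm$q_xx); b <- if (a > 0) tm$q_xv / a else 0
      cc <- sqrt(max(tm$q_vv - b^2, 0))
      for (ax in 1:2) {
        z <- rnorm(2)
        st[j + 1, ax] <- st[j, ax] + tm$f_xv * st[j, ax + 2] + a * z[1]
        st[j + 1, ax + 2] <- tm$f_vv * st[j, ax + 2] + b * z[1] + cc * z[2]
      }
      nl <- unproject_xy(st[j + 1, 1], st[j + 1, 2], cfg$proj)
      if (nl[1] < cfg$lon_range[1] || nl[1] > cfg$lon_range[2] ||
          nl[2] < cfg$lat_range[1] || nl[2] > cfg$lat_range[2]) {
        n_used <- j + 1L
        truncated[i] <- TRUE
        break
      }
    }
    n <- n_used
    st <- st[seq_len(n), , drop = FALSE]
    times_h <- times_h[seq_len(n)]
    sig <- sig[seq_len(n - 1)]; bet <- bet[seq_len(n - 1)]
    ll_last <- unproject_xy(st[n, 1], st[n, 2], cfg$proj)
    raw_link[n, ] <- link1(ll_last[1], ll_last[2])
    if (anyNA(raw_link[n, ])) {
      # truncated track's final fix sits outside the field: carry forward
      for (v in seq_along(k_main)) {
        if (is.na(raw_link[n, v])) raw_link[n, v] <- raw_link[n - 1, v]
      }
    }
    Xs[n, ] <- std1(raw_link[n, ])
    Xs <- Xs[seq_len(n), , drop = FALSE]
    raw_link <- raw_link[seq_len(n), , drop = FALSE]
    true_ll <- unproject_xy(st[, 1], st[, 2], cfg$proj)
    # non-link covariates: sampled in one vectorized pass, gaps forward-filled
    extras_only <- setdiff(all_vars, k_main)
    extra_df <- if (length(extras_only)) {
      ed <- .sample_raw_covariates(fields, true_ll[, 1], true_ll[, 2], year,
                                   extras_only)
      for (v in names(ed)) {
        if (anyNA(ed[[v]])) ed[[v]] <- forward_fill(ed[[v]], v)
      }
      ed
    } else NULL
    raw_all <- cbind(as.data.frame(raw_link), extra_df)[all_vars]
    # observation layer: class mixture + per-class ellipse draws
    lc <- sample(names(cfg$class_probs), n, replace = TRUE,
                 prob = cfg$class_probs)
    smaj <- rgamma(n, shape = cfg$ellipse_shape,
                   rate = cfg$ellipse_shape / cfg$ellipse_smaj_mean[lc])
    smin <- smaj * runif(n, 0.3, 1)
    eor <- runif(n, 0, 180)
    esd <- ellipse_to_sd(smaj, smin, eor)
    obs <- cbind(st[, 1] + rnorm(n, 0, esd$sd_x),
                 st[, 2] + rnorm(n, 0, esd$sd_y))
    obs_ll <- unproject_xy(obs[, 1], obs[, 2], cfg$proj)
    withhold <- cfg$withhold_ellipses_period1 && period == 1L
    fixes <- data.frame(
      time = t0 + times_h * 3600,
      lon = obs_ll[, 1], lat = obs_ll[, 2],
      lc = lc,
      smaj = if (withhold) NA_real_ else smaj,
      smin = if (withhold) NA_real_ else smin,
      eor = if (withhold) NA_real_ else eor,
      x = obs[, 1], y = obs[, 2],
      sd_x = esd$sd_x, sd_y = esd$sd_y, sd_source = "ellipse",
      stringsAsFactors = FALSE)
    Xall <- apply_standardization(raw_all, fields$std)
    for (v in names(Xall)) fixes[[v]] <- Xall[[v]]
    tracks[[i]] <- ctcrw_track(id, fixes, meta)
    # Polar Front crossing truth from the true positions
    cross <- which(true_ll[, 2] <= -50)[1]
    truth_states[[i]] <- data.frame(time_h = times_h, st, lon = true_ll[, 1],
                                    lat = true_ll[, 2])
    truth_params[[i]] <- data.frame(sigma = sig, beta = bet, p = 3 / bet,
                                    delta = diff(times_h))
    tel_rows[[i]] <- data.frame(
      id = id, date = format(fixes$time, "%Y-%m-%dT%H:%M:%S"),
      lc = lc, lon = round(fixes$lon, 6), lat = round(fixes$lat, 6),
      smaj = fixes$smaj, smin = fixes$smin, eor = fixes$eor,
      stringsAsFactors = FALSE)
    meta_rows[[i]] <- data.frame(id = id, sex = meta$sex, calf = meta$calf,
                                 role = meta$role, period = meta$period,
                                 reached_50S = !is.na(cross),
                                 stringsAsFactors = FALSE)
  }
  meta_df <- do.call(rbind, meta_rows)
  fleet <- ctcrw_fleet(tracks, std = fields$std, covariates = all_vars)
  structure(list(
    fleet = fleet,
    telemetry = do.call(rbind, tel_rows),
    meta = meta_df[setdiff(names(meta_df), "reached_50S")],
    truth = list(theta = cfg$theta, grouping = cfg$grouping,
                 covariates = cfg$covariates,
                 states = truth_states, params = truth_params,
                 reached_50S = meta_df$reached_50S,
                 truncated = truncated, std = fields$std,
                 config = cfg, seed = seed)), class = "sim_fleet")
}

#' @export
print.sim_fleet <- function(x, ...) {
  cat(sprintf("<sim_fleet: %d animals, %d fixes, seed %d>\n",
              length(x$fleet$tracks), nrow(x$telemetry), x$truth$seed))
  invisible(x)
}

#' Write a simulated fleet to the CSV telemetry dialect
#'
#' @param sim a [sim_fleet()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`telemetry.csv`, `meta.csv`,
#'   `true_coefficients.csv`).
#' @export
write_fleet <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "telemetry.csv")
  p2 <- file.path(dir, "meta.csv")
  p3 <- file.path(dir, "true_coefficients.csv")
  write.csv(sim$telemetry, p1, row.names = FALSE)
  write.csv(sim$meta, p2, row.names = FALSE)
  write.csv(data.frame(coefficient = names(sim$truth$theta),
                       value = unname(sim$truth$theta)), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` fleets from known coefficients, refits the
#' pooled model with the true covariate set, and reports per-coefficient
#' bias, RMSE and 95% Wald coverage.  When `selection_pool` is given, every
#' admissible covariate subset is also fitted per replicate and the
#' frequency with which the true set attains dAIC = 0 is reported.
#'
#' @param config a [sim_config()] (typically `sim_config(migratory = FALSE)`).
#' @param n_replicates number of simulated fleets.
#' @param seed integer master seed; replicate r uses `seed * 1000 + r`.
#' @param selection_pool optional covariate pool for the AIC-selection leg.
#' @param forbidden forbidden pairs for [enumerate_models()].
#' @return list of class `recovery_report`: `coefficients` (one row per
#'   coefficient: truth, mean estimate, bias, RMSE, coverage — coverage is
#'   `NA` for a single replicate), `estimates` (per-replicate matrix),
#'   `selection` (per-replicate winning covariate set, or `NULL`) and
#'   `selection_freq`.
#' @export
recovery_experiment <- function(config = sim_config(migratory = FALSE),
                                n_replicates = 20, seed = 1L,
                                selection_pool = NULL, forbidden = list()) {
  theta <- config$theta
  nm <- names(theta)
  est <- se <- matrix(NA_real_, n_replicates, length(nm),
                      dimnames = list(NULL, nm))
  selection <- if (is.null(selection_pool)) NULL else character(n_replicates)
  fml <- stats::reformulate(config$covariates)
  for (r in seq_len(n_replicates)) {
    rseed <- (as.integer(seed) * 1000L + r) %% .Machine$integer.max
    sim <- sim_fleet(config, seed = rseed)
    fit <- ctcrw_fit(fml, sim$fleet, grouping = config$grouping)
    est[r, names(coef(fit))] <- coef(fit)
    se[r, names(fit$se)] <- fit$se
    if (!is.null(selection_pool)) {
      specs <- enumerate_models(selection_pool, forbidden, config$grouping)
      fits <- lapply(specs, function(sp) {
        ctcrw_fit(stats::reformulate(sp$covariates), sim$fleet,
                  grouping = sp$grouping)
      })
      tab <- aic_table(fits)
      selection[r] <- tab$covariates[1]
    }
  }
  cover <- if (n_replicates > 1) {
    colMeans(abs(est - rep(theta, each = n_replicates)) <= 1.96 * se,
             na.rm = TRUE)
  } else rep(NA_real_, length(nm))
  coef_tab <- data.frame(
    coefficient = nm, truth = unname(theta),
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(theta),
    rmse = sqrt(colMeans((est - rep(theta, each = n_replicates))^2,
                         na.rm = TRUE)),
    coverage = unname(cover), stringsAsFactors = FALSE)
  true_set <- paste(sort(config$covariates), collapse = "+")
  sel_freq <- if (is.null(selection)) NA_real_ else {
    mean(vapply(strsplit(selection, "+", fixed = TRUE),
                function(s) identical(sort(s), sort(config$covariates)),
                logical(1)))
  }
  structure(list(coefficients = coef_tab, estimates = est, se = se,
                 selection = selection, selection_freq = sel_freq,
                 true_set = true_set, n_replicates = n_replicates,
                 seed = seed), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: %d replicate fleets>\n", x$n_replicates))
  print(transform(x$coefficients,
                  bias = round(bias, 4), rmse = round(rmse, 4)))
  if (!is.na(x$selection_freq)) {
    cat(sprintf("true covariate set selected (dAIC = 0) in %.0f%% of replicates\n",
                100 * x$selection_freq))
  }
  invisible(x)
}
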