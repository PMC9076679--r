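#' @useDynLib crwlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames median sd quantile optim rnorm rgamma runif
#'   cor.test wilcox.test glm Gamma coef logLik pnorm qnorm var aggregate
#'   complete.cases
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# Argos location classes ordered best to worst; used for duplicate resolution.
.lc_levels <- c("3", "2", "1", "0", "A", "B")

.lc_rank <- function(lc) {
  r <- match(as.character(lc), .lc_levels)
  r[is.na(r)] <- length(.lc_levels) + 1L
  r
}

#' Construct a telemetry track
#'
#' A track bundles one animal's time-ordered fixes with its metadata.  Fixes
#' carry geographic and projected planar coordinates, the Argos location
#' class, and (when the tag reports one) the error ellipse.
#'
#' @param id animal identifier.
#' @param fixes data frame with columns `time` (POSIXct, UTC), `lon`, `lat`,
#'   and optionally `lc`, `smaj`, `smin`, `eor` (ellipse semi-major /
#'   semi-minor in metres, orientation in degrees from north), `x`, `y`
#'   (planar km).
#' @param meta named list with `sex` (`"F"`, `"M"`, `"U"`), `calf` (logical),
#'   `role` (`"Mo"`, `"Ad"`, `"Es"`, `"Un"`), `period` (1 or 2).
#' @return object of class `ctcrw_track`.
#' @export
ctcrw_track <- function(id, fixes, meta = list(sex = "U", calf = FALSE,
                                               role = "Un", period = 1L)) {
  stopifnot(is.data.frame(fixes), all(c("time", "lon", "lat") %in% names(fixes)))
  if (any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90] for animal ", id)
  }
  o <- order(fixes$time)
  fixes <- fixes[o, , drop = FALSE]
  rownames(fixes) <- NULL
  structure(list(id = as.character(id), meta = meta, fixes = fixes),
            class = "ctcrw_track")
}

#' @export
print.ctcrw_track <- function(x, ...) {
  cat(sprintf("<ctcrw_track %s: %d fixes, %s to %s, sex %s period %s>\n",
              x$id, nrow(x$fixes),
              format(min(x$fixes$time), "%Y-%m-%d"),
              format(max(x$fixes$time), "%Y-%m-%d"),
              x$meta$sex %||% "U", x$meta$period %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601-ish timestamp parsing that reports failures as NA per row rather
# than aborting on the first ambiguous string.
.parse_times <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    p <- strptime(x[idx], fmt, tz = "UTC")
    out[idx] <- as.POSIXct(p, tz = "UTC")
  }
  out
}

#' Group indicator for pooled models with deviations
#'
#' Maps track metadata to the 0/1 indicator G used by group-deviation terms.
#' Under sex grouping, mothers (females, all accompanied by a calf in this
#' population) are the deviated group (G = 1) and males plus
#' undetermined-sex animals ("males+") the reference; under period grouping
#' the second tagging period is deviated.
#'
#' @param meta track metadata list (see [ctcrw_track()]).
#' @param grouping `"none"`, `"sex"`, or `"period"`.
#' @return 0 or 1.
#' @export
group_indicator <- function(meta, grouping = c("none", "sex", "period")) {
  grouping <- match.arg(grouping)
  switch(grouping,
         none = 0L,
         sex = as.integer(identical(as.character(meta$sex), "F")),
         period = as.integer(as.integer(meta$period) == 2L))
}

#' Read telemetry and metadata tables into tracks
#'
#' Reads the CSV telemetry dialect (columns `id`, `date` ISO-8601, `lc`,
#' `lon`, `lat`, and optional `smaj`, `smin`, `eor`) plus a metadata CSV
#' (`id`, `sex`, `calf`, `role`, `period`), returning one [ctcrw_track()] per
#' animal with fixes time-sorted.  Rows duplicated on (animal, timestamp) are
#' reduced to the one with the best location class (3 > 2 > 1 > 0 > A > B),
#' first occurrence on ties.
#'
#' @param telemetry_file,meta_file CSV paths.
#' @param proj projection used to fill planar `x`, `y` (km); `NULL` to skip.
#' @return list of `ctcrw_track`.
#' @export
read_tracks <- function(telemetry_file, meta_file,
                        proj = aeqd_projection()) {
  tel <- read.csv(telemetry_file, stringsAsFactors = FALSE)
  req <- c("id", "date", "lon", "lat")
  miss <- setdiff(req, names(tel))
  if (length(miss)) stop("telemetry table is missing column(s): ",
                         paste(miss, collapse = ", "))
  meta <- read.csv(meta_file, stringsAsFactors = FALSE)
  mreq <- c("id", "sex", "calf", "role", "period")
  mmiss <- setdiff(mreq, names(meta))
  if (length(mmiss)) stop("metadata table is missing column(s): ",
                          paste(mmiss, collapse = ", "))
  tm <- .parse_times(tel$date)
  if (any(is.na(tm))) {
    stop("unparseable timestamp in telemetry row(s): ",
         paste(head(which(is.na(tm)), 5), collapse = ", "))
  }
  tel$time <- tm
  if (is.null(tel$lc)) tel$lc <- NA_character_
  for (col in c("smaj", "smin", "eor")) if (is.null(tel[[col]])) tel[[col]] <- NA_real_
  if (any(tel$smaj < tel$smin, na.rm = TRUE)) {
    stop("error-ellipse semi-major axis smaller than semi-minor axis")
  }
  tracks <- lapply(split(tel, tel$id), function(d) {
    d <- d[order(d$time, .lc_rank(d$lc)), , drop = FALSE]
    d <- d[!duplicated(d$time), , drop = FALSE] # keeps best class per timestamp
    mrow <- meta[match(d$id[1], meta$id), ]
    m <- if (nrow(mrow) && !is.na(mrow$id[1])) {
      list(sex = mrow$sex, calf = as.logical(mrow$calf),
           role = mrow$role, period = as.integer(mrow$period))
    } else list(sex = "U", calf = FALSE, role = "Un", period = 1L)
    fx <- d[c("time", "lon", "lat", "lc", "smaj", "smin", "eor")]
    if (!is.null(proj)) {
      xy <- project_lonlat(fx$lon, fx$lat, proj)
      fx$x <- xy[, 1]; fx$y <- xy[, 2]
    }
    ctcrw_track(d$id[1], fx, m)
  })
  unname(tracks)
}

#' Remove fixes implying unrealistic travel speeds
#'
#' Iteratively removes fixes whose implied speed from the previous retained
#' fix exceeds `vmax` (default 5 m/s, a conservative ceiling for sustained
#' humpback travel), recomputing speeds after each removal until the track is
#' stable.  The first fix is never removed.
#'
#' @param track a `ctcrw_track` with projected coordinates.
#' @param vmax maximum plausible speed, m/s.
#' @return filtered `ctcrw_track` (a subsequence of the input fixes).
#' @export
speed_filter <- function(track, vmax = 5) {
  stopifnot(inherits(track, "ctcrw_track"))
  fx <- track$fixes
  if (nrow(fx) < 2) stop("speed_filter() needs at least 2 fixes")
  vmax_kmh <- vmax * 3.6
  repeat {
    dt_h <- as.numeric(diff(fx$time), units = "hours")
    dd_km <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
    sp <- dd_km / pmax(dt_h, 1e-9)
    bad <- which(sp > vmax_kmh)
    if (!length(bad)) break
    fx <- fx[-(bad[1] + 1L), , drop = FALSE] # drop the arriving fix, re-check
    if (nrow(fx) < 2) {
      warning("speed filter removed all but one fix for animal ", track$id)
      break
    }
  }
  rownames(fx) <- NULL
  track$fixes <- fx
  track
}

#' Censor a track to its post-departure, front-reaching portion
#'
#' Drops breeding-ground fixes inside the continental-shelf polygon before
#' the first shelf exit, then rejects tracks whose transmissions ceased
#' before reaching the Polar Front latitude (`lat_cut`), mirroring the
#' pre-migration and `~50` degrees S censoring used for migratory analyses.
#'
#' @param track a `ctcrw_track`.
#' @param shelf two-column (lon, lat) polygon; default the packaged synthetic
#'   shelf proxy ([brazil_shelf_polygon()]).
#' @param lat_cut Polar Front latitude, degrees (negative south).
#' @return the censored `ctcrw_track`, or a `ctcrw_rejection` (list with
#'   `id` and `reason`) when the track is discarded.
#' @export
censor_track <- function(track, shelf = brazil_shelf_polygon(), lat_cut = -50) {
  stopifnot(inherits(track, "ctcrw_track"))
  fx <- track$fixes
  on_shelf <- point_in_polygon(fx$lon, fx$lat, shelf)
  first_off <- which(!on_shelf)[1]
  if (is.na(first_off)) {
    return(structure(list(id = track$id, reason = "never departed"),
                     class = "ctcrw_rejection"))
  }
  fx <- fx[seq(first_off, nrow(fx)), , drop = FALSE]
  if (!any(fx$lat <= lat_cut)) {
    return(structure(list(id = track$id,
                          reason = "transmission ceased before Polar Front"),
                     class = "ctcrw_rejection"))
  }
  rownames(fx) <- NULL
  track$fixes <- fx
  track
}

#' @export
print.ctcrw_rejection <- function(x, ...) {
  cat(sprintf("<rejected track %s: %s>\n", x$id, x$reason))
  invisible(x)
}

#' Polar Front crossing date and migratory duration
#'
#' Returns the first time a censored track reaches `lat_cut`, interpolating
#' linearly in time between the bracketing fixes, and the migratory duration
#' in whole days from the first retained fix.  Both are `NA` when the
#' retained data already start south of `lat_cut` (the migration itself was
#' not observed).
#'
#' @inheritParams censor_track
#' @return list with `date` (POSIXct) and `duration_days` (integer).
#' @export
crossing_date <- function(track, lat_cut = -50) {
  stopifnot(inherits(track, "ctcrw_track"))
  fx <- track$fixes
  if (fx$lat[1] <= lat_cut) {
    return(list(date = as.POSIXct(NA, tz = "UTC"), duration_days = NA_integer_))
  }
  k <- which(fx$lat <= lat_cut)[1]
  if (is.na(k)) {
    return(list(date = as.POSIXct(NA, tz = "UTC"), duration_days = NA_integer_))
  }
  # linear interpolation in time along the bracketing pair
  f <- (lat_cut - fx$lat[k - 1]) / (fx$lat[k] - fx$lat[k - 1])
  tcross <- fx$time[k - 1] + f * as.numeric(difftime(fx$time[k], fx$time[k - 1],
                                                     units = "secs"))
  dur <- floor(as.numeric(difftime(tcross, fx$time[1], units = "days")))
  list(date = tcross, duration_days = as.integer(dur))
}

#' Per-animal deployment summary with pooled footer
#'
#' Builds the standard deployment table: number of locations, retained date
#' range, Polar Front crossing date, migratory duration (days), tracking
#' duration (whole days first-to-last retained fix), and the percentage of
#' fixes inside the August / October ice zones when an ice indicator per fix
#' is supplied.
#'
#' @param tracks list of censored `ctcrw_track`.
#' @param ice08,ice10 optional lists (parallel to `tracks`) of per-fix 0/1
#'   ice-zone indicators.
#' @param lat_cut Polar Front latitude.
#' @return list with `animals` (one row per animal) and `footer`
#'   (mean / median / sample SD over animals; see [summary_footer()]).
#' @export
summarize_tracks <- function(tracks, ice08 = NULL, ice10 = NULL, lat_cut = -50) {
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    fx <- tr$fixes
    cr <- crossing_date(tr, lat_cut)
    data.frame(
      id = tr$id, sex = tr$meta$sex %||% "U",
      calf = isTRUE(tr$meta$calf), role = tr$meta$role %||% "Un",
      period = as.integer(tr$meta$period %||% 1L),
      locs = nrow(fx),
      start = as.Date(min(fx$time)), end = as.Date(max(fx$time)),
      date50s = as.Date(cr$date),
      m_time = cr$duration_days,
      td = as.integer(floor(as.numeric(difftime(max(fx$time), min(fx$time),
                                                units = "days")))),
      ice08_pct = if (is.null(ice08)) NA_real_ else 100 * mean(ice08[[i]] > 0),
      ice10_pct = if (is.null(ice10)) NA_real_ else 100 * mean(ice10[[i]] > 0),
      stringsAsFactors = FALSE)
  })
  animals <- do.call(rbind, rows)
  list(animals = animals, footer = summary_footer(animals))
}

#' Footer statistics for a deployment table
#'
#' Mean, median, and sample (n-1) standard deviation of the numeric summary
#' columns, excluding missing values (animals whose migration was not
#' observed contribute no migratory duration).  With a single animal the SD
#' is reported as 0 by convention.
#'
#' @param animals data frame with numeric columns among `locs`, `m_time`,
#'   `td`, `ice08_pct`, `ice10_pct`.
#' @return data frame with rows `mean`, `median`, `sd`.
#' @export
summary_footer <- function(animals) {
  cols <- intersect(c("locs", "m_time", "td", "ice08_pct", "ice10_pct"),
                    names(animals))
  stat <- function(f) vapply(cols, function(cl) {
    v <- animals[[cl]]; v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(as.numeric(v))
  }, numeric(1))
  out <- rbind(mean = stat(mean), median = stat(median),
               sd = stat(function(v) if (length(v) < 2) 0 else sd(v)))
  as.data.frame(out)
}

#' Packaged synthetic proxy for the Brazilian continental-shelf boundary
#'
#' A coarse hand-drawn polygon approximating the 200 m isobath off eastern
#' Brazil, shipped as a GeoJSON fixture.  It is a synthetic stand-in adequate
#' for censoring simulated tracks, not a hydrographic product.
#'
#' @return two-column (lon, lat) matrix.
#' @export
brazil_shelf_polygon <- function() {
  read_geojson_coords(system.file("extdata", "synthetic_shelf_polygon.geojson",
                                  package = "crwlink", mustWork = TRUE))
}
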