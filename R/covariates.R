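#' Lightweight regular lon/lat grid
#'
#' The package's in-memory raster: a regular longitude/latitude grid with a
#' value matrix (rows index longitude, columns latitude) and an optional
#' time stamp.  Grids serialize to plain text via [write_grid()] /
#' [read_grid()].
#'
#' @param lon,lat strictly increasing cell-centre coordinate vectors, degrees.
#' @param values `length(lon)` x `length(lat)` numeric matrix; `NA` marks
#'   masked cells (e.g. land).
#' @param time optional POSIXct stamp of the layer.
#' @param name optional variable name.
#' @return object of class `lonlat_grid`.
#' @export
lonlat_grid <- function(lon, lat, values, time = NULL, name = NULL) {
  values <- as.matrix(values)
  stopifnot(all(diff(lon) > 0), all(diff(lat) > 0),
            nrow(values) == length(lon), ncol(values) == length(lat))
  structure(list(lon = lon, lat = lat, values = values, time = time,
                 name = name), class = "lonlat_grid")
}

#' @export
print.lonlat_grid <- function(x, ...) {
  cat(sprintf("<lonlat_grid %s: %d x %d cells, lon [%g, %g], lat [%g, %g]%s>\n",
              x$name %||% "", length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              if (is.null(x$time)) "" else paste0(", ", format(x$time))))
  invisible(x)
}

#' @rdname lonlat_grid
#' @param grid a `lonlat_grid`.
#' @param path CSV path (long format: lon, lat, value).
#' @export
write_grid <- function(grid, path) {
  df <- data.frame(lon = rep(grid$lon, times = length(grid$lat)),
                   lat = rep(grid$lat, each = length(grid$lon)),
                   value = as.vector(grid$values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname lonlat_grid
#' @export
read_grid <- function(path, time = NULL, name = NULL) {
  df <- read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  v <- matrix(NA_real_, length(lon), length(lat))
  v[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$value
  lonlat_grid(lon, lat, v, time = time, name = name)
}

#' Bilinear sampling of a grid at point locations
#'
#' Bilinear interpolation in space; points outside the grid extent or with
#' any masked (`NA`) corner cell sample as missing.
#'
#' @param grid a [lonlat_grid()].
#' @param lon,lat point coordinates, degrees.
#' @return numeric vector of sampled values (`NA` where missing), with
#'   attribute `n_outside` counting points outside the extent.
#' @export
sample_grid <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "lonlat_grid"), length(lon) == length(lat))
  gl <- grid$lon; gb <- grid$lat; v <- grid$values
  out <- rep(NA_real_, length(lon))
  inside <- lon >= gl[1] & lon <= gl[length(gl)] &
    lat >= gb[1] & lat <= gb[length(gb)]
  n_outside <- sum(!inside, na.rm = TRUE)
  idx <- which(inside)
  if (length(idx)) {
    i <- pmin(pmax(findInterval(lon[idx], gl), 1L), length(gl) - 1L)
    j <- pmin(pmax(findInterval(lat[idx], gb), 1L), length(gb) - 1L)
    tx <- (lon[idx] - gl[i]) / (gl[i + 1] - gl[i])
    ty <- (lat[idx] - gb[j]) / (gb[j + 1] - gb[j])
    out[idx] <- (1 - tx) * (1 - ty) * v[cbind(i, j)] +
      tx * (1 - ty) * v[cbind(i + 1, j)] +
      (1 - tx) * ty * v[cbind(i, j + 1)] +
      tx * ty * v[cbind(i + 1, j + 1)]
  }
  if (n_outside) {
    warning(n_outside, " point(s) outside grid extent sampled as missing")
  }
  structure(out, n_outside = n_outside)
}

#' Time-resolved grid stack
#'
#' A list of [lonlat_grid()] layers of one variable at increasing times.
#' Temporal matching is nearest-not-after: a fix samples the latest layer at
#' or before its time (the first layer when none precedes it, so monthly
#' climatologies degrade gracefully).
#'
#' @param grids list of `lonlat_grid`.
#' @param times POSIXct vector parallel to `grids`, increasing.
#' @return object of class `grid_stack`.
#' @export
grid_stack <- function(grids, times) {
  stopifnot(length(grids) == length(times), !is.unsorted(times))
  structure(list(grids = grids, times = as.POSIXct(times, tz = "UTC")),
            class = "grid_stack")
}

#' @rdname grid_stack
#' @param stack a `grid_stack` (a bare `lonlat_grid` is treated as static).
#' @param lon,lat,time fix coordinates and times.
#' @export
sample_stack <- function(stack, lon, lat, time) {
  if (inherits(stack, "lonlat_grid")) return(sample_grid(stack, lon, lat))
  stopifnot(inherits(stack, "grid_stack"))
  sl <- findInterval(as.numeric(time), as.numeric(stack$times))
  sl[sl < 1L] <- 1L
  out <- rep(NA_real_, length(lon))
  for (k in unique(sl)) {
    idx <- sl == k
    out[idx] <- suppressWarnings(sample_grid(stack$grids[[k]], lon[idx], lat[idx]))
  }
  out
}

#' Forward-fill gaps in a per-animal covariate series
#'
#' Replaces each missing value with the most recent non-missing value for
#' the same animal (leading gaps take the first available value).  Used for
#' monthly chlorophyll, the only covariate with coverage gaps.
#'
#' @param x numeric series, time-ordered within one animal.
#' @param label label used in the error message when `x` is all-missing.
#' @return filled series.
#' @export
forward_fill <- function(x, label = "covariate") {
  if (all(is.na(x))) stop(label, " is entirely missing; cannot forward-fill")
  if (!anyNA(x)) return(x)
  filled <- x
  first_ok <- which(!is.na(x))[1]
  if (first_ok > 1) filled[seq_len(first_ok - 1)] <- x[first_ok]
  for (i in seq_along(filled)) {
    if (is.na(filled[i])) filled[i] <- filled[i - 1]
  }
  filled
}

#' Ten-day sea-ice presence binaries
#'
#' Reduces a month of daily ice-fraction layers to a 0/1 covariate: ice is
#' "present" at a fix location when the fraction exceeds `threshold` on any
#' of ten evenly spaced days of the month (days 1, 4, 7, ..., 28 for a
#' 28-31 day month).  Computed for August (ICE08) and October (ICE10) of
#' each animal's tagging year.
#'
#' @param daily list of [lonlat_grid()] layers, one per day of the month, in
#'   day order.
#' @param lon,lat fix coordinates.
#' @param threshold ice fraction above which a cell counts as ice-covered.
#' @return integer 0/1 vector per fix.
#' @export
build_ice_binary <- function(daily, lon, lat, threshold = 0) {
  n_days <- length(daily)
  if (n_days < 10) stop("need at least 10 daily ice layers, got ", n_days)
  step <- max(1L, floor((n_days - 1) / 9))
  days <- seq(1L, by = step, length.out = 10L)
  present <- rep(FALSE, length(lon))
  for (d in days) {
    frac <- suppressWarnings(sample_grid(daily[[d]], lon, lat))
    present <- present | (!is.na(frac) & frac > threshold)
  }
  as.integer(present)
}

#' Great-circle distance from fixes to a front polyline
#'
#' Minimum great-circle distance from each fix to a polyline (e.g. the mean
#' position of the Southern Boundary of the Antarctic Circumpolar Current).
#' Segments are densified to chords of at most `max_chord_km` before the
#' vertex-wise minimum is taken.
#'
#' @param lon,lat fix coordinates, degrees.
#' @param line two-column (lon, lat) polyline matrix.
#' @param max_chord_km densification chord length, km.
#' @return distances in metres.
#' @export
distance_to_front <- function(lon, lat, line, max_chord_km = 1) {
  line <- as.matrix(line)
  stopifnot(ncol(line) == 2, nrow(line) >= 1)
  dense <- densify_polyline(line, max_chord_km)
  pts <- cbind(lon, lat)
  if (length(lon) >= nrow(dense)) {
    # iterate over the shorter dimension; distHaversine vectorizes the other
    best <- rep(Inf, length(lon))
    for (v in seq_len(nrow(dense))) {
      best <- pmin(best, geosphere::distHaversine(dense[v, ], pts))
    }
    best
  } else {
    vapply(seq_len(nrow(pts)), function(i) {
      min(geosphere::distHaversine(pts[i, ], dense))
    }, numeric(1))
  }
}

#' @rdname distance_to_front
#' @export
densify_polyline <- function(line, max_chord_km = 1) {
  line <- as.matrix(line)
  if (nrow(line) == 1) return(line)
  pieces <- vector("list", nrow(line) - 1)
  for (s in seq_len(nrow(line) - 1)) {
    d_km <- geosphere::distHaversine(line[s, ], line[s + 1, ]) / 1000
    k <- max(1L, ceiling(d_km / max_chord_km))
    f <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    pieces[[s]] <- cbind(line[s, 1] + f * (line[s + 1, 1] - line[s, 1]),
                         line[s, 2] + f * (line[s + 1, 2] - line[s, 2]))
  }
  rbind(do.call(rbind, pieces), line[nrow(line), , drop = FALSE])
}

#' Pooled standardization of continuous covariates
#'
#' Centres and scales each continuous covariate by its pooled mean and SD
#' over all retained fixes of all animals, so individually fitted and pooled
#' models share a coefficient scale.  Binary ice covariates pass through
#' unstandardized.
#'
#' @param df data frame of raw covariate columns.
#' @param binary character vector of columns passed through as-is.
#' @return list with `spec` (per-column `center`, `scale`) and `data` (the
#'   standardized frame).
#' @export
standardize_covariates <- function(df, binary = c("ICE08", "ICE10")) {
  cont <- setdiff(names(df), binary)
  center <- vapply(df[cont], mean, numeric(1), na.rm = TRUE)
  scale <- vapply(df[cont], sd, numeric(1), na.rm = TRUE)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop("zero or undefined spread for covariate(s): ",
         paste(cont[!is.finite(scale) | scale <= 0], collapse = ", "))
  }
  spec <- structure(list(center = center, scale = scale, binary = binary),
                    class = "standardization_spec")
  list(spec = spec, data = apply_standardization(df, spec))
}

#' @rdname standardize_covariates
#' @param spec a `standardization_spec`.
#' @param invert logical; `TRUE` maps standardized values back to raw.
#' @export
apply_standardization <- function(df, spec, invert = FALSE) {
  stopifnot(inherits(spec, "standardization_spec"))
  out <- df
  for (cl in names(spec$center)) {
    if (!cl %in% names(out)) next
    out[[cl]] <- if (invert) out[[cl]] * spec$scale[[cl]] + spec$center[[cl]]
    else (out[[cl]] - spec$center[[cl]]) / spec$scale[[cl]]
  }
  out
}

#' Pearson correlation screening of covariate pairs
#'
#' Flags covariate pairs too correlated to enter a model together:
#' `|r| >= r_thresh` with `p < p_thresh` under the usual t test.  Flagged
#' pairs become "forbidden" combinations for model enumeration.
#'
#' @param df data frame of covariate columns.
#' @param r_thresh absolute correlation threshold.
#' @param p_thresh p-value threshold.
#' @return data frame of pairs with `r`, `p`, and logical `forbidden`.
#' @export
correlation_screen <- function(df, r_thresh = 0.5, p_thresh = 0.01) {
  nm <- names(df)
  combs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    ok <- complete.cases(df[[a]], df[[b]])
    degenerate <- sum(ok) < 3 || sd(df[[a]][ok]) == 0 || sd(df[[b]][ok]) == 0
    if (degenerate) {
      # a constant column carries no correlation evidence: not forbidden
      return(data.frame(var_a = a, var_b = b, r = NA_real_, p = NA_real_,
                        forbidden = FALSE, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(cor.test(df[[a]][ok], df[[b]][ok]))
    r <- unname(ct$estimate)
    p <- if (abs(r) >= 1 - 1e-12) 0 else ct$p.value
    data.frame(var_a = a, var_b = b, r = r, p = p,
               forbidden = abs(r) >= r_thresh & p < p_thresh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
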