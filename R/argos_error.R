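#' Decompose an Argos error ellipse into per-axis standard deviations
#'
#' Converts a reported error ellipse (semi-major / semi-minor axes in metres,
#' orientation in degrees clockwise from north) into independent east-west
#' (`sd_x`) and north-south (`sd_y`) Gaussian standard deviations in km:
#' \deqn{sd_x^2 = (M^2 \sin^2 c + m^2 \cos^2 c) / 2, \quad
#'       sd_y^2 = (M^2 \cos^2 c + m^2 \sin^2 c) / 2.}
#' The 1/2 split treats the axes as 1-sigma extents shared between the two
#' planar axes; `scale` swaps in an alternate convention (e.g. a 95% ellipse)
#' by multiplying both axes before decomposition.
#'
#' @param smaj,smin semi-major and semi-minor axes, metres.
#' @param eor ellipse orientation, degrees from north.
#' @param scale multiplier applied to both axes before decomposition.
#' @param floor_km minimum SD substituted (with a warning) for degenerate
#'   zero ellipses.
#' @return data frame with `sd_x`, `sd_y` (km) and `source = "ellipse"`.
#' @export
ellipse_to_sd <- function(smaj, smin, eor, scale = 1, floor_km = 0.05) {
  n <- max(length(smaj), length(smin), length(eor))
  smaj <- rep_len(smaj, n); smin <- rep_len(smin, n); eor <- rep_len(eor, n)
  if (any(smaj < 0 | smin < 0, na.rm = TRUE)) stop("negative ellipse axis")
  if (any(smaj < smin, na.rm = TRUE)) stop("semi-major axis smaller than semi-minor")
  M <- smaj / 1000 * scale
  m <- smin / 1000 * scale
  c_rad <- eor * pi / 180
  sd_x <- sqrt((M^2 * sin(c_rad)^2 + m^2 * cos(c_rad)^2) / 2)
  sd_y <- sqrt((M^2 * cos(c_rad)^2 + m^2 * sin(c_rad)^2) / 2)
  degen <- which(sd_x <= 0 | sd_y <= 0)
  if (length(degen)) {
    warning(length(degen), " zero ellipse(s) floored at ", floor_km, " km")
    sd_x[degen] <- pmax(sd_x[degen], floor_km)
    sd_y[degen] <- pmax(sd_y[degen], floor_km)
  }
  data.frame(sd_x = sd_x, sd_y = sd_y, source = "ellipse",
             stringsAsFactors = FALSE)
}

#' Fit per-class gamma regressions of location-error SD on latitude
#'
#' For each Argos location class, fits a gamma GLM with log link,
#' `mean SD = exp(g0 + g1 * lat)`, to ellipse-derived standard deviations,
#' with the shape estimated by maximum likelihood.  Tags deployed before
#' error ellipses were reported can then be assigned stochastic SDs from
#' these class models ([impute_sd()]).  Classes with fewer than `min_n`
#' fixes are skipped (the pooled model is their fallback).
#'
#' @param sd_km positive ellipse-derived SDs, km (one axis, or the mean of
#'   both axes).
#' @param lc Argos class per fix.
#' @param lat latitude per fix, degrees.
#' @param min_n minimum fixes per class.
#' @return object of class `class_error_model`: per class (plus `"pooled"`)
#'   the log-scale intercept `g0`, latitude slope `g1`, and gamma shape `nu`.
#' @export
fit_class_gamma <- function(sd_km, lc, lat, min_n = 10) {
  stopifnot(length(sd_km) == length(lc), length(sd_km) == length(lat))
  if (any(sd_km <= 0, na.rm = TRUE)) stop("non-positive SD in training data")
  ok <- complete.cases(sd_km, lc, lat)
  sd_km <- sd_km[ok]; lc <- as.character(lc)[ok]; lat <- lat[ok]
  fit1 <- function(s, l) {
    fm <- glm(s ~ l, family = Gamma(link = "log"))
    nu <- MASS::gamma.shape(fm)$alpha
    list(g0 = unname(coef(fm)[1]), g1 = unname(coef(fm)[2]), nu = nu,
         n = length(s))
  }
  classes <- intersect(.lc_levels, unique(lc))
  models <- list()
  for (cl in classes) {
    idx <- lc == cl
    if (sum(idx) < min_n) {
      warning("class ", cl, " has < ", min_n, " fixes; falling back to pooled model")
      next
    }
    models[[cl]] <- fit1(sd_km[idx], lat[idx])
  }
  models[["pooled"]] <- fit1(sd_km, lat)
  structure(models, class = "class_error_model")
}

#' @export
print.class_error_model <- function(x, ...) {
  cat("<class_error_model>\n")
  for (cl in names(x)) {
    cat(sprintf("  %-6s g0 = %7.3f  g1 = %8.4f  shape = %7.2f  (n = %d)\n",
                cl, x[[cl]]$g0, x[[cl]]$g1, x[[cl]]$nu, x[[cl]]$n))
  }
  invisible(x)
}

#' Impute observation SDs for fixes without error ellipses
#'
#' Draws one SD per fix from the fitted class gamma model,
#' `Gamma(shape = nu, mean = exp(g0 + g1 * lat))`, applied to both planar
#' axes (class-based Argos errors are reported isotropically).  Draws are
#' reproducible given `seed`; classes absent from the model fall back to the
#' pooled sub-model with a warning.
#'
#' @param lc Argos class per fix.
#' @param lat latitude per fix, degrees.
#' @param model a `class_error_model`.
#' @param seed integer seed for the draws.
#' @return data frame with `sd_x`, `sd_y` (km, equal) and `source = "imputed"`.
#' @export
impute_sd <- function(lc, lat, model, seed = 1L) {
  stopifnot(inherits(model, "class_error_model"), length(lc) == length(lat))
  lc <- as.character(lc)
  known <- lc %in% setdiff(names(model), "pooled")
  if (any(!known)) {
    warning(sum(!known), " fix(es) with class absent from the error model; ",
            "using the pooled sub-model")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  draw <- numeric(length(lc))
  for (i in seq_along(lc)) {
    m <- if (known[i]) model[[lc[i]]] else model[["pooled"]]
    mu <- exp(m$g0 + m$g1 * lat[i])
    draw[i] <- rgamma(1, shape = m$nu, rate = m$nu / mu)
  }
  data.frame(sd_x = draw, sd_y = draw, source = "imputed",
             stringsAsFactors = FALSE)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Attach observation-error SDs to a track
#'
#' Uses the ellipse decomposition where the tag reported an ellipse and the
#' class gamma model elsewhere.  Imputation is seeded per animal from
#' `master_seed` so a fleet is reproducible as a whole.
#'
#' @param track a `ctcrw_track`.
#' @param model optional `class_error_model` for fixes without ellipses.
#' @param master_seed integer; combined with the animal id to seed imputation.
#' @inheritParams ellipse_to_sd
#' @return the track with `sd_x`, `sd_y`, `sd_source` columns filled.
#' @export
attach_errors <- function(track, model = NULL, master_seed = 1L,
                          scale = 1, floor_km = 0.05) {
  fx <- track$fixes
  have_ellipse <- !is.na(fx$smaj) & !is.na(fx$smin) & !is.na(fx$eor)
  sd_x <- sd_y <- rep(NA_real_, nrow(fx))
  src <- rep(NA_character_, nrow(fx))
  if (any(have_ellipse)) {
    e <- ellipse_to_sd(fx$smaj[have_ellipse], fx$smin[have_ellipse],
                       fx$eor[have_ellipse], scale = scale, floor_km = floor_km)
    sd_x[have_ellipse] <- e$sd_x; sd_y[have_ellipse] <- e$sd_y
    src[have_ellipse] <- "ellipse"
  }
  if (any(!have_ellipse)) {
    if (is.null(model)) {
      stop("track ", track$id, " has fixes without ellipses and no error model")
    }
    seed <- (as.integer(master_seed) +
               sum(utf8ToInt(track$id)) * 131L) %% .Machine$integer.max
    im <- impute_sd(fx$lc[!have_ellipse], fx$lat[!have_ellipse], model, seed)
    sd_x[!have_ellipse] <- im$sd_x; sd_y[!have_ellipse] <- im$sd_y
    src[!have_ellipse] <- "imputed"
  }
  track$fixes$sd_x <- sd_x
  track$fixes$sd_y <- sd_y
  track$fixes$sd_source <- src
  track
}

#' Save / load a class error model as JSON
#'
#' @param model a `class_error_model`.
#' @param path JSON file path.
#' @export
write_error_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "class_error_model")
}
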