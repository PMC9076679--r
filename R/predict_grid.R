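#' Gridded prediction of expected movement parameters
#'
#' Evaluates a fitted pooled model over a regular lon/lat grid of raw
#' covariate layers for one year-month: covariates are standardized with
#' the training spec, the linear predictors evaluated for group `G`, and
#' `sigma_hat = exp(mu1)`, `p_hat = 3 / exp(mu2)` returned as grids.  Cells
#' with any missing covariate predict as missing; cells whose standardized
#' covariates fall outside the training range are flagged as extrapolation.
#'
#' @param fit a `ctcrw_fit` (pooled).
#' @param layers named list of [lonlat_grid()] rasters, one per model
#'   covariate, on a common grid.
#' @param std `standardization_spec` used in training; defaults to the one
#'   stored in the fit.
#' @param G group indicator for the prediction (0 = reference group).
#' @param train_range optional k x 2 matrix of per-covariate standardized
#'   training ranges for the extrapolation flag.
#' @return list of class `ctcrw_prediction`: `lon`, `lat`, matrices `sigma`
#'   and `p`, logical matrix `extrapolated`, and `extrapolated_fraction`.
#' @export
predict_grid <- function(fit, layers, std = fit$std, G = 0,
                         train_range = NULL) {
  stopifnot(inherits(fit, "ctcrw_fit"))
  miss <- setdiff(fit$covariates, names(layers))
  if (length(miss)) stop("covariate layer(s) absent: ",
                         paste(miss, collapse = ", "))
  g1 <- layers[[fit$covariates[1]]]
  lon <- g1$lon; lat <- g1$lat
  raw <- lapply(fit$covariates, function(cv) {
    g <- layers[[cv]]
    if (!identical(g$lon, lon) || !identical(g$lat, lat)) {
      stop("layer ", cv, " is not on the common prediction grid")
    }
    as.vector(g$values)
  })
  df <- as.data.frame(setNames(raw, fit$covariates))
  if (!is.null(std)) df <- apply_standardization(df, std)
  ok <- complete.cases(df)
  out_sigma <- out_p <- rep(NA_real_, nrow(df))
  extrap <- rep(NA, nrow(df))
  if (is.null(train_range)) {
    tr <- do.call(rbind, lapply(fit$data, `[[`, "X"))
    train_range <- t(apply(tr, 2, range))
  }
  if (any(ok)) {
    dfo <- df[ok, , drop = FALSE]
    dfo$G <- G
    pr <- predict(fit, dfo)
    out_sigma[ok] <- pr$sigma
    out_p[ok] <- pr$p
    ex <- rep(FALSE, nrow(dfo))
    for (j in seq_along(fit$covariates)) {
      ex <- ex | dfo[[j]] < train_range[j, 1] | dfo[[j]] > train_range[j, 2]
    }
    extrap[ok] <- ex
  }
  structure(list(
    lon = lon, lat = lat,
    sigma = matrix(out_sigma, length(lon), length(lat)),
    p = matrix(out_p, length(lon), length(lat)),
    extrapolated = matrix(extrap, length(lon), length(lat)),
    extrapolated_fraction = mean(extrap[ok]),
    G = G), class = "ctcrw_prediction")
}

#' @export
print.ctcrw_prediction <- function(x, ...) {
  cat(sprintf("<ctcrw_prediction: %d x %d cells, G = %d, %.1f%% missing, %.1f%% extrapolated>\n",
              length(x$lon), length(x$lat), x$G,
              100 * mean(is.na(x$sigma)),
              100 * (x$extrapolated_fraction %||% NA)))
  invisible(x)
}

#' Multi-year summary of prediction fields
#'
#' Cell-wise mean and coefficient of variation (sample SD over mean) of
#' yearly prediction fields, quartile bins of each mean field, and the
#' joint mask of cells in the lowest quartile of both `sigma` and `p` (the
#' spatial ARS footprint).
#'
#' @param predictions list of `ctcrw_prediction` for successive years on a
#'   common grid.
#' @return list with `lon`, `lat`, and for each of `sigma` and `p`:
#'   `mean`, `cv`, `quartile` matrices; plus logical `joint_lowest` mask.
#' @export
multi_year_summary <- function(predictions) {
  stopifnot(length(predictions) >= 1)
  lon <- predictions[[1]]$lon; lat <- predictions[[1]]$lat
  summarize_var <- function(var) {
    arr <- vapply(predictions, function(p) p[[var]],
                  matrix(0, length(lon), length(lat)))
    dim(arr) <- c(length(lon) * length(lat), length(predictions))
    m <- rowMeans(arr, na.rm = TRUE)
    m[!is.finite(m)] <- NA
    s <- apply(arr, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else sd(v)
    })
    cv <- ifelse(is.na(m) | m == 0, NA, s / m)
    q <- rep(NA_integer_, length(m))
    q[!is.na(m)] <- classify_quartiles(m[!is.na(m)])
    list(mean = matrix(m, length(lon), length(lat)),
         cv = matrix(cv, length(lon), length(lat)),
         quartile = matrix(q, length(lon), length(lat)))
  }
  s_sig <- summarize_var("sigma")
  s_p <- summarize_var("p")
  list(lon = lon, lat = lat, sigma = s_sig, p = s_p,
       joint_lowest = !is.na(s_sig$quartile) & s_sig$quartile == 1L &
         !is.na(s_p$quartile) & s_p$quartile == 1L)
}
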