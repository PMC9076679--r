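#' Ice-presence grid for one month and year
#'
#' Collapses the sampled-day rule of [build_ice_binary()] to a cell-wise 0/1
#' grid (ice on any of the ten sampled days), used to supply the ICE
#' covariate layer for gridded prediction.
#'
#' @param fields a `sim_fields` object (or any list with `ice_aug` /
#'   `ice_oct` per-year daily stacks).
#' @param year tagging year.
#' @param month 8 (August) or 10 (October).
#' @param threshold ice-fraction presence threshold.
#' @return a [lonlat_grid()].
#' @export
ice_presence_grid <- function(fields, year, month = 8, threshold = 0) {
  daily <- if (month == 8) fields$ice_aug[[as.character(year)]] else
    fields$ice_oct[[as.character(year)]]
  if (is.null(daily)) stop("no daily ice layers for year ", year,
                           ", month ", month)
  n_days <- length(daily)
  step <- max(1L, floor((n_days - 1) / 9))
  days <- seq(1L, by = step, length.out = 10L)
  v <- Reduce(function(acc, d) acc | (daily[[d]]$values > threshold),
              days, init = matrix(FALSE, length(daily[[1]]$lon),
                                  length(daily[[1]]$lat)))
  lonlat_grid(daily[[1]]$lon, daily[[1]]$lat, v + 0,
              name = sprintf("ICE%02d_%d", month, year))
}

#' Run configuration for the end-to-end analysis
#'
#' @param sim a [sim_config()] describing the synthetic study system.
#' @param seed master seed for simulation and imputation.
#' @param pool covariate pool for model selection.
#' @param groupings groupings crossed with the pool.
#' @param vmax speed-filter threshold, m/s.
#' @param lat_cut Polar Front latitude.
#' @param out_dir output directory.
#' @param ... further overrides stored in the config.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), seed = 1L,
                       pool = c("SST", "ICE08"), groupings = "none",
                       vmax = 5, lat_cut = -50, out_dir = tempfile("ctcrw_run"),
                       ...) {
  structure(list(sim = sim, seed = as.integer(seed), pool = pool,
                 groupings = groupings, vmax = vmax, lat_cut = lat_cut,
                 out_dir = out_dir, extra = list(...)), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end analysis
#'
#' Orchestrates the full chain on a synthetic study system: simulate
#' (writing the standard CSV dialect), ingest (reading those files back),
#' speed filter and censoring, error-model fit and imputation for fixes
#' without ellipses, covariate sampling with forward-fill and pooled
#' standardization, correlation screening, covariate-set enumeration and
#' AIC selection, behavioural classification, gridded prediction, and a
#' provenance manifest with a checksum for every input and output file.
#' Outputs are deterministic given the configuration.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the run directory, the AIC table, the
#'   best fit, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(file.path(out, "inputs"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "results"), showWarnings = FALSE)

  fields <- .stage("simulate", gen_covariate_fields(config$sim, config$seed))
  sim <- .stage("simulate", sim_fleet(config$sim, config$seed, fields))
  inputs <- .stage("simulate", write_fleet(sim, file.path(out, "inputs")))

  tracks <- .stage("ingest", read_tracks(file.path(out, "inputs", "telemetry.csv"),
                                         file.path(out, "inputs", "meta.csv"),
                                         proj = config$sim$proj))
  tracks <- .stage("ingest", lapply(tracks, speed_filter, vmax = config$vmax))
  kept <- list(); rejections <- list()
  for (tr in tracks) {
    res <- .stage("censor", censor_track(tr, lat_cut = config$lat_cut))
    if (inherits(res, "ctcrw_rejection")) rejections[[tr$id]] <- res$reason
    else kept[[tr$id]] <- res
  }
  if (!length(kept)) stop("pipeline stage 'censor' failed: no track retained")

  # error model from fixes with ellipses; imputation for the rest
  ell <- do.call(rbind, lapply(kept, function(tr) {
    fx <- tr$fixes
    ok <- !is.na(fx$smaj)
    if (!any(ok)) return(NULL)
    e <- ellipse_to_sd(fx$smaj[ok], fx$smin[ok], fx$eor[ok])
    data.frame(sd = (e$sd_x + e$sd_y) / 2, lc = fx$lc[ok], lat = fx$lat[ok])
  }))
  err_model <- .stage("errors",
                      suppressWarnings(fit_class_gamma(ell$sd, ell$lc, ell$lat)))
  write_error_model(err_model, file.path(out, "results", "error_model.json"))
  kept <- .stage("errors", lapply(kept, attach_errors, model = err_model,
                                  master_seed = config$seed))

  # covariates at observed fixes, pooled standardization, screening
  vars <- config$pool
  kept <- .stage("covariates", lapply(kept, function(tr) {
    yr <- as.integer(substr(tr$id, 1, 4))
    raw <- .sample_raw_covariates(fields, tr$fixes$lon, tr$fixes$lat, yr, vars)
    for (v in names(raw)) {
      if (anyNA(raw[[v]])) raw[[v]] <- forward_fill(raw[[v]], paste0(v, "/", tr$id))
    }
    for (v in names(raw)) tr$fixes[[v]] <- raw[[v]]
    tr
  }))
  pooled <- do.call(rbind, lapply(kept, function(tr) tr$fixes[vars]))
  stdz <- .stage("covariates", standardize_covariates(pooled))
  kept <- lapply(kept, function(tr) {
    tr$fixes[vars] <- apply_standardization(tr$fixes[vars], stdz$spec)
    tr
  })
  screen <- .stage("covariates", correlation_screen(stdz$data))
  write.csv(screen, file.path(out, "results", "correlation_screen.csv"),
            row.names = FALSE)

  fleet <- ctcrw_fleet(unname(kept), std = stdz$spec, covariates = vars)
  specs <- enumerate_models(config$pool, screen[screen$forbidden, 1:2],
                            config$groupings)
  fits <- .stage("fit", lapply(specs, function(sp) {
    ctcrw_fit(stats::reformulate(sp$covariates), fleet, grouping = sp$grouping)
  }))
  tab <- aic_table(fits)
  write.csv(tab, file.path(out, "results", "aic_table.csv"), row.names = FALSE)
  best <- fits[[tab$model[1]]]
  jsonlite::write_json(
    list(model = tab$model[1], coefficients = as.list(coef(best)),
         se = as.list(best$se), logLik = best$logLik, AIC = best$AIC,
         converged = best$convergence, seed = config$seed),
    file.path(out, "results", "best_fit.json"), auto_unbox = TRUE, digits = NA)

  beh <- .stage("classify", behavior_series(best))
  write.csv(beh, file.path(out, "results", "behavior.csv"), row.names = FALSE)

  layers <- .stage("predict", {
    l <- list()
    for (v in setdiff(best$covariates, c("ICE08", "ICE10"))) l[[v]] <- fields[[v]]
    l
  })
  preds <- .stage("predict", lapply(unique(config$sim$years), function(yr) {
    ly <- layers
    if ("ICE08" %in% best$covariates) ly$ICE08 <- ice_presence_grid(fields, yr, 8)
    if ("ICE10" %in% best$covariates) ly$ICE10 <- ice_presence_grid(fields, yr, 10)
    predict_grid(best, ly, std = stdz$spec, G = 0)
  }))
  msum <- multi_year_summary(preds)
  write_grid(lonlat_grid(msum$lon, msum$lat, msum$sigma$mean, name = "sigma_mean"),
             file.path(out, "results", "sigma_mean.csv"))
  write_grid(lonlat_grid(msum$lon, msum$lat, msum$p$mean, name = "p_mean"),
             file.path(out, "results", "p_mean.csv"))

  all_files <- sort(c(inputs, list.files(file.path(out, "results"),
                                         full.names = TRUE)))
  manifest <- list(
    seed = config$seed,
    config_hash = .config_hash(config),
    rejections = rejections,
    files = lapply(setNames(nm = basename(all_files)), function(f) {
      unname(tools::md5sum(all_files[basename(all_files) == f]))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out, aic = tab, best = best, manifest = manifest,
                 rejections = rejections))
}

.config_hash <- function(config) {
  # hash the scientific configuration only; the output path is run-specific
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "\n")
  # digest-free stable hash: md5 of the deparse via a temp file
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
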