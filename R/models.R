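#' Enumerate candidate covariate sets
#'
#' All non-empty subsets of the covariate pool that contain no forbidden
#' (too-correlated) pair, crossed with the requested groupings.  In the
#' humpback analysis SST, CHL and DSB are mutually exclusive, as are the two
#' ice binaries.
#'
#' @param pool character vector of candidate covariates.
#' @param forbidden list of length-2 character vectors (or a two-column data
#'   frame, e.g. the forbidden rows of [correlation_screen()]).
#' @param groupings character vector of groupings to cross with.
#' @return list of model specs, each `list(covariates, grouping)`, named
#'   `"<cov>+...+<cov>|<grouping>"`.
#' @export
enumerate_models <- function(pool, forbidden = list(),
                             groupings = "none") {
  if (is.data.frame(forbidden)) {
    forbidden <- lapply(seq_len(nrow(forbidden)),
                        function(i) c(forbidden[[1]][i], forbidden[[2]][i]))
  }
  subsets <- list()
  for (m in seq_along(pool)) {
    cmb <- utils::combn(pool, m, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  ok <- vapply(subsets, function(s) {
    !any(vapply(forbidden, function(pr) all(pr %in% s), logical(1)))
  }, logical(1))
  subsets <- subsets[ok]
  specs <- list()
  for (g in groupings) {
    for (s in subsets) {
      specs[[paste0(paste(s, collapse = "+"), "|", g)]] <-
        list(covariates = s, grouping = g)
    }
  }
  specs
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `ctcrw_fit` objects (names label the model
#'   specs).
#' @return data frame sorted by ascending AIC with `dAIC = AIC - min(AIC)`;
#'   ties sort by model name for stability.
#' @export
aic_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  tab <- data.frame(
    model = nm,
    covariates = vapply(fits, function(f) paste(f$covariates, collapse = "+"),
                        character(1)),
    grouping = vapply(fits, `[[`, character(1), "grouping"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    converged = vapply(fits, `[[`, logical(1), "convergence"),
    stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab <- tab[order(tab$AIC, tab$model), ]
  rownames(tab) <- NULL
  tab
}

#' Ice-effect ratio of expected movement parameters
#'
#' Ratio of the expected parameter in ice-free versus ice-covered habitat at
#' reference covariate values, from the displayed ratio forms
#' `exp(A0 + a0 G) / exp(A0 + a0 G + (A_ice + a_ice G))`, which reduce to
#' `exp(-(A_ice + a_ice G))` for sigma and `exp(-(B_ice + b_ice G))` for
#' beta.  A ratio above 1 means the parameter is expected larger outside the
#' ice zone.
#'
#' @param object a `ctcrw_fit`, or a named coefficient vector using the
#'   same naming scheme (`A_ICE08`, `a_ICE08`, ...).
#' @param target `"sigma"` or `"beta"`.
#' @param group `"reference"` (G = 0, males+ under sex grouping) or
#'   `"deviated"` (G = 1, mothers).
#' @param ice name of the ice covariate in the model.
#' @return scalar ratio.
#' @export
ice_effect_ratio <- function(object, target = c("sigma", "beta"),
                             group = c("reference", "deviated"),
                             ice = "ICE08") {
  target <- match.arg(target)
  group <- match.arg(group)
  theta <- if (inherits(object, "ctcrw_fit")) coef(object) else object
  lead <- if (target == "sigma") "A" else "B"
  main <- paste0(lead, "_", ice)
  if (!main %in% names(theta)) {
    stop("model has no ", ice, " coefficient for ", target)
  }
  eff <- theta[[main]]
  if (group == "deviated") {
    dev <- paste0(tolower(lead), "_", ice)
    eff <- eff + if (dev %in% names(theta)) theta[[dev]] else 0
  }
  unname(exp(-eff))
}

#' Published SWA humpback deployment summary
#'
#' The transcribed deployment table of the 22 satellite-tagged Southwest
#' Atlantic humpback whales retained after censoring: per-animal location
#' counts, retained date range, Polar Front crossing date, migratory
#' duration (days), tracking duration (days), and the percentage of fixes
#' inside the August / October ice zones.  One whale (flagged by `m_time`
#' `NA`) transmitted a migratory data gap so its retained track lies
#' entirely south of the Polar Front.
#'
#' @return data frame, one row per animal.
#' @export
swa_deployments <- function() {
  df <- read.csv(system.file("extdata", "swa_deployments.csv",
                             package = "crwlink", mustWork = TRUE),
                 stringsAsFactors = FALSE)
  df$start <- as.Date(df$start); df$end <- as.Date(df$end)
  df$date50s <- as.Date(df$date50s)
  df
}

#' Published best pooled-model coefficients
#'
#' The coefficient table of the best-supported pooled model for the SWA
#' humpback fleet (covariates DEPTH + SST + CURL + SSTA + ICE08 with sex
#' deviations): maximum-likelihood estimates and standard errors for the
#' sigma (`A`) and beta (`B`) linear predictors and their mother-deviation
#' terms (`a`, `b`).  Link noise SDs eps1 = eps2 were fixed at 0.001.
#'
#' @param as_vector logical; `TRUE` returns a named coefficient vector in
#'   the package's naming scheme (usable with [ice_effect_ratio()] and
#'   [linear_predictors()]), `FALSE` the raw table.
#' @return named numeric vector or data frame.
#' @export
swa_pmodel_coefficients <- function(as_vector = TRUE) {
  df <- read.csv(system.file("extdata", "swa_pmodel_coefficients.csv",
                             package = "crwlink", mustWork = TRUE),
                 stringsAsFactors = FALSE)
  if (!as_vector) return(df)
  nm <- ifelse(df$term == "(Intercept)",
               paste0(df$block, "0"), paste0(df$block, "_", df$term))
  setNames(df$estimate, nm)
}
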