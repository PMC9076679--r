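#' Bundle tracks into a fleet ready for fitting
#'
#' A fleet holds censored, error-attached tracks whose fixes carry
#' standardized covariate columns, plus the pooled standardization spec used
#' to build them (so predictions onto new data reuse the training scale).
#'
#' @param tracks list of [ctcrw_track()] with `sd_x`, `sd_y` and covariate
#'   columns in `fixes`.
#' @param std optional `standardization_spec` from
#'   [standardize_covariates()].
#' @param covariates character vector of covariate column names; defaults to
#'   every column beyond the core fix fields.
#' @return object of class `ctcrw_fleet`.
#' @export
ctcrw_fleet <- function(tracks, std = NULL, covariates = NULL) {
  stopifnot(length(tracks) >= 1, all(vapply(tracks, inherits, TRUE, "ctcrw_track")))
  core <- c("time", "lon", "lat", "lc", "smaj", "smin", "eor", "x", "y",
            "sd_x", "sd_y", "sd_source")
  if (is.null(covariates)) {
    covariates <- setdiff(names(tracks[[1]]$fixes), core)
  }
  structure(list(tracks = tracks, std = std, covariates = covariates),
            class = "ctcrw_fleet")
}

#' @export
print.ctcrw_fleet <- function(x, ...) {
  nf <- vapply(x$tracks, function(t) nrow(t$fixes), integer(1))
  cat(sprintf("<ctcrw_fleet: %d animals, %d fixes (median %d/animal)>\n",
              length(x$tracks), sum(nf), as.integer(median(nf))))
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# Assemble per-animal likelihood inputs for a covariate set and grouping.
.fit_data <- function(fleet, covariates, grouping) {
  lapply(fleet$tracks, function(tr) {
    fx <- tr$fixes
    miss <- setdiff(covariates, names(fx))
    if (length(miss)) stop("covariate(s) absent from track ", tr$id, ": ",
                           paste(miss, collapse = ", "))
    X <- as.matrix(fx[covariates])
    if (length(covariates) == 0) X <- matrix(0, nrow(fx), 0)
    if (anyNA(X)) stop("missing covariate values on track ", tr$id,
                       "; forward-fill before fitting")
    times_h <- as.numeric(difftime(fx$time, fx$time[1], units = "hours"))
    if (any(diff(times_h) <= 0)) stop("non-increasing times on track ", tr$id)
    if (any(!is.finite(fx$sd_x) | fx$sd_x <= 0) ||
        any(!is.finite(fx$sd_y) | fx$sd_y <= 0)) {
      stop("invalid observation SDs on track ", tr$id)
    }
    list(id = tr$id, times_h = times_h, dt = diff(times_h),
         y = cbind(fx$x, fx$y),
         sd_x = fx$sd_x, sd_y = fx$sd_y,
         r2x = fx$sd_x^2, r2y = fx$sd_y^2,
         X = X,
         G = group_indicator(tr$meta, grouping))
  })
}

.par_template <- function(covariates, grouped) {
  nm <- c("A0", if (length(covariates)) paste0("A_", covariates),
          "B0", if (length(covariates)) paste0("B_", covariates))
  if (grouped) {
    nm <- c(nm, "a0", if (length(covariates)) paste0("a_", covariates),
            "b0", if (length(covariates)) paste0("b_", covariates))
  }
  nm
}

# sigma_t, beta_t per interval for one animal under coefficient vector theta.
.link_params <- function(theta, X, G, covariates, grouped, latent_sd = 0) {
  k <- length(covariates)
  A0 <- theta[["A0"]]; B0 <- theta[["B0"]]
  A <- if (k) theta[paste0("A_", covariates)] else numeric(0)
  B <- if (k) theta[paste0("B_", covariates)] else numeric(0)
  if (grouped) {
    A0 <- A0 + G * theta[["a0"]]
    B0 <- B0 + G * theta[["b0"]]
    if (k) {
      A <- A + G * theta[paste0("a_", covariates)]
      B <- B + G * theta[paste0("b_", covariates)]
    }
  }
  mu1 <- rep(A0, nrow(X)) + if (k) drop(X %*% A) else 0
  mu2 <- rep(B0, nrow(X)) + if (k) drop(X %*% B) else 0
  if (latent_sd > 0) {
    mu1 <- mu1 + rnorm(length(mu1), 0, latent_sd)
    mu2 <- mu2 + rnorm(length(mu2), 0, latent_sd)
  }
  # clamp the linear predictors (overflow guard); the excess feeds a penalty
  # in the fitting objective so the surface keeps curvature outside the box
  excess <- sum(pmax(abs(mu1) - 25, 0)^2) + sum(pmax(abs(mu2) - 25, 0)^2)
  mu1 <- pmin(pmax(mu1, -25), 25)
  mu2 <- pmin(pmax(mu2, -25), 25)
  list(sigma = exp(mu1), beta = exp(mu2), penalty = excess)
}

#' Per-interval movement parameters from link coefficients
#'
#' Evaluates the log-linear links `sigma_t = exp(A0 + a0 G + (A + a G) X_t)`
#' and `beta_t = exp(B0 + b0 G + (B + b G) X_t)` for one animal.  Parameters
#' are piecewise constant per inter-fix interval, anchored at the interval's
#' starting fix.  The default is the deterministic-link limit; `latent_sd`
#' adds the `Normal(0, eps)` perturbation of the latent formulation
#' (eps = 0.001 in this analysis, numerically indistinguishable from the
#' deterministic limit).
#'
#' @param theta named coefficient vector (names `A0`, `A_<cov>`, `B0`,
#'   `B_<cov>`, optionally `a0`, `a_<cov>`, `b0`, `b_<cov>`).
#' @param X n x k matrix of standardized covariates at the fixes.
#' @param G 0/1 group indicator.
#' @param covariates covariate names, ordering the columns of `X`.
#' @param latent_sd SD of the latent log-scale perturbation (0 = off).
#' @return data frame with per-interval `sigma`, `beta`, `p = 3 / beta`
#'   (rows 1..n-1, anchored at the starting fix).
#' @export
linear_predictors <- function(theta, X, G = 0, covariates = colnames(X),
                              latent_sd = 0) {
  X <- as.matrix(X)
  grouped <- "a0" %in% names(theta)
  lp <- .link_params(theta, X, G, covariates, grouped, latent_sd)
  n <- nrow(X)
  idx <- seq_len(max(n - 1, 1))
  data.frame(sigma = lp$sigma[idx], beta = lp$beta[idx],
             p = 3 / lp$beta[idx])
}

.fleet_negloglik <- function(theta, dat, covariates, grouped, init_pos_var) {
  total <- 0
  for (d in dat) {
    lp <- .link_params(theta, d$X, d$G, covariates, grouped)
    n <- length(d$times_h)
    ii <- seq_len(n - 1)
    sig <- lp$sigma[ii]; bet <- lp$beta[ii]
    tm <- .tm_core(bet, sig, d$dt)
    ll <- ctcrw_kalman_cpp(d$y[, 1], d$y[, 2], d$r2x, d$r2y,
                           tm$f_xv, tm$f_vv, tm$q_xx, tm$q_xv, tm$q_vv,
                           init_pos_var, sig[1]^2 / (2 * bet[1]))
    if (!is.finite(ll)) return(1e10)
    total <- total + ll - 1e3 * lp$penalty
  }
  -total
}

# Method-of-moments starting intercepts: empirical velocity variance and
# lag-one velocity autocorrelation at the median gap.
.mom_start <- function(dat) {
  vels <- lapply(dat, function(d) {
    dt <- diff(d$times_h)
    cbind(diff(d$y[, 1]) / dt, diff(d$y[, 2]) / dt)
  })
  v <- do.call(rbind, vels)
  gaps <- unlist(lapply(dat, function(d) diff(d$times_h)))
  med_gap <- median(gaps)
  rho <- suppressWarnings(mean(c(
    stats::cor(v[-nrow(v), 1], v[-1, 1]),
    stats::cor(v[-nrow(v), 2], v[-1, 2])), na.rm = TRUE))
  if (!is.finite(rho)) rho <- 0.5
  beta0 <- min(max(-log(min(max(rho, 0.05), 0.95)) / med_gap, 1e-3), 2)
  sigma0 <- sqrt(max(2 * beta0 * mean(apply(v, 2, var)), 1e-6))
  c(A0 = log(sigma0), B0 = log(beta0))
}

#' Fit a covariate-driven CTCRW by maximum likelihood
#'
#' The package's central fitting function.  Movement parameters
#' `(sigma_t, beta_t)` are log-linear in the standardized covariates named
#' by `formula`, optionally with group-deviation intercepts and slopes
#' (`grouping = "sex"` contrasts mothers against males+; `"period"`
#' contrasts the two tagging periods).  `mode = "P"` pools all animals into
#' one coefficient set (complete pooling); `mode = "I"` fits each animal
#' independently and returns one fit per animal.  Optimization is
#' quasi-Newton ([stats::nlminb()]) from method-of-moments intercepts with
#' zero slopes; standard errors come from the inverse numerical Hessian at
#' the optimum.
#'
#' @param formula one-sided formula naming covariate columns of the fleet's
#'   fixes, e.g. `~ SST + ICE08`; `~ 1` fits intercept-only.
#' @param fleet a [ctcrw_fleet()].
#' @param grouping `"none"`, `"sex"`, or `"period"`.
#' @param mode `"P"` (pooled) or `"I"` (individual).
#' @param init_pos_var diffuse initial position variance, km^2.
#' @param control list: `maxit` (BFGS iterations), `grad_tol` (convergence
#'   threshold on the infinity-norm gradient of the per-fix mean
#'   log-likelihood), `restarts` (extra optimizer restarts from jittered
#'   starts, taken only if they improve).
#' @return object of class `ctcrw_fit` (or a `ctcrw_fit_list` of per-animal
#'   fits for `mode = "I"`), with methods `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `AIC`, `fitted`, `residuals`, `predict`, `simulate`
#'   and `plot`.
#' @export
ctcrw_fit <- function(formula = ~1, fleet, grouping = c("none", "sex", "period"),
                      mode = c("P", "I"), init_pos_var = 1e6,
                      control = list()) {
  grouping <- match.arg(grouping)
  mode <- match.arg(mode)
  stopifnot(inherits(fleet, "ctcrw_fleet"))
  covariates <- setdiff(all.vars(formula), ".")
  ctl <- utils::modifyList(list(maxit = 400, grad_tol = 1e-4, restarts = 0), control)

  if (mode == "I") {
    fits <- lapply(seq_along(fleet$tracks), function(i) {
      tr <- fleet$tracks[[i]]
      covs_i <- covariates
      zerovar <- vapply(covs_i, function(cl) {
        v <- tr$fixes[[cl]]
        !is.numeric(v) || length(unique(v[!is.na(v)])) < 2
      }, logical(1))
      if (any(zerovar)) {
        warning("dropping invariant covariate(s) for animal ", tr$id, ": ",
                paste(covs_i[zerovar], collapse = ", "))
        covs_i <- covs_i[!zerovar]
      }
      sub <- ctcrw_fleet(list(tr), std = fleet$std, covariates = fleet$covariates)
      .ctcrw_fit_one(covs_i, sub, grouping = "none", init_pos_var, ctl)
    })
    names(fits) <- vapply(fleet$tracks, `[[`, character(1), "id")
    return(structure(fits, class = "ctcrw_fit_list"))
  }
  if (grouping != "none") {
    gs <- vapply(fleet$tracks, function(t) group_indicator(t$meta, grouping),
                 integer(1))
    if (length(unique(gs)) < 2) {
      stop("grouping '", grouping, "' requires both groups in the fleet")
    }
  }
  .ctcrw_fit_one(covariates, fleet, grouping, init_pos_var, ctl)
}

.ctcrw_fit_one <- function(covariates, fleet, grouping, init_pos_var, ctl) {
  grouped <- grouping != "none"
  dat <- .fit_data(fleet, covariates, grouping)
  nm <- .par_template(covariates, grouped)
  start <- setNames(numeric(length(nm)), nm)
  ms <- .mom_start(dat)
  start["A0"] <- ms["A0"]; start["B0"] <- ms["B0"]
  nll <- function(th) .fleet_negloglik(setNames(th, nm), dat, covariates,
                                       grouped, init_pos_var)
  n_fixes_total <- sum(vapply(dat, function(d) length(d$times_h), numeric(1)))
  octl <- list(iter.max = ctl$maxit, eval.max = 10 * ctl$maxit,
               rel.tol = 1e-10)
  run1 <- function(s) {
    o <- stats::nlminb(s, nll, control = octl)
    list(par = o$par, value = o$objective, convergence = o$convergence)
  }
  opt <- run1(start)
  if (ctl$restarts > 0) {
    for (r in seq_len(ctl$restarts)) {
      o2 <- tryCatch(run1(start + rnorm(length(start), 0, 0.3)),
                     error = function(e) NULL)
      if (!is.null(o2) && o2$value < opt$value) opt <- o2
    }
  }
  theta <- setNames(opt$par, nm)
  H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) {
    d <- diag(vc); d[d < 0] <- NA
    sqrt(d)
  } else rep(NA_real_, length(theta))
  n_fixes <- sum(vapply(dat, function(d) length(d$times_h), numeric(1)))
  # convergence: optimizer code plus gradient of the per-fix mean loglik
  gr <- tryCatch(.num_grad(nll, theta) / n_fixes, error = function(e) Inf)
  converged <- opt$convergence == 0 && max(abs(gr)) < ctl$grad_tol
  k <- length(theta)
  ll <- -opt$value
  structure(list(
    coefficients = theta, se = setNames(se, nm), vcov = vc,
    logLik = ll, k = k, AIC = 2 * k - 2 * ll,
    convergence = converged, grad_norm = max(abs(gr)),
    covariates = covariates, grouping = grouping, mode = "P",
    n_animals = length(dat), n_fixes = n_fixes,
    animal_ids = vapply(dat, `[[`, character(1), "id"),
    init_pos_var = init_pos_var,
    data = dat, std = fleet$std), class = "ctcrw_fit")
}

.num_grad <- function(f, x, h = 1e-3) {
  vapply(seq_along(x), function(i) {
    e <- x; e[i] <- e[i] + h
    w <- x; w[i] <- w[i] - h
    (f(e) - f(w)) / (2 * h)
  }, numeric(1))
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat(sprintf("Covariate-driven CTCRW fit (%s)\n",
              if (x$grouping == "none") "pooled" else
                paste0("pooled, ", x$grouping, " deviations")))
  cat(sprintf("  covariates: %s\n",
              if (length(x$covariates)) paste(x$covariates, collapse = " + ")
              else "(intercept only)"))
  cat(sprintf("  %d animals, %d fixes; logLik = %.2f, k = %d, AIC = %.1f%s\n",
              x$n_animals, x$n_fixes, x$logLik, x$k, x$AIC,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
print.ctcrw_fit_list <- function(x, ...) {
  cat(sprintf("<ctcrw_fit_list: %d individual fits>\n", length(x)))
  for (nm in names(x)) {
    f <- x[[nm]]
    cat(sprintf("  %-14s logLik %10.2f  AIC %10.1f%s\n", nm, f$logLik, f$AIC,
                if (f$convergence) "" else "  [not converged]"))
  }
  invisible(x)
}

#' @export
coef.ctcrw_fit <- function(object, ...) object$coefficients

#' @export
vcov.ctcrw_fit <- function(object, ...) object$vcov

#' @export
logLik.ctcrw_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_fixes,
            class = "logLik")
}

#' @export
summary.ctcrw_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    z = z, p = 2 * pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.ctcrw_fit"
  out
}

#' @export
print.summary.ctcrw_fit <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests:\n")
  stats::printCoefmat(as.matrix(x$coef_table), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
fitted.ctcrw_fit <- function(object, ...) {
  out <- lapply(object$data, function(d) {
    lp <- linear_predictors(object$coefficients, d$X, d$G, object$covariates)
    cbind(id = d$id, lp)
  })
  do.call(rbind, out)
}

#' @export
residuals.ctcrw_fit <- function(object, ...) {
  out <- lapply(object$data, function(d) {
    lp <- .link_params(object$coefficients, d$X, d$G, object$covariates,
                       object$grouping != "none")
    n <- length(d$times_h)
    tm <- transition_moments(lp$beta[seq_len(n - 1)], lp$sigma[seq_len(n - 1)],
                             diff(d$times_h))
    v0var <- lp$sigma[1]^2 / (2 * lp$beta[1])
    fx <- .ctcrw_filter_axis(d$y[, 1], d$sd_x^2, tm, object$init_pos_var, v0var)
    fy <- .ctcrw_filter_axis(d$y[, 2], d$sd_y^2, tm, object$init_pos_var, v0var)
    data.frame(id = d$id,
               rx = (d$y[, 1] - fx$m_pred[, 1]) /
                 sqrt(fx$P_pred[, 1, 1] + d$sd_x^2),
               ry = (d$y[, 2] - fy$m_pred[, 1]) /
                 sqrt(fy$P_pred[, 1, 1] + d$sd_y^2))
  })
  do.call(rbind, out)
}

#' Predict movement parameters at new covariate values
#'
#' @param object a `ctcrw_fit`.
#' @param newdata data frame with the fit's covariate columns already on the
#'   standardized scale, plus an optional `G` column (0/1 group indicator,
#'   default the reference group).
#' @param ... unused.
#' @return data frame with `sigma`, `beta`, `p` per row of `newdata`.
#' @export
predict.ctcrw_fit <- function(object, newdata, ...) {
  G <- if ("G" %in% names(newdata)) newdata$G else rep(0, nrow(newdata))
  X <- as.matrix(newdata[object$covariates])
  grouped <- object$grouping != "none"
  out <- data.frame(sigma = numeric(nrow(X)), beta = numeric(nrow(X)))
  for (g in unique(G)) {
    idx <- G == g
    lp <- .link_params(object$coefficients, X[idx, , drop = FALSE], g,
                       object$covariates, grouped)
    out$sigma[idx] <- lp$sigma
    out$beta[idx] <- lp$beta
  }
  out$p <- 3 / out$beta
  out
}

#' Simulate observation sets from a fitted model
#'
#' Parametric-bootstrap style simulation: redraws every animal's states and
#' observations at the fitted coefficients along the original fix times,
#' covariates and observation errors.
#'
#' @param object a `ctcrw_fit`.
#' @param nsim number of replicate fleets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of length `nsim`; each element a list (per animal) of n x 2
#'   observation matrices.
#' @export
simulate.ctcrw_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  lapply(seq_len(nsim), function(s) {
    lapply(object$data, function(d) {
      lp <- .link_params(object$coefficients, d$X, d$G, object$covariates,
                         object$grouping != "none")
      n <- length(d$times_h)
      sim <- simulate_states(d$times_h, lp$sigma[seq_len(n - 1)],
                             lp$beta[seq_len(n - 1)], d$sd_x, d$sd_y,
                             start = d$y[1, ])
      sim$obs
    })
  })
}

#' @export
plot.ctcrw_fit <- function(x, animal = 1, ...) {
  d <- x$data[[animal]]
  lp <- linear_predictors(x$coefficients, d$X, d$G, x$covariates)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  th <- d$times_h[-length(d$times_h)]
  graphics::plot(th, lp$sigma, type = "l", xlab = "hours",
                 ylab = expression(sigma[t]), main = d$id, ...)
  graphics::plot(th, lp$p, type = "l", xlab = "hours",
                 ylab = expression(p[t] == 3 / beta[t]), ...)
  invisible(x)
}
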