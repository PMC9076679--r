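#' Exact CTCRW transition moments for one axis
#'
#' The continuous-time correlated random walk models velocity as an
#' Ornstein-Uhlenbeck process, `dv = -beta v dt + sigma dW`, and position as
#' integrated velocity.  Over an interval of length `delta` (hours) the
#' transition of the state `(x, v)` is linear-Gaussian with
#' \deqn{v' = e^{-\beta\Delta} v + w_v, \quad
#'       x' = x + v (1 - e^{-\beta\Delta})/\beta + w_x,}
#' and noise covariance
#' \deqn{Var(w_v) = \sigma^2 (1 - e^{-2\beta\Delta}) / (2\beta)}
#' \deqn{Var(w_x) = \sigma^2/\beta^2 [\Delta - 2(1 - e^{-\beta\Delta})/\beta
#'                  + (1 - e^{-2\beta\Delta})/(2\beta)]}
#' \deqn{Cov(w_x, w_v) = \sigma^2 (1 - e^{-\beta\Delta})^2 / (2\beta^2).}
#' A series expansion replaces the closed forms when `beta * delta < 1e-4`
#' to avoid catastrophic cancellation.
#'
#' @param beta OU decay rate, 1/h (> 0). Directional persistence is
#'   `p = 3 / beta` hours.
#' @param sigma velocity diffusion scale, km h^-3/2 (> 0); stationary
#'   velocity SD is `sigma / sqrt(2 beta)`.
#' @param delta interval length, hours (> 0).
#' @return data frame with one row per interval: `f_xv`, `f_vv` (transition
#'   entries: `T = rbind(c(1, f_xv), c(0, f_vv))`), and `q_xx`, `q_xv`,
#'   `q_vv` (process covariance entries).
#' @export
transition_moments <- function(beta, sigma, delta) {
  as.data.frame(.tm_core(beta, sigma, delta))
}

# list-returning core of transition_moments (hot path: no data.frame cost)
.tm_core <- function(beta, sigma, delta) {
  n <- max(length(beta), length(sigma), length(delta))
  beta <- rep_len(beta, n); sigma <- rep_len(sigma, n); delta <- rep_len(delta, n)
  if (any(!is.finite(beta) | !is.finite(sigma) | !is.finite(delta)) ||
      any(beta <= 0 | sigma <= 0 | delta <= 0)) {
    stop("transition_moments() requires positive finite beta, sigma, delta")
  }
  x <- beta * delta
  e1 <- exp(-x); e2 <- exp(-2 * x)
  f_xv <- (1 - e1) / beta
  f_vv <- e1
  s2 <- sigma^2
  q_vv <- s2 / (2 * beta) * (1 - e2)
  q_xv <- s2 / (2 * beta^2) * (1 - e1)^2
  q_xx <- s2 / beta^2 * (delta - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta))
  small <- x < 1e-4
  if (any(small)) {
    xs <- x[small]; d <- delta[small]; ss <- s2[small]
    f_xv[small] <- d * (1 - xs / 2 + xs^2 / 6)
    q_vv[small] <- ss * d * (1 - xs + 2 * xs^2 / 3)
    q_xv[small] <- ss * d^2 / 2 * (1 - xs + 7 * xs^2 / 12)
    q_xx[small] <- ss * d^3 * (1 / 3 - xs / 4 + 7 * xs^2 / 60)
  }
  list(f_xv = f_xv, f_vv = f_vv, q_xx = q_xx, q_xv = q_xv, q_vv = q_vv)
}

.check_track_inputs <- function(times_h, y, sd_x, sd_y, sigma, beta) {
  n <- length(times_h)
  stopifnot(n >= 2, is.matrix(y), nrow(y) == n, ncol(y) == 2,
            length(sd_x) == n, length(sd_y) == n,
            length(sigma) == n - 1, length(beta) == n - 1)
  if (any(!is.finite(times_h)) || any(!is.finite(y)) ||
      any(!is.finite(sd_x)) || any(!is.finite(sd_y))) {
    stop("non-finite observation inputs")
  }
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  if (any(sd_x <= 0) || any(sd_y <= 0)) stop("observation SDs must be positive")
  invisible(NULL)
}

#' Kalman-filter marginal log-likelihood of a CTCRW track
#'
#' Exact linear-Gaussian marginal log-likelihood of observed planar
#' locations under the CTCRW with interval-specific `(sigma, beta)` and
#' per-fix independent axis observation errors.  The two planar axes are
#' conditionally independent and share movement parameters.  The initial
#' state is diffuse in position (mean at the first observation, variance
#' `init_pos_var`) with the stationary velocity prior of the first interval.
#'
#' @param times_h fix times in hours (strictly increasing).
#' @param y n x 2 matrix of observed planar coordinates, km.
#' @param sd_x,sd_y per-fix observation SDs, km.
#' @param sigma,beta per-interval movement parameters (length n-1).
#' @param init_pos_var initial position variance, km^2.
#' @return scalar log-likelihood.
#' @export
ctcrw_loglik <- function(times_h, y, sd_x, sd_y, sigma, beta,
                         init_pos_var = 1e6) {
  .check_track_inputs(times_h, y, sd_x, sd_y, sigma, beta)
  tm <- .tm_core(beta, sigma, diff(times_h))
  v0var <- sigma[1]^2 / (2 * beta[1])
  ll <- ctcrw_kalman_cpp(y[, 1], y[, 2], sd_x^2, sd_y^2,
                         tm$f_xv, tm$f_vv, tm$q_xx, tm$q_xv, tm$q_vv,
                         init_pos_var, v0var)
  if (!is.finite(ll)) stop("non-finite log-likelihood (innovation variance ",
                           "collapsed); check inputs")
  ll
}

# Full R-level Kalman filter for one axis; returns predicted and filtered
# moments (used by the smoother and residual methods; the C++ routine covers
# the optimizer hot path).
.ctcrw_filter_axis <- function(yv, r2, tm, init_pos_var, v0var) {
  n <- length(yv)
  m_pred <- matrix(0, n, 2); m_filt <- matrix(0, n, 2)
  P_pred <- array(0, c(n, 2, 2)); P_filt <- array(0, c(n, 2, 2))
  ll <- 0
  m <- c(yv[1], 0)
  P <- diag(c(init_pos_var, v0var))
  for (i in seq_len(n)) {
    if (i > 1) {
      Tm <- rbind(c(1, tm$f_xv[i - 1]), c(0, tm$f_vv[i - 1]))
      Q <- rbind(c(tm$q_xx[i - 1], tm$q_xv[i - 1]),
                 c(tm$q_xv[i - 1], tm$q_vv[i - 1]))
      m <- as.vector(Tm %*% m)
      P <- Tm %*% P %*% t(Tm) + Q
    }
    m_pred[i, ] <- m; P_pred[i, , ] <- P
    S <- P[1, 1] + r2[i]
    if (S <= 0) stop("non-positive innovation variance at fix ", i)
    e <- yv[i] - m[1]
    ll <- ll - 0.5 * (log(2 * pi * S) + e^2 / S)
    K <- P[, 1] / S
    m <- m + K * e
    P <- P - tcrossprod(K, P[, 1])
    P <- (P + t(P)) / 2
    m_filt[i, ] <- m; P_filt[i, , ] <- P
  }
  list(loglik = ll, m_pred = m_pred, P_pred = P_pred,
       m_filt = m_filt, P_filt = P_filt)
}

.ctcrw_smooth_axis <- function(f, tm) {
  n <- nrow(f$m_filt)
  m_s <- f$m_filt; P_s <- f$P_filt
  for (i in seq(n - 1, 1)) {
    Tm <- rbind(c(1, tm$f_xv[i]), c(0, tm$f_vv[i]))
    Pp <- f$P_pred[i + 1, , ]
    J <- f$P_filt[i, , ] %*% t(Tm) %*% solve(Pp)
    m_s[i, ] <- f$m_filt[i, ] + as.vector(J %*% (m_s[i + 1, ] - f$m_pred[i + 1, ]))
    P_s[i, , ] <- f$P_filt[i, , ] +
      J %*% (P_s[i + 1, , ] - Pp) %*% t(J)
    P_s[i, , ] <- (P_s[i, , ] + t(P_s[i, , ])) / 2
  }
  list(m = m_s, P = P_s)
}

#' Smoothed states of a CTCRW track
#'
#' Rauch-Tung-Striebel smoothing of positions and velocities given movement
#' parameters and observation errors; the smoothed speed series
#' `sqrt(vx^2 + vy^2)` is the basis for behavioural summaries.
#'
#' @inheritParams ctcrw_loglik
#' @return data frame with smoothed means (`x`, `y`, `vx`, `vy`), their
#'   variances (`var_x`, `var_y`, `var_vx`, `var_vy`), filtered position
#'   variances (`fvar_x`, `fvar_y`), and `speed` (km/h).
#' @export
smooth_states <- function(times_h, y, sd_x, sd_y, sigma, beta,
                          init_pos_var = 1e6) {
  .check_track_inputs(times_h, y, sd_x, sd_y, sigma, beta)
  tm <- transition_moments(beta, sigma, diff(times_h))
  v0var <- sigma[1]^2 / (2 * beta[1])
  fx <- .ctcrw_filter_axis(y[, 1], sd_x^2, tm, init_pos_var, v0var)
  fy <- .ctcrw_filter_axis(y[, 2], sd_y^2, tm, init_pos_var, v0var)
  sx <- .ctcrw_smooth_axis(fx, tm)
  sy <- .ctcrw_smooth_axis(fy, tm)
  data.frame(
    x = sx$m[, 1], y = sy$m[, 1], vx = sx$m[, 2], vy = sy$m[, 2],
    var_x = sx$P[, 1, 1], var_y = sy$P[, 1, 1],
    var_vx = sx$P[, 2, 2], var_vy = sy$P[, 2, 2],
    fvar_x = fx$P_filt[, 1, 1], fvar_y = fy$P_filt[, 1, 1],
    speed = sqrt(sx$m[, 2]^2 + sy$m[, 2]^2))
}

#' Simulate true states and noisy observations from the CTCRW
#'
#' Draws exactly from the model evaluated by [ctcrw_loglik()]: state
#' advanced with the exact transition moments, observations corrupted with
#' independent per-axis Gaussian error.
#'
#' @inheritParams ctcrw_loglik
#' @param start numeric length-2 start position, km.
#' @param v0 numeric length-2 initial velocity, km/h; `NULL` draws from the
#'   stationary velocity distribution of the first interval.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list with `states` (data frame `x`, `y`, `vx`, `vy`) and `obs`
#'   (n x 2 matrix).
#' @export
simulate_states <- function(times_h, sigma, beta, sd_x, sd_y,
                            start = c(0, 0), v0 = NULL, seed = NULL) {
  n <- length(times_h)
  stopifnot(n >= 2, length(sigma) == n - 1, length(beta) == n - 1,
            length(sd_x) == n, length(sd_y) == n)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  tm <- transition_moments(beta, sigma, diff(times_h))
  st <- matrix(0, n, 4, dimnames = list(NULL, c("x", "y", "vx", "vy")))
  if (is.null(v0)) {
    sd_v <- sigma[1] / sqrt(2 * beta[1])
    v0 <- rnorm(2, 0, sd_v)
  }
  st[1, ] <- c(start, v0)
  for (i in seq_len(n - 1)) {
    # sample correlated (position, velocity) noise from the 2x2 covariance
    a <- sqrt(tm$q_xx[i])
    b <- if (a > 0) tm$q_xv[i] / a else 0
    c2 <- tm$q_vv[i] - b^2
    cc <- sqrt(max(c2, 0))
    for (ax in 1:2) {
      z <- rnorm(2)
      wx <- a * z[1]
      wv <- b * z[1] + cc * z[2]
      st[i + 1, ax] <- st[i, ax] + tm$f_xv[i] * st[i, ax + 2] + wx
      st[i + 1, ax + 2] <- tm$f_vv[i] * st[i, ax + 2] + wv
    }
  }
  obs <- cbind(st[, 1] + rnorm(n, 0, sd_x), st[, 2] + rnorm(n, 0, sd_y))
  list(states = as.data.frame(st), obs = obs)
}

#' Euler-Maruyama simulation of the OU velocity / integrated position pair
#'
#' Brute-force SDE simulation used as an independent check of the exact
#' transition moments: `nrep` replicates of `dv = -beta v dt + sigma dW`
#' with `x` the running integral of `v`, stepped at `dt` from `(0, v0)`.
#'
#' @inheritParams transition_moments
#' @param v0 initial velocity.
#' @param dt Euler step, hours.
#' @param nrep number of replicates.
#' @return `nrep` x 2 matrix of `(x, v)` at time `delta`.
#' @export
simulate_ou_em <- function(beta, sigma, delta, v0 = 0, dt = 1e-3,
                           nrep = 1e5) {
  stopifnot(beta > 0, sigma > 0, delta > 0, dt > 0, nrep >= 1)
  ou_em_cpp(beta, sigma, delta, v0, dt, as.integer(nrep))
}
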