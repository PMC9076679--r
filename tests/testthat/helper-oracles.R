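# Independent oracles used across the suite.  None of these share code with
# the implementation paths they check.

# Log-density of a multivariate normal via Cholesky.
dmvnorm_log <- function(x, mean, sigma) {
  ch <- chol(sigma)
  r <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

# Brute-force joint-Gaussian CTCRW marginal likelihood: builds the full
# covariance of all states by composing the per-interval transition moments,
# projects onto the observations, and evaluates the joint normal density.
joint_gaussian_loglik <- function(times_h, y, sd_x, sd_y, sigma, beta,
                                  init_pos_var = 1e6) {
  n <- length(times_h)
  tm <- transition_moments(beta, sigma, diff(times_h))
  axis_ll <- function(yv, sds) {
    mu <- matrix(0, n, 2)
    mu[1, ] <- c(yv[1], 0)
    C <- matrix(0, 2 * n, 2 * n)
    C[1:2, 1:2] <- diag(c(init_pos_var, sigma[1]^2 / (2 * beta[1])))
    for (j in 2:n) {
      Tj <- rbind(c(1, tm$f_xv[j - 1]), c(0, tm$f_vv[j - 1]))
      Qj <- rbind(c(tm$q_xx[j - 1], tm$q_xv[j - 1]),
                  c(tm$q_xv[j - 1], tm$q_vv[j - 1]))
      mu[j, ] <- Tj %*% mu[j - 1, ]
      for (i in 1:(j - 1)) {
        blk <- C[(2 * i - 1):(2 * i), (2 * (j - 1) - 1):(2 * (j - 1))] %*% t(Tj)
        C[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- blk
        C[(2 * j - 1):(2 * j), (2 * i - 1):(2 * i)] <- t(blk)
      }
      C[(2 * j - 1):(2 * j), (2 * j - 1):(2 * j)] <-
        Tj %*% C[(2 * (j - 1) - 1):(2 * (j - 1)),
                 (2 * (j - 1) - 1):(2 * (j - 1))] %*% t(Tj) + Qj
    }
    H <- matrix(0, n, 2 * n)
    for (i in 1:n) H[i, 2 * i - 1] <- 1
    dmvnorm_log(yv, as.vector(H %*% as.vector(t(mu))),
                H %*% C %*% t(H) + diag(sds^2, n))
  }
  axis_ll(y[, 1], sd_x) + axis_ll(y[, 2], sd_y)
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled sample into the two groups.
perm_wilcox_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pool), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Convex polygon area by angle-sorting the hull vertices around their
# centroid and applying the shoelace sum directly.
convex_area_oracle <- function(x, y) {
  o <- order(atan2(y - mean(y), x - mean(x)))
  x <- x[o]; y <- y[o]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Random CTCRW track (parameters + simulated observations) for oracle tests.
random_track <- function(n, seed) {
  set.seed(seed)
  times <- cumsum(c(0, runif(n - 1, 0.5, 5)))
  sigma <- exp(runif(n - 1, -2, 0.5))
  beta <- exp(runif(n - 1, -3, 0))
  sd_x <- runif(n, 0.2, 3)
  sd_y <- runif(n, 0.2, 3)
  sim <- simulate_states(times, sigma, beta, sd_x, sd_y,
                         start = c(runif(1, -100, 100), runif(1, -100, 100)))
  list(times = times, sigma = sigma, beta = beta, sd_x = sd_x, sd_y = sd_y,
       obs = sim$obs, states = sim$states)
}
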