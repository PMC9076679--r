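#' Quartile classification of movement-parameter series
#'
#' Splits values at the pooled (all-animals) empirical quartiles; the
#' lowest quartile of persistence `p` and of `sigma` is the
#' area-restricted-search (ARS) proxy.  Values equal to a break fall in the
#' lower class; with degenerate breaks (all values equal) everything is Q1.
#'
#' @param values numeric vector pooled over all retained fixes.
#' @param breaks optional precomputed quartile breaks (e.g. from another
#'   dataset); default the empirical quartiles of `values`.
#' @return integer vector in 1..4 with attribute `breaks`.
#' @export
classify_quartiles <- function(values, breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- quantile(values, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  }
  lab <- 1L + (values > breaks[1]) + (values > breaks[2]) + (values > breaks[3])
  structure(as.integer(lab), breaks = breaks)
}

#' Behavioural series from a fitted model
#'
#' Combines per-interval movement parameters at the MLE with smoothed
#' speeds into the per-fix behavioural table: `sigma`, `p`, `speed`, pooled
#' quartile classes, and ARS flags.  The marginal ARS flags mark the lowest
#' quartile of `p` and of `sigma` separately; `ars_joint` requires both.
#'
#' @param fit a `ctcrw_fit`.
#' @return data frame with one row per fix (`sigma`, `p` repeat the last
#'   interval's value on each final fix), columns `id`, `time_h`, `lon`/`lat`
#'   when available, `speed`, `sigma`, `p`, `q_sigma`, `q_p`, `ars_sigma`,
#'   `ars_p`, `ars_joint`.
#' @export
behavior_series <- function(fit) {
  stopifnot(inherits(fit, "ctcrw_fit"))
  rows <- lapply(fit$data, function(d) {
    lp <- .link_params(fit$coefficients, d$X, d$G, fit$covariates,
                       fit$grouping != "none")
    n <- length(d$times_h)
    sm <- smooth_states(d$times_h, d$y, d$sd_x, d$sd_y,
                        lp$sigma[seq_len(n - 1)], lp$beta[seq_len(n - 1)],
                        fit$init_pos_var)
    sig <- lp$sigma; sig[n] <- sig[n - 1]
    bet <- lp$beta; bet[n] <- bet[n - 1]
    data.frame(id = d$id, time_h = d$times_h, x = sm$x, y = sm$y,
               speed = sm$speed, sigma = sig, p = 3 / bet, G = d$G)
  })
  out <- do.call(rbind, rows)
  out$q_sigma <- classify_quartiles(out$sigma)
  out$q_p <- classify_quartiles(out$p)
  out$ars_sigma <- out$q_sigma == 1L
  out$ars_p <- out$q_p == 1L
  out$ars_joint <- out$ars_sigma & out$ars_p
  out
}

#' Stratified speed summaries with rank-sum comparison
#'
#' Descriptive statistics of a speed series per stratum plus a two-sided
#' Wilcoxon rank-sum comparison of the two strata (exact for small untied
#' samples, tie-corrected normal approximation otherwise) — the comparison
#' used to contrast mothers against males+ north and south of the Polar
#' Front.
#'
#' @param speed numeric speeds (km/h).
#' @param stratum factor-like with exactly two levels.
#' @return list with `table` (mean / median / SD / range / n per stratum)
#'   and `test` (the `htest` from [stats::wilcox.test()], first level vs
#'   second).
#' @export
speed_stats <- function(speed, stratum) {
  stratum <- as.factor(stratum)
  keep <- !is.na(speed) & !is.na(stratum)
  speed <- speed[keep]; stratum <- droplevels(stratum[keep])
  lv <- levels(stratum)
  if (length(lv) != 2) stop("speed_stats() expects exactly two strata, got ",
                            length(lv))
  tab <- do.call(rbind, lapply(lv, function(l) {
    v <- speed[stratum == l]
    data.frame(stratum = l, n = length(v), mean = mean(v), median = median(v),
               sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  test <- wilcox.test(speed[stratum == lv[1]], speed[stratum == lv[2]])
  list(table = tab, test = test)
}

#' Migratory-duration statistics by group
#'
#' Mean, median, sample SD and range of per-animal migratory duration,
#' overall or by sex / tagging period, excluding animals whose migration was
#' not observed (`NA` durations).
#'
#' @param animals per-animal summary frame with columns `m_time`, `sex`,
#'   `period` (e.g. `summarize_tracks()$animals` or [swa_deployments()]).
#' @param grouping `"all"`, `"sex"` (mothers vs males+), or `"period"`.
#' @return data frame, one row per group.
#' @export
migration_duration_stats <- function(animals, grouping = c("all", "sex", "period")) {
  grouping <- match.arg(grouping)
  grp <- switch(grouping,
                all = rep("all", nrow(animals)),
                sex = ifelse(animals$sex == "F", "mothers", "males+"),
                period = paste0("period", animals$period))
  rows <- lapply(sort(unique(grp)), function(g) {
    v <- animals$m_time[grp == g]
    v <- v[!is.na(v)]
    data.frame(group = g, n = length(v), mean = mean(v), median = median(v),
               sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Minimum convex polygon range area
#'
#' The standard home-range summary: drop the `1 - coverage` fraction of
#' fixes farthest from the centroid (planar km), take the convex hull of the
#' rest, and report its planar area.
#'
#' @param x,y planar coordinates, km.
#' @param coverage fraction of fixes retained (default 95%).
#' @return list with `area_km2`, `hull` (two-column matrix of hull vertices,
#'   counter-clockwise), and `kept` (logical vector of retained fixes).
#' @export
mcp_area <- function(x, y, coverage = 0.95) {
  stopifnot(length(x) == length(y), coverage > 0, coverage <= 1)
  n <- length(x)
  d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  n_keep <- max(3L, ceiling(coverage * n))
  kept <- rank(d, ties.method = "first") <= n_keep
  if (sum(kept) < 3) stop("fewer than 3 fixes retained for the MCP")
  hx <- x[kept]; hy <- y[kept]
  h <- grDevices::chull(hx, hy)
  hull <- cbind(x = hx[h], y = hy[h])
  list(area_km2 = polygon_area(hull[, 1], hull[, 2]), hull = hull, kept = kept)
}

#' Shoelace polygon area
#'
#' @param x,y vertex coordinates of a simple polygon (open or closed ring).
#' @return absolute enclosed area in the squared input unit.
#' @export
polygon_area <- function(x, y) {
  n <- length(x)
  if (isTRUE(all.equal(c(x[1], y[1]), c(x[n], y[n])))) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
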