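# Shared fixtures and small independent oracles, built in code.

toy_counts <- function() {
  counts <- integer(13)
  counts[11:13] <- c(1L, 2L, 1L)  # bins 10, 11, 12 Ma
  counts
}

toy_dataset <- function() clade_dataset("toy", "family", toy_counts(), 0)

fixture_path <- function(file) system.file("extdata", file, package = "bbbridge")

# AR(1) series with known autocorrelation time
ar1_series <- function(n, rho, seed) {
  set.seed(seed)
  e <- stats::rnorm(n)
  a <- numeric(n)
  a[1] <- e[1]
  for (i in 2:n) a[i] <- rho * a[i - 1] + e[i]
  a
}

# Independent Wilcoxon signed-rank oracle (normal approximation, no
# continuity correction) used to cross-check prior_sensitivity_test.
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  2 * stats::pnorm(-abs(W - mu) / sig)
}

# Sequential-conditional bridge density oracle: the same joint density as
# bridge_log_prior, but factorised point by point through bridge_moments
# instead of increments-over-marginal.
sequential_bridge_logdens <- function(log_n, t0, te, sigma2, anchors) {
  bins <- lifespan_bins(t0, te)
  ages <- rev(bins) + 0.5           # oldest first
  vals <- rev(log_n)
  lp <- 0
  a_prev <- t0
  v_prev <- anchors[["old"]]
  for (i in seq_along(ages)) {
    m <- bridge_moments(a_prev, v_prev, anchors[["young_age"]],
                        anchors[["young"]], ages[i], sigma2)
    lp <- lp + stats::dnorm(vals[i], m$mean, sqrt(m$var), log = TRUE)
    a_prev <- ages[i]
    v_prev <- vals[i]
  }
  lp
}

# Direct Riemann integration of the trajectory for one fixed t0 (tiny
# problems only): marginal likelihood over the interior log-diversity grid.
riemann_marginal <- function(counts, t0, te, sigma2, q0, beta, yend,
                             young_age, ygrid) {
  bins <- rev(lifespan_bins(t0, te))  # oldest first
  stopifnot(length(bins) <= 4)
  dy <- ygrid[2] - ygrid[1]
  grid <- as.matrix(expand.grid(rep(list(ygrid), length(bins))))
  ages <- c(t0, bins + 0.5, young_age)
  vals <- cbind(0, grid, yend)
  lp <- 0
  for (i in seq_along(bins) + 1) {
    lp <- lp + stats::dnorm(vals[, i] - vals[, i - 1], 0,
                            sqrt(sigma2 * (ages[i - 1] - ages[i])),
                            log = TRUE)
  }
  lp <- lp + stats::dnorm(yend - vals[, ncol(vals) - 1], 0,
                          sqrt(sigma2 * (ages[length(ages) - 1] - young_age)),
                          log = TRUE)
  for (i in seq_along(bins)) {
    x <- if (bins[i] + 1 <= length(counts)) counts[bins[i] + 1] else 0
    lam <- q0 * exp(beta * (t0 - (bins[i] + 0.5))) * exp(grid[, i])
    lp <- lp + x * log(lam) - lam - lgamma(x + 1)
  }
  sum(exp(lp)) * dy^length(bins) /
    stats::dnorm(yend, 0, sqrt(sigma2 * (t0 - young_age)))
}

# prior-support edges of a dataset (older edge of oldest non-empty bin,
# younger edge of youngest non-empty bin), both in Ma
oldest_bin_edge <- function(ds) max(which(ds$counts > 0))
youngest_bin_edge <- function(ds) min(which(ds$counts > 0)) - 1
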