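#' Grid-quadrature posterior of the root age (reference evaluator)
#'
#' Deterministic brute-force integration of the unnormalized posterior of
#' `t0` for small datasets, used to validate the MCMC sampler.  The latent
#' trajectory prior is Markov, so for each `t0` on a fine grid the
#' trajectory is integrated out exactly (up to discretisation) by a forward
#' pass over a grid of log-diversity values: free random-walk transition
#' kernels between consecutive bin midpoints, Poisson observation weights
#' at each bin, the diversity floor as the grid's lower limit at 0, and
#' division by the free marginal of the young anchor (which conditions the
#' walk on both anchors).  This shares no code with the sampler.
#'
#' The remaining parameters (`te`, `sigma2`, `q0`, `beta`) are held fixed;
#' the result is the posterior of `t0` conditional on them, under the same
#' uniform root-age prior the sampler uses.
#'
#' @param data A [clade_dataset()].
#' @param prior A [prior_config()].
#' @param te,sigma2,q0,beta Fixed values of the other parameters.
#' @param t0_step Spacing of the `t0` grid in Myr (default 0.1).
#' @param y_max Upper limit of the log-diversity grid (default 6, i.e.
#'   diversity up to ~400 species).
#' @param n_y Number of log-diversity grid points (default 161).
#' @return A list with `t0` (grid), `density` (normalized posterior
#'   density), `median`, `ci_low`, `ci_high` (95% equal-tailed interval).
#' @export
bbb_grid_quadrature <- function(data, prior, te, sigma2, q0, beta,
                                t0_step = 0.1, y_max = 6, n_y = 161) {
  counts <- data$counts
  lo_t0 <- oldest_bin(counts) + 1
  yend <- if (data$is_extinct) 0 else log(data$extant_richness)
  young_age <- if (data$is_extinct) te else 0
  ygrid <- seq(0, y_max, length.out = n_y)   # floor: log N >= 0
  dy <- ygrid[2] - ygrid[1]
  # unit-spacing transition kernel between interior bin midpoints:
  # K[i, j] = density of moving from ygrid[j] to ygrid[i] in 1 Myr
  K <- outer(ygrid, ygrid,
             function(to, from) stats::dnorm(to, from, sqrt(sigma2)))
  t0_grid <- seq(lo_t0, prior$max_age, by = t0_step)
  log_lik <- vapply(t0_grid, function(t0) {
    bins <- rev(lifespan_bins(t0, te))  # oldest first
    mid <- bins + 0.5
    x <- ifelse(bins + 1L <= length(counts), counts[bins + 1L], 0L)
    lam <- preservation_rate(q0, beta, mid, t0) %o% exp(ygrid)
    obs_w <- exp(x * log(lam) - lam - lgamma(x + 1))  # bins x ygrid
    # forward pass from the old anchor (t0, 0); a t0 exactly on the first
    # midpoint pins the first value at the anchor (delta at y = 0)
    dt1 <- t0 - mid[1]
    f <- if (dt1 < 1e-9) {
      as.numeric(ygrid == 0) / dy * obs_w[1, ]
    } else {
      stats::dnorm(ygrid, 0, sqrt(sigma2 * dt1)) * obs_w[1, ]
    }
    log_scale <- 0
    if (length(bins) > 1) {
      for (i in 2:length(bins)) {
        f <- as.vector(K %*% f) * dy * obs_w[i, ]
        s <- sum(f)
        if (s == 0) return(-Inf)
        log_scale <- log_scale + log(s)
        f <- f / s
      }
    }
    # close with the young anchor and condition on it
    span <- mid[length(mid)] - young_age
    lik <- if (span < 1e-9) {
      stats::approx(ygrid, f, xout = yend, rule = 2)$y
    } else {
      sum(f * stats::dnorm(yend, ygrid, sqrt(sigma2 * span))) * dy
    }
    log(lik) + log_scale -
      stats::dnorm(yend, 0, sqrt(sigma2 * (t0 - young_age)), log = TRUE)
  }, numeric(1))
  w <- exp(log_lik - max(log_lik))
  dens <- w / sum(w) / t0_step
  cdf <- cumsum(w) / sum(w)
  qfun <- function(p) t0_grid[which(cdf >= p)[1]]
  list(t0 = t0_grid, density = dens, median = qfun(0.5),
       ci_low = qfun(0.025), ci_high = qfun(0.975))
}
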