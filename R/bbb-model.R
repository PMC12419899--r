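#' Prior configuration for a clade analysis
#'
#' @param max_age Upper bound (Ma) of the uniform prior on the root age; must
#'   strictly exceed the older edge of the oldest non-empty count bin.
#' @param q_var 1 for a time-increasing preservation rate (the default used
#'   throughout), 0 to hold the rate constant (`beta` fixed at 0).
#' @param s2_rate,q0_rate Rates of the exponential hyperpriors on the
#'   random-walk variance `sigma2` (per Myr; default rate 20, mean 0.05)
#'   and the baseline preservation rate `q0` (species per lineage per Myr;
#'   default rate 40, mean 0.025).  The defaults centre each parameter on
#'   the scale typical of deep-time insect fossil records — per-lineage
#'   sampling rates of a few species per hundred lineage-Myr and modest
#'   per-Myr log-diversity steps; for clades with only a handful of
#'   fossils these hyperpriors carry the inference, so their scale must be
#'   realistic rather than merely proper.  An exponential keeps full
#'   support on (0, Inf), so rich records can overrule the scale freely.
#' @param beta_rate Rate of the exponential hyperprior on the preservation
#'   time-increase coefficient `beta` (default rate 200, mean 0.005 per
#'   Myr — a doubling of the sampling rate over ~140 Myr).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(max_age, q_var = 1, s2_rate = 20, q0_rate = 40,
                         beta_rate = 200) {
  stopifnot(is.finite(max_age), max_age > 0, q_var %in% c(0, 1),
            s2_rate > 0, q0_rate > 0, beta_rate > 0)
  structure(list(max_age = max_age, q_var = q_var, s2_rate = s2_rate,
                 q0_rate = q0_rate, beta_rate = beta_rate),
            class = "prior_config")
}

#' Model state
#'
#' One point in the parameter space: root age `t0`, extinction age `te` (0
#' for extant clades), log-diversity random-walk variance `sigma2` (per Myr),
#' preservation parameters `q0` and `beta`, and the latent log-diversity
#' trajectory `log_n` over the lifespan bins.
#'
#' @param t0,te Root and extinction ages (Ma); `t0 > te >= 0`.
#' @param sigma2,q0,beta Positive variance, positive baseline preservation
#'   rate, non-negative time-increase coefficient.
#' @param log_n Numeric vector of log diversity at the midpoints of the
#'   lifespan bins, ordered youngest to oldest bin (see [lifespan_bins()]).
#' @return A list of class `model_state`.
#' @export
model_state <- function(t0, te, sigma2, q0, beta, log_n) {
  stopifnot(t0 > te, te >= 0, sigma2 > 0, q0 > 0, beta >= 0)
  structure(list(t0 = t0, te = te, sigma2 = sigma2, q0 = q0, beta = beta,
                 log_n = as.numeric(log_n)),
            class = "model_state")
}

#' Lifespan bins of a clade
#'
#' Bin `k` (0-based, covering `[k, k + 1)` Ma) is inside the clade lifespan
#' when its midpoint `k + 0.5` lies strictly between the anchors, i.e. in
#' `(te, t0)`; a midpoint coinciding exactly with an anchor age would give
#' the bridge a zero-length (degenerate) increment, so such a bin belongs
#' to the anchor, not the interior.
#'
#' @param t0,te Root and extinction ages (Ma).
#' @return Integer vector of bin indices, ascending (youngest first); empty
#'   when the lifespan covers no bin midpoint.
#' @export
lifespan_bins <- function(t0, te) {
  lo <- floor(te - 0.5) + 1        # smallest k with k + 0.5 > te
  hi <- ceiling(t0 - 0.5) - 1      # largest k with k + 0.5 < t0
  if (hi < lo) return(integer())
  seq.int(lo, hi)
}

#' Fossil preservation rate
#'
#' Expected number of sampled species per living lineage per Myr:
#' `q0 * exp(beta * (t_ref - t))`, increasing towards the present when
#' `beta > 0` and constant (`q0`) when `beta = 0`.  The reference time
#' `t_ref` is the clade's root age, so `q0` is the rate at the clade origin.
#'
#' @param q0 Baseline rate (> 0).
#' @param beta Time-increase coefficient (>= 0).
#' @param t Age(s) in Ma at which to evaluate the rate; `t <= t_ref`.
#' @param t_ref Reference age in Ma.
#' @return Rate(s) per lineage per Myr.
#' @examples
#' preservation_rate(0.1, 0.01, t = 200, t_ref = 300)  # 0.1 * e
#' @export
preservation_rate <- function(q0, beta, t, t_ref) {
  if (any(q0 <= 0) || any(beta < 0)) stop("need q0 > 0 and beta >= 0")
  if (any(t > t_ref)) stop("preservation rate is defined for t <= t_ref")
  q0 * exp(beta * (t_ref - t))
}

# Ordered (age, value) support points of the trajectory: the old anchor at
# (t0, log N(t0)), the bin midpoints from oldest to youngest, and the young
# anchor at (te or 0, log of extinction/extant diversity).
trajectory_points <- function(log_n, t0, te, anchors) {
  bins <- lifespan_bins(t0, te)
  if (length(log_n) != length(bins))
    stop("trajectory length ", length(log_n),
         " inconsistent with lifespan [", te, ", ", t0, "] (",
         length(bins), " bins)")
  list(ages = c(t0, rev(bins) + 0.5, anchors["young_age"]),
       values = c(anchors["old"], rev(log_n), anchors["young"]))
}

#' Brownian-bridge log prior of a latent trajectory
#'
#' Log density of the interior log-diversity values under a Brownian bridge
#' with per-Myr variance `sigma2` between the two anchors: the product of
#' Gaussian increment densities along the path divided by the marginal
#' density of the end anchor given the start anchor (which conditions the
#' walk on both endpoints).  The diversity floor (at least one species while
#' the clade exists, `log_n >= 0`) is enforced by returning `-Inf`.
#'
#' @param log_n Interior log-diversity values, youngest bin first (aligned
#'   with [lifespan_bins()]).
#' @param t0,te Root and extinction ages (Ma).
#' @param sigma2 Per-Myr variance of the log-diversity walk.
#' @param anchors Named numeric vector: `old` (log diversity at `t0`, 0 for
#'   a single founding species), `young` (log diversity at the young
#'   anchor), `young_age` (age of the young anchor: `te` for extinct clades,
#'   0 for extant ones).
#' @return Log density (0 for a lifespan with no interior bin).
#' @export
bridge_log_prior <- function(log_n, t0, te, sigma2,
                             anchors = c(old = 0, young = 0, young_age = te)) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (length(log_n) && any(log_n < 0)) return(-Inf)
  pts <- trajectory_points(log_n, t0, te, anchors)
  dt <- -diff(pts$ages)
  if (any(dt <= 0)) stop("trajectory ages must be strictly decreasing")
  inc <- sum(stats::dnorm(diff(pts$values), 0, sqrt(sigma2 * dt), log = TRUE))
  span <- pts$ages[1] - pts$ages[length(pts$ages)]
  marg <- stats::dnorm(anchors[["young"]] - anchors[["old"]], 0,
                       sqrt(sigma2 * span), log = TRUE)
  inc - marg
}

#' Poisson observation log likelihood
#'
#' Sum over the lifespan bins of the Poisson log pmf of the observed species
#' count with mean `preservation_rate(t) * N_t`.  Any fossil count in a bin
#' outside `[te, t0]` is impossible under the model and yields `-Inf`, which
#' is what forces the root age above the oldest fossil and the extinction
#' age below the youngest.
#'
#' @param counts Per-bin species counts on the global grid (entry `k + 1` =
#'   bin `k`).
#' @param log_n Latent log diversity on the lifespan bins (youngest first).
#' @param q0,beta Preservation parameters (reference time `t0`).
#' @param t0,te Root and extinction ages (Ma).
#' @return Log likelihood.
#' @export
observation_log_likelihood <- function(counts, log_n, q0, beta, t0, te) {
  bins <- lifespan_bins(t0, te)
  if (length(log_n) != length(bins))
    stop("trajectory length inconsistent with lifespan")
  outside <- setdiff(which(counts > 0) - 1L, bins)
  if (length(outside)) return(-Inf)
  x <- ifelse(bins + 1L <= length(counts), counts[bins + 1L], 0L)
  lam <- preservation_rate(q0, beta, bins + 0.5, t0) * exp(log_n)
  sum(stats::dpois(x, lam, log = TRUE))
}

#' Unnormalized log posterior of a model state
#'
#' Sum of the bridge log prior of the trajectory, the Poisson observation
#' log likelihood, a uniform root-age prior on `[older edge of the oldest
#' non-empty bin, max_age]`, a uniform extinction-age prior on `[0, younger
#' edge of the youngest non-empty bin]` for extinct clades (extant clades
#' have `te` fixed at 0), and exponential hyperpriors on `sigma2`, `q0` and
#' (when `q_var = 1`) `beta`.
#'
#' @param state A [model_state()].
#' @param data A [clade_dataset()].
#' @param prior A [prior_config()].
#' @return Unnormalized log posterior; `-Inf` outside the support.
#' @export
log_posterior <- function(state, data, prior) {
  counts <- data$counts
  lo_t0 <- oldest_bin(counts) + 1
  if (state$t0 < lo_t0 || state$t0 > prior$max_age) return(-Inf)
  if (data$is_extinct) {
    if (state$te < 0 || state$te > youngest_bin(counts)) return(-Inf)
    anchors <- c(old = 0, young = 0, young_age = state$te)
  } else {
    if (state$te != 0) return(-Inf)
    anchors <- c(old = 0, young = log(data$extant_richness), young_age = 0)
  }
  lp <- bridge_log_prior(state$log_n, state$t0, state$te, state$sigma2,
                         anchors)
  if (!is.finite(lp)) return(lp)
  ll <- observation_log_likelihood(counts, state$log_n, state$q0, state$beta,
                                   state$t0, state$te)
  if (!is.finite(ll)) return(ll)
  hyper <- stats::dexp(state$sigma2, prior$s2_rate, log = TRUE) +
    stats::dexp(state$q0, prior$q0_rate, log = TRUE)
  if (prior$q_var == 1) {
    hyper <- hyper + stats::dexp(state$beta, prior$beta_rate, log = TRUE)
  } else if (state$beta != 0) {
    return(-Inf)
  }
  lp + ll + hyper
}

#' Conditional mean and variance of a Brownian bridge at one age
#'
#' For a bridge with per-Myr variance `sigma2` pinned at `(age_left,
#' y_left)` and `(age_right, y_right)` (ages in Ma, `age_left > age_right`),
#' the value at an interior age is Gaussian with mean the linear
#' interpolation of the anchors and variance `sigma2 * a * b / (a + b)`,
#' where `a = age_left - age` and `b = age - age_right`.
#'
#' @param age_left,y_left Older anchor (age, value).
#' @param age_right,y_right Younger anchor.
#' @param age Interior age, strictly between the anchors.
#' @param sigma2 Per-Myr variance.
#' @return List with elements `mean` and `var`.
#' @export
bridge_moments <- function(age_left, y_left, age_right, y_right, age, sigma2) {
  if (!(age_left > age && age > age_right)) stop("age must lie between anchors")
  a <- age_left - age
  b <- age - age_right
  list(mean = y_left + (y_right - y_left) * a / (a + b),
       var = sigma2 * a * b / (a + b))
}

#' Sample a Brownian-bridge segment
#'
#' Draws the trajectory values at the given interior ages exactly from the
#' Brownian bridge conditional on both anchors, sequentially from the older
#' end (each draw conditions on the previous point and the young anchor).
#' As `sigma2` tends to 0 the draw tends to the linear interpolation of the
#' anchors.  Uses R's global random number generator, so results are
#' reproducible under [set.seed()].
#'
#' @inheritParams bridge_moments
#' @param ages Interior ages (Ma), strictly decreasing, all inside
#'   `(age_right, age_left)`.
#' @return Numeric vector of sampled values, ordered like `ages`.
#' @export
sample_bridge_segment <- function(age_left, y_left, age_right, y_right,
                                  ages, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (length(ages) && (any(diff(ages) >= 0) || any(ages >= age_left) ||
                       any(ages <= age_right)))
    stop("ages must be strictly decreasing inside (age_right, age_left)")
  out <- numeric(length(ages))
  a_prev <- age_left; y_prev <- y_left
  for (i in seq_along(ages)) {
    m <- bridge_moments(a_prev, y_prev, age_right, y_right, ages[i], sigma2)
    out[i] <- stats::rnorm(1, m$mean, sqrt(m$var))
    a_prev <- ages[i]; y_prev <- out[i]
  }
  out
}
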