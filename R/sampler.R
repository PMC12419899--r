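#' MCMC settings
#'
#' @param iterations Total Metropolis-Hastings iterations per chain
#'   (default 1e6).  Must be divisible by `sampling_freq`.
#' @param sampling_freq Thinning interval (default 1000).
#' @param burnin Fraction of iterations discarded as burn-in, in `[0, 0.5]`
#'   (default 0.10).  Proposal scales are tuned during burn-in only and
#'   frozen afterwards.
#' @param seed Master seed; chain `i` runs under the sub-seed
#'   `seed + 77003 * (i - 1)`, so chains are independent and reproducible
#'   whether run serially or concurrently.
#' @param n_chains Number of independent chains (default 2).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 1e6, sampling_freq = 1000,
                          burnin = 0.10, seed = NULL, n_chains = 2) {
  iterations <- as.integer(iterations)
  sampling_freq <- as.integer(sampling_freq)
  stopifnot(iterations > 0, sampling_freq > 0,
            iterations %% sampling_freq == 0,
            burnin >= 0, burnin <= 0.5, n_chains >= 1)
  structure(list(iterations = iterations, sampling_freq = sampling_freq,
                 burnin = burnin, seed = seed,
                 n_chains = as.integer(n_chains)),
            class = "mcmc_settings")
}

#' Run the MCMC sampler on one clade
#'
#' Samples the posterior of the clade-age model by Metropolis-Hastings with
#' latent-trajectory augmentation (compiled core).  Each chain is
#' initialised at `t0` one Myr above the older edge of the oldest non-empty
#' bin, `te` halfway between 0 and the younger edge of the youngest
#' non-empty bin (extinct clades), and a linearly interpolated trajectory.
#' Moves: sliding windows on `t0` and `te` (with the changed trajectory
#' segment redrawn from the conditional bridge prior, so prior terms cancel
#' in the acceptance ratio), log-scale multipliers on `sigma2`, `q0` and
#' `beta`, and block trajectory redraws from the conditional bridge.
#'
#' @param data A [clade_dataset()].
#' @param prior A [prior_config()].
#' @param settings An [mcmc_settings()].
#' @param fixed Optional named list holding parameters constant, e.g.
#'   `list(sigma2 = 0.05, q0 = 0.3, beta = 0, te = 5)`.  A fixed parameter
#'   is initialised at the given value and never updated.
#' @param prior_only Internal diagnostic switch: replace the observation
#'   likelihood by a constant *and* drop the diversity floor, so the
#'   marginal of `t0` is exactly its uniform prior (used by the
#'   detailed-balance smoke test).
#' @return A `bbb_trace_set`: list with `chains` (one `bbb_trace` data frame
#'   per chain with columns `state`, `logpost`, `t0`, `te`, `sigma2`, `q0`,
#'   `beta`), `data`, `prior`, `settings`, `fixed`, and `final` (last state
#'   of each chain, including the latent trajectory).
#' @export
run_mcmc <- function(data, prior, settings = mcmc_settings(),
                     fixed = list(), prior_only = FALSE) {
  stopifnot(inherits(data, "clade_dataset"), inherits(prior, "prior_config"),
            inherits(settings, "mcmc_settings"))
  counts <- data$counts
  if (!any(counts > 0)) stop("all-zero count vector")
  kf_max <- oldest_bin(counts)
  kf_min <- youngest_bin(counts)
  min_t0 <- kf_max + 1              # older edge of the oldest non-empty bin
  te_max <- if (data$is_extinct) kf_min else 0
  if (prior$max_age <= min_t0)
    stop("max_age (", prior$max_age, ") must exceed the older edge of the ",
         "oldest non-empty bin (", min_t0, ")")

  init <- list(t0 = min(min_t0 + 1, (min_t0 + prior$max_age) / 2),
               te = if (data$is_extinct) te_max / 2 else 0,
               sigma2 = 0.05, q0 = 0.25,
               beta = if (prior$q_var == 1) 0.005 else 0)
  # start q0 on the ridge implied by the initial (linearly interpolated)
  # trajectory, so data-rich clades do not begin far off scale
  young_age <- if (data$is_extinct) init$te else 0
  yend <- if (data$is_extinct) 0 else log(data$extant_richness)
  bins <- lifespan_bins(init$t0, young_age)
  if (length(bins)) {
    n_init <- exp(yend * (init$t0 - (bins + 0.5)) / (init$t0 - young_age))
    init$q0 <- min(2, max(1e-3, sum(counts) / sum(n_init)))
  }
  for (nm in names(fixed)) {
    if (!nm %in% names(init)) stop("unknown fixed parameter: ", nm)
    init[[nm]] <- fixed[[nm]]
  }
  if (init$t0 < min_t0 || init$t0 > prior$max_age)
    stop("fixed/initial t0 outside the prior support")

  seed <- if (is.null(settings$seed)) {
    sample.int(.Machine$integer.max, 1)
  } else {
    as.integer(settings$seed)
  }
  chains <- vector("list", settings$n_chains)
  finals <- vector("list", settings$n_chains)
  for (i in seq_len(settings$n_chains)) {
    set.seed((seed + 77003 * (i - 1)) %% .Machine$integer.max)
    res <- bbb_mcmc_cpp(
      counts = counts, extant_richness = data$extant_richness,
      is_extinct = data$is_extinct, max_age = prior$max_age,
      min_t0 = min_t0, te_max = te_max,
      iterations = settings$iterations,
      sampling_freq = settings$sampling_freq,
      burnin_frac = settings$burnin, q_var = prior$q_var,
      s2_rate = prior$s2_rate, q0_rate = prior$q0_rate,
      beta_rate = prior$beta_rate,
      init_t0 = init$t0, init_te = init$te, init_s2 = init$sigma2,
      init_q0 = init$q0, init_beta = init$beta,
      update_t0 = !"t0" %in% names(fixed),
      update_te = !"te" %in% names(fixed),
      update_s2 = !"sigma2" %in% names(fixed),
      update_q0 = !"q0" %in% names(fixed),
      update_beta = !"beta" %in% names(fixed),
      prior_only = prior_only, adapt = TRUE)
    tr <- as.data.frame(res$samples)
    names(tr) <- c("state", "logpost", "t0", "te", "sigma2", "q0", "beta")
    class(tr) <- c("bbb_trace", "data.frame")
    chains[[i]] <- tr
    finals[[i]] <- res[c("final_y", "final_klo", "final_khi", "final_t0",
                         "final_te", "final_sigma2", "final_q0",
                         "final_beta", "accepts", "proposals", "logpost")]
  }
  structure(list(chains = chains, data = data, prior = prior,
                 settings = settings, fixed = fixed, seed = seed,
                 final = finals),
            class = "bbb_trace_set")
}

# Parameters actually sampled in a trace set (used for ESS reporting).
sampled_params <- function(ts) {
  p <- c("t0", "te", "sigma2", "q0", "beta")
  p <- setdiff(p, names(ts$fixed))
  if (!ts$data$is_extinct) p <- setdiff(p, "te")
  if (ts$prior$q_var != 1) p <- setdiff(p, "beta")
  p
}

#' Effective sample size of an MCMC series
#'
#' Autocorrelation-time ESS, `n / (1 + 2 * sum(rho_k))`, with the
#' autocorrelation sum truncated at the first non-positive term of the
#' initial positive sequence of paired autocorrelations
#' (`rho_{2m} + rho_{2m+1}`).  Capped at `n`.
#'
#' @param series Numeric vector of at least 10 samples.
#' @return ESS (a scalar).  A zero-variance series returns its length with
#'   a degeneracy warning.
#' @export
effective_sample_size <- function(series) {
  n <- length(series)
  if (n < 10) stop("need at least 10 samples for an ESS estimate")
  if (stats::var(series) == 0) {
    warning("zero-variance series; ESS set to the series length")
    return(n)
  }
  rho <- stats::acf(series, lag.max = n - 1, plot = FALSE,
                    demean = TRUE)$acf[-1]
  tau <- 1
  m <- 1
  while (m <= length(rho)) {
    gam <- rho[m] + if (m + 1 <= length(rho)) rho[m + 1] else 0
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 2
  }
  min(n, n / tau)
}

#' Posterior summary of one parameter
#'
#' Pools the post-burn-in samples of all chains and reports the median and
#' the equal-tailed 95% credible interval (2.5% and 97.5% quantiles, linear
#' interpolation).  ESS is computed per chain and summed.
#'
#' @param traces A `bbb_trace_set` from [run_mcmc()], or a list of trace
#'   data frames.
#' @param param Column name, e.g. `"t0"`.
#' @return A list with `param`, `median`, `ci_low`, `ci_high`, `ess`,
#'   `n_samples`, and `low_sample` (TRUE with a warning when fewer than 100
#'   pooled samples are available).
#' @export
summarize_param <- function(traces, param) {
  chains <- if (inherits(traces, "bbb_trace_set")) traces$chains else traces
  x <- unlist(lapply(chains, function(tr) tr[[param]]), use.names = FALSE)
  low <- length(x) < 100
  if (low) warning("fewer than 100 pooled samples for ", param)
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), type = 7))
  ess <- sum(vapply(chains, function(tr)
    effective_sample_size(tr[[param]]), numeric(1)))
  list(param = param, median = q[2], ci_low = q[1], ci_high = q[3],
       ess = ess, n_samples = length(x), low_sample = low)
}

#' Convergence check on effective sample sizes
#'
#' A run is declared convergent when every reported ESS exceeds the
#' threshold (200 by default).
#'
#' @param ess Named numeric vector of effective sample sizes.
#' @param threshold ESS threshold (default 200).
#' @return A list with `converged` (logical) and `failing` (names of the
#'   parameters at or below the threshold).
#' @export
check_convergence <- function(ess, threshold = 200) {
  if (length(ess) == 0) stop("no ESS values to assess")
  failing <- names(ess)[ess <= threshold]
  if (is.null(names(ess)) && any(ess <= threshold))
    failing <- paste0("param", which(ess <= threshold))
  list(converged = all(ess > threshold), failing = failing,
       threshold = threshold)
}

#' Write a trace in Tracer's tab-delimited dialect
#'
#' First column `state` (iteration index), then the log posterior and the
#' model parameters, tab-separated with a header row, as read by Tracer.
#'
#' @param trace A `bbb_trace` data frame (one chain).
#' @param sink Output file path.
#' @return `sink`, invisibly.
#' @export
write_trace_log <- function(trace, sink) {
  if (nrow(trace) == 0) stop("empty trace")
  ok <- try(utils::write.table(
    trace, sink, sep = "\t", quote = FALSE, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write trace log to ", sink, ": ", attr(ok, "condition")$message)
  invisible(sink)
}

#' Read back a Tracer-dialect trace log
#'
#' @param source Path written by [write_trace_log()].
#' @return A `bbb_trace` data frame.
#' @export
read_trace_log <- function(source) {
  tr <- utils::read.table(source, header = TRUE, sep = "\t")
  class(tr) <- c("bbb_trace", "data.frame")
  tr
}

#' Summarize a full run into one results row
#'
#' @param traces A `bbb_trace_set`.
#' @param ess_threshold Convergence threshold on ESS (default 200).
#' @return One-row data frame with clade, rank, occurrence count, root and
#'   extinction medians and 95% CIs (extinction columns `NA` for extant
#'   clades), per-parameter ESS, and the convergence flag.
#' @export
summarize_run <- function(traces, ess_threshold = 200) {
  d <- traces$data
  pars <- sampled_params(traces)
  s_t0 <- summarize_param(traces, "t0")
  ess <- c(t0 = s_t0$ess, te = NA_real_, sigma2 = NA_real_,
           q0 = NA_real_, beta = NA_real_)
  row <- data.frame(
    clade = d$clade_name, rank = d$rank, max_age = traces$prior$max_age,
    n_occurrences = sum(d$counts),
    root_median = s_t0$median, root_CI_low = s_t0$ci_low,
    root_CI_high = s_t0$ci_high,
    ext_median = NA_real_, ext_CI_low = NA_real_, ext_CI_high = NA_real_,
    stringsAsFactors = FALSE)
  if (d$is_extinct && "te" %in% pars) {
    s_te <- summarize_param(traces, "te")
    row$ext_median <- s_te$median
    row$ext_CI_low <- s_te$ci_low
    row$ext_CI_high <- s_te$ci_high
    ess["te"] <- s_te$ess
  }
  for (p in intersect(pars, c("sigma2", "q0", "beta")))
    ess[p] <- summarize_param(traces, p)$ess
  conv <- check_convergence(ess[!is.na(ess)], ess_threshold)
  row$ess_t0 <- ess[["t0"]]; row$ess_te <- ess[["te"]]
  row$ess_sigma2 <- ess[["sigma2"]]; row$ess_q0 <- ess[["q0"]]
  row$ess_beta <- ess[["beta"]]
  row$converged <- conv$converged
  row
}
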