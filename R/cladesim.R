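#' Simulate a latent diversity trajectory
#'
#' Forward simulation of the geometric random walk the model assumes: log
#' diversity starts at 0 (one species) at the root age `t0` and steps by
#' `Normal(0, sigma2)` per Myr, evaluated at the 1-Myr bin midpoints.  A
#' clade goes extinct when its diversity first drops below one species; the
#' extinction age is the older edge of the bin where that happens.
#' Rejection sampling conditions on the requested fate: `mode = "extant"`
#' keeps only walks surviving to the present (and records the present-day
#' richness), `mode = "extinct"` only walks dying before the present.
#' Unlike the inference machinery, this is an unconditioned walk plus
#' rejection — mechanistically independent of the bridge construction.
#'
#' Uses R's global RNG ([set.seed()] for reproducibility).
#'
#' @param t0 Root age (Ma), > 0.
#' @param sigma2 Per-Myr variance of the log-diversity walk (>= 0).
#' @param mode `"extant"` or `"extinct"`.
#' @param max_tries Rejection cap; exceeding it is an error suggesting a
#'   parameter change.
#' @return A list with `bins` (0-based lifespan bin indices, ascending),
#'   `log_n` (log diversity at those bin midpoints, aligned), `t0`, `te`
#'   (0 for extant walks), and `extant_richness` (`max(1, round(N(0)))` for
#'   extant walks, 0 otherwise).
#' @export
simulate_trajectory <- function(t0, sigma2, mode = c("extant", "extinct"),
                                max_tries = 50000) {
  mode <- match.arg(mode)
  stopifnot(t0 > 0, sigma2 >= 0)
  bins <- rev(lifespan_bins(t0, 0))  # oldest first
  mid <- bins + 0.5
  dt <- c(t0 - mid[1], -diff(mid))
  for (try in seq_len(max_tries)) {
    y <- cumsum(stats::rnorm(length(mid), 0, sqrt(sigma2 * dt)))
    dead <- which(y < 0)
    if (mode == "extant") {
      if (length(dead)) next
      y0 <- y[length(y)] +
        stats::rnorm(1, 0, sqrt(sigma2 * mid[length(mid)]))
      richness <- max(1, round(exp(y0)))
      return(list(bins = rev(bins), log_n = rev(y), t0 = t0, te = 0,
                  extant_richness = richness))
    } else {
      if (!length(dead)) next
      last <- dead[1] - 1L               # last bin with >= 1 species
      te <- bins[dead[1]] + 1            # older edge of the failing bin
      if (te <= 0) next
      if (last == 0L) next               # dead on arrival; no surviving bin
      keep <- seq_len(last)
      return(list(bins = rev(bins[keep]), log_n = rev(y[keep]), t0 = t0,
                  te = te, extant_richness = 0))
    }
  }
  stop("no ", mode, " trajectory accepted after ", max_tries,
       " tries; adjust t0 or sigma2")
}

#' Simulate fossil counts for a trajectory
#'
#' Per-bin species counts drawn `Poisson(preservation_rate(t) * N_t)` inside
#' the lifespan (reference time `t0`), zero outside.
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param q0,beta Preservation parameters.
#' @return Integer count vector on the global grid (entry `k + 1` = bin `k`),
#'   of length `max(bins) + 1`.
#' @export
simulate_fossil_counts <- function(traj, q0, beta) {
  if (q0 < 0 || beta < 0) stop("need q0 >= 0 and beta >= 0")
  lam <- if (q0 == 0) rep(0, length(traj$bins)) else
    preservation_rate(q0, beta, traj$bins + 0.5, traj$t0) * exp(traj$log_n)
  x <- stats::rpois(length(lam), lam)
  counts <- integer(max(traj$bins) + 1L)
  counts[traj$bins + 1L] <- x
  counts
}

#' Simulate one clade with its truth record
#'
#' Draws true parameters from the given ranges (uniform), simulates a
#' trajectory of the requested fate and its fossil counts, and retries
#' until the record contains at least one fossil (a clade with no fossils
#' is unobservable and outside the model's scope).
#'
#' @param mode `"extant"` or `"extinct"`.
#' @param name Clade label for the dataset.
#' @param t0_range,sigma2_range,q0_range,beta_range Ranges of the true
#'   parameter values.  Defaults span the scale of a deep-time insect
#'   fossil record: root ages 80-320 Ma, walk variance 0.01-0.1 per Myr,
#'   baseline preservation 0.005-0.05 species per lineage per Myr, and
#'   preservation increase 0-0.01 per Myr.
#' @return A `simulated_clade`: list with `truth` (t0, te, sigma2, q0,
#'   beta, trajectory) and `dataset` (a [clade_dataset()]).
#' @export
simulate_clade <- function(mode = c("extant", "extinct"), name = "sim",
                           t0_range = c(80, 320),
                           sigma2_range = c(0.01, 0.1),
                           q0_range = c(0.005, 0.05),
                           beta_range = c(0, 0.01)) {
  mode <- match.arg(mode)
  for (try in 1:1000) {
    t0 <- stats::runif(1, t0_range[1], t0_range[2])
    sigma2 <- stats::runif(1, sigma2_range[1], sigma2_range[2])
    q0 <- stats::runif(1, q0_range[1], q0_range[2])
    beta <- stats::runif(1, beta_range[1], beta_range[2])
    traj <- simulate_trajectory(t0, sigma2, mode)
    counts <- simulate_fossil_counts(traj, q0, beta)
    if (!any(counts > 0)) next
    ds <- clade_dataset(name, "family", counts, traj$extant_richness)
    return(structure(list(
      truth = list(t0 = t0, te = traj$te, sigma2 = sigma2, q0 = q0,
                   beta = beta, bins = traj$bins, log_n = traj$log_n,
                   extant_richness = traj$extant_richness),
      dataset = ds), class = "simulated_clade"))
  }
  stop("failed to simulate a clade with at least one fossil")
}

#' Benchmark suites of simulated clades
#'
#' The three standard compositions used for parameter-recovery experiments:
#' 10 extant clades (`"extant10"`), five extant and five extinct
#' (`"mixed5_5"`), or 10 extinct (`"extinct10"`).
#'
#' @param preset `"extant10"`, `"mixed5_5"` or `"extinct10"`.
#' @param seed Seed for the suite (applied via [set.seed()]).
#' @param ... Passed on to [simulate_clade()] (truth-range overrides).
#' @return List of `simulated_clade` objects with names `sim_extant_i` /
#'   `sim_extinct_i`.
#' @export
make_benchmark_suite <- function(preset = c("extant10", "mixed5_5",
                                            "extinct10"), seed = 1, ...) {
  preset <- match.arg(preset)
  comp <- switch(preset,
                 extant10 = c(extant = 10, extinct = 0),
                 mixed5_5 = c(extant = 5, extinct = 5),
                 extinct10 = c(extant = 0, extinct = 10))
  set.seed(seed)
  suite <- list()
  for (mode in c("extant", "extinct")) {
    for (i in seq_len(comp[[mode]])) {
      nm <- sprintf("sim_%s_%d", mode, i)
      suite[[nm]] <- simulate_clade(mode, name = nm, ...)
    }
  }
  suite
}

#' Write a benchmark suite to disk
#'
#' One TSV of per-bin counts per clade plus a truth-table TSV.
#'
#' @param suite From [make_benchmark_suite()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- do.call(rbind, lapply(names(suite), function(nm) {
    tr <- suite[[nm]]$truth
    data.frame(clade = nm, t0 = tr$t0, te = tr$te, sigma2 = tr$sigma2,
               q0 = tr$q0, beta = tr$beta,
               extant_richness = tr$extant_richness,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(suite)) {
    ds <- suite[[nm]]$dataset
    tab <- data.frame(bin = seq_along(ds$counts) - 1L, count = ds$counts,
                      extant_richness = ds$extant_richness)
    utils::write.table(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
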