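#' Configuration of a full multi-rank analysis
#'
#' @param occurrences,richness,timescale Paths to the input tables (see
#'   [read_occurrence_table()], [read_richness_table()],
#'   [read_timescale()]).
#' @param max_ages Maximum-age prior settings (Ma); every clade is analysed
#'   once per setting.  Default `c(325, 350, 386, 407)`.
#' @param q_var 1 (default) for the time-increasing preservation model.
#' @param settings An [mcmc_settings()].
#' @param outdir Output directory for trace logs and tables (`NULL` to skip
#'   writing).
#' @param seed Master seed; per-run seeds are derived by hashing (master
#'   seed, clade, rank, max_age), so adding clades never perturbs other
#'   clades' chains.
#' @param order_name Label of the pooled order-level analysis using all
#'   occurrences (default `"order_pooled"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(occurrences, richness = NULL, timescale = NULL,
                       max_ages = c(325, 350, 386, 407), q_var = 1,
                       settings = mcmc_settings(), outdir = NULL, seed = 1,
                       order_name = "order_pooled") {
  if (!length(max_ages)) stop("max_ages must be non-empty")
  structure(list(occurrences = occurrences, richness = richness,
                 timescale = timescale, max_ages = max_ages, q_var = q_var,
                 settings = settings, outdir = outdir, seed = seed,
                 order_name = order_name),
            class = "run_config")
}

# Deterministic 31-bit seed from (master seed, clade, rank, max_age).
derive_seed <- function(master, clade, rank, max_age) {
  s <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(paste(clade, rank, max_age, sep = "|")))
    s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

#' Run the full multi-rank analysis
#'
#' Ingests the occurrence table, deduplicates it by species and stage,
#' builds the analysis plan over the four taxonomic ranks plus one pooled
#' order-level dataset, and runs the sampler once per (clade, max_age).
#' Propagation aliases (monotypic higher ranks) copy the smaller-rank
#' summary instead of re-running.  Failed runs are recorded with an error
#' message, never silently dropped.
#'
#' @param config A [run_config()].
#' @return A data frame with one row per (clade, max_age): the summary
#'   columns of [summarize_run()] plus `action` (`run`/`alias`/`error`),
#'   `suborder`, and `error` (message, `NA` on success).  Attribute
#'   `n_failed` counts failed runs.
#' @export
run_analysis <- function(config) {
  occs <- read_occurrence_table(config$occurrences)
  if (nrow(occs) == 0L) stop("empty occurrence table")
  ts <- if (is.null(config$timescale)) read_timescale() else
    read_timescale(config$timescale)
  occs <- deduplicate_occurrences(occs, ts)
  richness <- if (is.null(config$richness)) NULL else
    read_richness_table(config$richness)
  plan <- build_analysis_plan(occs)
  oldest <- max(mean_age(occs))
  if (any(config$max_ages <= oldest))
    stop("every max_age must exceed the oldest occurrence mean age (",
         round(oldest, 2), " Ma)")

  # suborder label of each clade (for the period tallies)
  suborder_of <- function(clade, rank) {
    if (rank == "suborder") return(clade)
    if (rank == "order") return(NA_character_)
    v <- occs$suborder[!is.na(occs[[rank]]) & occs[[rank]] == clade]
    if (length(unique(v[!is.na(v)])) == 1L) unique(v[!is.na(v)]) else
      NA_character_
  }

  plan <- rbind(plan, data.frame(clade = config$order_name, rank = "order",
                                 n_occurrences = nrow(occs), action = "run",
                                 alias_clade = NA, alias_rank = NA))
  if (!is.null(config$outdir))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(plan))) {
    if (plan$action[i] != "run") next
    clade <- plan$clade[i]; rank <- plan$rank[i]
    dataset <- assemble_clade_dataset(occs, clade, rank, richness)
    for (ma in config$max_ages) {
      st <- config$settings
      st$seed <- derive_seed(config$seed, clade, rank, ma)
      res <- tryCatch({
        tr <- run_mcmc(dataset, prior_config(ma, q_var = config$q_var), st)
        if (!is.null(config$outdir))
          for (ci in seq_along(tr$chains))
            write_trace_log(tr$chains[[ci]], file.path(
              config$outdir,
              sprintf("%s_%s_ma%g_chain%d.log", rank, clade, ma, ci)))
        row <- summarize_run(tr)
        row$action <- "run"; row$error <- NA_character_
        row
      }, error = function(e) {
        data.frame(clade = clade, rank = rank, max_age = ma,
                   n_occurrences = sum(dataset$counts),
                   root_median = NA_real_, root_CI_low = NA_real_,
                   root_CI_high = NA_real_, ext_median = NA_real_,
                   ext_CI_low = NA_real_, ext_CI_high = NA_real_,
                   ess_t0 = NA_real_, ess_te = NA_real_,
                   ess_sigma2 = NA_real_, ess_q0 = NA_real_,
                   ess_beta = NA_real_, converged = FALSE,
                   action = "error", error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      if (res$action[1] == "error") n_failed <- n_failed + 1L
      res$suborder <- suborder_of(clade, rank)
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  # propagation aliases copy the smaller-rank rows
  for (i in which(plan$action == "alias")) {
    src <- out[out$clade == plan$alias_clade[i] &
                 out$rank == plan$alias_rank[i], , drop = FALSE]
    src$clade <- plan$clade[i]
    src$rank <- plan$rank[i]
    src$action <- "alias"
    src$suborder <- suborder_of(plan$clade[i], plan$rank[i])
    out <- rbind(out, src)
  }
  rank_order <- c(family = 1, superfamily = 2, infraorder = 3,
                  suborder = 4, order = 5)
  out <- out[order(rank_order[out$rank], out$clade, out$max_age), ]
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  attr(out, "plan") <- plan
  out
}

#' Prior-sensitivity test across maximum-age settings
#'
#' Compares family-level root-age medians obtained under different
#' maximum-age priors: for each pair of settings, a paired two-sided
#' Wilcoxon signed-rank test on the per-family medians (families paired
#' with themselves across settings), with a two-sample Kolmogorov-Smirnov
#' check as a secondary report.
#'
#' @param summaries A summary data frame (as from [run_analysis()] or
#'   [write_summary_table()] read back) with columns `clade`, `rank`,
#'   `max_age`, `root_median`.  Only `rank == "family"` rows are used.
#' @param min_pairs Minimum families required per pair (default 6); below
#'   it a power warning is issued and no p-value returned for that pair.
#' @return Data frame with one row per settings pair: `max_age_a`,
#'   `max_age_b`, `n_pairs`, `statistic`, `p_value`, `ks_p_value`.
#' @export
prior_sensitivity_test <- function(summaries, min_pairs = 6) {
  fam <- summaries[summaries$rank == "family" &
                     is.finite(summaries$root_median), , drop = FALSE]
  settings <- sort(unique(fam$max_age))
  if (length(settings) < 2)
    stop("need summaries under at least two max_age settings; run the ",
         "analysis with multiple priors first")
  pairs <- utils::combn(settings, 2)
  out <- NULL
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- fam[fam$max_age == a, c("clade", "root_median")]
    xb <- fam[fam$max_age == b, c("clade", "root_median")]
    m <- merge(xa, xb, by = "clade", suffixes = c("_a", "_b"))
    n <- nrow(m)
    if (n < min_pairs) {
      warning("only ", n, " family pairs for max_age ", a, " vs ", b,
              "; too few for a sensitivity test")
      out <- rbind(out, data.frame(max_age_a = a, max_age_b = b,
                                   n_pairs = n, statistic = NA_real_,
                                   p_value = NA_real_,
                                   ks_p_value = NA_real_))
      next
    }
    d <- m$root_median_a - m$root_median_b
    if (all(d == 0)) {
      w <- list(statistic = 0, p.value = 1)  # no detectable difference
    } else {
      w <- suppressWarnings(
        stats::wilcox.test(m$root_median_a, m$root_median_b,
                           paired = TRUE, exact = FALSE))
    }
    ks <- suppressWarnings(
      stats::ks.test(m$root_median_a, m$root_median_b))
    out <- rbind(out, data.frame(
      max_age_a = a, max_age_b = b, n_pairs = n,
      statistic = unname(w$statistic), p_value = w$p.value,
      ks_p_value = ks$p.value))
  }
  out
}

#' Origination and extinction counts per geological period
#'
#' Assigns each clade's origination to the geological period containing its
#' posterior root-age median, and each extinct clade's extinction to the
#' period of its extinction median, tallied per suborder.  Periods are
#' half-open on the young side, so an age exactly on a boundary goes to the
#' older period.
#'
#' @param summaries Summary data frame with columns `clade`, `suborder`,
#'   `root_median`, `ext_median` (NA for extant clades).  Typically the
#'   family-level rows under one max_age setting.
#' @param ts A `geo_timescale` providing period-level intervals.
#' @return An `event_counts` data frame: `period`, `suborder`, `event`
#'   (`origination`/`extinction`), `n`, covering all periods (zero-filled),
#'   ordered old to young.
#' @export
count_events_by_period <- function(summaries, ts) {
  periods <- ts[ts$level == "period", , drop = FALSE]
  periods <- periods[order(-periods$age_older), ]
  subs <- unique(summaries$suborder)
  if (anyNA(subs)) subs[is.na(subs)] <- "unassigned"
  subs <- unique(subs)
  if (!length(subs)) subs <- "unassigned"
  grid <- expand.grid(period = periods$name, suborder = subs,
                      event = c("origination", "extinction"),
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  assign1 <- function(age, clade) {
    p <- timescale_interval(ts, age, "period")
    if (is.na(p))
      stop("median age ", age, " of clade '", clade,
           "' falls outside the timescale span")
    p
  }
  for (i in seq_len(nrow(summaries))) {
    sb <- summaries$suborder[i]
    if (is.na(sb)) sb <- "unassigned"
    if (is.finite(summaries$root_median[i])) {
      p <- assign1(summaries$root_median[i], summaries$clade[i])
      j <- grid$period == p & grid$suborder == sb &
        grid$event == "origination"
      grid$n[j] <- grid$n[j] + 1L
    }
    if (!is.null(summaries$ext_median) &&
        is.finite(summaries$ext_median[i])) {
      p <- assign1(summaries$ext_median[i], summaries$clade[i])
      j <- grid$period == p & grid$suborder == sb &
        grid$event == "extinction"
      grid$n[j] <- grid$n[j] + 1L
    }
  }
  class(grid) <- c("event_counts", "data.frame")
  grid
}

#' Write (and read back) the summary table
#'
#' One row per (clade, max_age), tab-separated, rows ordered by rank then
#' clade name then max_age.
#'
#' @param summaries Summary data frame from [run_analysis()].
#' @param sink Output TSV path.
#' @return `sink`, invisibly.
#' @export
write_summary_table <- function(summaries, sink) {
  if (is.null(summaries) || nrow(summaries) == 0)
    stop("no summaries to write")
  rank_order <- c(family = 1, superfamily = 2, infraorder = 3,
                  suborder = 4, order = 5)
  summaries <- summaries[order(rank_order[summaries$rank],
                               summaries$clade, summaries$max_age), ]
  ok <- try(utils::write.table(summaries, sink, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write summary table to ", sink)
  invisible(sink)
}

#' @rdname write_summary_table
#' @param source Path of a summary TSV.
#' @export
read_summary_table <- function(source) {
  utils::read.table(source, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
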