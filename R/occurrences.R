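#' Read a fossil occurrence table
#'
#' One row per species occurrence: a species recorded from one deposit with a
#' stratigraphic age interval (older and younger boundary in Ma) and optional
#' rank labels (family, superfamily, infraorder, suborder).  Rows with
#' missing or inverted ages are rejected and reported by row index.
#'
#' @param source Path to a CSV or TSV file.  Mandatory columns: `species`,
#'   `suborder`, `age_older`, `age_younger`.  Recognised optional columns:
#'   `family`, `superfamily`, `infraorder`, `deposit`, `stage`.
#' @return A `fossil_occurrences` data frame with one row per valid
#'   occurrence.  Invalid rows are dropped with a warning listing their
#'   indices (an error if *all* rows are invalid ages inverted).
#' @examples
#' src <- system.file("extdata", "synthetic_occurrences.csv", package = "bbbridge")
#' occ <- read_occurrence_table(src)
#' nrow(occ)
#' @export
read_occurrence_table <- function(source) {
  tab <- read_delim_auto(source)
  # tolerate a "species_name" alias
  if (!"species" %in% names(tab) && "species_name" %in% names(tab))
    names(tab)[names(tab) == "species_name"] <- "species"
  need <- c("species", "suborder", "age_older", "age_younger")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("occurrence table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("family", "superfamily", "infraorder", "deposit", "stage"))
    if (!col %in% names(tab)) tab[[col]] <- rep(NA_character_, nrow(tab))
  tab$age_older   <- suppressWarnings(as.numeric(tab$age_older))
  tab$age_younger <- suppressWarnings(as.numeric(tab$age_younger))

  if (nrow(tab) == 0L) {
    warning("occurrence table has a header but no rows")
    return(empty_occurrences())
  }
  bad_missing <- which(is.na(tab$age_older) | is.na(tab$age_younger) |
                         is.na(tab$species) | tab$species == "")
  bad_order <- which(!seq_len(nrow(tab)) %in% bad_missing &
                       tab$age_older < tab$age_younger)
  if (length(bad_order))
    stop("rows with age_older < age_younger: ",
         paste(bad_order, collapse = ", "))
  if (any(tab$age_younger < 0, na.rm = TRUE))
    stop("negative ages in occurrence table")
  if (length(bad_missing)) {
    warning("dropping ", length(bad_missing),
            " row(s) with missing species or ages: ",
            paste(bad_missing, collapse = ", "))
    tab <- tab[-bad_missing, , drop = FALSE]
  }
  out <- tab[, c("species", "family", "superfamily", "infraorder", "suborder",
                 "deposit", "stage", "age_older", "age_younger")]
  rownames(out) <- NULL
  class(out) <- c("fossil_occurrences", "data.frame")
  out
}

empty_occurrences <- function() {
  out <- data.frame(species = character(), family = character(),
                    superfamily = character(), infraorder = character(),
                    suborder = character(), deposit = character(),
                    stage = character(), age_older = numeric(),
                    age_younger = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("fossil_occurrences", "data.frame")
  out
}

#' Mean age of a species occurrence
#'
#' The midpoint of the stratigraphic age interval, `(age_older +
#' age_younger) / 2`.  Using the midpoint rather than either boundary avoids
#' systematically inflating or deflating species ages for deposits whose age
#' spans two stages (amber deposits are the classic case).
#'
#' @param occ A `fossil_occurrences` data frame (or any data frame with
#'   `age_older` / `age_younger` columns).
#' @return Numeric vector of mean ages in Ma, one per occurrence.
#' @examples
#' mean_age(data.frame(age_older = 325, age_younger = 315))  # 320
#' @export
mean_age <- function(occ) {
  if (any(occ$age_older < occ$age_younger, na.rm = TRUE))
    stop("age_older < age_younger")
  (occ$age_older + occ$age_younger) / 2
}

#' Deduplicate occurrences by species and geological stage
#'
#' Keeps one occurrence per species, except when a species is recorded from
#' deposits assigned to different stages, in which case one occurrence is
#' kept per stage (the first in input order within each stage).  Occurrences
#' without a stage label are assigned the stage containing the midpoint of
#' their age interval.
#'
#' @param occs A `fossil_occurrences` data frame.
#' @param ts A `geo_timescale`, used to resolve missing stage labels.
#' @return The retained occurrences, with a filled-in `stage` column.
#' @export
deduplicate_occurrences <- function(occs, ts) {
  if (nrow(occs) == 0L) return(occs)
  stage <- occs$stage
  need <- which(is.na(stage) | stage == "")
  if (length(need)) {
    mid <- mean_age(occs[need, , drop = FALSE])
    resolved <- timescale_interval(ts, mid, "stage")
    if (anyNA(resolved))
      stop("unresolvable stage for occurrence row(s) ",
           paste(need[is.na(resolved)], collapse = ", "),
           " (age midpoint outside the timescale span and no stage label)")
    stage[need] <- resolved
  }
  occs$stage <- stage
  keep <- !duplicated(paste(occs$species, stage, sep = "\r"))
  out <- occs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compile species occurrences into 1-Myr bins
#'
#' Bin `k` (0-based) covers ages `[k, k + 1)` Ma counted from the present, so
#' bin 0 is 0-1 Ma and an age exactly on a boundary falls in the bin whose
#' lower edge it equals.  Entry `k + 1` of the returned vector is the number
#' of occurrences whose mean age lies in bin `k`.
#'
#' @param occs Deduplicated `fossil_occurrences`.
#' @return Integer vector of per-bin species counts, of length
#'   `ceiling(max(mean_age)) + 1` (length 1 for empty input); its sum equals
#'   the number of occurrences.
#' @export
bin_species_counts <- function(occs) {
  ages <- mean_age(occs)
  if (length(ages) == 0L) return(0L)
  bins <- floor(ages)
  len <- ceiling(max(ages)) + 1L
  counts <- tabulate(bins + 1L, nbins = max(len, max(bins) + 1L))
  as.integer(counts)
}

#' Assemble the per-clade dataset for one analysis
#'
#' Restricts the occurrences to one clade at one taxonomic rank, bins them,
#' and attaches the clade's extant species richness (0, i.e. extinct, when
#' the clade is absent from the richness table).
#'
#' @param occs Deduplicated `fossil_occurrences`.
#' @param clade_name Clade label to select.
#' @param rank One of `"family"`, `"superfamily"`, `"infraorder"`,
#'   `"suborder"`, `"order"`.  Rank `"order"` pools all occurrences.
#' @param richness A data frame with columns `clade`, `rank`,
#'   `extant_species`, or `NULL` for an extinct clade.
#' @return A [clade_dataset()] object.
#' @export
assemble_clade_dataset <- function(occs, clade_name, rank, richness = NULL) {
  rank <- match.arg(rank, c("family", "superfamily", "infraorder",
                            "suborder", "order"))
  sel <- if (rank == "order") occs else
    occs[!is.na(occs[[rank]]) & occs[[rank]] == clade_name, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("clade '", clade_name, "' has no occurrences at rank ", rank,
         "; the model is undefined without fossils")
  rich <- 0
  if (!is.null(richness)) {
    hit <- which(richness$clade == clade_name & richness$rank == rank)
    if (length(hit)) rich <- richness$extant_species[hit[1]]
  }
  clade_dataset(clade_name, rank, bin_species_counts(sel), rich)
}

#' Per-clade species-count dataset
#'
#' The observation unit of the model: a vector of species counts per 1-Myr
#' bin (entry `k + 1` = bin `[k, k + 1)` Ma) plus the clade's present-day
#' species richness.  A clade is extinct exactly when its extant richness
#' is 0.
#'
#' @param clade_name,rank Clade identity.
#' @param counts Non-negative integer vector of per-bin species counts with
#'   at least one non-zero entry.
#' @param extant_richness Non-negative integer; 0 marks an extinct clade.
#' @return A list of class `clade_dataset` with fields `clade_name`, `rank`,
#'   `counts`, `extant_richness`, `is_extinct`.
#' @export
clade_dataset <- function(clade_name, rank, counts, extant_richness = 0) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("negative species counts")
  if (!any(counts > 0)) stop("clade_dataset needs at least one non-zero bin")
  if (extant_richness < 0) stop("negative extant richness")
  structure(list(clade_name = as.character(clade_name),
                 rank = as.character(rank),
                 counts = counts,
                 extant_richness = as.numeric(extant_richness),
                 is_extinct = extant_richness == 0),
            class = "clade_dataset")
}

#' @export
print.clade_dataset <- function(x, ...) {
  nz <- which(x$counts > 0) - 1L
  cat("clade_dataset:", x$clade_name, paste0("(", x$rank, ")"), "\n",
      " occurrences:", sum(x$counts),
      " in bins", min(nz), "-", max(nz), "Ma\n",
      if (x$is_extinct) " extinct\n" else
        paste(" extant richness:", x$extant_richness, "\n"))
  invisible(x)
}

# bin indices (0-based) of the oldest / youngest non-empty bin
oldest_bin <- function(counts) max(which(counts > 0)) - 1L
youngest_bin <- function(counts) min(which(counts > 0)) - 1L

#' Build the multi-rank analysis plan
#'
#' Lists one analysis per clade per rank (family, superfamily, infraorder,
#' suborder).  When a higher-rank clade contains exactly one clade at the
#' rank immediately below (all of its occurrences carrying that single
#' label), the analysis is not duplicated: the higher rank becomes an alias
#' of the smaller-rank run and inherits its result.  Aliases resolve
#' transitively to an actual run.
#'
#' @param occs Deduplicated `fossil_occurrences` with rank-label columns.
#' @return A data frame with columns `clade`, `rank`, `n_occurrences`,
#'   `action` (`"run"` or `"alias"`), `alias_clade`, `alias_rank` (the run a
#'   propagation alias points to; `NA` for runs).
#' @export
build_analysis_plan <- function(occs) {
  ranks <- c("family", "superfamily", "infraorder", "suborder")
  # hierarchy consistency: each label maps to a single parent label
  for (i in seq_len(length(ranks) - 1L)) {
    lo <- occs[[ranks[i]]]; hi <- occs[[ranks[i + 1L]]]
    ok <- !is.na(lo) & !is.na(hi)
    parents <- tapply(hi[ok], lo[ok], function(v) length(unique(v)))
    if (any(parents > 1L))
      stop(ranks[i], " '", names(parents)[parents > 1L][1],
           "' is mapped to more than one ", ranks[i + 1L])
  }
  plan <- NULL
  for (ri in seq_along(ranks)) {
    rk <- ranks[ri]
    labs <- occs[[rk]]
    for (clade in unique(labs[!is.na(labs)])) {
      members <- occs[!is.na(labs) & labs == clade, , drop = FALSE]
      action <- "run"; ac <- NA_character_; ar <- NA_character_
      if (ri > 1L) {
        child_lab <- members[[ranks[ri - 1L]]]
        kids <- unique(child_lab[!is.na(child_lab)])
        if (length(kids) == 1L && !anyNA(child_lab)) {
          # monotypic: propagate the smaller-rank result upward
          action <- "alias"; ac <- kids; ar <- ranks[ri - 1L]
          # resolve chains (e.g. suborder -> infraorder -> superfamily run)
          repeat {
            hit <- which(plan$clade == ac & plan$rank == ar)
            if (!length(hit) || plan$action[hit] == "run") break
            ar <- plan$alias_rank[hit]; ac <- plan$alias_clade[hit]
          }
        }
      }
      plan <- rbind(plan, data.frame(clade = clade, rank = rk,
                                     n_occurrences = nrow(members),
                                     action = action, alias_clade = ac,
                                     alias_rank = ar,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(plan) <- NULL
  plan
}

#' Read a clade richness table
#'
#' @param source CSV/TSV with columns `clade`, `rank`, `extant_species`.
#' @return Data frame with those columns.
#' @export
read_richness_table <- function(source) {
  tab <- read_delim_auto(source)
  need <- c("clade", "rank", "extant_species")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("richness table is missing column(s): ", paste(miss, collapse = ", "))
  tab$extant_species <- as.numeric(tab$extant_species)
  if (any(!is.finite(tab$extant_species)) || any(tab$extant_species < 0))
    stop("extant_species must be non-negative numbers")
  tab[, need]
}
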