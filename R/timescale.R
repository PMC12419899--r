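#' Read a geological timescale table
#'
#' Reads a CSV/TSV table of named geological intervals at two hierarchical
#' levels (`stage` and `period`) and validates it: within each level the
#' intervals must be non-overlapping and contiguous over the span they cover,
#' and each interval must have `age_older > age_younger`.
#'
#' @param source Path to a CSV or TSV file with columns `name`, `level`,
#'   `age_older`, `age_younger` (ages in Ma, older first).
#' @return A `geo_timescale` object: a data frame of intervals ordered from
#'   youngest to oldest within each level.
#' @examples
#' ts <- read_timescale()          # packaged ICS-derived fixture
#' head(ts[ts$level == "period", ])
#' @export
read_timescale <- function(source = system.file("extdata", "timescale_ics.csv",
                                                package = "bbbridge")) {
  tab <- read_delim_auto(source)
  need <- c("name", "level", "age_older", "age_younger")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("timescale table is missing column(s): ", paste(miss, collapse = ", "))
  tab$age_older   <- as.numeric(tab$age_older)
  tab$age_younger <- as.numeric(tab$age_younger)
  if (any(!is.finite(tab$age_older)) || any(!is.finite(tab$age_younger)))
    stop("timescale table has non-numeric ages")
  if (any(tab$age_older <= tab$age_younger))
    stop("timescale intervals must have age_older > age_younger")
  if (!all(tab$level %in% c("stage", "period")))
    stop("timescale levels must be 'stage' or 'period'")
  out <- NULL
  for (lev in unique(tab$level)) {
    sub <- tab[tab$level == lev, , drop = FALSE]
    sub <- sub[order(sub$age_younger), , drop = FALSE]
    gaps <- abs(sub$age_older[-nrow(sub)] - sub$age_younger[-1])
    if (any(gaps > 1e-6))
      stop("timescale level '", lev, "' is not contiguous near ",
           sub$name[which(gaps > 1e-6)[1]])
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  class(out) <- c("geo_timescale", "data.frame")
  out
}

#' Look up the interval containing an age
#'
#' Intervals are half-open on the old side, `[age_younger, age_older)`, so
#' an age exactly on a boundary belongs to the older interval (e.g. 66 Ma,
#' the Cretaceous/Palaeogene boundary, is Cretaceous).  The oldest interval
#' of a level includes its older edge.
#'
#' @param ts A `geo_timescale`.
#' @param age Numeric vector of ages in Ma.
#' @param level `"stage"` or `"period"`.
#' @return Character vector of interval names (`NA` where the age falls
#'   outside the span of the level).
#' @export
timescale_interval <- function(ts, age, level = c("stage", "period")) {
  level <- match.arg(level)
  sub <- ts[ts$level == level, , drop = FALSE]
  vapply(age, function(a) {
    if (!is.finite(a)) return(NA_character_)
    hit <- which(a >= sub$age_younger & a < sub$age_older)
    if (!length(hit) && a == max(sub$age_older)) hit <- which.max(sub$age_older)
    if (!length(hit)) NA_character_ else sub$name[hit[1]]
  }, character(1))
}

# Shared reader: sniffs tab vs comma from the header line.
read_delim_auto <- function(source) {
  header <- readLines(source, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, strip.white = TRUE,
                    na.strings = c("NA", ""), comment.char = "")
}
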