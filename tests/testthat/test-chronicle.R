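tiny_settings <- mcmc_settings(4000, 20, 0.1, n_chains = 1)

tiny_config <- function(outdir = NULL, max_ages = c(330, 345), seed = 9) {
  run_config(occurrences = fixture_path("synthetic_occurrences.csv"),
             richness = fixture_path("synthetic_richness.csv"),
             max_ages = max_ages, settings = tiny_settings,
             outdir = outdir, seed = seed)
}

test_that("the batch analysis covers every clade under every prior", {
  res <- suppressWarnings(run_analysis(tiny_config()))
  # 10 runs + 1 pooled order run + 5 propagation aliases, x 2 priors
  expect_equal(nrow(res), 32L)
  expect_equal(attr(res, "n_failed"), 0L)
  expect_equal(sum(res$action == "alias"), 10L)
  plan <- attr(res, "plan")
  expect_equal(sum(plan$action == "run"), 11L)

  # the monotypic superfamily inherits its family's summary verbatim
  a <- res[res$clade == "Primoidea" & res$max_age == 330, ]
  b <- res[res$clade == "Primidae" & res$max_age == 330, ]
  expect_equal(a$root_median, b$root_median)
  expect_equal(a$ext_median, b$ext_median)
  expect_equal(a$root_CI_low, b$root_CI_low)

  # root medians sit above each clade's oldest occurrence; extinction
  # medians below its youngest
  occ <- deduplicate_occurrences(
    read_occurrence_table(fixture_path("synthetic_occurrences.csv")),
    read_timescale())
  for (i in which(res$action == "run" & res$rank == "family")) {
    ages <- mean_age(occ[occ$family %in% res$clade[i], , drop = FALSE])
    expect_gte(res$root_median[i], max(ages))
    if (is.finite(res$ext_median[i]))
      expect_lte(res$ext_median[i], min(ages))
  }

  # extant clades carry no extinction estimate; extinct ones do
  expect_true(all(is.na(res$ext_median[res$clade == "Alphidae"])))
  expect_true(all(is.finite(res$ext_median[res$clade == "Primidae"])))

  # the same master seed reproduces every summary bit-exactly
  res2 <- suppressWarnings(run_analysis(tiny_config()))
  attributes(res) <- attributes(res2) <- NULL
  expect_identical(res, res2)
})

test_that("batch analysis rejects invalid inputs up front", {
  cfg <- tiny_config(max_ages = c(100))
  expect_error(run_analysis(cfg), "exceed the oldest occurrence")
  f <- tempfile(fileext = ".csv")
  writeLines("species,suborder,age_older,age_younger", f)
  cfg2 <- tiny_config()
  cfg2$occurrences <- f
  expect_error(suppressWarnings(run_analysis(cfg2)), "empty occurrence")
})

test_that("prior sensitivity testing detects shifts and only shifts", {
  set.seed(43)
  base <- data.frame(clade = sprintf("fam%02d", 1:60), rank = "family",
                     root_median = runif(60, 80, 300))
  four <- do.call(rbind, lapply(c(325, 350, 386, 407), function(ma) {
    x <- base
    x$max_age <- ma
    x
  }))
  # identical summaries across settings: no detectable difference
  res <- prior_sensitivity_test(four)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$p_value == 1))
  expect_equal(res$n_pairs, rep(60L, 6))

  # one setting shifted by +20 Myr: strongly significant, and the p-value
  # agrees with an independent signed-rank oracle
  set.seed(44)
  shifted <- four
  sel <- shifted$max_age == 407
  shifted$root_median[sel] <- shifted$root_median[sel] + 20 +
    rnorm(sum(sel), 0, 0.5)
  res2 <- prior_sensitivity_test(shifted)
  hit <- res2[res2$max_age_b == 407, ]
  expect_true(all(hit$p_value < 0.01))
  expect_true(all(res2$p_value[res2$max_age_b != 407] == 1))
  a <- shifted[shifted$max_age == 325, ]
  b <- shifted[shifted$max_age == 407, ]
  oracle <- signed_rank_p(a$root_median[match(b$clade, a$clade)],
                          b$root_median)
  expect_lt(oracle, 0.01)

  # too few families: power warning, no p-value
  small <- four[four$clade %in% c("fam01", "fam02", "fam03"), ]
  w <- capture_warnings(res3 <- prior_sensitivity_test(small))
  expect_match(w, "too few", all = TRUE)
  expect_length(w, 6L)  # one power warning per settings pair
  expect_true(all(is.na(res3$p_value)))

  # a single setting cannot be compared
  expect_error(prior_sensitivity_test(base[, ] |> transform(max_age = 350)),
               "at least two")
})

test_that("origination and extinction tallies follow the period fixture", {
  ts <- read_timescale()
  summ <- data.frame(
    clade = c("Cercopidae-like", "boundary", "extinct1"),
    suborder = c("S1", "S1", "S2"),
    root_median = c(68.61, 66.0, 260),
    ext_median = c(NA, NA, 210))
  ev <- count_events_by_period(summ, ts)
  pick <- function(period, sub, event)
    ev$n[ev$period == period & ev$suborder == sub & ev$event == event]
  # a 68.61 Ma root is a Cretaceous origination
  expect_equal(pick("Cretaceous", "S1", "origination"), 2L)
  # an age exactly on the K/Pg boundary belongs to the older period
  expect_equal(pick("Paleogene", "S1", "origination"), 0L)
  expect_equal(pick("Permian", "S2", "origination"), 1L)
  expect_equal(pick("Triassic", "S2", "extinction"), 1L)
  # totals: one origination per clade, one extinction per extinct clade
  expect_equal(sum(ev$n[ev$event == "origination"]), 3L)
  expect_equal(sum(ev$n[ev$event == "extinction"]), 1L)
  # row order must not matter
  ev2 <- count_events_by_period(summ[c(3, 1, 2), ], ts)
  expect_equal(sum(ev2$n), sum(ev$n))
  expect_equal(pick("Cretaceous", "S1", "origination"),
               ev2$n[ev2$period == "Cretaceous" & ev2$suborder == "S1" &
                       ev2$event == "origination"])
  # empty input: all-zero table
  ev0 <- count_events_by_period(summ[0, ], ts)
  expect_true(all(ev0$n == 0L))
  # an age outside the timescale names the offending clade
  bad <- summ
  bad$root_median[1] <- 999
  expect_error(count_events_by_period(bad, ts), "Cercopidae-like")
})

test_that("summary tables round-trip and keep stable ordering", {
  res <- suppressWarnings(run_analysis(tiny_config(max_ages = 330)))
  f <- tempfile(fileext = ".tsv")
  write_summary_table(res, f)
  back <- read_summary_table(f)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$clade, res$clade)  # rank, then clade, then max_age
  expect_equal(back$root_median, res$root_median, tolerance = 1e-9)
  expect_type(back$converged, "logical")
  expect_error(write_summary_table(res[0, ], f), "no summaries")
})

test_that("the command-line interface is deterministic and validates usage", {
  out1 <- tempfile(); out2 <- tempfile()
  expect_equal(bbb_cli(c("simulate", "--preset", "mixed5_5", "--seed", "7",
                         "--out", out1)), 0L)
  expect_equal(bbb_cli(c("simulate", "--preset", "mixed5_5", "--seed", "7",
                         "--out", out2)), 0L)
  expect_identical(readLines(file.path(out1, "truth.tsv")),
                   readLines(file.path(out2, "truth.tsv")))

  # unknown subcommand and unknown flags are usage errors
  expect_equal(bbb_cli(c("frobnicate")), 2L)
  expect_equal(bbb_cli(character()), 2L)
  expect_equal(bbb_cli(c("simulate", "--bogus", "1")), 2L)

  # prep writes the plan and per-family counts
  out3 <- tempfile()
  expect_equal(bbb_cli(c("prep", "--occurrences",
                         fixture_path("synthetic_occurrences.csv"),
                         "--out", out3)), 0L)
  expect_true(file.exists(file.path(out3, "plan.tsv")))
  expect_true(file.exists(file.path(out3, "counts_family_Alphidae.tsv")))

  # a full run on the shipped fixture completes and writes a summary
  out4 <- tempfile()
  st <- suppressWarnings(
    bbb_cli(c("run", "--occurrences",
              fixture_path("synthetic_occurrences.csv"),
              "--richness", fixture_path("synthetic_richness.csv"),
              "--max-ages", "330", "--iterations", "2000",
              "--sampling-freq", "20", "--chains", "1", "--seed", "5",
              "--out", out4)))
  expect_equal(st, 0L)
  summ <- read_summary_table(file.path(out4, "summary.tsv"))
  expect_equal(nrow(summ), 16L)

  # a YAML config file can carry the run options; the run writes a manifest
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c(paste0("occurrences: ",
                      fixture_path("synthetic_occurrences.csv")),
               paste0("richness: ", fixture_path("synthetic_richness.csv")),
               "max_ages: 330", "iterations: 2000", "sampling_freq: 20",
               "chains: 1", "seed: 5"), cfgf)
  out4b <- tempfile()
  st2 <- suppressWarnings(bbb_cli(c("run", "--config", cfgf,
                                    "--out", out4b)))
  expect_equal(st2, 0L)
  expect_true(file.exists(file.path(out4b, "manifest.json")))
  summ_b <- read_summary_table(file.path(out4b, "summary.tsv"))
  expect_equal(summ_b$root_median, summ$root_median)  # same seed, same flags

  # sensitivity on single-prior results is an actionable runtime error
  f <- tempfile(fileext = ".tsv")
  write_summary_table(summ, f)
  expect_equal(suppressWarnings(bbb_cli(c("sensitivity", "--summary", f))),
               1L)

  # period tallies from the run summary
  out5 <- tempfile(fileext = ".tsv")
  expect_equal(bbb_cli(c("periods", "--summary", f, "--out", out5)), 0L)
  ev <- read.table(out5, header = TRUE, sep = "\t")
  expect_equal(sum(ev$n[ev$event == "origination"]),
               sum(is.finite(summ$root_median)))
})
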