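ts <- read_timescale()

write_occ_file <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE, na = "")
  f
}

test_that("occurrence ingestion keeps valid rows and rejects broken ones", {
  f <- write_occ_file(data.frame(
    species = c("a sp1", "a sp2", "a sp3"), suborder = "X",
    age_older = c(100, 90.5, 80), age_younger = c(95, 90.5, 70)))
  occ <- read_occurrence_table(f)
  expect_s3_class(occ, "fossil_occurrences")
  expect_equal(nrow(occ), 3L)

  # inverted interval is a hard row error naming the row
  f2 <- write_occ_file(data.frame(species = c("a", "b"), suborder = "X",
                                  age_older = c(315, 100),
                                  age_younger = c(325, 90)))
  expect_error(read_occurrence_table(f2), "age_older < age_younger.*1")

  # missing mandatory column is a schema error
  f3 <- write_occ_file(data.frame(species = "a", age_older = 10,
                                  age_younger = 5))
  expect_error(read_occurrence_table(f3), "suborder")

  # header-only file: empty result with a warning
  f4 <- write_occ_file(data.frame(species = character(),
                                  suborder = character(),
                                  age_older = numeric(),
                                  age_younger = numeric()))
  expect_warning(occ4 <- read_occurrence_table(f4), "no rows")
  expect_equal(nrow(occ4), 0L)
})

test_that("mean age is the interval midpoint, inside the interval", {
  expect_equal(mean_age(data.frame(age_older = 325, age_younger = 315)), 320)
  expect_equal(mean_age(data.frame(age_older = 100, age_younger = 100)), 100)
  # deposit spanning Burdigalian-Langhian per the shipped timescale
  burd <- ts[ts$name == "Burdigalian", ]
  lang <- ts[ts$name == "Langhian", ]
  expect_equal(
    mean_age(data.frame(age_older = burd$age_older,
                        age_younger = lang$age_younger)), 17.13)
  # property: midpoint always inside the interval
  set.seed(4)
  young <- runif(50, 0, 300)
  old <- young + runif(50, 0, 40)
  m <- mean_age(data.frame(age_older = old, age_younger = young))
  expect_true(all(m >= young & m <= old))
})

test_that("deduplication keeps one occurrence per species per stage", {
  occ <- read_occurrence_table(fixture_path("synthetic_occurrences.csv"))
  dd <- deduplicate_occurrences(occ, ts)
  # same species in two same-stage deposits collapses to the first record
  ap <- dd[dd$species == "Alpha primaeva", ]
  expect_equal(nrow(ap), 1L)
  expect_equal(ap$deposit, "D_perm1")
  # same species in two different stages keeps both records
  expect_equal(nrow(dd[dd$species == "Alpha quinta", ]), 2L)
  # single occurrences pass through unchanged
  expect_true("Beta nova" %in% dd$species)
  # missing stage labels are resolved from the age midpoint
  expect_equal(dd$stage[dd$species == "Beta media"], "Cenomanian")
  # idempotence
  expect_identical(deduplicate_occurrences(dd, ts), dd)
  # an interval outside the timescale with no label is unresolvable
  bad <- occ[1, ]
  bad$stage <- NA
  bad$age_older <- 900
  bad$age_younger <- 800
  expect_error(deduplicate_occurrences(bad, ts), "unresolvable stage")
})

test_that("1-Myr binning uses half-open bins anchored at the present", {
  occ <- data.frame(age_older = c(66.5, 66.9, 70.2) * 2,
                    age_younger = 0)  # mean ages 66.5, 66.9, 70.2
  counts <- bin_species_counts(occ)
  expect_equal(counts[66 + 1], 2L)
  expect_equal(counts[70 + 1], 1L)
  expect_equal(sum(counts), 3L)
  expect_equal(length(counts), 72L)  # ceiling(70.2) + 1

  expect_equal(bin_species_counts(occ[0, ]), 0L)

  # a species retained in two stages contributes to both bins
  occ2 <- data.frame(age_older = c(100.5, 96.2) * 2, age_younger = 0)
  c2 <- bin_species_counts(occ2)
  expect_equal(c2[c(100, 96) + 1], c(1L, 1L))

  # boundary ages go to the bin whose lower edge they equal
  c3 <- bin_species_counts(data.frame(age_older = 10, age_younger = 10))
  expect_equal(which(c3 == 1L) - 1L, 10L)

  # translation consistency: +1 Myr shifts the vector by one index
  set.seed(11)
  ages <- runif(40, 0, 120)
  base <- bin_species_counts(data.frame(age_older = ages, age_younger = ages))
  shift <- bin_species_counts(data.frame(age_older = ages + 1,
                                         age_younger = ages + 1))
  expect_equal(shift[-1][seq_along(base)], base)
})

test_that("clade dataset assembly anchors richness and flags extinction", {
  occ <- deduplicate_occurrences(
    read_occurrence_table(fixture_path("synthetic_occurrences.csv")), ts)
  rich <- read_richness_table(fixture_path("synthetic_richness.csv"))
  ds <- assemble_clade_dataset(occ, "Alphidae", "family", rich)
  expect_false(ds$is_extinct)
  expect_equal(ds$extant_richness, 120)
  expect_equal(sum(ds$counts), 8L)  # 9 rows - 1 same-stage duplicate
  # clade absent from the richness table is extinct by default
  ds2 <- assemble_clade_dataset(occ, "Primidae", "family", rich)
  expect_true(ds2$is_extinct)
  expect_equal(ds2$extant_richness, 0)
  # clade with no occurrences is an error
  expect_error(assemble_clade_dataset(occ, "Nosuchidae", "family", rich),
               "no occurrences")
  # conservation of occurrences across family datasets
  fams <- unique(occ$family[!is.na(occ$family)])
  tot <- sum(vapply(fams, function(f)
    sum(assemble_clade_dataset(occ, f, "family", rich)$counts), numeric(1)))
  expect_equal(tot, sum(!is.na(occ$family)))
})

test_that("analysis plan collapses monotypic higher ranks onto their child", {
  occ <- deduplicate_occurrences(
    read_occurrence_table(fixture_path("synthetic_occurrences.csv")), ts)
  plan <- build_analysis_plan(occ)
  # every clade with fossils appears exactly once
  expect_false(any(duplicated(plan[c("clade", "rank")])))
  expect_equal(nrow(plan), 15L)
  expect_equal(sum(plan$action == "run"), 10L)
  # a monotypic superfamily is an alias of its only family
  prim <- plan[plan$clade == "Primoidea", ]
  expect_equal(prim$action, "alias")
  expect_equal(prim$alias_clade, "Primidae")
  # alias chains resolve to an actual run
  gam <- plan[plan$clade == "Gammomorpha", ]
  expect_equal(gam$alias_clade, "Gammidae")
  expect_equal(gam$alias_rank, "family")
  # a superfamily with several families is run at both levels
  expect_equal(plan$action[plan$clade == "Alphoidea"], "run")
  # a family mapped to two superfamilies is a hierarchy error
  bad <- occ
  bad$superfamily[bad$species == "Alpha septima"] <- "Wrongoidea"
  expect_error(build_analysis_plan(bad), "more than one superfamily")
})

test_that("timescale fixture is contiguous and assigns boundary ages old", {
  expect_s3_class(ts, "geo_timescale")
  expect_true(all(ts$age_older > ts$age_younger))
  # Cretaceous/Palaeogene boundary belongs to the Cretaceous
  expect_equal(timescale_interval(ts, 66, "period"), "Cretaceous")
  expect_equal(timescale_interval(ts, 65.99, "period"), "Paleogene")
  expect_equal(timescale_interval(ts, 0, "period"), "Quaternary")
  expect_equal(timescale_interval(ts, 320, "stage"), "Bashkirian")
  expect_true(is.na(timescale_interval(ts, 1000, "period")))
})
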