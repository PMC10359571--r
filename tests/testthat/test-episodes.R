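test_that("365-day collapsing anchors at the earliest authorisation date", {
  d <- as.Date("2010-01-01")
  ep <- collapse_episodes(make_records(c(d, d + 300)))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$episode_date, d)

  ep <- collapse_episodes(make_records(c(d, d + 366)))
  expect_equal(nrow(ep), 2L)

  # d+400 is within 365 of d+300 but beyond the anchor: new episode
  ep <- collapse_episodes(make_records(c(d, d + 300, d + 400)))
  expect_equal(ep$n_records, c(2L, 1L))
  expect_equal(ep$episode_date, c(d, d + 400))
})

test_that("collapsing matches the greedy-anchor reference on random multisets", {
  base <- as.Date("2005-06-15")
  grid <- seq(0L, 1000L, by = 100L)
  cases <- list()
  for (k in 1:3) {
    cases <- c(cases, lapply(
      asplit(as.matrix(expand.grid(rep(list(grid), k))), 1), as.integer
    ))
  }
  set.seed(99)
  for (i in 1:300) {
    k <- sample(1:5, 1L)
    cases[[length(cases) + 1L]] <- sample(0:1000, k, replace = TRUE)
  }
  for (offsets in cases) {
    dates <- base + offsets
    got <- collapse_episodes(make_records(dates))
    want <- oracle_episode_sizes(dates)
    expect_equal(got$n_records, want)
    expect_equal(sum(got$n_records), length(dates))
  }
})

test_that("collapsing is idempotent on episode dates", {
  set.seed(7)
  dates <- as.Date("2003-01-01") + sample(0:2000, 12)
  ep <- collapse_episodes(make_records(dates))
  ep2 <- collapse_episodes(make_records(ep$episode_date))
  expect_equal(ep2$episode_date, ep$episode_date)
})

test_that("deduplication removes only true duplicates", {
  d <- as.Date("2010-01-01")
  rec <- make_records(c(d, d))
  out <- deduplicate(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_removed"), 1L)

  rec2 <- make_records(c(d, d), result_label = "positive")
  rec2$variant_cdna <- c("c.100A>G", "c.200C>T")
  expect_equal(nrow(deduplicate(rec2)), 2L)

  empty <- make_records(as.Date(character()))
  expect_equal(nrow(deduplicate(empty)), 0L)
})

test_that("most significant result follows the severity total order", {
  expect_equal(most_significant_result(c("P", "VUS")), "P")
  expect_equal(most_significant_result(c("normal", "normal")), "normal")
  expect_equal(most_significant_result(c("abnormal_unclassified", "LB")),
               "abnormal_unclassified")
  expect_error(most_significant_result(character(0)), "empty")

  # equivalence with the order oracle over every non-empty subset
  rank <- function(x) match(x, RESULT_HIERARCHY)
  for (bits in 1:(2^5 - 1)) {
    subset <- RESULT_HIERARCHY[as.logical(bitwAnd(bits, 2^(0:4)))]
    expect_equal(most_significant_result(subset),
                 subset[which.min(rank(subset))])
  }
})

test_that("adding a member record never lowers the most significant result", {
  rank <- function(x) match(x, RESULT_HIERARCHY)
  for (bits in 1:(2^5 - 1)) {
    subset <- RESULT_HIERARCHY[as.logical(bitwAnd(bits, 2^(0:4)))]
    for (extra in RESULT_HIERARCHY) {
      expect_lte(rank(most_significant_result(c(subset, extra))),
                 rank(most_significant_result(subset)))
    }
  }
})

test_that("episode scope follows the mapped field, then the decision table", {
  d <- as.Date("2012-03-01")
  mapped_targeted <- make_records(d, scope = "targeted")
  expect_equal(classify_scope(mapped_targeted),
               list(scope = "targeted", derived = FALSE))

  panel <- make_records(rep(d, 4), gene = MMR_GENES)
  expect_equal(classify_scope(panel)$scope, "full_gene")

  # ambiguous single-gene screen with no mapped type: full-gene, flagged
  ambiguous <- make_records(d)
  ambiguous$scope_derived <- TRUE
  sc <- classify_scope(ambiguous)
  expect_equal(sc$scope, "full_gene")
  expect_true(sc$derived)

  # wording-derived targeted single-variant presence test stays targeted
  derived_tg <- make_records(d, scope = "targeted")
  derived_tg$scope_derived <- TRUE
  sc <- classify_scope(derived_tg)
  expect_equal(sc$scope, "targeted")
  expect_true(sc$derived)
})

test_that("gene combinations are canonically ordered", {
  expect_equal(gene_combination(c("MSH2", "MLH1")), "MLH1+MSH2")
  expect_equal(gene_combination(rev(MMR_GENES)), "MLH1+MSH2+MSH6+PMS2")
  expect_equal(gene_combination("PMS2"), "PMS2")
})

test_that("episode building partitions deduplicated records per patient", {
  cfg <- small_config(150, seed = 31)
  res <- run_pipeline(cfg, key = test_key, out_dir = withr::local_tempdir())
  dedup <- deduplicate(res$cdm)
  expect_equal(sum(res$episodes$n_records), nrow(dedup))
  # episodes of one patient are date-disjoint beyond the window
  by_patient <- split(res$episodes, res$episodes$patient_key)
  for (ep in by_patient) {
    if (nrow(ep) > 1L) {
      gaps <- diff(sort(ep$episode_date))
      expect_true(all(as.integer(gaps) > 365L))
    }
  }
})
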