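test_that("adjustment factor is the pooled ratio over overlap years", {
  expect_equal(compute_adjustment_factor(80, 100), 0.8)
  # pooled ratio, not mean of per-year ratios
  pooled <- compute_adjustment_factor(c(50, 50), c(60, 65))
  expect_equal(pooled, 100 / 125)
  mean_of_ratios <- mean(c(50 / 60, 50 / 65))
  expect_false(isTRUE(all.equal(pooled, mean_of_ratios)))

  expect_warning(f <- compute_adjustment_factor(110, 100), "clamped")
  expect_equal(f, 1)
  expect_warning(f <- compute_adjustment_factor(numeric(0), numeric(0)),
                 "overlap")
  expect_true(is.na(f))
})

test_that("audit down-adjustment applies only to pre-observation years", {
  audit <- tibble::tibble(
    lab_code = "L1",
    financial_year = c(1999L, 2000L, 2001L),
    audit_count = c(125L, 125L, 125L)
  )
  adj <- adjust_audit(audit, c(L1 = 0.8), c(L1 = 2001L))
  expect_equal(adj$financial_year, c(1999L, 2000L))
  expect_equal(adj$adjusted_count, c(100L, 100L))
  # factor 1 is the identity
  adj1 <- adjust_audit(audit, c(L1 = 1), c(L1 = 2002L))
  expect_equal(adj1$adjusted_count, audit$audit_count)
  # labs without a factor are dropped (flagged upstream)
  expect_equal(nrow(adjust_audit(audit, c(L1 = NA_real_), c(L1 = 2001L))), 0L)
})

test_that("pre-audit years are back-filled flat from the earliest estimate", {
  adjusted <- tibble::tibble(
    lab_code = c("L1", "L1", "L2"),
    financial_year = c(1998L, 1999L, 1998L),
    adjusted_count = c(30L, 40L, 25L)
  )
  out <- interpolate_pre_audit(adjusted,
                               active_from = c(L1 = 1996L, L2 = 2004L))
  expect_equal(out$lab_code, c("L1", "L1"))
  expect_equal(out$financial_year, 1996:1997)
  expect_equal(out$adjusted_count, c(30L, 30L))
  # lab first active mid-window fills only from its start
  out2 <- interpolate_pre_audit(adjusted,
                                active_from = c(L1 = 1997L, L2 = 2004L))
  expect_equal(out2$financial_year, 1997L)
})

test_that("combined totals take observed where available, else imputed", {
  observed <- tibble::tibble(
    lab_code = "L1", financial_year = 2010:2012,
    n_full_gene = c(60L, 70L, 80L), n_targeted = c(40L, 30L, 20L)
  )
  adjusted <- tibble::tibble(
    lab_code = "L1", financial_year = 2008:2009,
    adjusted_count = c(50L, 55L)
  )
  cov <- combine_totals(observed, adjusted)
  expect_equal(cov$observed_total, 300L)
  expect_equal(cov$consensus_total, 405L)
  expect_gte(cov$consensus_total, cov$observed_total)
  expect_equal(cov$coverage_pct, 100 * 300 / 405)
  expect_equal(cov$full_gene_total + cov$targeted_total, cov$consensus_total)

  # a lab-year in both sources is a hard failure
  bad <- dplyr::bind_rows(adjusted, tibble::tibble(
    lab_code = "L1", financial_year = 2010L, adjusted_count = 10L
  ))
  expect_error(combine_totals(observed, bad), "double-count")

  empty <- combine_totals(
    tibble::tibble(lab_code = character(), financial_year = integer(),
                   n_full_gene = integer(), n_targeted = integer()),
    adjusted[0, ]
  )
  expect_equal(empty$consensus_total, 0L)
})

test_that("synthetic audit inflation is recovered as its reciprocal", {
  cfg <- small_config(2000, seed = 51)
  cfg$labs$first_submission_year <- c(2005L, 2010L, 2008L)
  patients <- generate_patients(cfg)
  dir <- withr::local_tempdir()
  audit_truth <- write_audit_counts(patients, cfg,
                                    file.path(dir, "audit.csv"))
  # observed side from the truth ledger: submitted tests per lab-year
  tests <- flatten_tests(patients)
  tests$financial_year <- financial_year(tests$authorised_date)
  obs <- dplyr::count(tests[tests$submitted, ],
                      lab_code, financial_year, name = "n")
  for (i in seq_len(nrow(cfg$labs))) {
    lab <- cfg$labs$lab_code[[i]]
    overlap <- dplyr::inner_join(
      obs[obs$lab_code == lab, ],
      audit_truth[audit_truth$lab_code == lab,
                  c("financial_year", "audit_count")],
      by = "financial_year"
    )
    f <- compute_adjustment_factor(overlap$n, overlap$audit_count)
    expect_equal(f, 1 / cfg$labs$audit_inflation[[i]], tolerance = 0.02)
    # adjusted counts recover truth within +/- 1 per lab-year
    pre <- audit_truth[audit_truth$lab_code == lab &
                         audit_truth$financial_year <
                           min(overlap$financial_year), ]
    recovered <- round_half_up(pre$audit_count * f)
    expect_true(all(abs(recovered - pre$true_count) <= 1))
  }
})

test_that("carrier arithmetic reproduces the published worked example", {
  carriers <- estimate_carriers(14191, 12428)
  expect_identical(carriers$carriers_fullgene, 2129L)
  expect_identical(carriers$carriers_cascade, 5593L)
  expect_equal(estimate_carriers(1000, 1000, 0, 0),
               list(carriers_fullgene = 0L, carriers_cascade = 0L))

  pct <- carrier_fraction(2129 + 5593, 279, 56e6)
  expect_equal(pct, 100 * 7722 / (56e6 / 279))
  expect_lt(pct, 5)
  expect_equal(carrier_fraction(0, 279, 56e6), 0)
  expect_equal(carrier_fraction(56e6 / 279, 279, 56e6), 100)
})
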