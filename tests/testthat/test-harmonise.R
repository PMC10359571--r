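test_that("HGVS extraction finds grammar members in order and nothing else", {
  got <- extract_hgvs("heterozygous variant c.942+3A>T detected")
  expect_equal(got$kind, "cdna")
  expect_equal(got$token, "c.942+3A>T")

  expect_equal(nrow(extract_hgvs("deletion of exons 1-6 of MSH2")), 0L)

  got <- extract_hgvs("c.100A>G p.(Thr34Ala)")
  expect_equal(got$kind, c("cdna", "protein"))
  expect_equal(got$token, c("c.100A>G", "p.(Thr34Ala)"))

  got <- extract_hgvs(
    "variants c.35_39del and c.100_105delinsTTG plus p.(Arg100Ter) seen"
  )
  expect_equal(got$token, c("c.35_39del", "c.100_105delinsTTG",
                            "p.(Arg100Ter)"))
  expect_equal(nrow(extract_hgvs("")), 0L)
  expect_equal(nrow(extract_hgvs(NA_character_)), 0L)
})

test_that("syntactic validation accepts the supported grammar", {
  valid <- c("c.100A>G", "c.942+3A>T", "c.35-12C>A", "c.100_105del",
             "c.76_77insAT", "c.100_105delinsTTG", "c.88dup", "c.76delA",
             "p.(Thr34Ala)", "p.Thr34Ala", "p.(Arg100Ter)",
             "p.(Thr34LysfsTer9)", "p.(Thr34fs)", "p.(Gly12del)",
             "p.(Thr34=)")
  res <- validate_hgvs(valid)
  expect_true(all(res$valid), info = paste(res$token[!res$valid],
                                           collapse = ", "))
})

test_that("syntactic validation rejects malformed tokens with a reason", {
  cases <- tibble::tribble(
    ~token, ~reason_re,
    "c.100A>", "missing alternate",
    "c.0A>G", "position",
    "c.100A>A", "reference equals alternate",
    "c.105_100del", "range",
    "g.100A>G", "prefix",
    "p.(Thr0Ala)", "position",
    "p.(Thr34Thr)", "reference equals alternate",
    "c.100", "grammar",
    "deletion of exons 1-6", "prefix"
  )
  res <- validate_hgvs(cases$token)
  expect_false(any(res$valid))
  for (i in seq_len(nrow(cases))) {
    expect_match(res$reason[[i]], cases$reason_re[[i]], ignore.case = TRUE)
  }
})

test_that("CNV natural-language lexicon matches phrases, not HGVS", {
  expect_true(all(detect_cnv_language(c(
    "deletion of exons 1-6", "duplication of exons 3-5",
    "deletion of exon 7", "whole gene duplication",
    "Exon 9 deletion detected", "large genomic rearrangement"
  ))))
  expect_false(any(detect_cnv_language(c(
    "c.100A>G", "no variant identified", "p.(Thr34Ala)", NA
  ))))
})

test_that("classification labels normalise through the synonym map", {
  expect_equal(
    normalise_classification(c("Pathogenic", "likely pathogenic", "class 3",
                               "CLASS 5", "Benign", "Likely benign", "VUS",
                               "uncertain significance", "", "???")),
    c("P", "LP", "VUS", "P", "B", "LB", "VUS", "VUS",
      "unclassified", "unclassified")
  )
  expect_equal(normalise_classification(NA_character_), "unclassified")
})

test_that("concordance audit enforces the 95% per-gene threshold", {
  comp <- tibble::tibble(gene = c("MLH1", "MSH2"), tests = c(100, 96),
                         abnormal = c(20, 20))
  man <- tibble::tibble(gene = c("MLH1", "MSH2"), tests = c(100, 100),
                        abnormal = c(20, 20))
  res <- concordance_audit(comp, man)
  expect_true(res$pass)
  expect_equal(res$per_gene$ratio_tests, c(1, 0.96))

  comp$tests[2] <- 94
  expect_false(concordance_audit(comp, man)$pass)

  comp$tests[2] <- 0; man$tests[2] <- 0
  expect_warning(res <- concordance_audit(comp, man), "zero")
  expect_true(res$pass)
})

test_that("structured extracts map to one CDM record per input row", {
  cfg <- small_config(100, seed = 21)
  patients <- generate_patients(cfg)
  dir <- withr::local_tempdir()
  paths <- write_lab_extracts(patients, cfg, dir)
  st_lab <- cfg$labs$lab_code[cfg$labs$dialect == "structured"][[1]]
  raw <- readr::read_csv(paths[[st_lab]], show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  out <- map_extract(paths[[st_lab]], dialect_spec("structured"), test_key,
                     lab_code = st_lab)
  expect_equal(nrow(out$records) + nrow(out$quarantine), nrow(raw))
  expect_equal(nrow(out$quarantine), 0L)
  expect_true(all(out$records$gene %in% MMR_GENES))
  expect_false(any(c("nhs_number", "dob", "postcode") %in%
                     names(out$records)))
})

test_that("both date dialects parse and bad rows are quarantined with reasons", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "x.csv")
  readr::write_csv(tibble::tibble(
    nhs_number = c("9434765919", "9434765919", "9434765919"),
    date_of_birth = "1960-01-02",
    postcode = "SW1A 1AA",
    authorised_date = c("2010-06-01", "not a date", "2010-06-01"),
    report_date = "2010-06-20",
    test_type = "Diagnostic",
    gene = c("MLH1", "MLH1", "BRCA1"),
    result = "Normal",
    classification = "",
    variant_cdna = "", variant_protein = "", cnv_desc = ""
  ), f, na = "")
  out <- map_extract(f, dialect_spec("structured"), test_key, "LABX")
  expect_equal(nrow(out$records), 1L)
  expect_setequal(out$quarantine$reason,
                  c("unparseable_authorised_date", "unknown_gene"))
  expect_equal(out$records$authorised_date, as.Date("2010-06-01"))

  # UK dialect: DD/MM/YYYY
  f2 <- file.path(dir, "y.csv")
  readr::write_csv(tibble::tibble(
    NHSNO = "9434765919", DOB = "02/01/1960", POSTCODE = "SW1A 1AA",
    AUTH_DATE = "01/06/2010", REP_DATE = "20/06/2010",
    TEST_TYPE = "FULL SCREEN", GENE = "MSH2", RESULT = "VARIANT DETECTED",
    CLASS = "CLASS 4", CDNA = "c.100A>G", PROTEIN = "", CNV_DESC = ""
  ), f2, na = "")
  out2 <- map_extract(f2, dialect_spec("structured_uk"), test_key, "LABY")
  expect_equal(out2$records$authorised_date, as.Date("2010-06-01"))
  expect_equal(out2$records$result_label, "positive")
  expect_equal(out2$records$classification, "LP")
  expect_equal(out2$records$scope, "full_gene")
})

test_that("free-text reports parse to per-gene records with full recall", {
  cfg <- small_config(250, seed = 22)
  patients <- generate_patients(cfg)
  dir <- withr::local_tempdir()
  paths <- write_lab_extracts(patients, cfg, dir)
  ft_lab <- cfg$labs$lab_code[cfg$labs$dialect == "freetext"][[1]]
  out <- map_extract(paths[[ft_lab]], dialect_spec("freetext"), test_key,
                     lab_code = ft_lab)
  expect_equal(nrow(out$quarantine), 0L)

  truth <- flatten_tests(patients)
  truth <- truth[truth$lab_code == ft_lab & truth$submitted, ]
  # every planted gene yields a record: per-report gene counts match truth
  expect_equal(nrow(out$records), sum(lengths(truth$genes)))
  # planted SNVs recalled verbatim on the right gene
  snv <- truth[!is.na(truth$variant_cdna), ]
  rec_pos <- out$records[out$records$result_label == "positive" &
                           !is.na(out$records$variant_cdna), ]
  expect_setequal(rec_pos$variant_cdna, unique(snv$variant_cdna))
  # CNVs are captured as text, never as HGVS
  cnv_rec <- out$records[!is.na(out$records$cnv_text), ]
  expect_true(all(is.na(cnv_rec$variant_cdna)))
  expect_equal(nrow(cnv_rec), sum(!is.na(truth$cnv_phrase)))
  # classifications present where planted abnormal reported them
  planted_cls <- truth[truth$classification_reported &
                         truth$true_result %in% c("P", "LP", "VUS"), ]
  got_cls <- out$records[out$records$classification %in% c("P", "LP", "VUS"), ]
  expect_equal(nrow(got_cls), nrow(planted_cls))
})

test_that("CDM tables round-trip through CSV and JSONL identically", {
  cfg <- small_config(60, seed = 23)
  patients <- generate_patients(cfg)
  dir <- withr::local_tempdir()
  paths <- write_lab_extracts(patients, cfg, dir)
  st_lab <- cfg$labs$lab_code[cfg$labs$dialect == "structured"][[1]]
  rec <- map_extract(paths[[st_lab]], dialect_spec("structured"), test_key,
                     st_lab)$records
  csv <- file.path(dir, "cdm.csv"); jl <- file.path(dir, "cdm.jsonl")
  write_cdm(rec, csv); write_cdm(rec, jl)
  expect_equal(as.data.frame(read_cdm(csv)), as.data.frame(rec))
  expect_equal(as.data.frame(read_cdm(jl)), as.data.frame(rec))
})
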