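# Synthetic source data with known ground truth: per-laboratory extract
# files in several dialects, a cancer registry and inflated audit counts.
# The generator is first-class, tested code; its truth ledger is read only
# by tests, never by the pipeline.

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

AUDIT_YEARS <- 1998:2015   # financial years covered by the activity audit

#' Default synthetic laboratory roster
#'
#' Three laboratories covering the three supported extract dialects, with
#' staggered activity start and first patient-level submission years so that
#' pre-submission history exists to impute.
#'
#' @return tibble with one row per laboratory.
#' @export
default_labs <- function() {
  tibble::tibble(
    lab_code = c("LAB1", "LAB2", "LAB3"),
    dialect = c("structured", "structured_uk", "freetext"),
    activity_start_year = c(1997L, 2000L, 1999L),
    first_submission_year = c(2005L, 2010L, 2008L),
    audit_inflation = c(1.0, 1.25, 1.5)
  )
}

#' Build and validate a generator configuration
#'
#' Default rates mirror the testing landscape the pipeline is designed for:
#' a 15% pathogenic/likely-pathogenic yield and 6% VUS yield on full-gene
#' analysis, a 45% abnormal rate on targeted (cascade) tests, copy-number
#' variants making up a fifth of abnormal results, pathogenicity
#' classifications supplied for only 29% of abnormal results, and roughly
#' 70% of full-gene probands carrying a pre-test cancer registration.
#'
#' @param n_patients number of synthetic patients.
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param labs laboratory roster as from [default_labs()].
#' @param rate_plp fraction of full-gene tests with a P or LP result.
#' @param plp_p_share share of P within P+LP (14:1 by default).
#' @param rate_vus fraction of full-gene tests with a VUS result.
#' @param rate_benign fraction of full-gene tests whose only variant is
#'   benign or likely benign (counted as normal downstream).
#' @param rate_cnv_among_abnormal fraction of abnormal results that are
#'   copy-number variants, reported in natural language rather than HGVS.
#' @param rate_hgvs_invalid fraction of planted HGVS strings that are
#'   subtly malformed (position 0, reference equal to alternate) so the
#'   syntactic validator has true negatives to find.
#' @param rate_classification_reported probability an abnormal result comes
#'   with a pathogenicity classification.
#' @param rate_targeted fraction of patients receiving a targeted rather
#'   than full-gene test.
#' @param rate_targeted_abnormal probability a targeted test finds the
#'   familial variant.
#' @param id_missingness named vector `c(p_no_nhs=, p_no_dob_postcode=)`:
#'   independent probabilities that a patient lacks an NHS number, or lacks
#'   both DOB and postcode.
#' @param pretest_cancer_rate_fullgene probability a full-gene patient has a
#'   cancer registration pre-dating the test.
#' @param pretest_cancer_rate_targeted,posttest_cancer_rate analogous rates
#'   for targeted patients and for post-test diagnoses.
#' @param second_cancer_rate probability of a second pre-test primary among
#'   patients with one.
#' @param repeat_episode_rate probability a patient returns for a second
#'   test episode more than a year after the first.
#' @param registry_cancer_site_mix named weights over ICD-10 site groups
#'   `colorectal`, `uterine`, `other`.
#' @return validated config object (class `lynchledger_config`).
#' @export
generator_config <- function(n_patients = 1000L,
                             seed = 1L,
                             labs = default_labs(),
                             rate_plp = 0.15,
                             plp_p_share = 14 / 15,
                             rate_vus = 0.06,
                             rate_benign = 0.04,
                             rate_cnv_among_abnormal = 0.20,
                             rate_hgvs_invalid = 0.04,
                             rate_classification_reported = 0.29,
                             rate_targeted = 0.42,
                             rate_targeted_abnormal = 0.45,
                             id_missingness = c(p_no_nhs = 0.093,
                                                p_no_dob_postcode = 0.012),
                             pretest_cancer_rate_fullgene = 0.70,
                             pretest_cancer_rate_targeted = 0.104,
                             posttest_cancer_rate = 0.066,
                             second_cancer_rate = 0.20,
                             repeat_episode_rate = 0.03,
                             registry_cancer_site_mix = c(colorectal = 0.60,
                                                          uterine = 0.14,
                                                          other = 0.26)) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed), labs = labs,
    rate_plp = rate_plp, plp_p_share = plp_p_share, rate_vus = rate_vus,
    rate_benign = rate_benign,
    rate_cnv_among_abnormal = rate_cnv_among_abnormal,
    rate_hgvs_invalid = rate_hgvs_invalid,
    rate_classification_reported = rate_classification_reported,
    rate_targeted = rate_targeted,
    rate_targeted_abnormal = rate_targeted_abnormal,
    id_missingness = id_missingness,
    pretest_cancer_rate_fullgene = pretest_cancer_rate_fullgene,
    pretest_cancer_rate_targeted = pretest_cancer_rate_targeted,
    posttest_cancer_rate = posttest_cancer_rate,
    second_cancer_rate = second_cancer_rate,
    repeat_episode_rate = repeat_episode_rate,
    registry_cancer_site_mix = registry_cancer_site_mix
  )
  validate_generator_config(cfg)
  structure(cfg, class = "lynchledger_config")
}

validate_generator_config <- function(cfg) {
  fractions <- c(
    cfg$rate_plp, cfg$plp_p_share, cfg$rate_vus, cfg$rate_benign,
    cfg$rate_cnv_among_abnormal, cfg$rate_hgvs_invalid,
    cfg$rate_classification_reported, cfg$rate_targeted,
    cfg$rate_targeted_abnormal, cfg$id_missingness,
    cfg$pretest_cancer_rate_fullgene, cfg$pretest_cancer_rate_targeted,
    cfg$posttest_cancer_rate, cfg$second_cancer_rate,
    cfg$repeat_episode_rate
  )
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    abort("generator config: all rates must be fractions in [0, 1]",
          class = "lynchledger_config_error")
  }
  if (cfg$n_patients < 0) {
    abort("generator config: n_patients must be non-negative",
          class = "lynchledger_config_error")
  }
  needed <- c("lab_code", "dialect", "activity_start_year",
              "first_submission_year", "audit_inflation")
  if (!all(needed %in% names(cfg$labs))) {
    abort("generator config: labs roster is missing columns",
          class = "lynchledger_config_error")
  }
  if (any(cfg$labs$audit_inflation < 1)) {
    abort("generator config: audit_inflation must be >= 1",
          class = "lynchledger_config_error")
  }
  bad <- setdiff(cfg$labs$dialect, c("structured", "structured_uk", "freetext"))
  if (length(bad)) {
    abort(sprintf("generator config: unknown dialect '%s'", bad[[1]]),
          class = "lynchledger_config_error")
  }
  if (!all(names(cfg$registry_cancer_site_mix) %in%
           c("colorectal", "uterine", "other")) ||
      any(cfg$registry_cancer_site_mix < 0)) {
    abort("generator config: bad registry_cancer_site_mix",
          class = "lynchledger_config_error")
  }
  invisible(cfg)
}

# Valid NHS numbers: random 9-digit bodies whose mod-11 check digit is not
# 10 (those bodies have no valid number and are redrawn).
random_nhs_numbers <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    body <- matrix(sample(0:9, need * 9L, replace = TRUE), ncol = 9L)
    # avoid leading zero for realism
    body[, 1L][body[, 1L] == 0L] <- sample(1:9, sum(body[, 1L] == 0L),
                                           replace = TRUE)
    check <- 11L - (as.integer(body %*% 10:2) %% 11L)
    check[check == 11L] <- 0L
    keep <- check != 10L
    nums <- paste0(apply(body[keep, , drop = FALSE], 1L, paste, collapse = ""),
                   check[keep])
    out <- unique(c(out, nums))
  }
  out[seq_len(n)]
}

random_postcodes <- function(n) {
  paste0(
    sample(LETTERS, n, replace = TRUE),
    sample(c("", LETTERS), n, replace = TRUE),
    sample(1:9, n, replace = TRUE),
    " ",
    sample(0:9, n, replace = TRUE),
    sample(LETTERS, n, replace = TRUE),
    sample(LETTERS, n, replace = TRUE)
  )
}

# One synthetic HGVS cDNA variant (optionally malformed), with an optional
# protein-level description. Malformed variants still match the extraction
# grammar but fail syntactic validation.
random_hgvs <- function(n, p_invalid = 0) {
  kind <- sample(c("sub", "intronic", "del", "dup", "ins", "delins"), n,
                 replace = TRUE,
                 prob = c(0.55, 0.08, 0.13, 0.08, 0.08, 0.08))
  pos <- sample(1:3200, n, replace = TRUE)
  width <- sample(1:12, n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  bases <- vapply(width, function(w) {
    paste(sample(c("A", "C", "G", "T"), min(w, 6L), replace = TRUE),
          collapse = "")
  }, character(1))
  offset <- sample(c(1:8, -8:-1), n, replace = TRUE)
  cdna <- dplyr::case_when(
    kind == "sub" ~ paste0("c.", pos, ref, ">", alt),
    kind == "intronic" ~ paste0("c.", pos, ifelse(offset > 0, "+", ""),
                                offset, ref, ">", alt),
    kind == "del" ~ paste0("c.", pos, "_", pos + width, "del"),
    kind == "dup" ~ paste0("c.", pos, "_", pos + width, "dup"),
    kind == "ins" ~ paste0("c.", pos, "_", pos + 1L, "ins", bases),
    TRUE ~ paste0("c.", pos, "_", pos + width, "delins", bases)
  )
  # malformed plants: substitutions at position 0 or with ref == alt
  invalid <- stats::runif(n) < p_invalid
  malformed_kind <- sample(c("pos0", "refalt"), n, replace = TRUE)
  cdna[invalid & malformed_kind == "pos0"] <-
    paste0("c.0", ref, ">", alt)[invalid & malformed_kind == "pos0"]
  cdna[invalid & malformed_kind == "refalt"] <-
    paste0("c.", pos, ref, ">", ref)[invalid & malformed_kind == "refalt"]
  aa_from <- sample(AA3, n, replace = TRUE)
  aa_to <- vapply(aa_from, function(a) sample(setdiff(AA3, a), 1L),
                  character(1))
  aa_pos <- sample(1:1000, n, replace = TRUE)
  fs <- stats::runif(n) < 0.15
  protein <- ifelse(
    fs,
    paste0("p.(", aa_from, aa_pos, aa_to, "fsTer",
           sample(2:40, n, replace = TRUE), ")"),
    paste0("p.(", aa_from, aa_pos, aa_to, ")")
  )
  # protein description only for substitutions, only some of the time
  protein[!(kind %in% c("sub")) | stats::runif(n) > 0.6] <- NA_character_
  protein[invalid] <- NA_character_
  tibble::tibble(variant_cdna = cdna, variant_protein = protein,
                 hgvs_valid = !invalid)
}

random_cnv_phrases <- function(n) {
  i <- sample(1:12, n, replace = TRUE)
  j <- i + sample(1:6, n, replace = TRUE)
  kind <- sample(c("delrange", "duprange", "delone", "whole"), n,
                 replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1))
  dplyr::case_when(
    kind == "delrange" ~ paste0("deletion of exons ", i, "-", j),
    kind == "duprange" ~ paste0("duplication of exons ", i, "-", j),
    kind == "delone" ~ paste0("deletion of exon ", i),
    TRUE ~ "whole gene deletion"
  )
}

# Era-dependent full-gene combinations: MLH1/MSH2 early, MSH6 from the
# mid-2000s, four-gene panels dominating recent years.
sample_gene_combo <- function(year) {
  combos_early <- list(c("MLH1", "MSH2"), "MLH1", "MSH2")
  combos_mid <- list(c("MLH1", "MSH2"), c("MLH1", "MSH2", "MSH6"),
                     c("MSH2", "MSH6"), "MLH1", "MSH6")
  combos_late <- list(MMR_GENES, c("MLH1", "MSH2", "MSH6"),
                      c("MLH1", "MSH2"), "PMS2")
  if (year < 2006) {
    combos <- combos_early; w <- c(0.6, 0.25, 0.15)
  } else if (year < 2011) {
    combos <- combos_mid; w <- c(0.35, 0.3, 0.1, 0.15, 0.1)
  } else {
    combos <- combos_late; w <- c(0.65, 0.2, 0.1, 0.05)
  }
  combos[[sample.int(length(combos), 1L, prob = w)]]
}

#' Generate synthetic source patients
#'
#' Draws `n_patients` ground-truth patients: identifiers (valid NHS numbers,
#' DOB, postcode, with configured missingness), planted tests (dates, labs,
#' scope, genes, true results, variants) and planted cancer registrations.
#' The result is the generator's truth and is consumed only by the writer
#' functions and by test oracles.
#'
#' @param config a [generator_config()].
#' @return tibble with one row per patient and list-columns `tests` and
#'   `cancers`.
#' @export
generate_patients <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  empty <- tibble::tibble(
    person_uid = character(), nhs_number = character(),
    dob = as.Date(character()), postcode = character(),
    tests = list(), cancers = list()
  )
  if (n == 0L) return(empty)

  patients <- tibble::tibble(
    person_uid = sprintf("PT%06d", seq_len(n)),
    nhs_number = random_nhs_numbers(n),
    dob = random_dates(n, "1930-01-01", "1995-12-31"),
    postcode = random_postcodes(n)
  )
  no_nhs <- stats::runif(n) < config$id_missingness[["p_no_nhs"]]
  no_dp <- stats::runif(n) < config$id_missingness[["p_no_dob_postcode"]]
  patients$nhs_number[no_nhs] <- NA_character_
  patients$dob[no_dp] <- as.Date(NA)
  patients$postcode[no_dp] <- NA_character_

  labs <- config$labs
  lab_idx <- sample.int(nrow(labs), n, replace = TRUE)
  start <- as.Date(paste0(pmax(labs$activity_start_year[lab_idx], 1997L),
                          "-01-01"))
  end <- as.Date("2019-12-01")
  auth <- start + vapply(as.integer(end - start), function(k) {
    sample.int(k + 1L, 1L) - 1L
  }, integer(1))

  scope <- ifelse(stats::runif(n) < config$rate_targeted,
                  "targeted", "full_gene")
  year <- as.integer(format(auth, "%Y"))

  # full-gene true result draw
  p_p <- config$rate_plp * config$plp_p_share
  p_lp <- config$rate_plp - p_p
  probs <- c(P = p_p, LP = p_lp, VUS = config$rate_vus,
             LB = config$rate_benign / 2, B = config$rate_benign / 2)
  probs <- c(probs, normal = 1 - sum(probs))
  result_fg <- sample(names(probs), n, replace = TRUE, prob = probs)
  result_tg <- ifelse(stats::runif(n) < config$rate_targeted_abnormal,
                      "P", "normal")
  true_result <- ifelse(scope == "targeted", result_tg, result_fg)

  genes <- vector("list", n)
  for (i in seq_len(n)) {
    genes[[i]] <- if (scope[[i]] == "targeted") {
      sample(MMR_GENES, 1L)
    } else {
      sample_gene_combo(year[[i]])
    }
  }
  variant_gene <- ifelse(
    true_result == "normal", NA_character_,
    vapply(genes, function(g) sample(g, 1L), character(1))
  )

  has_variant <- true_result != "normal"
  is_cnv <- has_variant & true_result %in% c("P", "LP", "VUS") &
    stats::runif(n) < config$rate_cnv_among_abnormal
  hgvs <- random_hgvs(n, p_invalid = config$rate_hgvs_invalid)
  cnv <- random_cnv_phrases(n)

  tests <- tibble::tibble(
    person_uid = patients$person_uid,
    lab_code = labs$lab_code[lab_idx],
    authorised_date = auth,
    report_date = auth + sample(7:60, n, replace = TRUE),
    scope = scope,
    genes = genes,
    true_result = true_result,
    variant_gene = variant_gene,
    variant_cdna = ifelse(has_variant & !is_cnv, hgvs$variant_cdna,
                          NA_character_),
    variant_protein = ifelse(has_variant & !is_cnv, hgvs$variant_protein,
                             NA_character_),
    cnv_phrase = ifelse(is_cnv, cnv, NA_character_),
    hgvs_valid = ifelse(has_variant & !is_cnv, hgvs$hgvs_valid, NA),
    classification_reported =
      has_variant &
      (true_result %in% c("LB", "B") |
         stats::runif(n) < config$rate_classification_reported)
  )

  # repeat test episodes > 365 days after the first
  rep_idx <- which(stats::runif(n) < config$repeat_episode_rate &
                     scope == "full_gene")
  if (length(rep_idx)) {
    rep_tests <- tests[rep_idx, ]
    gap <- sample(400:1200, length(rep_idx), replace = TRUE)
    rep_tests$authorised_date <- rep_tests$authorised_date + gap
    rep_tests$report_date <- rep_tests$authorised_date +
      sample(7:60, length(rep_idx), replace = TRUE)
    keep <- rep_tests$authorised_date <= as.Date("2019-12-31")
    rep_tests <- rep_tests[keep, ]
    m <- nrow(rep_tests)
    if (m) {
      rep_res <- sample(names(probs), m, replace = TRUE, prob = probs)
      rep_hgvs <- random_hgvs(m, p_invalid = config$rate_hgvs_invalid)
      rep_cnv_flag <- rep_res %in% c("P", "LP", "VUS") &
        stats::runif(m) < config$rate_cnv_among_abnormal
      rep_tests$true_result <- rep_res
      rep_tests$variant_gene <- ifelse(
        rep_res == "normal", NA_character_,
        vapply(rep_tests$genes, function(g) sample(g, 1L), character(1))
      )
      rep_tests$variant_cdna <- ifelse(rep_res != "normal" & !rep_cnv_flag,
                                       rep_hgvs$variant_cdna, NA_character_)
      rep_tests$variant_protein <- ifelse(rep_res != "normal" & !rep_cnv_flag,
                                          rep_hgvs$variant_protein,
                                          NA_character_)
      rep_tests$cnv_phrase <- ifelse(rep_cnv_flag, random_cnv_phrases(m),
                                     NA_character_)
      rep_tests$hgvs_valid <- ifelse(rep_res != "normal" & !rep_cnv_flag,
                                     rep_hgvs$hgvs_valid, NA)
      rep_tests$classification_reported <- rep_res != "normal" &
        (rep_res %in% c("LB", "B") |
           stats::runif(m) < config$rate_classification_reported)
      tests <- dplyr::bind_rows(tests, rep_tests)
    }
  }

  # patient-level history starts at a financial-year boundary so observed
  # and audited years are directly comparable
  submission_start <- labs$first_submission_year[
    match(tests$lab_code, labs$lab_code)]
  tests$submitted <- financial_year(tests$authorised_date) >= submission_start
  tests <- dplyr::arrange(tests, .data$person_uid, .data$authorised_date)

  cancers <- plant_cancers(patients, tests, config)

  patients$tests <- split_reassemble(tests, patients$person_uid)
  patients$cancers <- split_reassemble(cancers, patients$person_uid)
  patients
}

# split a flat per-person table back into a list-column aligned to uids
split_reassemble <- function(flat, uids) {
  idx <- split(seq_len(nrow(flat)), factor(flat$person_uid, levels = uids))
  lapply(idx, function(i) flat[i, setdiff(names(flat), "person_uid")])
}

plant_cancers <- function(patients, tests, config) {
  first_test <- tests |>
    dplyr::group_by(.data$person_uid) |>
    dplyr::summarise(
      first_auth = min(.data$authorised_date),
      first_report = min(.data$report_date),
      scope = .data$scope[which.min(.data$authorised_date)],
      .groups = "drop"
    )
  n <- nrow(first_test)
  if (!n) {
    return(tibble::tibble(person_uid = character(), icd10 = character(),
                          diagnosis_date = as.Date(character())))
  }
  p_pre <- ifelse(first_test$scope == "full_gene",
                  config$pretest_cancer_rate_fullgene,
                  config$pretest_cancer_rate_targeted)
  has_pre <- stats::runif(n) < p_pre
  has_second <- has_pre & stats::runif(n) < config$second_cancer_rate
  has_post <- stats::runif(n) < config$posttest_cancer_rate

  draw_site <- function(m) {
    mix <- config$registry_cancer_site_mix
    group <- sample(names(mix), m, replace = TRUE, prob = mix)
    pools <- list(
      colorectal = c("C18.0", "C18.2", "C18.7", "C18.9", "C19", "C20"),
      uterine = c("C54.1", "C54.9", "C55"),
      other = c("C16.9", "C25.9", "C50.9", "C56", "C61", "C64", "C67.9",
                "C71.9")
    )
    vapply(group, function(g) sample(pools[[g]], 1L), character(1))
  }
  pre_dates <- function(idx) {
    back <- sample(365:5475, length(idx), replace = TRUE)
    pmax(first_test$first_auth[idx] - back, as.Date("1995-01-01"))
  }
  rows <- list()
  if (any(has_pre)) {
    idx <- which(has_pre)
    rows$pre <- tibble::tibble(
      person_uid = first_test$person_uid[idx],
      icd10 = draw_site(length(idx)),
      diagnosis_date = pre_dates(idx),
      planted_timing = "before_test"
    )
  }
  if (any(has_second)) {
    idx <- which(has_second)
    rows$second <- tibble::tibble(
      person_uid = first_test$person_uid[idx],
      icd10 = draw_site(length(idx)),
      diagnosis_date = pre_dates(idx),
      planted_timing = "before_test"
    )
  }
  if (any(has_post)) {
    idx <- which(has_post)
    fwd <- sample(90:2000, length(idx), replace = TRUE)
    dd <- first_test$first_report[idx] + fwd
    keep <- dd <= as.Date("2019-12-31")
    rows$post <- tibble::tibble(
      person_uid = first_test$person_uid[idx][keep],
      icd10 = draw_site(sum(keep)),
      diagnosis_date = dd[keep],
      planted_timing = "after_test"
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(person_uid = character(), icd10 = character(),
                          diagnosis_date = as.Date(character()),
                          planted_timing = character()))
  }
  dplyr::arrange(out, .data$person_uid, .data$diagnosis_date)
}
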