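# Writers emitting the synthetic source files consumed by the pipeline:
# per-lab extracts (CSV or JSONL depending on dialect), the cancer registry,
# the laboratory activity audit and the ground-truth ledger.

#' Flatten planted tests to one row per test
#'
#' @param patients output of [generate_patients()].
#' @return tibble with identifiers joined to each planted test.
#' @export
flatten_tests <- function(patients) {
  if (!nrow(patients)) {
    return(tibble::tibble(
      person_uid = character(), lab_code = character(),
      authorised_date = as.Date(character()),
      report_date = as.Date(character()), scope = character(),
      genes = list(), true_result = character(),
      variant_gene = character(), variant_cdna = character(),
      variant_protein = character(), cnv_phrase = character(),
      hgvs_valid = logical(), classification_reported = logical(),
      submitted = logical(), nhs_number = character(),
      dob = as.Date(character()), postcode = character()
    ))
  }
  flat <- dplyr::bind_rows(
    stats::setNames(patients$tests, patients$person_uid),
    .id = "person_uid"
  )
  dplyr::left_join(
    flat,
    patients[c("person_uid", "nhs_number", "dob", "postcode")],
    by = "person_uid"
  )
}

#' Flatten planted cancers to one row per registration
#'
#' @inheritParams flatten_tests
#' @return tibble with identifiers joined to each planted cancer.
#' @export
flatten_cancers <- function(patients) {
  if (!nrow(patients)) {
    return(tibble::tibble(person_uid = character()))
  }
  flat <- dplyr::bind_rows(
    stats::setNames(patients$cancers, patients$person_uid),
    .id = "person_uid"
  )
  dplyr::left_join(
    flat,
    patients[c("person_uid", "nhs_number", "dob", "postcode")],
    by = "person_uid"
  )
}

classification_of <- function(true_result, reported) {
  ifelse(reported & true_result != "normal", true_result, NA_character_)
}

# expand one row per (test, gene) with per-gene result labels
expand_per_gene <- function(tests) {
  tests$test_id <- seq_len(nrow(tests))
  long <- tidyr::unnest(tests, "genes") |>
    dplyr::rename(gene = "genes")
  long$is_variant_gene <- !is.na(long$variant_gene) &
    long$gene == long$variant_gene
  long$gene_abnormal <- long$is_variant_gene &
    long$true_result %in% c("P", "LP", "VUS")
  long$gene_has_variant <- long$is_variant_gene & long$true_result != "normal"
  long
}

class_text <- c(P = "Pathogenic", LP = "Likely pathogenic",
                VUS = "Uncertain significance", LB = "Likely benign",
                B = "Benign")
class_number <- c(B = 1L, LB = 2L, VUS = 3L, LP = 4L, P = 5L)

write_structured_extract <- function(tests, path, uk = FALSE) {
  long <- expand_per_gene(tests)
  cls <- classification_of(long$true_result, long$classification_reported)
  cls[!long$gene_has_variant] <- NA_character_
  out <- tibble::tibble(
    nhs_number = long$nhs_number,
    date_of_birth = format(long$dob, if (uk) "%d/%m/%Y" else "%Y-%m-%d"),
    postcode = long$postcode,
    authorised_date = format(long$authorised_date,
                             if (uk) "%d/%m/%Y" else "%Y-%m-%d"),
    report_date = format(long$report_date,
                         if (uk) "%d/%m/%Y" else "%Y-%m-%d"),
    test_type = ifelse(long$scope == "targeted",
                       if (uk) "PREDICTIVE" else "Predictive",
                       if (uk) "FULL SCREEN" else "Diagnostic"),
    gene = long$gene,
    result = ifelse(long$gene_abnormal,
                    if (uk) "VARIANT DETECTED" else "Abnormal",
                    if (uk) "NAD" else "Normal"),
    classification = if (uk) {
      ifelse(is.na(cls), NA_character_, paste("CLASS", class_number[cls]))
    } else {
      ifelse(is.na(cls), NA_character_, class_text[cls])
    },
    variant_cdna = ifelse(long$gene_has_variant, long$variant_cdna,
                          NA_character_),
    variant_protein = ifelse(long$gene_has_variant, long$variant_protein,
                             NA_character_),
    cnv_desc = ifelse(long$gene_has_variant, long$cnv_phrase, NA_character_)
  )
  if (uk) {
    names(out) <- c("NHSNO", "DOB", "POSTCODE", "AUTH_DATE", "REP_DATE",
                    "TEST_TYPE", "GENE", "RESULT", "CLASS", "CDNA",
                    "PROTEIN", "CNV_DESC")
  }
  readr::write_csv(out, path, na = "")
  path
}

gene_list_phrase <- function(genes) {
  if (length(genes) == 1L) return(genes)
  paste0(paste(genes[-length(genes)], collapse = ", "), " and ",
         genes[length(genes)])
}

# Free-text report wording, templated with randomised filler so downstream
# extraction cannot succeed by position.
build_report_text <- function(row, leak_identifier = FALSE) {
  opener <- sample(c("", "As requested, ", "Further to the recent referral, "),
                   1L)
  sentences <- character(0)
  positive <- !is.na(row$variant_gene)
  class_sentence <- NULL
  if (positive && row$classification_reported) {
    label <- row$true_result
    class_sentence <- if (stats::runif(1) < 0.5) {
      paste0("This variant is classified as ",
             tolower(class_text[[label]]), ".")
    } else {
      paste0("This is a class ", class_number[[label]], " variant.")
    }
  }
  if (row$scope == "targeted") {
    sentences <- c(sentences, paste0(
      opener, "Targeted ", sample(c("analysis", "testing"), 1L),
      " for the familial ", row$genes[[1]], " variant was ",
      sample(c("performed", "undertaken"), 1L), "."
    ))
    if (positive) {
      found <- if (!is.na(row$cnv_phrase)) {
        paste0("The familial ", row$cnv_phrase, " of ", row$variant_gene,
               " was ", sample(c("detected", "identified"), 1L), ".")
      } else {
        paste0("The familial variant ", row$variant_cdna, " was ",
               sample(c("detected", "identified"), 1L), " in ",
               row$variant_gene, ".")
      }
      sentences <- c(sentences, found, class_sentence)
    } else {
      sentences <- c(sentences, paste0(
        "The familial ", row$genes[[1]], " variant was not detected."
      ))
    }
  } else {
    sentences <- c(sentences, paste0(
      opener,
      sample(c("Screening", "Sequence and dosage analysis",
               "Full gene analysis"), 1L),
      " of ", gene_list_phrase(row$genes[[1]]), " was ",
      sample(c("performed", "undertaken"), 1L), "."
    ))
    if (positive) {
      found <- if (!is.na(row$cnv_phrase)) {
        paste0("A ", row$cnv_phrase, " of ", row$variant_gene,
               " was identified.")
      } else {
        paste0(
          "A heterozygous ", sample(c("variant", "sequence variant"), 1L),
          " ", row$variant_cdna,
          ifelse(is.na(row$variant_protein), "",
                 paste0(" ", row$variant_protein)),
          " was ", sample(c("identified", "detected"), 1L), " in ",
          row$variant_gene, "."
        )
      }
      sentences <- c(sentences, found, class_sentence)
    }
    normal_genes <- setdiff(row$genes[[1]],
                            if (positive) row$variant_gene else character(0))
    if (length(normal_genes)) {
      sentences <- c(sentences, paste0(
        sample(c("No pathogenic variant", "No clinically significant variant"),
               1L),
        " was ", sample(c("identified", "detected"), 1L), " in ",
        gene_list_phrase(normal_genes), "."
      ))
    }
  }
  if (leak_identifier && !is.na(row$nhs_number)) {
    sentences <- c(sentences, paste0(
      "Sample logged for patient ", row$nhs_number, "."
    ))
  }
  paste(sentences, collapse = " ")
}

write_freetext_extract <- function(tests, path) {
  lines <- vapply(seq_len(nrow(tests)), function(i) {
    row <- tests[i, ]
    leak <- stats::runif(1) < 0.02
    rec <- list(
      nhs_number = row$nhs_number,
      date_of_birth = if (is.na(row$dob)) NULL else format(row$dob, "%Y-%m-%d"),
      postcode = row$postcode,
      authorised_date = format(row$authorised_date, "%Y-%m-%d"),
      report_date = format(row$report_date, "%Y-%m-%d"),
      report_text = build_report_text(row, leak_identifier = leak)
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  path
}

#' Write one extract file per laboratory
#'
#' Structured dialects carry gene, result and variant in columns (one row
#' per gene per test); the free-text dialect embeds variants and
#' classifications in generated clinical report wording, with copy-number
#' variants described in natural language and never in HGVS. Only tests
#' dated on or after the laboratory's first submission year are written,
#' mirroring the unextractable history of older laboratory systems.
#'
#' @inheritParams flatten_tests
#' @param config the [generator_config()] used to generate `patients`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, one per laboratory.
#' @export
write_lab_extracts <- function(patients, config, dir) {
  validate_generator_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 77003L)
  tests <- flatten_tests(patients)
  if (nrow(tests)) {
    unknown <- setdiff(unique(tests$lab_code), config$labs$lab_code)
    if (length(unknown)) {
      abort(sprintf("planted tests reference unknown lab '%s'", unknown[[1]]),
            class = "lynchledger_config_error")
    }
  }
  paths <- character(0)
  for (i in seq_len(nrow(config$labs))) {
    lab <- config$labs[i, ]
    rows <- tests[tests$lab_code == lab$lab_code & tests$submitted, ,
                  drop = FALSE]
    path <- switch(
      lab$dialect,
      structured = write_structured_extract(
        rows, file.path(dir, paste0("extract_", lab$lab_code, ".csv"))),
      structured_uk = write_structured_extract(
        rows, file.path(dir, paste0("extract_", lab$lab_code, ".csv")),
        uk = TRUE),
      freetext = write_freetext_extract(
        rows, file.path(dir, paste0("extract_", lab$lab_code, ".jsonl"))),
      abort(sprintf("unknown dialect '%s'", lab$dialect),
            class = "lynchledger_config_error")
    )
    paths[[lab$lab_code]] <- path
  }
  paths
}

#' Write the synthetic cancer registry
#'
#' One row per planted cancer registration carrying the patient's raw
#' identifiers (pseudonymised later under the same scheme as the extracts),
#' the ICD-10 site code and the diagnosis date.
#'
#' @inheritParams flatten_tests
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_registry <- function(patients, path) {
  cancers <- flatten_cancers(patients)
  out <- tibble::tibble(
    nhs_number = character(), dob = character(), postcode = character(),
    icd10 = character(), diagnosis_date = character()
  )
  if (nrow(cancers)) {
    out <- tibble::tibble(
      nhs_number = cancers$nhs_number,
      dob = format(cancers$dob, "%Y-%m-%d"),
      postcode = cancers$postcode,
      icd10 = cancers$icd10,
      diagnosis_date = format(cancers$diagnosis_date, "%Y-%m-%d")
    )
    out <- dplyr::arrange(out, .data$nhs_number, .data$dob, .data$icd10,
                          .data$diagnosis_date)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write per-laboratory annual audit counts
#'
#' The audit records each laboratory's true annual test count multiplied by
#' its configured inflation factor (emulating inclusion of non-NHS and
#' microsatellite-instability analyses), rounded half-up, for financial
#' years 1998-2015 only.
#'
#' @inheritParams write_lab_extracts
#' @param path output CSV path.
#' @return the audit tibble, invisibly.
#' @export
write_audit_counts <- function(patients, config, path) {
  validate_generator_config(config)
  tests <- flatten_tests(patients)
  grid <- tidyr::expand_grid(
    lab_code = config$labs$lab_code,
    financial_year = AUDIT_YEARS
  )
  if (nrow(tests)) {
    counts <- tests |>
      dplyr::mutate(financial_year = financial_year(.data$authorised_date)) |>
      dplyr::filter(.data$financial_year %in% AUDIT_YEARS) |>
      dplyr::count(.data$lab_code, .data$financial_year, name = "true_count")
  } else {
    counts <- tibble::tibble(lab_code = character(),
                             financial_year = integer(),
                             true_count = integer())
  }
  audit <- grid |>
    dplyr::left_join(counts, by = c("lab_code", "financial_year")) |>
    dplyr::mutate(
      true_count = dplyr::coalesce(.data$true_count, 0L),
      inflation = config$labs$audit_inflation[
        match(.data$lab_code, config$labs$lab_code)],
      audit_count = as.integer(round_half_up(.data$true_count *
                                               .data$inflation))
    ) |>
    dplyr::filter(.data$true_count > 0L | .data$audit_count > 0L)
  readr::write_csv(
    audit[c("lab_code", "financial_year", "audit_count")], path, na = ""
  )
  invisible(audit)
}

#' Write the ground-truth ledger
#'
#' JSONL, one line per patient, holding everything the generator planted.
#' The ledger exists for test oracles only and is never read by the
#' pipeline.
#'
#' @inheritParams flatten_tests
#' @param path output JSONL path.
#' @return the path, invisibly.
#' @export
write_truth_ledger <- function(patients, path) {
  lines <- vapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    tests <- p$tests[[1]]
    tests$genes <- vapply(tests$genes, paste, character(1), collapse = "+")
    rec <- list(
      person_uid = p$person_uid,
      nhs_number = p$nhs_number,
      dob = if (is.na(p$dob)) NULL else format(p$dob, "%Y-%m-%d"),
      postcode = p$postcode,
      tests = tests,
      cancers = p$cancers[[1]]
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null",
                     dataframe = "rows")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
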