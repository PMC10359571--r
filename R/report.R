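# Summary tables (per-year totals, gene combinations, result breakdowns,
# linkage strata, cancer timing) and the end-to-end pipeline runner.

#' Summarise episodes, linkage and coverage into reporting tables
#'
#' Produces the descriptive tables of the dataset as tidy tibbles:
#' per-calendar-year episode totals by scope, gene-combination proportions
#' among first full-gene episodes, result-severity breakdowns with
#' classification availability, linkage strata, the cancer-timing site
#' table and the per-financial-year coverage table. Result and gene tables
#' are binned by calendar year, coverage by financial year.
#'
#' @param episodes episode table from [build_episodes()].
#' @param linkage result of [link_records()], or `NULL`.
#' @param timing result of [assign_timing()], or `NULL`.
#' @param coverage a `lynchledger_coverage` object, or `NULL`.
#' @param years calendar-year window for the descriptive tables.
#' @return list of tibbles (class `lynchledger_summary`).
#' @export
summarise_dataset <- function(episodes, linkage = NULL, timing = NULL,
                              coverage = NULL, years = 2001:2019) {
  episodes$year <- as.integer(format(episodes$episode_date, "%Y"))
  in_window <- episodes[episodes$year %in% years, ]

  tests_per_year <- in_window |>
    dplyr::count(.data$year, .data$scope) |>
    tidyr::pivot_wider(names_from = "scope", values_from = "n",
                       values_fill = 0L)

  first_fg <- in_window |>
    dplyr::filter(.data$scope == "full_gene", .data$episode_index == 1L)
  gene_combinations <- first_fg |>
    dplyr::count(.data$year, .data$genes) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  fg <- in_window[in_window$scope == "full_gene", ]
  results_per_year <- fg |>
    dplyr::count(.data$year,
                 most_significant = factor(.data$most_significant,
                                           levels = RESULT_HIERARCHY)) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  abnormal <- fg$most_significant != "normal"
  classification_availability <- tibble::tibble(
    n_abnormal = sum(abnormal),
    n_classified = sum(abnormal &
                         fg$most_significant %in% c("P", "LP", "VUS")),
    classified_pct = if (sum(abnormal) > 0) {
      100 * sum(abnormal & fg$most_significant %in% c("P", "LP", "VUS")) /
        sum(abnormal)
    } else {
      NA_real_
    }
  )

  cancer_timing <- NULL
  if (!is.null(timing) && nrow(timing$cancers)) {
    scope_by_patient <- episodes |>
      dplyr::filter(.data$episode_index == 1L) |>
      dplyr::select("patient_key", "scope")
    cancer_timing <- timing$cancers |>
      dplyr::inner_join(scope_by_patient, by = "patient_key") |>
      dplyr::count(.data$scope, .data$site_group, .data$timing)
  }

  structure(
    list(
      tests_per_year = tests_per_year,
      gene_combinations = gene_combinations,
      results_per_year = results_per_year,
      classification_availability = classification_availability,
      linkage_strata = if (is.null(linkage)) NULL else linkage$strata,
      cancer_timing = cancer_timing,
      coverage_table = if (is.null(coverage)) NULL else coverage$table
    ),
    class = "lynchledger_summary"
  )
}

#' Estimate the underlying P/LP detection rate
#'
#' Pathogenicity classifications are available for only a minority of
#' abnormal results, so the raw share of episodes labelled P/LP
#' underestimates the true yield. Provided classification availability is
#' independent of the class itself, the yield is recoverable as the
#' abnormal rate multiplied by the P/LP share among
#' classification-available abnormal episodes.
#'
#' @param episodes episode table (first episodes of full-gene patients are
#'   used).
#' @return list with `abnormal_rate`, `plp_share_classified` and
#'   `plp_rate` (all fractions), plus the counts behind them.
#' @export
estimate_plp_rate <- function(episodes) {
  fg <- episodes[episodes$scope == "full_gene" &
                   episodes$episode_index == 1L, ]
  abnormal <- fg$most_significant != "normal"
  classified <- fg$most_significant %in% c("P", "LP", "VUS")
  plp <- fg$most_significant %in% c("P", "LP")
  abnormal_rate <- mean(abnormal)
  plp_share <- if (sum(classified) > 0) sum(plp) / sum(classified) else
    NA_real_
  list(
    n_fullgene = nrow(fg),
    n_abnormal = sum(abnormal),
    n_classified = sum(classified),
    abnormal_rate = abnormal_rate,
    plp_share_classified = plp_share,
    plp_rate = abnormal_rate * plp_share
  )
}

#' Run the full pipeline on synthetic data
#'
#' Generates synthetic source files (unless `source_dir` provides them),
#' harmonises every laboratory extract into the common data model,
#' deduplicates and collapses test episodes, links to the pseudonymised
#' registry, estimates national coverage from the audit counts and writes
#' the summary tables plus a run manifest to `out_dir`.
#'
#' @param config a [generator_config()].
#' @param key pseudonymisation secret.
#' @param out_dir output directory.
#' @param source_dir directory with pre-existing source files laid out as
#'   the generator writes them; when given, generation is skipped.
#' @return invisible list with all intermediate objects (`cdm`,
#'   `episodes`, `linkage`, `timing`, `coverage`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config, key, out_dir,
                         source_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  src <- source_dir %||% file.path(out_dir, "source")

  if (is.null(source_dir)) {
    patients <- generate_patients(config)
    extract_paths <- write_lab_extracts(patients, config, src)
    write_registry(patients, file.path(src, "registry.csv"))
    write_audit_counts(patients, config, file.path(src, "audit.csv"))
    write_truth_ledger(patients, file.path(src, "truth_ledger.jsonl"))
  } else {
    ext <- ifelse(config$labs$dialect == "freetext", "jsonl", "csv")
    extract_paths <- stats::setNames(
      file.path(src, paste0("extract_", config$labs$lab_code, ".", ext)),
      config$labs$lab_code
    )
  }

  mapped <- purrr::map(config$labs$lab_code, function(lab) {
    spec <- dialect_spec(config$labs$dialect[config$labs$lab_code == lab])
    map_extract(extract_paths[[lab]], spec, key, lab_code = lab)
  })
  cdm <- dplyr::bind_rows(purrr::map(mapped, "records"))
  quarantine <- dplyr::bind_rows(purrr::map(mapped, "quarantine"))

  episodes <- build_episodes(cdm)
  registry <- pseudonymise_registry(file.path(src, "registry.csv"), key)
  linkage <- link_records(episodes, registry)
  timing <- assign_timing(linkage$matches, episodes)

  audit <- readr::read_csv(
    file.path(src, "audit.csv"),
    col_types = readr::cols(lab_code = "c", financial_year = "i",
                            audit_count = "i"),
    progress = FALSE
  )
  active_from <- stats::setNames(config$labs$activity_start_year,
                                 config$labs$lab_code)
  coverage <- estimate_coverage(observed_counts(episodes), audit,
                                active_from = active_from)

  summary <- summarise_dataset(episodes, linkage, timing, coverage)

  write_cdm(cdm, file.path(out_dir, "cdm.csv"))
  write_cdm(cdm, file.path(out_dir, "cdm.jsonl"))
  readr::write_csv(episodes, file.path(out_dir, "episodes.csv"), na = "")
  readr::write_csv(timing$cancers, file.path(out_dir, "linked_cancers.csv"),
                   na = "")
  jsonlite::write_json(linkage$strata, file.path(out_dir, "strata.json"))
  readr::write_csv(coverage$table, file.path(out_dir, "coverage.csv"),
                   na = "")
  for (nm in names(summary)) {
    if (!is.null(summary[[nm]]) && is.data.frame(summary[[nm]])) {
      readr::write_csv(summary[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       na = "")
    }
  }
  if (nrow(quarantine)) {
    writeLines(
      vapply(seq_len(nrow(quarantine)), function(i) {
        jsonlite::toJSON(as.list(quarantine[i, ]), auto_unbox = TRUE)
      }, character(1)),
      file.path(out_dir, "quarantine.jsonl")
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lynchledger")),
    seed = config$seed,
    n_patients = config$n_patients,
    key_fingerprint = substr(as.character(openssl::sha256(key)), 1L, 16L),
    counts = list(
      cdm_records = nrow(cdm),
      quarantined = nrow(quarantine),
      episodes = nrow(episodes),
      patients = dplyr::n_distinct(episodes$patient_key),
      linked_cancers = nrow(timing$cancers)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    cdm = cdm, quarantine = quarantine, episodes = episodes,
    linkage = linkage, timing = timing, coverage = coverage,
    summary = summary, manifest = manifest
  ))
}
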