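# Deterministic linkage of pseudonymised test episodes to the
# pseudonymised cancer registry, cancer-timing classification relative to
# the first test episode, and ICD-10 site grouping.

#' Pseudonymise the cancer registry
#'
#' Reads a raw registry CSV (identifiers, ICD-10 code, diagnosis date),
#' computes the same pseudonym pair as for laboratory extracts under the
#' same key, and strips the raw identifiers.
#'
#' @param path registry CSV.
#' @param key pseudonymisation secret; must match the extract key.
#' @return tibble with `pseudo_id1`, `pseudo_id2`, `icd10`,
#'   `diagnosis_date`.
#' @export
pseudonymise_registry <- function(path, key) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!nrow(raw)) {
    return(tibble::tibble(
      pseudo_id1 = character(), pseudo_id2 = character(),
      icd10 = character(), diagnosis_date = as.Date(character())
    ))
  }
  raw$dob <- parse_date_quiet(raw$dob)
  out <- add_pseudonyms(raw, key)
  out$diagnosis_date <- parse_date_quiet(out$diagnosis_date)
  out <- strip_identifiers(out, text_cols = character(0))
  out[c("pseudo_id1", "pseudo_id2", "icd10", "diagnosis_date")]
}

#' Group an ICD-10 code into the reporting site groups
#'
#' C18-C20 is colorectal, C54-C55 uterine, and any other malignant code
#' "other". Malformed codes raise an error.
#'
#' @param code character vector of ICD-10 codes (e.g. `"C18.9"`).
#' @return character vector over `colorectal`, `uterine`, `other`.
#' @examples
#' group_icd10(c("C18.9", "C54.1", "C50.9"))
#' @export
group_icd10 <- function(code) {
  ok <- grepl("^[CD][0-9]{2}(\\.[0-9X]{1,2})?$", code)
  if (any(!ok | is.na(code))) {
    abort(sprintf("malformed ICD-10 code '%s'",
                  code[!ok | is.na(code)][[1]]))
  }
  num <- as.integer(substr(code, 2L, 3L))
  letter <- substr(code, 1L, 1L)
  dplyr::case_when(
    letter == "C" & num >= 18L & num <= 20L ~ "colorectal",
    letter == "C" & num >= 54L & num <= 55L ~ "uterine",
    TRUE ~ "other"
  )
}

#' Link test episodes to cancer registrations
#'
#' Deterministic two-stage linkage at patient level: match on pseudo-ID1
#' when both sides carry it, otherwise on pseudo-ID2; patients with neither
#' pseudonym are unlinkable. When an ID1 match exists but the ID2 values
#' disagree, ID1 wins and the conflict is counted.
#'
#' @param episodes episode table from [build_episodes()].
#' @param registry pseudonymised registry from [pseudonymise_registry()].
#' @return list with `matches` (one row per patient-cancer pair, with
#'   `matched_via`), `strata` (patient counts per identifier stratum) and
#'   `n_conflicts`.
#' @export
link_records <- function(episodes, registry) {
  patients <- dplyr::distinct(
    episodes, .data$patient_key, .data$pseudo_id1, .data$pseudo_id2
  )
  strata <- patients |>
    dplyr::count(
      stratum = id_stratum(.data$pseudo_id1, .data$pseudo_id2),
      .drop = FALSE, name = "n_patients"
    )

  reg <- registry
  reg$registry_row <- seq_len(nrow(reg))

  via1 <- patients |>
    dplyr::filter(!is.na(.data$pseudo_id1)) |>
    dplyr::inner_join(
      dplyr::filter(reg, !is.na(.data$pseudo_id1)),
      by = "pseudo_id1", suffix = c("", "_reg")
    ) |>
    dplyr::mutate(matched_via = "id1")
  n_conflicts <- sum(
    !is.na(via1$pseudo_id2) & !is.na(via1$pseudo_id2_reg) &
      via1$pseudo_id2 != via1$pseudo_id2_reg
  )
  if (n_conflicts > 0) {
    warn(sprintf(
      "linkage: %d ID1 matches had conflicting pseudo-ID2; ID1 wins",
      n_conflicts
    ))
  }

  # ID2 fallback only for patients with no usable ID1 link on either side
  via2 <- patients |>
    dplyr::filter(is.na(.data$pseudo_id1), !is.na(.data$pseudo_id2)) |>
    dplyr::inner_join(
      dplyr::filter(reg, !is.na(.data$pseudo_id2)),
      by = "pseudo_id2", suffix = c("", "_reg")
    ) |>
    dplyr::mutate(matched_via = "id2")

  keep <- c("patient_key", "icd10", "diagnosis_date", "registry_row",
            "matched_via")
  matches <- dplyr::bind_rows(via1[keep], via2[keep])
  matches$site_group <- if (nrow(matches)) group_icd10(matches$icd10) else
    character(0)
  list(matches = matches, strata = strata, n_conflicts = n_conflicts)
}

#' Classify cancer timing relative to the first test episode
#'
#' The reference date is the report date of the patient's first test
#' episode; a diagnosis on or before the reference date counts as before
#' the test. Patients with cancers on both sides are flagged `both`.
#'
#' @param matches match table from [link_records()].
#' @param episodes episode table.
#' @return list with `cancers` (per-cancer `timing`) and `patients`
#'   (per-patient flag `pre_only`/`post_only`/`both`/`no_cancer` over all
#'   episode patients).
#' @export
assign_timing <- function(matches, episodes) {
  reference <- episodes |>
    dplyr::filter(.data$episode_index == 1L) |>
    dplyr::select("patient_key", reference_date = "report_date")
  missing_dx <- is.na(matches$diagnosis_date)
  if (any(missing_dx)) {
    warn(sprintf("assign_timing: %d cancers without diagnosis date excluded",
                 sum(missing_dx)))
    matches <- matches[!missing_dx, ]
  }
  cancers <- matches |>
    dplyr::inner_join(reference, by = "patient_key") |>
    dplyr::mutate(
      timing = ifelse(.data$diagnosis_date <= .data$reference_date,
                      "before_test", "after_test")
    )
  flags <- cancers |>
    dplyr::group_by(.data$patient_key) |>
    dplyr::summarise(
      flag = dplyr::case_when(
        any(timing == "before_test") & any(timing == "after_test") ~ "both",
        any(timing == "before_test") ~ "pre_only",
        TRUE ~ "post_only"
      ),
      .groups = "drop"
    )
  patients <- reference |>
    dplyr::left_join(flags, by = "patient_key") |>
    dplyr::mutate(flag = dplyr::coalesce(.data$flag, "no_cancer")) |>
    dplyr::select("patient_key", "flag")
  list(cancers = cancers, patients = patients)
}
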