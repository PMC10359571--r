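# Collapse per-gene CDM records into per-patient test episodes: deduplicate,
# anchor 365-day windows at the earliest authorisation date, and summarise
# each episode by scope, gene combination and most significant result.

#' Patient key from a pseudonym pair
#'
#' Patients are identified by pseudo-ID1 when available, else pseudo-ID2.
#' Records with neither pseudonym cannot be linked across submissions;
#' they fall back to `fallback` (by default a unique key per record; the
#' episode builder uses laboratory plus authorisation date so the per-gene
#' rows of one unlinkable test still form one episode).
#'
#' @param pseudo_id1,pseudo_id2 character vectors.
#' @param fallback key used where both pseudonyms are absent.
#' @return character vector of patient keys.
#' @export
patient_key <- function(pseudo_id1, pseudo_id2,
                        fallback = paste0("unlinkable-",
                                          seq_along(pseudo_id1))) {
  dplyr::coalesce(pseudo_id1, pseudo_id2, fallback)
}

#' Deduplicate common-data-model records
#'
#' Records identical on (pseudonym pair, gene, authorised date, variant,
#' classification) are reduced to one; the number removed is attached as
#' attribute `n_removed`.
#'
#' @param records CDM tibble.
#' @return deduplicated tibble.
#' @export
deduplicate <- function(records) {
  if (!nrow(records)) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  keys <- c("pseudo_id1", "pseudo_id2", "gene", "authorised_date",
            "variant_cdna", "cnv_text", "classification")
  out <- dplyr::distinct(records, dplyr::across(dplyr::all_of(keys)),
                         .keep_all = TRUE)
  attr(out, "n_removed") <- nrow(records) - nrow(out)
  out
}

#' Severity of a single record
#'
#' A record is abnormal when labelled positive or carrying a P/LP/VUS
#' classification (an unclassified positive is "abnormal unclassified");
#' normal when labelled negative or carrying only benign/likely-benign
#' variants.
#'
#' @param result_label `"positive"`/`"negative"`.
#' @param classification one of [CLASSIFICATION_LEVELS].
#' @return character vector over [RESULT_HIERARCHY].
#' @export
record_severity <- function(result_label, classification) {
  dplyr::case_when(
    classification %in% c("P", "LP", "VUS") ~ classification,
    classification %in% c("LB", "B") ~ "normal",
    result_label == "positive" ~ "abnormal_unclassified",
    TRUE ~ "normal"
  )
}

#' Most significant result of a set of member results
#'
#' Maximum under the total order P > LP > VUS > abnormal unclassified >
#' normal. Benign/likely-benign inputs count as normal.
#'
#' @param results character vector over [RESULT_HIERARCHY] (LB/B accepted).
#' @return single element of [RESULT_HIERARCHY].
#' @export
most_significant_result <- function(results) {
  if (!length(results)) {
    abort("most_significant_result: empty input")
  }
  results[results %in% c("LB", "B")] <- "normal"
  bad <- setdiff(results, RESULT_HIERARCHY)
  if (length(bad)) {
    abort(sprintf("unknown result '%s'", bad[[1]]))
  }
  RESULT_HIERARCHY[min(match(results, RESULT_HIERARCHY))]
}

#' Episode scope from member records
#'
#' Scope comes from the mapped test-type field when present. When every
#' member's scope was derived rather than mapped, a single-gene episode
#' whose only content is a presence/absence call for one specific variant
#' is targeted; anything else is full-gene, and the derivation is flagged.
#'
#' @param members CDM records of one episode.
#' @return list with `scope` and `derived` flag.
#' @export
classify_scope <- function(members) {
  mapped <- members[!members$scope_derived, ]
  if (nrow(mapped)) {
    return(list(
      scope = if (any(mapped$scope == "full_gene")) "full_gene" else "targeted",
      derived = FALSE
    ))
  }
  derived_scope <- unique(members$scope)
  if (length(derived_scope) == 1L && derived_scope == "targeted") {
    return(list(scope = "targeted", derived = TRUE))
  }
  n_genes <- length(unique(members$gene))
  n_variants <- sum(!is.na(members$variant_cdna) | !is.na(members$cnv_text))
  if (any(members$scope == "targeted") && n_genes == 1L && n_variants <= 1L) {
    list(scope = "targeted", derived = TRUE)
  } else {
    list(scope = "full_gene", derived = TRUE)
  }
}

#' Canonical gene-combination label
#'
#' Genes sorted in the fixed MLH1, MSH2, MSH6, PMS2 order and joined with
#' `+`, e.g. `"MLH1+MSH2"`.
#'
#' @param genes character vector of gene symbols.
#' @return single label string.
#' @export
gene_combination <- function(genes) {
  paste(MMR_GENES[MMR_GENES %in% genes], collapse = "+")
}

#' Collapse one patient's records into test episodes
#'
#' Records are sorted by authorisation date and collapsed greedily: the
#' first record opens an episode anchored at its date, subsequent records
#' join while they fall within 365 days of the anchor, and the first record
#' beyond the window opens a new episode. Every record lands in exactly one
#' episode, and the earliest authorisation date is the episode date.
#'
#' @param records CDM records sharing one pseudonym pair.
#' @param window_days episode window (365).
#' @return tibble of episodes with a `members` list-column of record
#'   indices into the sorted input.
#' @export
collapse_episodes <- function(records, window_days = 365L) {
  if (!nrow(records)) {
    return(tibble::tibble(
      episode_date = as.Date(character()), report_date = as.Date(character()),
      lab_codes = character(), scope = character(),
      scope_derived = logical(), genes = character(),
      most_significant = character(), n_records = integer(),
      members = list()
    ))
  }
  ord <- order(records$authorised_date)
  records <- records[ord, ]
  anchor <- records$authorised_date[[1]]
  episode_id <- integer(nrow(records))
  current <- 1L
  episode_id[[1]] <- current
  for (i in seq_len(nrow(records))[-1]) {
    if (as.integer(records$authorised_date[[i]] - anchor) > window_days) {
      current <- current + 1L
      anchor <- records$authorised_date[[i]]
    }
    episode_id[[i]] <- current
  }
  purrr::map_dfr(split(seq_len(nrow(records)), episode_id), function(idx) {
    members <- records[idx, ]
    sc <- classify_scope(members)
    report <- members$report_date[!is.na(members$report_date)]
    tibble::tibble(
      episode_date = min(members$authorised_date),
      report_date = if (length(report)) min(report) else
        min(members$authorised_date),
      lab_codes = paste(sort(unique(members$lab_code)), collapse = ","),
      scope = sc$scope,
      scope_derived = sc$derived,
      genes = gene_combination(unique(members$gene)),
      most_significant = most_significant_result(
        record_severity(members$result_label, members$classification)
      ),
      n_records = length(idx),
      members = list(idx)
    )
  })
}

#' Build the episode table for a whole CDM dataset
#'
#' Deduplicates, groups records by patient (pseudo-ID1 when available, else
#' pseudo-ID2) and collapses each patient's records into 365-day episodes.
#'
#' @param records CDM tibble.
#' @param window_days episode window.
#' @return tibble with one row per episode, carrying the pseudonym pair,
#'   patient key and an `episode_index` per patient.
#' @export
build_episodes <- function(records, window_days = 365L) {
  records <- deduplicate(records)
  n_dedup <- attr(records, "n_removed")
  if (!nrow(records)) {
    out <- tibble::tibble(
      patient_key = character(), pseudo_id1 = character(),
      pseudo_id2 = character(), episode_index = integer(),
      episode_date = as.Date(character()), report_date = as.Date(character()),
      lab_codes = character(), scope = character(), scope_derived = logical(),
      genes = character(), most_significant = character(),
      n_records = integer()
    )
    attr(out, "n_dedup_removed") <- n_dedup
    return(out)
  }
  records$patient_key <- patient_key(
    records$pseudo_id1, records$pseudo_id2,
    fallback = paste0("unlinkable-", records$lab_code, "-",
                      format(records$authorised_date, "%Y-%m-%d"))
  )
  out <- records |>
    dplyr::group_by(.data$patient_key) |>
    dplyr::group_modify(function(df, key) {
      ep <- collapse_episodes(df, window_days = window_days)
      ep$pseudo_id1 <- df$pseudo_id1[[1]]
      ep$pseudo_id2 <- df$pseudo_id2[[1]]
      ep$episode_index <- seq_len(nrow(ep))
      ep
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"members")
  out <- out[c("patient_key", "pseudo_id1", "pseudo_id2", "episode_index",
               "episode_date", "report_date", "lab_codes", "scope",
               "scope_derived", "genes", "most_significant", "n_records")]
  attr(out, "n_dedup_removed") <- n_dedup
  out
}
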