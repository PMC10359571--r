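# Shared fixtures: all synthetic, built in code at test time.

test_key <- "unit-test-secret"

# small, fast configuration: every lab submits from the start of activity
# so all planted tests are extractable unless a test needs history
small_config <- function(n = 200, seed = 42, dialects = NULL, ...) {
  labs <- default_labs()
  if (!is.null(dialects)) {
    labs <- labs[match(dialects, labs$dialect), ]
    labs$lab_code <- paste0("LAB", seq_len(nrow(labs)))
  }
  labs$first_submission_year <- labs$activity_start_year
  generator_config(n_patients = n, seed = seed, labs = labs, ...)
}

# minimal CDM-shaped records for episode/collapse tests
make_records <- function(dates,
                         gene = "MLH1",
                         result_label = "negative",
                         classification = "unclassified",
                         scope = "full_gene",
                         lab_code = "LABX",
                         pseudo_id1 = "tok1",
                         pseudo_id2 = "tok2") {
  n <- length(dates)
  tibble::tibble(
    pseudo_id1 = rep_len(pseudo_id1, n),
    pseudo_id2 = rep_len(pseudo_id2, n),
    lab_code = rep_len(lab_code, n),
    authorised_date = as.Date(dates),
    report_date = as.Date(dates) + 14L,
    scope = rep_len(scope, n),
    scope_derived = FALSE,
    gene = rep_len(gene, n),
    result_label = rep_len(result_label, n),
    classification = rep_len(classification, n),
    variant_cdna = NA_character_,
    variant_protein = NA_character_,
    cnv_text = NA_character_,
    source_text = NA_character_,
    source_row = seq_len(n)
  )
}

# independent greedy-anchor reference: sort, open an episode at the first
# date, join while within the window, else re-anchor
oracle_episode_sizes <- function(dates, window = 365L) {
  dates <- sort(as.Date(dates))
  sizes <- integer(0)
  anchor <- NULL
  for (d in seq_along(dates)) {
    if (is.null(anchor) ||
        as.integer(dates[[d]] - anchor) > window) {
      anchor <- dates[[d]]
      sizes <- c(sizes, 1L)
    } else {
      sizes[length(sizes)] <- sizes[length(sizes)] + 1L
    }
  }
  sizes
}
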