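# Dialect specifications and the extract-to-CDM mapper. Each laboratory
# dialect is described declaratively (column mappings, date format, result
# vocabulary, free-text fields to scan); the mapper quarantines rows it
# cannot interpret rather than dropping them.

#' Load a dialect specification
#'
#' Built-in dialects (`structured`, `structured_uk`, `freetext`) are YAML
#' files shipped with the package; a path to a custom YAML file is also
#' accepted.
#'
#' @param name dialect name or path to a YAML spec.
#' @return dialect spec list (class `lynchledger_dialect`).
#' @export
dialect_spec <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "dialects", paste0(name, ".yaml"),
                package = "lynchledger")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("unknown dialect '%s'", name),
          class = "lynchledger_config_error")
  }
  spec <- yaml::read_yaml(path)
  required <- c("dialect_name", "format", "date_format", "columns")
  if (!all(required %in% names(spec))) {
    abort(sprintf("dialect spec '%s' is missing required fields", name),
          class = "lynchledger_config_error")
  }
  structure(spec, class = "lynchledger_dialect")
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(tibble::tibble())
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA_character_
    tibble::as_tibble(rec)
  })
  dplyr::bind_rows(rows)
}

vocab_lookup <- function(x, vocab) {
  cleaned <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  for (target in names(vocab)) {
    out[cleaned %in% tolower(vocab[[target]])] <- target
  }
  out
}

# Parse one free-text clinical report into per-gene results. Sentences are
# scanned for gene symbols, HGVS tokens, CNV language, negative-result
# phrasing and classification clauses; a classification sentence with no
# gene attaches to the most recent positive gene.
parse_report <- function(text) {
  empty <- tibble::tibble(
    gene = character(), result_label = character(),
    classification = character(), variant_cdna = character(),
    variant_protein = character(), cnv_text = character()
  )
  if (is.na(text) || !nzchar(text)) {
    return(list(records = empty, scope = NA_character_))
  }
  scope <- if (grepl("familial|predictive", text, ignore.case = TRUE)) {
    "targeted"
  } else {
    "full_gene"
  }
  sentences <- stringr::str_split(text, "(?<=\\.)\\s+(?=[A-Z])")[[1]]
  rows <- list()
  last_positive <- NULL
  for (s in sentences) {
    genes <- stringr::str_extract_all(
      s, "\\b(MLH1|MSH2|MSH6|PMS2)\\b")[[1]]
    genes <- unique(genes)
    hg <- extract_hgvs(s)
    cnv <- detect_cnv_language(s)
    if (grepl("was not detected|not identified|was absent", s)) {
      for (g in genes) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = g, result_label = "negative",
          classification = "unclassified",
          variant_cdna = NA_character_, variant_protein = NA_character_,
          cnv_text = NA_character_
        )
      }
    } else if ((nrow(hg) > 0L || cnv) && length(genes)) {
      cdna <- hg$token[hg$kind == "cdna"]
      prot <- hg$token[hg$kind == "protein"]
      cnv_text <- if (cnv) {
        stringr::str_extract(
          s,
          stringr::regex(paste0(
            "(deletion|duplication) of exons? \\d+(-\\d+)?",
            "|whole[- ]gene (deletion|duplication)"
          ), ignore_case = TRUE)
        )
      } else {
        NA_character_
      }
      for (g in genes) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = g, result_label = "positive",
          classification = "unclassified",
          variant_cdna = if (length(cdna)) cdna[[1]] else NA_character_,
          variant_protein = if (length(prot)) prot[[1]] else NA_character_,
          cnv_text = cnv_text
        )
        last_positive <- length(rows)
      }
    } else if (grepl("classified as|class [1-5]", s, ignore.case = TRUE) &&
               !is.null(last_positive)) {
      label <- stringr::str_match(s, "classified as ([a-z ]+?)\\.?$")[1, 2]
      if (is.na(label)) {
        label <- tolower(stringr::str_extract(
          s, stringr::regex("class [1-5]", ignore_case = TRUE)))
      }
      rows[[last_positive]]$classification <- normalise_classification(label)
    } else if (grepl("No pathogenic|No clinically significant", s) &&
               length(genes)) {
      for (g in genes) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = g, result_label = "negative",
          classification = "unclassified",
          variant_cdna = NA_character_, variant_protein = NA_character_,
          cnv_text = NA_character_
        )
      }
    }
  }
  records <- if (length(rows)) dplyr::bind_rows(rows) else empty
  list(records = records, scope = scope)
}

cdm_skeleton <- function() {
  tibble::tibble(
    pseudo_id1 = character(), pseudo_id2 = character(),
    lab_code = character(), authorised_date = as.Date(character()),
    report_date = as.Date(character()), scope = character(),
    scope_derived = logical(), gene = character(),
    result_label = character(), classification = character(),
    variant_cdna = character(), variant_protein = character(),
    cnv_text = character(), source_text = character(),
    source_row = integer()
  )
}

quarantine_skeleton <- function() {
  tibble::tibble(source_row = integer(), reason = character())
}

#' Map a laboratory extract into the common data model
#'
#' Reads one extract file under its dialect specification and emits one
#' common-data-model record per gene per test, pseudonymised with raw
#' identifiers stripped. Rows that cannot be interpreted (unparseable
#' dates, unknown gene symbols, unparseable reports, unknown result labels)
#' are quarantined with a reason code, never silently dropped:
#' `input rows = mapped source rows + quarantined rows`.
#'
#' @param path extract file.
#' @param spec a [dialect_spec()].
#' @param key pseudonymisation secret.
#' @param lab_code laboratory code recorded on each output row.
#' @return list with `records` (CDM tibble) and `quarantine`
#'   (`source_row`, `reason`).
#' @export
map_extract <- function(path, spec, key, lab_code) {
  stopifnot(inherits(spec, "lynchledger_dialect"))
  raw <- if (spec$format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else if (spec$format == "jsonl") {
    read_jsonl(path)
  } else {
    abort(sprintf("unsupported extract format '%s'", spec$format),
          class = "lynchledger_config_error")
  }
  if (!nrow(raw)) {
    return(list(records = cdm_skeleton(), quarantine = quarantine_skeleton()))
  }
  raw$source_row <- seq_len(nrow(raw))

  std <- tibble::tibble(source_row = raw$source_row)
  for (field in names(spec$columns)) {
    col <- spec$columns[[field]]
    std[[field]] <- if (col %in% names(raw)) {
      blank_to_na(as.character(raw[[col]]))
    } else {
      NA_character_
    }
  }
  for (sf in spec$scan_fields %||% character(0)) {
    std[[sf]] <- blank_to_na(as.character(raw[[sf]]))
  }

  std$authorised_date_parsed <- parse_date_quiet(std$authorised_date,
                                                 spec$date_format)
  std$report_date_parsed <- parse_date_quiet(std$report_date,
                                             spec$date_format)
  std$dob_parsed <- parse_date_quiet(std$dob, spec$date_format)

  quarantine <- list()
  bad_date <- !is.na(std$authorised_date) & is.na(std$authorised_date_parsed) |
    is.na(std$authorised_date)
  if (any(bad_date)) {
    quarantine$date <- tibble::tibble(
      source_row = std$source_row[bad_date],
      reason = "unparseable_authorised_date"
    )
    std <- std[!bad_date, ]
  }

  if (length(spec$scan_fields %||% character(0))) {
    mapped <- map_freetext_rows(std, spec)
  } else {
    mapped <- map_structured_rows(std, spec)
  }
  quarantine$mapping <- mapped$quarantine
  records <- mapped$records
  if (nrow(records)) {
    records$lab_code <- lab_code
    records <- add_pseudonyms(records, key)
    records <- strip_identifiers(records)
    records <- records[names(cdm_skeleton())]
  } else {
    records <- cdm_skeleton()
  }
  list(
    records = records,
    quarantine = dplyr::bind_rows(quarantine$date %||% quarantine_skeleton(),
                                  mapped$quarantine)
  )
}

map_structured_rows <- function(std, spec) {
  quarantine <- list()
  bad_gene <- is.na(std$gene) | !(std$gene %in% MMR_GENES)
  if (any(bad_gene)) {
    quarantine$gene <- tibble::tibble(
      source_row = std$source_row[bad_gene], reason = "unknown_gene"
    )
    std <- std[!bad_gene, ]
  }
  result_label <- vocab_lookup(std$result, spec$result_labels)
  bad_result <- is.na(result_label)
  if (any(bad_result)) {
    quarantine$result <- tibble::tibble(
      source_row = std$source_row[bad_result], reason = "unknown_result_label"
    )
    std <- std[!bad_result, ]
    result_label <- result_label[!bad_result]
  }
  scope <- vocab_lookup(std$test_type, spec$scope_labels)
  scope_derived <- is.na(scope)
  # scope fallback: a single-gene row carrying one specific variant and a
  # targeted-style vocabulary is a presence test; otherwise full-gene
  scope[is.na(scope)] <- "full_gene"
  records <- tibble::tibble(
    nhs_number = std$nhs_number,
    dob = std$dob_parsed,
    postcode = std$postcode,
    authorised_date = std$authorised_date_parsed,
    report_date = std$report_date_parsed,
    scope = scope,
    scope_derived = scope_derived,
    gene = std$gene,
    result_label = result_label,
    classification = normalise_classification(std$classification),
    variant_cdna = std$variant_cdna,
    variant_protein = std$variant_protein,
    cnv_text = std$cnv_text,
    source_text = NA_character_,
    source_row = std$source_row
  )
  list(records = records,
       quarantine = dplyr::bind_rows(quarantine) %||% quarantine_skeleton())
}

map_freetext_rows <- function(std, spec) {
  quarantine <- list()
  out <- vector("list", nrow(std))
  for (i in seq_len(nrow(std))) {
    parsed <- parse_report(std$report_text[[i]])
    if (!nrow(parsed$records)) {
      quarantine[[length(quarantine) + 1L]] <- tibble::tibble(
        source_row = std$source_row[[i]], reason = "unparseable_report"
      )
      next
    }
    rec <- parsed$records
    rec$nhs_number <- std$nhs_number[[i]]
    rec$dob <- std$dob_parsed[[i]]
    rec$postcode <- std$postcode[[i]]
    rec$authorised_date <- std$authorised_date_parsed[[i]]
    rec$report_date <- std$report_date_parsed[[i]]
    rec$scope <- parsed$scope
    rec$scope_derived <- TRUE
    rec$source_text <- std$report_text[[i]]
    rec$source_row <- std$source_row[[i]]
    out[[i]] <- rec
  }
  records <- dplyr::bind_rows(out)
  if (!nrow(records)) {
    records <- tibble::tibble()
  }
  list(
    records = records,
    quarantine = if (length(quarantine)) {
      dplyr::bind_rows(quarantine)
    } else {
      quarantine_skeleton()
    }
  )
}

#' Write and read common-data-model records
#'
#' CDM tables round-trip exactly: `read_cdm(write_cdm(x))` compares equal
#' field by field. CSV and JSONL carry bit-identical content.
#'
#' @param records CDM tibble.
#' @param path output path; format chosen by extension (`.csv` or
#'   `.jsonl`).
#' @return the path, invisibly.
#' @export
write_cdm <- function(records, path) {
  if (grepl("\\.jsonl$", path)) {
    out <- records
    out$authorised_date <- format(out$authorised_date, "%Y-%m-%d")
    out$report_date <- format(out$report_date, "%Y-%m-%d")
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, path)
  } else {
    readr::write_csv(records, path, na = "")
  }
  invisible(path)
}

#' @rdname write_cdm
#' @export
read_cdm <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    out <- read_jsonl(path)
    if (!nrow(out)) return(cdm_skeleton())
    out$authorised_date <- as.Date(out$authorised_date)
    out$report_date <- as.Date(out$report_date)
    out$scope_derived <- as.logical(out$scope_derived)
    out$source_row <- as.integer(out$source_row)
    tibble::as_tibble(out)[names(cdm_skeleton())]
  } else {
    out <- readr::read_csv(
      path,
      col_types = readr::cols(
        authorised_date = readr::col_date(),
        report_date = readr::col_date(),
        scope_derived = readr::col_logical(),
        source_row = readr::col_integer(),
        .default = readr::col_character()
      ),
      progress = FALSE
    )
    tibble::as_tibble(out)[names(cdm_skeleton())]
  }
}
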