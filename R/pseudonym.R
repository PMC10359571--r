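#' Validate an NHS number
#'
#' Checks the standard 10-digit NHS number format with its mod-11 check
#' digit: digits 1-9 are weighted 10 down to 2, the weighted sum is reduced
#' modulo 11 and the check digit must equal `11 - remainder`, with a result
#' of 11 mapped to 0 and a result of 10 meaning the number is invalid.
#' Internal whitespace is ignored (numbers are often written "943 476 5919").
#'
#' @param s character vector of candidate NHS numbers.
#' @return logical vector; `FALSE` for malformed input, never an error.
#' @examples
#' validate_nhs_number(c("9434765919", "9434765918", "12345"))
#' @export
validate_nhs_number <- function(s) {
  s <- canonical_nhs(s)
  out <- rep(FALSE, length(s))
  ok <- !is.na(s) & grepl("^[0-9]{10}$", s)
  if (!any(ok)) return(out)
  digits <- matrix(
    as.integer(unlist(strsplit(s[ok], "", fixed = TRUE))),
    ncol = 10L, byrow = TRUE
  )
  weighted <- digits[, 1:9, drop = FALSE] %*% 10:2
  check <- 11L - (as.integer(weighted) %% 11L)
  check[check == 11L] <- 0L
  out[ok] <- check != 10L & check == digits[, 10L]
  out
}

canonical_nhs <- function(s) {
  s <- gsub("[[:space:]-]", "", s)
  blank_to_na(s)
}

canonical_postcode <- function(postcode) {
  blank_to_na(toupper(gsub("[[:space:]]", "", postcode)))
}

# Keyed one-way digest (HMAC-SHA-256), hex-encoded. Reproducible for a
# fixed key, irrecoverable without it.
keyed_digest <- function(msg, key) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  out <- rep(NA_character_, length(msg))
  ok <- !is.na(msg)
  if (any(ok)) out[ok] <- as.character(openssl::sha256(msg[ok], key = key))
  out
}

#' Create pseudo-ID1 from an NHS number
#'
#' A reproducible keyed pseudonym: the HMAC-SHA-256 digest of the
#' canonicalised (whitespace-stripped) NHS number under a run-scoped secret
#' key. Numbers failing [validate_nhs_number()] yield `NA` — the record is
#' retained but cannot be linked on ID1.
#'
#' @param nhs_number character vector.
#' @param key single non-empty secret string.
#' @return character vector of 64-character hex tokens, `NA` where no valid
#'   NHS number was supplied.
#' @export
make_pseudo_id1 <- function(nhs_number, key) {
  nhs <- canonical_nhs(nhs_number)
  nhs[!validate_nhs_number(nhs)] <- NA_character_
  keyed_digest(nhs, key)
}

#' Create pseudo-ID2 from date of birth and postcode
#'
#' The HMAC-SHA-256 digest of the canonical form `"YYYY-MM-DD|POSTCODE"`,
#' where the postcode is upper-cased with internal whitespace removed.
#' Either field missing yields `NA` (the record is retained).
#'
#' @param dob `Date` vector or ISO-8601 strings.
#' @param postcode character vector.
#' @inheritParams make_pseudo_id1
#' @return character vector of 64-character hex tokens or `NA`.
#' @export
make_pseudo_id2 <- function(dob, postcode, key) {
  dob <- as.Date(dob)
  pc <- canonical_postcode(postcode)
  msg <- ifelse(is.na(dob) | is.na(pc), NA_character_,
                paste0(format(dob, "%Y-%m-%d"), "|", pc))
  keyed_digest(msg, key)
}

#' Identifier-availability stratum of each record
#'
#' Records fall into exactly one of four mutually exclusive strata according
#' to which linkage pseudonyms could be created.
#'
#' @param pseudo_id1,pseudo_id2 character vectors (`NA` = absent).
#' @return factor with levels `both`, `id1_only`, `id2_only`, `none`.
#' @export
id_stratum <- function(pseudo_id1, pseudo_id2) {
  has1 <- !is.na(pseudo_id1)
  has2 <- !is.na(pseudo_id2)
  factor(
    dplyr::case_when(
      has1 & has2 ~ "both",
      has1 ~ "id1_only",
      has2 ~ "id2_only",
      TRUE ~ "none"
    ),
    levels = c("both", "id1_only", "id2_only", "none")
  )
}

# Regexes for raw-identifier patterns that must never survive stripping.
.nhs_pattern <- "\\b[0-9]{3}[ -]?[0-9]{3}[ -]?[0-9]{4}\\b"
.dob_pattern <- "\\b[0-9]{4}-[0-9]{2}-[0-9]{2}\\b|\\b[0-9]{2}/[0-9]{2}/[0-9]{4}\\b"
.postcode_pattern <- "\\b[A-Z]{1,2}[0-9][A-Z0-9]?[ ]?[0-9][A-Z]{2}\\b"

redact_identifiers <- function(text) {
  for (p in c(.nhs_pattern, .dob_pattern, .postcode_pattern)) {
    text <- gsub(p, "[REDACTED]", text, perl = TRUE)
  }
  text
}

#' Strip raw identifiers from pseudonymised records
#'
#' Removes the raw identifier columns (`nhs_number`, `dob`, `postcode`),
#' redacts identifier-shaped substrings (NHS numbers, dates, postcodes) from
#' any free-text columns, and then asserts that no raw identifier value
#' survives anywhere in the output. A surviving identifier is a privacy
#' contract violation and raises a hard error rather than a warning.
#'
#' @param records tibble carrying `pseudo_id1`/`pseudo_id2` plus raw
#'   identifier columns; pseudonyms must already have been computed.
#' @param text_cols character vector of free-text column names to redact.
#' @return the records tibble without identifier columns.
#' @export
strip_identifiers <- function(records, text_cols = intersect("source_text", names(records))) {
  stopifnot(all(c("pseudo_id1", "pseudo_id2") %in% names(records)))
  id_cols <- intersect(c("nhs_number", "dob", "postcode"), names(records))
  raw_values <- unique(stats::na.omit(unlist(
    lapply(records[id_cols], function(x) as.character(x))
  )))
  out <- records[setdiff(names(records), id_cols)]
  for (col in text_cols) {
    out[[col]] <- redact_identifiers(out[[col]])
  }
  assert_no_identifiers(out, raw_values)
  out
}

# Scan every character column for identifier patterns (embedded NHS numbers
# or postcodes) and for whole surviving raw values; error on any hit.
assert_no_identifiers <- function(records, raw_values = character()) {
  chr_cols <- names(records)[vapply(records, is.character, logical(1))]
  chr_cols <- setdiff(chr_cols, c("pseudo_id1", "pseudo_id2"))
  canon <- canonical_nhs(raw_values)
  forbidden <- unique(c(raw_values, canon[!is.na(canon)]))
  for (col in chr_cols) {
    x <- records[[col]]
    x <- x[!is.na(x)]
    if (!length(x)) next
    hit <- grepl(.nhs_pattern, x, perl = TRUE) |
      grepl(.postcode_pattern, x, perl = TRUE) |
      x %in% forbidden
    if (any(hit)) {
      abort(sprintf(
        "privacy contract violated: raw identifier survived in column '%s'",
        col
      ))
    }
  }
  invisible(records)
}

#' Compute both pseudonyms for a table of raw identifiers
#'
#' Convenience wrapper used at ingest: adds `pseudo_id1` and `pseudo_id2`
#' columns derived from `nhs_number` and from `dob` + `postcode`.
#'
#' @param records tibble with columns `nhs_number`, `dob`, `postcode`.
#' @inheritParams make_pseudo_id1
#' @return `records` with two pseudonym columns prepended.
#' @export
add_pseudonyms <- function(records, key) {
  dplyr::mutate(
    records,
    pseudo_id1 = make_pseudo_id1(.data$nhs_number, key),
    pseudo_id2 = make_pseudo_id2(.data$dob, .data$postcode, key),
    .before = 1L
  )
}
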