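# Harmonisation of heterogeneous laboratory extracts into the common data
# model: one record per gene per test, pseudonymised, with variants
# extracted from free text where necessary and raw identifiers stripped.

#' Supported HGVS grammar subset
#'
#' Coding-DNA (`c.`) descriptions: substitutions, del, dup, ins and delins,
#' with single positions or ranges and intronic offsets (`c.942+3A>T`).
#' Protein (`p.`) descriptions: three-letter missense, nonsense (`Ter`),
#' frameshift (`fs`, `fsTer12`), del/dup and synonymous (`=`), with or
#' without parentheses. No `g.`/`m.`/`n.` prefixes, complex alleles or
#' mosaicism.
#' @name hgvs_grammar
#' @keywords internal
NULL

.cdna_re <- paste0(
  "c\\.\\d+(?:[+-]\\d+)?(?:_\\d+(?:[+-]\\d+)?)?",
  "(?:[ACGT]>[ACGT]|delins[ACGT]+|del[ACGT]*|dup[ACGT]*|ins[ACGT]+)"
)
.protein_re <- paste0(
  "p\\.\\(?(?:Ter|[A-Z][a-z]{2})\\d+",
  "(?:(?:[A-Z][a-z]{2}|Ter)(?:fsTer\\d+|fs)?|fsTer\\d+|fs|del|dup|=)\\)?"
)

#' Extract HGVS-compliant variant descriptions from free text
#'
#' Scans text for maximal substrings matching the supported HGVS grammar
#' subset (see `hgvs_grammar`), in order of appearance. Copy-number changes
#' described in natural language ("deletion of exons 1-6") are deliberately
#' not matched; route those through [detect_cnv_language()].
#'
#' @param text a single string.
#' @return tibble with columns `kind` (`"cdna"` or `"protein"`) and `token`,
#'   zero rows when nothing matches.
#' @examples
#' extract_hgvs("heterozygous variant c.942+3A>T p.(Thr34Ala) detected")
#' @export
extract_hgvs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) {
    return(tibble::tibble(kind = character(), token = character()))
  }
  tokens <- stringr::str_extract_all(
    text, paste0("(?:", .cdna_re, ")|(?:", .protein_re, ")")
  )[[1]]
  tibble::tibble(
    kind = ifelse(startsWith(tokens, "c."), "cdna", "protein"),
    token = tokens
  )
}

#' Syntactic validation of an HGVS token
#'
#' Grammar membership plus internal-consistency checks: positions must be
#' at least 1, intronic offsets non-zero, range ends not before starts, and
#' substitution reference and alternate bases must differ. No transcript or
#' reference-sequence lookup is performed.
#'
#' @param token character vector of candidate HGVS strings.
#' @return tibble with columns `token`, `valid` and `reason` (`NA` when
#'   valid).
#' @examples
#' validate_hgvs(c("c.100A>G", "c.100A>", "c.0A>G"))
#' @export
validate_hgvs <- function(token) {
  one <- function(tok) {
    if (is.na(tok)) return(c(FALSE, "missing token"))
    if (grepl("^c\\.", tok)) {
      if (grepl(">$", tok)) return(c(FALSE, "missing alternate"))
      if (!grepl(paste0("^", .cdna_re, "$"), tok)) {
        return(c(FALSE, "not in supported cDNA grammar"))
      }
      positions <- regmatches(tok, gregexpr("(?<![+-])\\d+", tok,
                                            perl = TRUE))[[1]]
      positions <- as.numeric(positions)
      if (any(positions == 0)) return(c(FALSE, "position must be >= 1"))
      offsets <- regmatches(tok, gregexpr("[+-]\\d+", tok, perl = TRUE))[[1]]
      if (length(offsets) && any(as.numeric(offsets) == 0)) {
        return(c(FALSE, "intron offset must be non-zero"))
      }
      if (grepl("_", tok) && length(positions) >= 2 &&
          positions[2] < positions[1]) {
        return(c(FALSE, "range end before start"))
      }
      sub <- stringr::str_match(tok, "([ACGT])>([ACGT])$")
      if (!is.na(sub[1, 1]) && sub[1, 2] == sub[1, 3]) {
        return(c(FALSE, "reference equals alternate"))
      }
      return(c("TRUE", NA_character_))
    }
    if (grepl("^p\\.", tok)) {
      if (!grepl(paste0("^", .protein_re, "$"), tok)) {
        return(c(FALSE, "not in supported protein grammar"))
      }
      pos <- as.numeric(stringr::str_match(tok, "(\\d+)")[1, 2])
      if (pos == 0) return(c(FALSE, "position must be >= 1"))
      m <- stringr::str_match(
        tok, "^p\\.\\(?([A-Z][a-z]{2})\\d+([A-Z][a-z]{2})\\)?$"
      )
      if (!is.na(m[1, 1]) && m[1, 2] == m[1, 3]) {
        return(c(FALSE, "reference equals alternate"))
      }
      return(c("TRUE", NA_character_))
    }
    c(FALSE, "unsupported prefix")
  }
  res <- t(vapply(token, one, character(2)))
  tibble::tibble(
    token = token,
    valid = as.logical(res[, 1]),
    reason = res[, 2]
  )
}

.cnv_patterns <- c(
  "\\b(deletion|duplication|rearrangement|loss|gain)\\b[^.]{0,40}\\bexons?\\b",
  "\\bexons?\\b[^.]{0,40}\\b(deletion|duplication|deleted|duplicated|rearrangement)\\b",
  "whole[- ]gene (deletion|duplication)",
  "large (genomic )?(deletion|duplication|rearrangement)"
)

#' Detect natural-language copy-number variant descriptions
#'
#' Copy-number variants are mostly reported in highly variable natural
#' language rather than HGVS; this matches a curated lexicon of exon
#' deletion/duplication/rearrangement phrasings.
#'
#' @param text character vector.
#' @return logical vector.
#' @examples
#' detect_cnv_language(c("deletion of exons 1-6", "c.100A>G"))
#' @export
detect_cnv_language <- function(text) {
  out <- rep(FALSE, length(text))
  ok <- !is.na(text)
  for (p in .cnv_patterns) {
    out[ok] <- out[ok] | grepl(p, text[ok], ignore.case = TRUE, perl = TRUE)
  }
  out
}

.class_synonyms <- c(
  "pathogenic" = "P", "class 5" = "P", "pathogenic variant" = "P",
  "likely pathogenic" = "LP", "probably pathogenic" = "LP", "class 4" = "LP",
  "vus" = "VUS", "uncertain" = "VUS", "uncertain significance" = "VUS",
  "of uncertain significance" = "VUS",
  "variant of uncertain significance" = "VUS",
  "unknown significance" = "VUS", "class 3" = "VUS",
  "likely benign" = "LB", "probably benign" = "LB", "class 2" = "LB",
  "benign" = "B", "class 1" = "B"
)

#' Normalise a pathogenicity classification label
#'
#' Case-insensitive synonym map covering the five-tier wording and the
#' numeric IARC classes ("class 5" is pathogenic). Anything unrecognised,
#' empty or missing maps to `"unclassified"`.
#'
#' @param label character vector of raw labels.
#' @return character vector over [CLASSIFICATION_LEVELS].
#' @examples
#' normalise_classification(c("Pathogenic", "class 3", ""))
#' @export
normalise_classification <- function(label) {
  cleaned <- tolower(trimws(label))
  cleaned <- gsub("[[:space:]]+", " ", cleaned)
  out <- unname(.class_synonyms[cleaned])
  out[is.na(out)] <- "unclassified"
  out
}

#' Audit concordance between computational and manual extraction
#'
#' The harmonisation contract: for every gene, the smaller of the
#' computational and manual counts must be at least 95% of the larger, for
#' both total tests and abnormal results.
#'
#' @param computational,manual tibbles with columns `gene`, `tests`,
#'   `abnormal`.
#' @param threshold minimum acceptable min/max ratio.
#' @return list with `pass` (logical) and `per_gene` ratio table.
#' @export
concordance_audit <- function(computational, manual, threshold = 0.95) {
  stopifnot(setequal(computational$gene, manual$gene))
  joined <- dplyr::inner_join(computational, manual, by = "gene",
                              suffix = c("_comp", "_man"))
  ratio <- function(a, b) {
    r <- pmin(a, b) / pmax(a, b)
    zero <- pmax(a, b) == 0
    if (any(zero)) {
      warn("concordance audit: gene with zero counts skipped")
      r[zero] <- NA_real_
    }
    r
  }
  per_gene <- tibble::tibble(
    gene = joined$gene,
    ratio_tests = ratio(joined$tests_comp, joined$tests_man),
    ratio_abnormal = ratio(joined$abnormal_comp, joined$abnormal_man)
  )
  per_gene$pass <- (is.na(per_gene$ratio_tests) |
                      per_gene$ratio_tests >= threshold) &
    (is.na(per_gene$ratio_abnormal) | per_gene$ratio_abnormal >= threshold)
  list(pass = all(per_gene$pass), per_gene = per_gene)
}
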