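# Imputation of total historic national testing activity: down-adjust
# inflated laboratory audit counts using overlap years, back-fill the two
# pre-audit years, combine with observed patient-level counts, and derive
# carrier-yield estimates.

#' Centre-specific audit down-adjustment factor
#'
#' Pooled ratio of observed to audited counts over the years where both
#' sources exist: `sum(observed) / sum(audit)`, clamped to (0, 1]. The
#' pooled ratio (rather than a mean of per-year ratios) keeps small years
#' from dominating.
#'
#' @param observed,audit equal-length numeric vectors of counts for the
#'   overlap years.
#' @return scalar factor in (0, 1], or `NA` when there are no usable
#'   overlap years.
#' @examples
#' compute_adjustment_factor(c(50, 50), c(60, 65))
#' @export
compute_adjustment_factor <- function(observed, audit) {
  stopifnot(length(observed) == length(audit))
  use <- !is.na(observed) & !is.na(audit)
  if (!any(use) || sum(audit[use]) <= 0) {
    warn("no usable overlap years; adjustment factor absent")
    return(NA_real_)
  }
  factor <- sum(observed[use]) / sum(audit[use])
  if (factor > 1) {
    warn(sprintf("observed exceeds audit (factor %.3f); clamped to 1", factor))
    factor <- 1
  }
  factor
}

#' Down-adjust audit counts for pre-observation years
#'
#' Applies each laboratory's adjustment factor to its audit counts for
#' financial years before its earliest observed submission, rounding
#' half-up at the last step.
#'
#' @param audit tibble `lab_code`, `financial_year`, `audit_count`.
#' @param factors named numeric vector of per-lab factors.
#' @param first_observed_fy named integer vector: each lab's earliest
#'   financial year with observed patient-level data.
#' @return tibble `lab_code`, `financial_year`, `adjusted_count`, restricted
#'   to pre-observation years of labs with a factor.
#' @export
adjust_audit <- function(audit, factors, first_observed_fy) {
  out <- audit |>
    dplyr::mutate(
      factor = unname(factors[.data$lab_code]),
      first_fy = unname(first_observed_fy[.data$lab_code])
    ) |>
    dplyr::filter(
      !is.na(.data$factor),
      is.na(.data$first_fy) | .data$financial_year < .data$first_fy
    ) |>
    dplyr::mutate(
      adjusted_count = as.integer(round_half_up(.data$audit_count *
                                                  .data$factor))
    )
  out[c("lab_code", "financial_year", "adjusted_count")]
}

#' Back-fill the pre-audit financial years
#'
#' Activity predating the audit (financial years 1996 and 1997) is
#' interpolated flat: each missing pre-audit year of a laboratory active
#' before 1998 receives that laboratory's earliest available adjusted
#' annual count.
#'
#' @param adjusted output of [adjust_audit()].
#' @param active_from named integer vector: first financial year of each
#'   laboratory's activity.
#' @param pre_years the financial years to fill.
#' @return tibble `lab_code`, `financial_year`, `adjusted_count` for the
#'   filled years (zero rows for labs not active before the audit).
#' @export
interpolate_pre_audit <- function(adjusted, active_from,
                                  pre_years = 1996:1997) {
  earliest <- adjusted |>
    dplyr::group_by(.data$lab_code) |>
    dplyr::slice_min(.data$financial_year, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  rows <- list()
  for (i in seq_len(nrow(earliest))) {
    lab <- earliest$lab_code[[i]]
    from <- unname(active_from[lab])
    if (is.na(from) || from >= min(pre_years) + 2L) next
    fill_years <- pre_years[pre_years >= from]
    if (!length(fill_years)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      lab_code = lab,
      financial_year = fill_years,
      adjusted_count = as.integer(round_half_up(earliest$adjusted_count[[i]]))
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(lab_code = character(), financial_year = integer(),
                          adjusted_count = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Combine observed, adjusted and interpolated counts
#'
#' Per laboratory and financial year the consensus count is the observed
#' count where patient-level data exist, else the down-adjusted (or
#' interpolated) audit count. A lab-year present in both sources is a
#' double-count and raises a hard error. Scope totals split the imputed
#' counts by the observed full-gene share, since the audit does not
#' distinguish full-gene from targeted tests.
#'
#' @param observed tibble `lab_code`, `financial_year`, `n_full_gene`,
#'   `n_targeted`.
#' @param adjusted,interpolated tibbles as from [adjust_audit()] and
#'   [interpolate_pre_audit()].
#' @return object of class `lynchledger_coverage`: list with the per-year
#'   `table`, national totals and `coverage_pct`.
#' @export
combine_totals <- function(observed, adjusted, interpolated = NULL) {
  imputed <- dplyr::bind_rows(adjusted, interpolated)
  obs <- observed |>
    dplyr::mutate(observed_count = .data$n_full_gene + .data$n_targeted)
  if (nrow(imputed)) {
    dup <- dplyr::inner_join(
      obs[c("lab_code", "financial_year")],
      imputed[c("lab_code", "financial_year")],
      by = c("lab_code", "financial_year")
    )
    if (nrow(dup)) {
      abort(sprintf(
        "double-counted lab-year: %s fy%d appears in both observed and imputed",
        dup$lab_code[[1]], dup$financial_year[[1]]
      ))
    }
  }
  table <- dplyr::bind_rows(
    dplyr::mutate(obs[c("lab_code", "financial_year", "observed_count")],
                  source = "observed"),
    dplyr::mutate(
      dplyr::rename(imputed, observed_count = "adjusted_count"),
      source = "imputed"
    )
  ) |>
    dplyr::rename(consensus_count = "observed_count") |>
    dplyr::arrange(.data$lab_code, .data$financial_year)

  observed_total <- sum(obs$observed_count)
  consensus_total <- sum(table$consensus_count)
  share_full <- if (observed_total > 0) {
    sum(obs$n_full_gene) / observed_total
  } else {
    NA_real_
  }
  imputed_total <- consensus_total - observed_total
  full_gene_total <- as.integer(round_half_up(
    sum(obs$n_full_gene) + imputed_total * share_full
  ))
  targeted_total <- as.integer(consensus_total - full_gene_total)
  structure(
    list(
      table = table,
      observed_total = observed_total,
      consensus_total = consensus_total,
      full_gene_total = full_gene_total,
      targeted_total = targeted_total,
      coverage_pct = if (consensus_total > 0) {
        100 * observed_total / consensus_total
      } else {
        NA_real_
      }
    ),
    class = "lynchledger_coverage"
  )
}

#' Estimate detected mutation carriers
#'
#' Carriers found through full-gene (proband) testing and through targeted
#' (cascade) testing: totals multiplied by the respective detection rates
#' and rounded half-up. Defaults are a 15% pathogenic/likely-pathogenic
#' yield on full-gene analyses and a 45% abnormal rate on targeted tests.
#'
#' @param full_gene_total,targeted_total national test totals.
#' @param rate_fullgene,rate_targeted detection rates in `[0, 1]`.
#' @return list with `carriers_fullgene` and `carriers_cascade`.
#' @examples
#' estimate_carriers(14191, 12428)
#' @export
estimate_carriers <- function(full_gene_total, targeted_total,
                              rate_fullgene = 0.15, rate_targeted = 0.45) {
  stopifnot(rate_fullgene >= 0, rate_fullgene <= 1,
            rate_targeted >= 0, rate_targeted <= 1)
  list(
    carriers_fullgene = as.integer(round_half_up(full_gene_total *
                                                   rate_fullgene)),
    carriers_cascade = as.integer(round_half_up(targeted_total *
                                                  rate_targeted))
  )
}

#' Fraction of a population's carriers detected
#'
#' Detected carriers as a percentage of the expected carriers in the
#' population, `carriers / (population / k) * 100`, for a mutational
#' prevalence of 1 in `k`.
#'
#' @param carriers_total number of detected carriers.
#' @param prevalence_k carrier prevalence denominator (1 in `k`).
#' @param population population size.
#' @return percentage.
#' @examples
#' carrier_fraction(2129 + 5593, 279, 56e6)
#' @export
carrier_fraction <- function(carriers_total, prevalence_k, population) {
  stopifnot(prevalence_k > 0, population > 0)
  100 * carriers_total / (population / prevalence_k)
}

#' Observed per-lab-year counts from the episode table
#'
#' Tabulates test episodes by laboratory and financial year, split by
#' scope, as the observed side of the coverage estimate. Episodes spanning
#' several laboratories are attributed to the first (alphabetical) code.
#'
#' @param episodes episode table from [build_episodes()].
#' @return tibble `lab_code`, `financial_year`, `n_full_gene`, `n_targeted`.
#' @export
observed_counts <- function(episodes) {
  if (!nrow(episodes)) {
    return(tibble::tibble(lab_code = character(), financial_year = integer(),
                          n_full_gene = integer(), n_targeted = integer()))
  }
  episodes |>
    dplyr::mutate(
      lab_code = vapply(strsplit(.data$lab_codes, ","), `[[`, character(1), 1L),
      financial_year = financial_year(.data$episode_date)
    ) |>
    dplyr::count(.data$lab_code, .data$financial_year, .data$scope) |>
    tidyr::pivot_wider(names_from = "scope", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename(dplyr::any_of(c(n_full_gene = "full_gene",
                                  n_targeted = "targeted"))) |>
    (\(d) {
      if (!"n_full_gene" %in% names(d)) d$n_full_gene <- 0L
      if (!"n_targeted" %in% names(d)) d$n_targeted <- 0L
      d
    })()
}

#' End-to-end coverage estimation
#'
#' Convenience wrapper chaining factor computation, audit down-adjustment,
#' pre-audit interpolation and combination for a full audit table and
#' episode-derived observed counts.
#'
#' @param observed tibble as from [observed_counts()].
#' @param audit audit tibble `lab_code`, `financial_year`, `audit_count`.
#' @param active_from named integer vector of first activity years.
#' @return a `lynchledger_coverage` object with `factors` attached.
#' @export
estimate_coverage <- function(observed, audit, active_from = NULL) {
  labs <- unique(audit$lab_code)
  obs_tot <- observed |>
    dplyr::mutate(n = .data$n_full_gene + .data$n_targeted)
  factors <- vapply(labs, function(lab) {
    overlap <- dplyr::inner_join(
      obs_tot[obs_tot$lab_code == lab, c("financial_year", "n")],
      audit[audit$lab_code == lab, c("financial_year", "audit_count")],
      by = "financial_year"
    )
    if (!nrow(overlap)) return(NA_real_)
    compute_adjustment_factor(overlap$n, overlap$audit_count)
  }, numeric(1))
  first_fy <- vapply(labs, function(lab) {
    fy <- obs_tot$financial_year[obs_tot$lab_code == lab]
    if (length(fy)) min(fy) else NA_integer_
  }, numeric(1))
  adjusted <- adjust_audit(audit, factors, first_fy)
  interpolated <- if (is.null(active_from)) {
    NULL
  } else {
    interpolate_pre_audit(adjusted, active_from)
  }
  out <- combine_totals(observed, adjusted, interpolated)
  out$factors <- factors
  out
}
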