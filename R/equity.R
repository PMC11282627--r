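#' Q5-Q1 wealth gap in delivery-care coverage, per country
#'
#' Weighted delivery-care coverage among the richest quintile minus the
#' poorest, in percentage points. Women with a missing wealth quintile are
#' excluded here (they still count for coverage estimation elsewhere). A
#' country missing either extreme quintile is flagged (`NA` gap) and later
#' excluded from phase averages.
#'
#' @param records scored multi-country table.
#' @return tibble: `country_id`, `q5`, `q1`, `gap_pp`.
#' @export
quintile_gaps <- function(records) {
  assert_women(records, scored = TRUE)
  recs <- records[!is.na(records$wealth_quintile), , drop = FALSE]
  rows <- lapply(sort(unique(records$country_id)), function(cid) {
    sub <- recs[recs$country_id == cid, , drop = FALSE]
    est_q <- function(q) {
      s <- sub[sub$wealth_quintile == q, , drop = FALSE]
      if (nrow(s) == 0L) return(NA_real_)
      weighted_coverage(s, "delivery_care")$point
    }
    q5 <- est_q(5L); q1 <- est_q(1L)
    tibble::tibble(country_id = cid, q5 = q5, q1 = q1, gap_pp = q5 - q1)
  })
  out <- dplyr::bind_rows(rows)
  if (any(is.na(out$gap_pp))) {
    warning(sum(is.na(out$gap_pp)), " country(-ies) lack an extreme wealth ",
            "quintile; flagged with NA gap", call. = FALSE)
  }
  out
}

#' Mean wealth gap per obstetric-transition phase
#'
#' Unweighted mean of country Q5-Q1 gaps within each MMR phase. Phases with
#' no contributing country are absent from the output rather than reported
#' as zero. By default gaps keep their sign (the richest quintile leads in
#' every displayed phase of the source analysis); `absolute = TRUE` averages
#' absolute gaps instead.
#'
#' @param gaps output of [quintile_gaps()] (NA gaps are excluded).
#' @param mmr tibble with `country_id`, `mmr`; must cover every gap country.
#' @param absolute average `|gap|` instead of signed gaps.
#' @return tibble: `phase`, `mean_gap_pp`, `n_countries`.
#' @export
phase_average_gap <- function(gaps, mmr, absolute = FALSE) {
  absent <- setdiff(gaps$country_id, mmr$country_id)
  if (length(absent) > 0L) {
    stop("countries missing from the MMR table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  g <- gaps[!is.na(gaps$gap_pp), , drop = FALSE]
  phase <- assign_phase(mmr$mmr)[match(g$country_id, mmr$country_id)]
  val <- if (absolute) abs(g$gap_pp) else g$gap_pp
  out <- tibble::tibble(phase = phase, gap = val) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(mean_gap_pp = mean(.data$gap),
                     n_countries = dplyr::n(), .groups = "drop")
  out[order(match(out$phase, phase_levels())), , drop = FALSE]
}

#' Gap between facility-delivery and delivery-care coverage, per country
#'
#' Facility-delivery coverage minus delivery-care (mean rescaled score)
#' coverage, in percentage points. Positive gaps mean women reach a
#' facility but miss other recommended interventions; negative gaps arise
#' where many home births nonetheless have skilled attendance or a timely
#' postnatal check, so facility delivery understates delivery care.
#'
#' @param records scored multi-country table.
#' @return tibble: `country_id`, `facility`, `delivery_care`, `gap_pp`.
#' @export
facility_vs_care_gap <- function(records) {
  assert_women(records, scored = TRUE)
  rows <- lapply(sort(unique(records$country_id)), function(cid) {
    sub <- records[records$country_id == cid, , drop = FALSE]
    fac <- weighted_coverage(sub, "facility")$point
    care <- weighted_coverage(sub, "delivery_care")$point
    tibble::tibble(country_id = cid, facility = fac, delivery_care = care,
                   gap_pp = fac - care)
  })
  dplyr::bind_rows(rows)
}
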