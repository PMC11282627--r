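# Level labels for the five-step effective-coverage cascade.
CASCADE_LABELS <- c("population_in_need", "facility", "facility_sba",
                    "facility_sba_stay24", "facility_sba_stay24_pnc48")

# Logical matrix of the nested cascade conditions, one column per level 2-5.
cascade_conditions <- function(records) {
  facility <- records$place %in% c("lower", "hospital")
  c3 <- facility & records$sba == "yes"
  c4 <- c3 & records$stay24 == "yes"
  c5 <- c4 & records$pnc48 == "yes"
  cbind(facility = facility, facility_sba = c3,
        facility_sba_stay24 = c4, facility_sba_stay24_pnc48 = c5)
}

#' Effective-coverage cascade over a population in need
#'
#' Five nested levels, each expressed as a weighted percentage of the
#' population in need (women with a live birth in the two years before the
#' survey): (1) the population in need, 100% by construction; (2) delivered
#' in a facility; (3) ... with a skilled attendant; (4) ... and stayed in
#' the facility 24+ hours; (5) ... and had a postnatal check within 48
#' hours. A missing component response fails its condition, consistent with
#' the scorer's missing-as-zero rule, so levels are monotone non-increasing.
#'
#' @param records harmonized table.
#' @param weights per-record weights; defaults to sampling weights.
#' @param pooled use [pooled_weights()] (inverse-proportion country
#'   adjustment) instead.
#' @return tibble: `level` (1-5), `label`, `percent`.
#' @export
build_cascade <- function(records, weights = NULL, pooled = FALSE) {
  assert_women(records)
  w <- weights %||% if (pooled) pooled_weights(records) else records$weight
  cond <- cascade_conditions(records)
  sw <- sum(w)
  if (sw <= 0) stop("weight sum must be positive", call. = FALSE)
  pct <- c(100, colSums(w * cond) / sw * 100)
  tibble::tibble(level = 1:5, label = CASCADE_LABELS, percent = unname(pct))
}

#' Cascades stratified by facility type, MMR phase, or country
#'
#' * `facility_type`: restricted to facility births; one cascade per
#'   facility category (hospital, lower), rebased so the stratum's births
#'   are the population in need (level 2 is then 100% by construction).
#' * `mmr_phase`: countries are grouped by obstetric-transition phase from
#'   the supplied MMR table; each phase pools its countries with
#'   inverse-proportion weights.
#' * `country`: one cascade per country on its own sampling weights.
#'
#' @param records harmonized multi-country table.
#' @param by `"facility_type"`, `"mmr_phase"` or `"country"`.
#' @param mmr tibble with `country_id` and `mmr` (required for
#'   `mmr_phase`); every country in `records` must appear.
#' @return tibble: `stratum`, `level`, `label`, `percent`.
#' @export
stratify_cascade <- function(records, by = c("facility_type", "mmr_phase",
                                             "country"), mmr = NULL) {
  by <- match.arg(by)
  assert_women(records)
  pieces <- switch(by,
    facility_type = {
      fac <- records[records$place %in% c("lower", "hospital"), , drop = FALSE]
      split(fac, fac$place)
    },
    mmr_phase = {
      if (is.null(mmr)) stop("mmr table required for mmr_phase", call. = FALSE)
      absent <- setdiff(unique(records$country_id), mmr$country_id)
      if (length(absent) > 0L) {
        stop("countries missing from the MMR table: ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
      phase <- assign_phase(mmr$mmr)[match(records$country_id, mmr$country_id)]
      split(records, phase, drop = TRUE)
    },
    country = split(records, records$country_id))
  rows <- lapply(names(pieces), function(s) {
    casc <- build_cascade(pieces[[s]], pooled = (by == "mmr_phase"))
    dplyr::bind_cols(tibble::tibble(stratum = s), casc)
  })
  dplyr::bind_rows(rows)
}
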