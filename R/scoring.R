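# Table of component points for the additive delivery-care score:
# place of delivery hospital = 2, lower-level facility = 1, home = 0;
# skilled attendant, 24+ hour facility stay and postnatal check within
# 48 hours each score 1; a missing response scores 0 (a woman is assumed
# not to have received an intervention she did not report).
PLACE_POINTS <- c(home = 0L, lower = 1L, hospital = 2L, missing = 0L)
YES_POINTS <- c(yes = 1L, no = 0L, missing = 0L)

#' Component points for harmonized woman records
#'
#' Vectorized assignment of the four component point values. Any value
#' outside the harmonized category sets is an internal error: records must
#' pass through harmonization (or the generator) first.
#'
#' @param place,sba,stay24,pnc48 harmonized category vectors.
#' @return tibble with `place_points` (0/1/2), `sba_points`, `stay_points`,
#'   `pnc_points` (each 0/1).
#' @export
score_components <- function(place, sba, stay24, pnc48) {
  if (!all(place %in% names(PLACE_POINTS)) ||
      !all(sba %in% names(YES_POINTS)) ||
      !all(stay24 %in% names(YES_POINTS)) ||
      !all(pnc48 %in% names(YES_POINTS))) {
    stop("unrecognized category in component responses; harmonize first",
         call. = FALSE)
  }
  tibble::tibble(place_points = unname(PLACE_POINTS[place]),
                 sba_points = unname(YES_POINTS[sba]),
                 stay_points = unname(YES_POINTS[stay24]),
                 pnc_points = unname(YES_POINTS[pnc48]))
}

#' Total and rescaled delivery-care score
#'
#' Sums the four component point values into the additive 0-5 score and
#' rescales it to 0-100 (`total / 5 * 100`).
#'
#' @param components table from [score_components()].
#' @return tibble with `score_total` (integer 0-5) and `score_rescaled`
#'   (0-100).
#' @export
total_score <- function(components) {
  total <- components$place_points + components$sba_points +
    components$stay_points + components$pnc_points
  tibble::tibble(score_total = as.integer(total),
                 score_rescaled = total / 5 * 100)
}

#' Score a harmonized woman-level table
#'
#' Appends component points, the 0-5 total, the 0-100 rescaled score, and
#' `imputed` — how many of the four components were missing and therefore
#' imputed as zero. The imputation count supports the audit of how much of
#' the score rests on the missing-as-zero assumption.
#'
#' @param records harmonized woman-level table.
#' @return `records` with score columns appended.
#' @export
score_women <- function(records) {
  assert_women(records)
  comp <- score_components(records$place, records$sba, records$stay24,
                           records$pnc48)
  tot <- total_score(comp)
  imputed <- (records$place == "missing") + (records$sba == "missing") +
    (records$stay24 == "missing") + (records$pnc48 == "missing")
  dplyr::bind_cols(records, comp, tot,
                   tibble::tibble(imputed = as.integer(imputed)))
}
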