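# Harmonized category sets shared across modules.
PLACE_LEVELS <- c("home", "lower", "hospital", "missing")
YESNO_LEVELS <- c("yes", "no", "missing")

# Columns every harmonized woman-level table must carry.
WOMAN_COLUMNS <- c("country_id", "stratum", "psu", "weight", "wealth_quintile",
                   "place", "sba", "stay24", "pnc48")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a harmonized woman-level table
#'
#' Checks the column contract and category sets that all downstream modules
#' rely on. Called internally; exported because analysis scripts use it as a
#' cheap guard after reading externally produced tables.
#'
#' @param records data frame of harmonized woman records.
#' @param scored require score columns (`score_total`, `score_rescaled`) too?
#' @return `records`, invisibly.
#' @export
assert_women <- function(records, scored = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame of woman records", call. = FALSE)
  }
  missing_cols <- setdiff(WOMAN_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$weight)) || any(records$weight <= 0)) {
    stop("all sampling weights must be positive and finite", call. = FALSE)
  }
  if (!all(records$place %in% PLACE_LEVELS)) {
    stop("place contains values outside {", paste(PLACE_LEVELS, collapse = ", "),
         "}", call. = FALSE)
  }
  for (col in c("sba", "stay24", "pnc48")) {
    if (!all(records[[col]] %in% YESNO_LEVELS)) {
      stop(col, " contains values outside {",
           paste(YESNO_LEVELS, collapse = ", "), "}", call. = FALSE)
    }
  }
  if (scored && !all(c("score_total", "score_rescaled") %in% names(records))) {
    stop("records must be scored first (see score_women())", call. = FALSE)
  }
  invisible(records)
}

# Weighted mean that refuses empty input and zero weight mass.
weighted_mean_checked <- function(y, w) {
  if (length(y) == 0L) stop("cannot average an empty set of records", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("weight sum must be positive", call. = FALSE)
  sum(w * y) / sw
}
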