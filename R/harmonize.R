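# Raw-file column contract for woman-level microdata.
RAW_COLUMNS <- c("survey_id", "country_id", "stratum", "psu", "weight",
                 "wealth_quintile", "months_since_birth", "place_code",
                 "attendant_code", "stay_value", "stay_unit", "pnc_value",
                 "pnc_unit")

#' Read a survey code-mapping configuration
#'
#' The mapping file is YAML with one section per survey under `surveys:`.
#' Each section provides `place` (raw code to one of home / lower / hospital /
#' private_hospital / private_clinic), `attendant` (raw code to skilled /
#' unskilled, following each survey's country definition of a skilled birth
#' attendant), `stay_units` and `pnc_units` (raw unit codes to hours / days,
#' plus `none` for "no postnatal check"). Private hospitals and clinics are
#' collapsed to hospital during recoding. Codes absent from a map recode to
#' missing, with a warning.
#'
#' @param path YAML mapping file.
#' @return list of class `mapping_config`.
#' @export
read_mapping_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$surveys) || length(raw$surveys) == 0L) {
    stop("mapping config must declare at least one survey under 'surveys:'",
         call. = FALSE)
  }
  place_targets <- c("home", "lower", "hospital", "private_hospital", "private_clinic")
  for (sid in names(raw$surveys)) {
    sv <- raw$surveys[[sid]]
    for (part in c("place", "attendant", "stay_units", "pnc_units")) {
      if (is.null(sv[[part]])) {
        stop("survey '", sid, "' mapping is missing section '", part, "'",
             call. = FALSE)
      }
    }
    bad <- setdiff(unlist(sv$place), place_targets)
    if (length(bad) > 0L) {
      stop("survey '", sid, "' maps place codes to unknown categories: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(unlist(sv$attendant), c("skilled", "unskilled"))
    if (length(bad) > 0L) {
      stop("survey '", sid, "' maps attendant codes to unknown categories: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(unlist(sv$stay_units), c("hours", "days"))
    if (length(bad) > 0L) {
      stop("survey '", sid, "' maps stay units to unknown units: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(unlist(sv$pnc_units), c("hours", "days", "none"))
    if (length(bad) > 0L) {
      stop("survey '", sid, "' maps pnc units to unknown units: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  structure(raw, class = "mapping_config")
}

#' Read raw woman-level microdata
#'
#' Reads a delimited file of one row per woman, validates the header against
#' the declared raw-column contract, and drops malformed rows (non-positive
#' or missing weight, empty stratum or PSU) with a warning. The number of
#' rows read and dropped is attached as attributes `n_read` / `n_malformed`.
#'
#' @param path CSV file.
#' @param mapping a `mapping_config` (validated here so schema problems
#'   surface before recoding).
#' @return tibble of raw woman records.
#' @export
read_records <- function(path, mapping) {
  if (!inherits(mapping, "mapping_config")) {
    stop("mapping must be a mapping_config (see read_mapping_config())",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("survey_id", "country_id", "stratum", "psu",
                          "place_code", "attendant_code", "stay_unit",
                          "pnc_unit"), names(raw))) {
    raw[[col]] <- as.character(raw[[col]])
  }
  missing_cols <- setdiff(RAW_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("input file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("input file contains no records: ", path, call. = FALSE)
  n_read <- nrow(raw)
  ok <- is.finite(raw$weight) & raw$weight > 0 &
    !is.na(raw$stratum) & nzchar(raw$stratum) &
    !is.na(raw$psu) & nzchar(raw$psu)
  if (any(!ok)) {
    warning(sum(!ok), " malformed row(s) dropped (non-positive weight or ",
            "empty stratum/PSU)", call. = FALSE)
  }
  out <- tibble::as_tibble(raw[ok, , drop = FALSE])
  attr(out, "n_read") <- n_read
  attr(out, "n_malformed") <- sum(!ok)
  out
}

# Look up codes in a named map; unmapped codes become NA.
map_codes <- function(codes, map) {
  unname(unlist(map)[as.character(codes)])
}

#' Recode raw survey responses into harmonized component indicators
#'
#' Applies the per-survey code maps: place of delivery to home / lower /
#' hospital (private hospitals and clinics count as hospital), attendant to
#' skilled / unskilled, facility-stay duration to hours (days are multiplied
#' by 24) and thresholded at 24 hours inclusive, and postnatal-check timing
#' thresholded at 48 hours inclusive ("within two days of delivery"); a
#' `none` timing unit means no check was received. Codes with no map entry
#' recode to missing and are counted in a warning, so no record is ever
#' silently dropped. A home birth reporting a facility-stay duration is
#' logically inconsistent and is recoded to `stay24 = "no"` with a warning.
#'
#' @param raw table from [read_records()].
#' @param mapping a `mapping_config` covering every `survey_id` present.
#' @return tibble of harmonized woman records (same row count as `raw`),
#'   retaining `months_since_birth` for eligibility filtering.
#' @export
recode_records <- function(raw, mapping) {
  if (!inherits(mapping, "mapping_config")) {
    stop("mapping must be a mapping_config", call. = FALSE)
  }
  unknown_surveys <- setdiff(unique(raw$survey_id), names(mapping$surveys))
  if (length(unknown_surveys) > 0L) {
    stop("mapping config has no section for survey(s): ",
         paste(unknown_surveys, collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  place <- character(n); sba <- character(n)
  stay24 <- character(n); pnc48 <- character(n)
  n_unmapped <- 0L

  for (sid in unique(raw$survey_id)) {
    i <- which(raw$survey_id == sid)
    sv <- mapping$surveys[[sid]]

    pl <- map_codes(raw$place_code[i], sv$place)
    pl[pl %in% c("private_hospital", "private_clinic")] <- "hospital"
    n_unmapped <- n_unmapped + sum(is.na(pl) & !is.na(raw$place_code[i]))
    place[i] <- ifelse(is.na(pl), "missing", pl)

    at <- map_codes(raw$attendant_code[i], sv$attendant)
    n_unmapped <- n_unmapped + sum(is.na(at) & !is.na(raw$attendant_code[i]))
    sba[i] <- ifelse(is.na(at), "missing", ifelse(at == "skilled", "yes", "no"))

    su <- map_codes(raw$stay_unit[i], sv$stay_units)
    stay_hours <- raw$stay_value[i] * ifelse(su == "days", 24, 1)
    stay24[i] <- ifelse(is.na(stay_hours), "missing",
                        ifelse(stay_hours >= 24, "yes", "no"))

    pu <- map_codes(raw$pnc_unit[i], sv$pnc_units)
    pnc_hours <- raw$pnc_value[i] * ifelse(pu == "days", 24, 1)
    pnc48[i] <- ifelse(!is.na(pu) & pu == "none", "no",
                       ifelse(is.na(pnc_hours), "missing",
                              ifelse(pnc_hours <= 48, "yes", "no")))
  }

  inconsistent <- place == "home" & stay24 == "yes"
  if (any(inconsistent)) {
    warning(sum(inconsistent), " home birth(s) reported a 24+ hour facility ",
            "stay; recoded stay24 = 'no'", call. = FALSE)
  }
  stay24[place == "home" & stay24 != "missing"] <- "no"

  if (n_unmapped > 0L) {
    warning(n_unmapped, " response(s) carried codes absent from the mapping ",
            "config; recoded as missing", call. = FALSE)
  }

  wq <- suppressWarnings(as.integer(raw$wealth_quintile))
  wq[!wq %in% 1:5] <- NA_integer_

  tibble::tibble(
    country_id = raw$country_id,
    stratum = raw$stratum,
    psu = raw$psu,
    weight = raw$weight,
    wealth_quintile = wq,
    months_since_birth = raw$months_since_birth,
    place = place, sba = sba, stay24 = stay24, pnc48 = pnc48)
}

#' Keep women whose most recent birth is within the two-year window
#'
#' Retains records with `months_since_birth < 24` (strictly within the two
#' years before the survey). Records with a negative months value are
#' dropped with a warning. Kept and dropped counts are attached as
#' attributes `n_kept` / `n_dropped`.
#'
#' @param records harmonized table carrying `months_since_birth`.
#' @return the eligible subset.
#' @export
filter_eligible <- function(records) {
  if (!"months_since_birth" %in% names(records)) {
    stop("records must carry months_since_birth", call. = FALSE)
  }
  m <- records$months_since_birth
  if (any(!is.na(m) & m < 0)) {
    warning(sum(!is.na(m) & m < 0),
            " record(s) with negative months_since_birth dropped", call. = FALSE)
  }
  keep <- !is.na(m) & m >= 0 & m < 24
  out <- records[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Drop design strata containing a single primary sampling unit
#'
#' A stratum with one PSU contributes no design-based variance information,
#' so all its records are removed (the treatment the source surveys apply to
#' lone clusters left after stratification). Dropped strata are reported and
#' attached as attribute `dropped_strata`.
#'
#' @param records harmonized table with `country_id`, `stratum`, `psu`.
#' @return records from multi-PSU strata only.
#' @export
drop_single_psu_strata <- function(records) {
  key <- paste(records$country_id, records$stratum, sep = "\r")
  n_psu <- tapply(records$psu, key, function(p) length(unique(p)))
  single <- names(n_psu)[n_psu == 1L]
  keep <- !(key %in% single)
  if (length(single) > 0L) {
    pretty <- sub("\r", ":", single, fixed = TRUE)
    warning("dropped ", length(single), " single-PSU stratum(-a): ",
            paste(pretty, collapse = ", "), call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped_strata") <- sub("\r", ":", single, fixed = TRUE)
  out
}
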