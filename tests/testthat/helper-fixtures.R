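# Small constructors and independent oracles shared across test files.

# Build a harmonized woman-level table from parallel category vectors.
# PSUs alternate 1/2 within a single stratum unless given, so any table is
# valid for design-based code paths.
make_women <- function(place, sba = "yes", stay24 = "yes", pnc48 = "yes",
                       weight = 1, country_id = "A", stratum = "S1",
                       psu = NULL, wealth_quintile = 3L) {
  n <- max(lengths(list(place, sba, stay24, pnc48, weight, country_id,
                        stratum, psu, wealth_quintile)))
  tibble::tibble(
    country_id = rep_len(country_id, n),
    stratum = rep_len(stratum, n),
    psu = if (is.null(psu)) as.character(rep_len(1:2, n)) else rep_len(psu, n),
    weight = rep_len(weight, n),
    wealth_quintile = rep_len(wealth_quintile, n),
    place = rep_len(place, n),
    sba = rep_len(sba, n),
    stay24 = rep_len(stay24, n),
    pnc48 = rep_len(pnc48, n))
}

# Independent brute-force scorer: literal if/else transcription of the
# component point table, one record at a time. Kept free of any package
# vectorization so it can serve as the oracle.
brute_force_score <- function(place, sba, stay24, pnc48) {
  pts <- 0L
  if (place == "hospital") {
    pts <- pts + 2L
  } else if (place == "lower") {
    pts <- pts + 1L
  }                                   # home or missing: 0
  if (identical(sba, "yes")) pts <- pts + 1L
  if (identical(stay24, "yes")) pts <- pts + 1L
  if (identical(pnc48, "yes")) pts <- pts + 1L
  pts
}

# Every scorer-input combination: five place inputs (the private-clinic
# alias collapses to hospital before scoring) x three values for each of
# the other components = 135 cases.
all_score_inputs <- function() {
  grid <- expand.grid(
    place_in = c("home", "lower", "hospital", "private_clinic", "missing"),
    sba = c("yes", "no", "missing"),
    stay24 = c("yes", "no", "missing"),
    pnc48 = c("yes", "no", "missing"),
    stringsAsFactors = FALSE)
  grid$place <- ifelse(grid$place_in == "private_clinic", "hospital",
                       grid$place_in)
  grid
}

# Write a tiny raw microdata CSV + matching mapping YAML for harmonize tests.
# Files live under the session temp dir for the duration of the test run.
write_raw_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("rawfix")
    dir.create(dir)
  }
  raw <- data.frame(
    survey_id = "SVY1",
    country_id = "AA",
    stratum = c("S1", "S1", "S1", "S1", "S2", "S1"),
    psu = c("1", "2", "1", "2", "1", "1"),
    weight = c(1, 1.5, 2, 1, 1, 1),
    wealth_quintile = c(1, 5, 3, 2, 4, 5),
    months_since_birth = c(3, 10, 23, 24, 5, 12),
    place_code = c("21", "22", "26", "11", "99", "11"),
    attendant_code = c("1", "1", "2", "2", "1", "1"),
    stay_value = c(36, 1, 12, NA, 2, 30),
    stay_unit = c("hrs", "day", "hrs", NA, "day", "hrs"),
    pnc_value = c(2, 49, NA, 1, 6, NA),
    pnc_unit = c("day", "hrs", "none", "day", "hrs", NA),
    stringsAsFactors = FALSE)
  mapping <- list(surveys = list(SVY1 = list(
    place = list(`11` = "home", `21` = "lower", `22` = "hospital",
                 `26` = "private_clinic"),
    attendant = list(`1` = "skilled", `2` = "unskilled"),
    stay_units = list(hrs = "hours", day = "days"),
    pnc_units = list(hrs = "hours", day = "days", none = "none"))))
  raw_path <- file.path(dir, "raw.csv")
  map_path <- file.path(dir, "mapping.yaml")
  utils::write.csv(raw, raw_path, row.names = FALSE)
  yaml::write_yaml(mapping, map_path)
  list(raw = raw_path, mapping = map_path, dir = dir)
}
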