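#' Configuration for the synthetic survey generator
#'
#' Builds and validates the parameter set for [generate_population()]. The
#' generator emulates a multi-country programme of nationally representative
#' household surveys with a stratified two-stage cluster design: women nested
#' in primary sampling units (PSUs) nested in strata, positive sampling
#' weights, a uniform wealth-quintile marginal, and four delivery-care
#' component responses drawn from a hierarchical model conditioned on
#' facility delivery.
#'
#' The hierarchical model: facility delivery is Bernoulli with
#' `plogis(qlogis(p_facility) + wealth_gradient * (quintile - 3))`; hospital
#' vs lower-level facility is drawn only among facility births; skilled
#' attendance and a postnatal check within 48 h have facility- and
#' home-specific probabilities; a 24+ hour facility stay is structurally
#' impossible for home births. Each component is then independently set to
#' `"missing"` with probability `missingness_rate` (missing completely at
#' random).
#'
#' Defaults describe a 71-country study population whose pooled component
#' coverages sit near 76% facility delivery (split evenly hospital vs
#' lower-level), 78% skilled attendance, 68% 24+ hour stay and 91% postnatal
#' check, with country facility-delivery coverage spread over roughly
#' 0.25-0.99 via Beta(3.8, 1.2) quantiles, and a country maternal mortality
#' ratio falling by 8 deaths per 100,000 live births per percentage point of
#' delivery-care coverage around an intercept of 900.
#'
#' @param n_countries number of countries.
#' @param women_per_country women per country (scalar or length `n_countries`).
#' @param n_strata_per_country design strata per country.
#' @param n_psu_per_stratum PSUs per stratum; must be >= 2 so that
#'   single-PSU dropping is exercised only when deliberately violated.
#' @param p_facility per-country probability of facility delivery at the
#'   middle wealth quintile (scalar or length `n_countries`). Default: the
#'   `ppoints(n_countries)` quantiles of Beta(3.8, 1.2).
#' @param p_hospital_given_facility probability a facility birth is in a
#'   hospital rather than a lower-level facility.
#' @param p_sba_given_facility,p_sba_given_home probability of a skilled
#'   attendant for facility and home births.
#' @param p_stay24_given_facility probability a facility birth stays 24+ h.
#' @param p_pnc48_given_facility,p_pnc48_given_home probability of a
#'   postnatal check within 48 h for facility and home births.
#' @param wealth_gradient log-odds shift in facility delivery per wealth
#'   quintile step (quintile centred at 3).
#' @param missingness_rate per-component MCAR missingness probability, < 1.
#' @param mmr_intercept,mmr_slope,mmr_noise_sd linear model for the country
#'   maternal mortality ratio (deaths per 100,000 live births) as a function
#'   of true delivery-care coverage on the 0-100 scale, plus Gaussian noise.
#' @param seed integer seed; identical seed + config gives byte-identical
#'   output.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_countries = 71L,
                             women_per_country = 1000L,
                             n_strata_per_country = 10L,
                             n_psu_per_stratum = 2L,
                             p_facility = NULL,
                             p_hospital_given_facility = 0.5,
                             p_sba_given_facility = 0.97,
                             p_sba_given_home = 0.18,
                             p_stay24_given_facility = 0.89,
                             p_pnc48_given_facility = 0.97,
                             p_pnc48_given_home = 0.72,
                             wealth_gradient = 0.5,
                             missingness_rate = 0.02,
                             mmr_intercept = 900,
                             mmr_slope = -8,
                             mmr_noise_sd = 190,
                             seed = 1L) {
  if (is.null(p_facility)) {
    p_facility <- qbeta(ppoints(n_countries), 3.8, 1.2)
  }
  cfg <- list(n_countries = as.integer(n_countries),
              women_per_country = women_per_country,
              n_strata_per_country = as.integer(n_strata_per_country),
              n_psu_per_stratum = as.integer(n_psu_per_stratum),
              p_facility = p_facility,
              p_hospital_given_facility = p_hospital_given_facility,
              p_sba_given_facility = p_sba_given_facility,
              p_sba_given_home = p_sba_given_home,
              p_stay24_given_facility = p_stay24_given_facility,
              p_pnc48_given_facility = p_pnc48_given_facility,
              p_pnc48_given_home = p_pnc48_given_home,
              wealth_gradient = wealth_gradient,
              missingness_rate = missingness_rate,
              mmr_intercept = mmr_intercept,
              mmr_slope = mmr_slope,
              mmr_noise_sd = mmr_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  check_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (any(!is.finite(v)) || any(v < min) || any(v != as.integer(v))) {
      stop("generator config field '", field, "' must be an integer >= ", min,
           call. = FALSE)
    }
  }
  check_count("n_countries")
  check_count("n_strata_per_country")
  check_count("n_psu_per_stratum", min = 2L)
  if (!length(cfg$women_per_country) %in% c(1L, cfg$n_countries)) {
    stop("generator config field 'women_per_country' must be scalar or one per country",
         call. = FALSE)
  }
  check_count("women_per_country")
  cfg$women_per_country <- as.integer(rep_len(cfg$women_per_country, cfg$n_countries))

  prob_fields <- c("p_facility", "p_hospital_given_facility",
                   "p_sba_given_facility", "p_sba_given_home",
                   "p_stay24_given_facility", "p_pnc48_given_facility",
                   "p_pnc48_given_home", "missingness_rate")
  for (field in prob_fields) {
    v <- cfg[[field]]
    if (!length(v) %in% c(1L, cfg$n_countries)) {
      stop("generator config field '", field,
           "' must be scalar or one value per country", call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("generator config field '", field, "' must lie in [0, 1]",
           call. = FALSE)
    }
    cfg[[field]] <- rep_len(v, cfg$n_countries)
  }
  if (any(cfg$missingness_rate >= 1)) {
    stop("generator config field 'missingness_rate' must be < 1", call. = FALSE)
  }
  if (!is.finite(cfg$mmr_intercept) || cfg$mmr_intercept < 0) {
    stop("generator config field 'mmr_intercept' must be >= 0", call. = FALSE)
  }
  if (!is.finite(cfg$mmr_noise_sd) || cfg$mmr_noise_sd < 0) {
    stop("generator config field 'mmr_noise_sd' must be >= 0", call. = FALSE)
  }
  if (!is.finite(cfg$mmr_slope) || !is.finite(cfg$wealth_gradient)) {
    stop("generator config fields 'mmr_slope' and 'wealth_gradient' must be finite",
         call. = FALSE)
  }
  cfg
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [generator_config()]; unknown keys are an
#' error so that typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `generator_config`.
#' @export
generator_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(generator_config)))
  if (length(unknown) > 0L) {
    stop("unknown generator config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(generator_config, raw)
}

# Expected delivery-care coverage (0-100, post missing-as-zero scoring) for
# women at facility-delivery probability pf in country c of cfg.
coverage_given_pf <- function(cfg, c, pf) {
  ph <- cfg$p_hospital_given_facility[c]
  keep <- 1 - cfg$missingness_rate[c]
  p_hosp <- pf * ph
  p_lower <- pf * (1 - ph)
  p_sba <- pf * cfg$p_sba_given_facility[c] + (1 - pf) * cfg$p_sba_given_home[c]
  p_stay <- pf * cfg$p_stay24_given_facility[c]
  p_pnc <- pf * cfg$p_pnc48_given_facility[c] + (1 - pf) * cfg$p_pnc48_given_home[c]
  keep * (2 * p_hosp + p_lower + p_sba + p_stay + p_pnc) / 5 * 100
}

facility_prob_by_quintile <- function(cfg, c) {
  plogis(qlogis(cfg$p_facility[c]) + cfg$wealth_gradient * ((1:5) - 3))
}

#' Closed-form truth table for a generator configuration
#'
#' Computes, per country, the expected values the downstream pipeline
#' estimates converge to: observed component coverages (after missing
#' responses are imputed as zero by the scorer, hence scaled by
#' `1 - missingness_rate`), the true mean rescaled delivery-care score, and
#' the true Q5-Q1 wealth gap implied by the logistic wealth gradient. All
#' quantities are exact expectations under the hierarchical model, with the
#' wealth quintile uniform on 1-5.
#'
#' @param config a `generator_config`.
#' @return tibble, one row per country.
#' @export
true_values <- function(config) {
  cfg <- validate_generator_config(config)
  rows <- lapply(seq_len(cfg$n_countries), function(c) {
    pfq <- facility_prob_by_quintile(cfg, c)
    pf <- mean(pfq)            # uniform quintile marginal
    ph <- cfg$p_hospital_given_facility[c]
    keep <- 1 - cfg$missingness_rate[c]
    cov_q <- vapply(pfq, function(p) coverage_given_pf(cfg, c, p), numeric(1))
    tibble::tibble(
      country_id = sprintf("C%02d", c),
      p_facility = keep * pf,
      p_hospital = keep * pf * ph,
      p_lower = keep * pf * (1 - ph),
      p_sba = keep * (pf * cfg$p_sba_given_facility[c] +
                        (1 - pf) * cfg$p_sba_given_home[c]),
      p_stay24 = keep * pf * cfg$p_stay24_given_facility[c],
      p_pnc48 = keep * (pf * cfg$p_pnc48_given_facility[c] +
                          (1 - pf) * cfg$p_pnc48_given_home[c]),
      true_score = mean(cov_q),
      true_gap = cov_q[5] - cov_q[1])
  })
  dplyr::bind_rows(rows)
}

#' Generate synthetic multi-country survey microdata
#'
#' Draws one row per woman from the hierarchical model described in
#' [generator_config()]. Women are spread evenly over strata and PSUs;
#' sampling weights are a PSU-level log-normal factor normalized within
#' country to sum to the country sample size (the convention that makes the
#' inverse-proportion pooling identity exact). Output is deterministic given
#' the config seed.
#'
#' @param config a `generator_config`.
#' @return list with `women` (harmonized woman-level tibble: design fields,
#'   wealth quintile, four component responses) and `truth` (the
#'   [true_values()] table).
#' @export
generate_population <- function(config) {
  cfg <- validate_generator_config(config)
  withr::local_seed(cfg$seed)
  truth <- true_values(cfg)

  out <- vector("list", cfg$n_countries)
  for (c in seq_len(cfg$n_countries)) {
    n <- cfg$women_per_country[c]
    n_psu_total <- cfg$n_strata_per_country * cfg$n_psu_per_stratum
    psu_global <- sort(rep_len(seq_len(n_psu_total), n))
    stratum <- (psu_global - 1L) %/% cfg$n_psu_per_stratum + 1L
    psu <- (psu_global - 1L) %% cfg$n_psu_per_stratum + 1L

    psu_factor <- exp(rnorm(n_psu_total, 0, 0.3))
    weight <- psu_factor[psu_global]
    weight <- weight * n / sum(weight)

    q <- sample.int(5L, n, replace = TRUE)
    pfq <- plogis(qlogis(cfg$p_facility[c]) + cfg$wealth_gradient * (q - 3))
    facility <- rbinom(n, 1L, pfq) == 1L

    place <- rep("home", n)
    nf <- sum(facility)
    if (nf > 0L) {
      hosp <- rbinom(nf, 1L, cfg$p_hospital_given_facility[c]) == 1L
      place[facility] <- ifelse(hosp, "hospital", "lower")
    }
    p_sba <- ifelse(facility, cfg$p_sba_given_facility[c], cfg$p_sba_given_home[c])
    sba <- ifelse(rbinom(n, 1L, p_sba) == 1L, "yes", "no")
    stay24 <- rep("no", n)   # structural zero for home births
    if (nf > 0L) {
      stay24[facility] <- ifelse(
        rbinom(nf, 1L, cfg$p_stay24_given_facility[c]) == 1L, "yes", "no")
    }
    p_pnc <- ifelse(facility, cfg$p_pnc48_given_facility[c], cfg$p_pnc48_given_home[c])
    pnc48 <- ifelse(rbinom(n, 1L, p_pnc) == 1L, "yes", "no")

    m <- cfg$missingness_rate[c]
    if (m > 0) {
      place[rbinom(n, 1L, m) == 1L] <- "missing"
      sba[rbinom(n, 1L, m) == 1L] <- "missing"
      stay24[rbinom(n, 1L, m) == 1L] <- "missing"
      pnc48[rbinom(n, 1L, m) == 1L] <- "missing"
    }

    out[[c]] <- tibble::tibble(
      country_id = sprintf("C%02d", c),
      stratum = sprintf("S%02d", stratum),
      psu = sprintf("P%02d", psu),
      weight = weight,
      wealth_quintile = as.integer(q),
      place = place, sba = sba, stay24 = stay24, pnc48 = pnc48)
  }
  women <- dplyr::bind_rows(out)
  list(women = women, truth = truth)
}

#' Generate country maternal mortality ratios linked to true coverage
#'
#' `MMR_c = max(0, mmr_intercept + mmr_slope * true_score_c + e_c)` with
#' `e_c ~ Normal(0, mmr_noise_sd)`, coverage on the 0-100 scale. The noise
#' stream is seeded from `config$seed + 1` so it is deterministic given the
#' config but independent of the population draws.
#'
#' @param truth the truth table from [generate_population()] / [true_values()].
#' @param config the same `generator_config`.
#' @return tibble with `country_id`, `mmr` (deaths per 100,000 live births)
#'   and `phase` (obstetric-transition phase, see [assign_phase()]).
#' @export
generate_mmr <- function(truth, config) {
  cfg <- validate_generator_config(config)
  if (nrow(truth) != cfg$n_countries) {
    stop("truth table must have one row per configured country", call. = FALSE)
  }
  withr::local_seed(cfg$seed + 1L)
  eps <- rnorm(nrow(truth), 0, cfg$mmr_noise_sd)
  mmr <- pmax(0, cfg$mmr_intercept + cfg$mmr_slope * truth$true_score + eps)
  tibble::tibble(country_id = truth$country_id,
                 mmr = mmr,
                 phase = assign_phase(mmr))
}
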