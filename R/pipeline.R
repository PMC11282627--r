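#' Pipeline run configuration
#'
#' Exactly one input source: either a `generator` (a [generator_config()],
#' for fully synthetic runs) or `inputs` — a list with `microdata` (raw CSV
#' path), `mapping` (YAML mapping config path) and `mmr` (CSV with
#' `country_id`, `mmr`).
#'
#' @param generator optional `generator_config`.
#' @param inputs optional list of input paths (see above).
#' @param bootstrap_B bootstrap replicates for country confidence intervals.
#' @param level confidence level.
#' @param seed integer seed for the estimation stage's resampling.
#' @param out_dir output directory (created if absent).
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = NULL, inputs = NULL, bootstrap_B = 1000L,
                       level = 0.95, seed = 1L, out_dir = "results") {
  if (is.null(generator) == is.null(inputs)) {
    stop("supply exactly one of 'generator' or 'inputs'", call. = FALSE)
  }
  if (!is.null(inputs)) {
    missing_keys <- setdiff(c("microdata", "mapping", "mmr"), names(inputs))
    if (length(missing_keys) > 0L) {
      stop("inputs is missing: ", paste(missing_keys, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(generator = generator, inputs = inputs,
                 bootstrap_B = as.integer(bootstrap_B), level = level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_table <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full delivery-care analysis pipeline
#'
#' Orchestrates harmonize, score, estimate, cascade, equity and
#' association over either synthetic or real inputs, writing every output
#' table as CSV plus a JSON run manifest (seed, package version, input
#' checksums, record counts at each stage). Outputs are byte-identical for
#' identical configuration and seed.
#'
#' Stage order: generate or read/recode/filter; drop single-PSU strata;
#' score; per-country and pooled estimates with score distribution and the
#' cross-country median/IQR; pooled, facility-type and MMR-phase cascades;
#' wealth-quintile and facility-vs-care gaps with phase averages; the
#' MMR-coverage linear fit.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of all result tables plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config",
                                            call. = FALSE)
  counts <- list()
  checksums <- list()
  truth <- NULL

  if (!is.null(config$generator)) {
    gen <- generate_population(config$generator)
    women <- gen$women
    truth <- gen$truth
    mmr <- generate_mmr(truth, config$generator)
    counts$generated <- nrow(women)
  } else {
    mapping <- read_mapping_config(config$inputs$mapping)
    raw <- read_records(config$inputs$microdata, mapping)
    counts$read <- attr(raw, "n_read")
    counts$malformed <- attr(raw, "n_malformed")
    women <- recode_records(raw, mapping)
    counts$recoded <- nrow(women)
    women <- filter_eligible(women)
    counts$eligible <- nrow(women)
    mmr_raw <- read.csv(config$inputs$mmr, stringsAsFactors = FALSE)
    if (!all(c("country_id", "mmr") %in% names(mmr_raw))) {
      stop("MMR table must carry country_id and mmr", call. = FALSE)
    }
    mmr <- tibble::tibble(country_id = as.character(mmr_raw$country_id),
                          mmr = mmr_raw$mmr,
                          phase = assign_phase(mmr_raw$mmr))
    for (key in c("microdata", "mapping", "mmr")) {
      checksums[[key]] <- unname(tools::md5sum(config$inputs[[key]]))
    }
  }

  women <- drop_single_psu_strata(women)
  counts$after_psu_drop <- nrow(women)
  if (nrow(women) == 0L) stop("no records left after dropping single-PSU strata",
                              call. = FALSE)
  scored <- score_women(women)

  component_inds <- c("facility", "hospital", "lower", "sba", "stay24", "pnc48")
  country_est <- estimate_by_country(scored,
                                     indicators = c(component_inds, "delivery_care"),
                                     B = config$bootstrap_B, seed = config$seed,
                                     level = config$level)
  pooled <- dplyr::bind_rows(lapply(c(component_inds, "delivery_care"),
                                    function(i) pooled_estimate(scored, i)))
  care_points <- country_est$point[country_est$indicator == "delivery_care"]
  summary_tab <- country_summary(care_points)
  dist_pooled <- score_distribution(scored, pooled = TRUE)

  cascade_pooled <- build_cascade(scored, pooled = TRUE)
  cascade_facility <- stratify_cascade(scored, by = "facility_type")
  cascade_phase <- stratify_cascade(scored, by = "mmr_phase", mmr = mmr)

  gaps <- quintile_gaps(scored)
  phase_gaps <- phase_average_gap(gaps, mmr)
  fac_care <- facility_vs_care_gap(scored)

  care_by_country <- country_est[country_est$indicator == "delivery_care",
                                 c("country_id", "point")]
  assoc_input <- dplyr::inner_join(
    tibble::tibble(country_id = care_by_country$country_id,
                   coverage = care_by_country$point),
    mmr, by = "country_id")
  fit <- fit_linear(assoc_input)
  fit_tab <- tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                            r_squared = fit$r_squared,
                            n_countries = fit$n_countries,
                            slope_se = fit$slope_se,
                            slope_ci_low = fit$slope_ci[1],
                            slope_ci_high = fit$slope_ci[2],
                            slope_se_robust = fit$slope_se_robust)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(scored, config$out_dir, "scored_women")
  write_table(country_est, config$out_dir, "country_estimates")
  write_table(pooled, config$out_dir, "pooled_estimates")
  write_table(summary_tab, config$out_dir, "country_summary")
  write_table(dist_pooled, config$out_dir, "score_distribution_pooled")
  write_table(cascade_pooled, config$out_dir, "cascade_pooled")
  write_table(cascade_facility, config$out_dir, "cascade_by_facility_type")
  write_table(cascade_phase, config$out_dir, "cascade_by_mmr_phase")
  write_table(gaps, config$out_dir, "wealth_gaps")
  write_table(phase_gaps, config$out_dir, "wealth_gaps_by_phase")
  write_table(fac_care, config$out_dir, "facility_vs_care_gaps")
  write_table(fit_tab, config$out_dir, "mmr_association")
  write_table(mmr, config$out_dir, "mmr_phases")
  if (!is.null(truth)) write_table(truth, config$out_dir, "generator_truth")

  manifest <- list(seed = config$seed,
                   bootstrap_B = config$bootstrap_B,
                   level = config$level,
                   package_version = as.character(utils::packageVersion("delivcare")),
                   generator_seed = if (!is.null(config$generator))
                     config$generator$seed else NULL,
                   input_checksums = checksums,
                   record_counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(scored = scored, country_estimates = country_est,
                 pooled = pooled, summary = summary_tab,
                 score_distribution = dist_pooled,
                 cascade_pooled = cascade_pooled,
                 cascade_by_facility_type = cascade_facility,
                 cascade_by_mmr_phase = cascade_phase,
                 wealth_gaps = gaps, wealth_gaps_by_phase = phase_gaps,
                 facility_vs_care_gaps = fac_care, fit = fit_tab,
                 mmr = mmr, truth = truth, manifest = manifest))
}
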