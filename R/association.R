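#' Obstetric-transition phase labels, highest mortality first
#' @return character vector of the five phase labels.
#' @export
phase_levels <- function() c(">=700", "300-699", "100-299", "20-99", "<20")

#' Assign obstetric-transition phases from maternal mortality ratios
#'
#' Half-open bands in maternal deaths per 100,000 live births:
#' \[700, Inf), \[300, 700), \[100, 300), \[20, 100), \[0, 20). Integer
#' boundary values therefore belong to the higher-mortality band's stated
#' range (700 is ">=700", 100 is "100-299"), and every non-negative MMR maps
#' to exactly one phase.
#'
#' @param mmr numeric vector, >= 0.
#' @return factor with levels [phase_levels()] (highest mortality first).
#' @export
assign_phase <- function(mmr) {
  if (any(!is.finite(mmr)) || any(mmr < 0)) {
    stop("mmr must be non-negative and finite", call. = FALSE)
  }
  idx <- findInterval(mmr, c(0, 20, 100, 300, 700))  # 1..5, low to high band
  factor(rev(phase_levels())[idx], levels = phase_levels())
}

#' Cross-country linear association between MMR and delivery-care coverage
#'
#' Ordinary least squares of the maternal mortality ratio on delivery-care
#' coverage (0-100 scale), unweighted across countries: the slope is in
#' deaths per 100,000 live births per percentage point of coverage, so a
#' slope of -8 reads as 80 fewer deaths per 100,000 for every 10-point
#' coverage improvement. Heteroskedasticity-robust (HC1) standard errors
#' are reported alongside the classical ones as auxiliary output.
#'
#' @param countries data frame with columns `coverage` (0-100) and `mmr`.
#' @return list: `slope`, `intercept`, `r_squared`, `n_countries`,
#'   `slope_se`, `slope_ci` (classical 95%), `slope_se_robust`, and the
#'   underlying `lm` fit.
#' @export
fit_linear <- function(countries) {
  if (!all(c("coverage", "mmr") %in% names(countries))) {
    stop("countries must carry columns 'coverage' and 'mmr'", call. = FALSE)
  }
  if (nrow(countries) < 3L) {
    stop("at least 3 countries are required", call. = FALSE)
  }
  if (var(countries$coverage) == 0) {
    stop("coverage is constant across countries; the slope is not identified",
         call. = FALSE)
  }
  fit <- lm(mmr ~ coverage, data = countries)
  s <- summary(fit)
  ci <- confint(fit, "coverage", level = 0.95)
  list(slope = unname(coef(fit)["coverage"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       r_squared = s$r.squared,
       n_countries = nrow(countries),
       slope_se = s$coefficients["coverage", "Std. Error"],
       slope_ci = c(ci[1, 1], ci[1, 2]),
       slope_se_robust = sqrt(sandwich::vcovHC(fit, type = "HC1")["coverage", "coverage"]),
       fit = fit)
}
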