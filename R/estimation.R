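# Indicators the estimation surface understands. Binary indicators yield a
# 0/1 value per woman (a missing response fails the condition, consistent
# with missing-as-zero scoring); delivery_care yields the rescaled score on
# the 0-1 scale so that coverage is the weighted mean rescaled score.
INDICATORS <- c("facility", "hospital", "lower", "sba", "stay24", "pnc48",
                "delivery_care", paste0("score_", 0:5))

#' Per-woman indicator values
#'
#' @param records harmonized (and, for score-based indicators, scored) table.
#' @param indicator one of `facility`, `hospital`, `lower`, `sba`, `stay24`,
#'   `pnc48`, `delivery_care`, or `score_0` ... `score_5`.
#' @return numeric vector in \[0, 1\], one value per woman.
#' @export
indicator_values <- function(records, indicator) {
  if (!indicator %in% INDICATORS) {
    stop("unknown indicator '", indicator, "'; expected one of: ",
         paste(INDICATORS, collapse = ", "), call. = FALSE)
  }
  if (indicator %in% c("delivery_care", paste0("score_", 0:5))) {
    assert_women(records, scored = TRUE)
  }
  switch(indicator,
    facility = as.numeric(records$place %in% c("lower", "hospital")),
    hospital = as.numeric(records$place == "hospital"),
    lower = as.numeric(records$place == "lower"),
    sba = as.numeric(records$sba == "yes"),
    stay24 = as.numeric(records$stay24 == "yes"),
    pnc48 = as.numeric(records$pnc48 == "yes"),
    delivery_care = records$score_rescaled / 100,
    as.numeric(records$score_total == as.integer(sub("score_", "", indicator))))
}

#' Survey-weighted coverage of one indicator
#'
#' Weighted percentage `sum(w * y) / sum(w) * 100`. For `delivery_care` this
#' is the weighted mean rescaled score, the quality-adjusted coverage
#' approximation.
#'
#' @param records harmonized/scored table (already restricted to the
#'   population of interest, e.g. one survey).
#' @param indicator see [indicator_values()].
#' @param weights per-record weights; defaults to the sampling weights.
#' @return one-row tibble: `indicator`, `point` (0-100), `n`, `weight_sum`.
#' @export
weighted_coverage <- function(records, indicator, weights = records$weight) {
  y <- indicator_values(records, indicator)
  tibble::tibble(indicator = indicator,
                 point = weighted_mean_checked(y, weights) * 100,
                 n = nrow(records),
                 weight_sum = sum(weights))
}

# PSU-level totals of w*y and w, per design stratum (country x stratum).
psu_totals <- function(records, y) {
  stratum <- paste(records$country_id, records$stratum, sep = "\r")
  psu <- paste(stratum, records$psu, sep = "\r")
  agg <- rowsum(cbind(wy = records$weight * y, w = records$weight),
                group = psu, reorder = TRUE)
  list(wy = agg[, "wy"], w = agg[, "w"],
       stratum = sub("\r[^\r]*$", "", rownames(agg)))
}

#' Stratified cluster-bootstrap confidence interval
#'
#' Rao-Wu rescaling bootstrap for a stratified multi-stage design: within
#' each design stratum of m PSUs, each replicate resamples m - 1 PSUs with
#' replacement and rescales their weight totals by m / (m - 1); the weighted
#' estimate is recomputed from the resampled PSU totals and the percentile
#' interval taken over replicates. Deterministic given `seed`.
#'
#' @param records harmonized/scored table; every (country, stratum) must
#'   hold at least 2 PSUs (guaranteed after [drop_single_psu_strata()]).
#' @param indicator see [indicator_values()].
#' @param B number of bootstrap replicates (>= 2); default 1000.
#' @param seed integer seed for the resampling stream.
#' @param level confidence level, default 0.95.
#' @return named numeric `c(ci_low, ci_high)` on the 0-100 scale.
#' @export
bootstrap_ci <- function(records, indicator, B = 1000L, seed = 1L,
                         level = 0.95) {
  if (B < 2L) stop("B must be at least 2", call. = FALSE)
  y <- indicator_values(records, indicator)
  if (length(y) == 0L) stop("cannot bootstrap an empty table", call. = FALSE)
  tot <- psu_totals(records, y)
  strata <- split(seq_along(tot$wy), tot$stratum)
  m <- lengths(strata)
  if (any(m < 2L)) {
    stop("stratum(-a) with a single PSU present: ",
         paste(names(strata)[m < 2L], collapse = ", "),
         "; run drop_single_psu_strata() first", call. = FALSE)
  }
  withr::local_seed(seed)
  num <- numeric(B)
  den <- numeric(B)
  for (h in seq_along(strata)) {
    idx <- strata[[h]]
    mh <- m[h]
    draw <- matrix(idx[sample.int(mh, (mh - 1L) * B, replace = TRUE)],
                   nrow = mh - 1L)
    scale <- mh / (mh - 1L)
    num <- num + scale * colSums(matrix(tot$wy[draw], nrow = mh - 1L))
    den <- den + scale * colSums(matrix(tot$w[draw], nrow = mh - 1L))
  }
  est <- num / den * 100
  alpha <- (1 - level) / 2
  ci <- unname(quantile(est, c(alpha, 1 - alpha), type = 7))
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Per-country coverage estimates with design-based intervals
#'
#' @param records harmonized/scored multi-country table.
#' @param indicators character vector of indicators.
#' @param B bootstrap replicates per estimate (0 skips intervals).
#' @param seed base seed; each country x indicator gets an offset stream.
#' @param level confidence level.
#' @return tibble: `country_id`, `indicator`, `point`, `ci_low`, `ci_high`,
#'   `n`, `weight_sum`.
#' @export
estimate_by_country <- function(records, indicators = "delivery_care",
                                B = 1000L, seed = 1L, level = 0.95) {
  assert_women(records, scored = any(indicators %in%
                                       c("delivery_care", paste0("score_", 0:5))))
  countries <- sort(unique(records$country_id))
  rows <- list()
  k <- 0L
  for (cid in countries) {
    sub <- records[records$country_id == cid, , drop = FALSE]
    for (ind in indicators) {
      k <- k + 1L
      est <- weighted_coverage(sub, ind)
      if (B > 0L) {
        ci <- bootstrap_ci(sub, ind, B = B, seed = seed + k, level = level)
      } else {
        ci <- c(ci_low = NA_real_, ci_high = NA_real_)
      }
      rows[[k]] <- tibble::tibble(country_id = cid, indicator = ind,
                                  point = est$point, ci_low = ci[["ci_low"]],
                                  ci_high = ci[["ci_high"]], n = est$n,
                                  weight_sum = est$weight_sum)
    }
  }
  dplyr::bind_rows(rows)
}

#' Pooling weights: inverse proportion of women contributed per country
#'
#' Within-country sampling weights are first normalized to sum to the
#' country sample size n_c, then multiplied by the inverse of the country's
#' share of the pooled sample (N / n_c). Under this convention every country
#' contributes equally to pooled estimates regardless of its sample size,
#' and the pooled estimate equals the unweighted mean of country estimates.
#'
#' @param records multi-country table.
#' @return numeric vector of adjusted weights, one per record.
#' @export
pooled_weights <- function(records) {
  n_total <- nrow(records)
  w <- records$weight
  for (cid in unique(records$country_id)) {
    i <- records$country_id == cid
    n_c <- sum(i)
    w[i] <- w[i] * n_c / sum(w[i])      # normalize to country sample size
    w[i] <- w[i] * n_total / n_c        # inverse-proportion adjustment
  }
  w
}

#' Pooled multi-country coverage estimate
#'
#' Weighted coverage under [pooled_weights()].
#'
#' @param records multi-country harmonized/scored table.
#' @param indicator see [indicator_values()].
#' @return one-row tibble: `indicator`, `point`, `n`, `n_countries`.
#' @export
pooled_estimate <- function(records, indicator) {
  est <- weighted_coverage(records, indicator, weights = pooled_weights(records))
  tibble::tibble(indicator = indicator, point = est$point, n = est$n,
                 n_countries = length(unique(records$country_id)))
}

#' Cross-country median and interquartile range
#'
#' Countries are unweighted; quartiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param points numeric vector of country point estimates.
#' @return one-row tibble: `median`, `q1`, `q3`, `n_countries`.
#' @export
country_summary <- function(points) {
  if (length(points) == 0L) stop("no country estimates supplied", call. = FALSE)
  q <- quantile(points, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3],
                 n_countries = length(points))
}

#' Weighted distribution of the 0-5 delivery-care score
#'
#' @param records scored table.
#' @param pooled use [pooled_weights()] instead of raw sampling weights.
#' @return tibble with `score` (0-5) and `proportion` (sums to 1).
#' @export
score_distribution <- function(records, pooled = FALSE) {
  assert_women(records, scored = TRUE)
  w <- if (pooled) pooled_weights(records) else records$weight
  props <- vapply(0:5, function(s) sum(w[records$score_total == s]), numeric(1))
  tibble::tibble(score = 0:5, proportion = props / sum(w))
}
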