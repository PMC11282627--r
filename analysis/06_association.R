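#!/usr/bin/env Rscript
# Stage 6: MMR-coverage association.
#
# Ordinary least squares of the country maternal mortality ratio on
# delivery-care coverage; the slope reads as deaths per 100,000 live births
# per percentage point of coverage.

suppressPackageStartupMessages(library(delivcare))

dir.create("results", showWarnings = FALSE)

est <- read.csv("results/country_estimates.csv", stringsAsFactors = FALSE)
mmr <- read.csv("scratch/data/mmr.csv", stringsAsFactors = FALSE)

care <- est[est$indicator == "delivery_care", c("country_id", "point")]
d <- merge(data.frame(country_id = care$country_id, coverage = care$point),
           mmr, by = "country_id")
fit <- fit_linear(d)

out <- data.frame(slope = fit$slope, intercept = fit$intercept,
                  r_squared = fit$r_squared, n_countries = fit$n_countries,
                  slope_se = fit$slope_se, slope_ci_low = fit$slope_ci[1],
                  slope_ci_high = fit$slope_ci[2],
                  slope_se_robust = fit$slope_se_robust)
write.csv(out, "results/mmr_association.csv", row.names = FALSE)

cat(sprintf("slope: %.2f deaths per 100,000 per coverage point (95%% CI %.2f to %.2f)\n",
            fit$slope, fit$slope_ci[1], fit$slope_ci[2]))
cat(sprintf("i.e. MMR falls by about %.0f deaths per 100,000 for every 10-point coverage gain; r^2 = %.2f over %d countries\n",
            -10 * fit$slope, fit$r_squared, fit$n_countries))
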