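#!/usr/bin/env Rscript
# Stage 3: survey-weighted estimation.
#
# Per-country weighted coverage for the four components and the composite
# delivery-care indicator (cluster-bootstrap 95% CIs for the composite),
# inverse-proportion pooled estimates, and the cross-country median / IQR.

suppressPackageStartupMessages(library(delivcare))

dir.create("results", showWarnings = FALSE)

scored <- read.csv("scratch/data/scored_women.csv", stringsAsFactors = FALSE)

components <- c("facility", "hospital", "lower", "sba", "stay24", "pnc48")
points <- estimate_by_country(scored, indicators = components, B = 0)
care <- estimate_by_country(scored, indicators = "delivery_care",
                            B = 1000, seed = 20260928L)
country_est <- rbind(points, care)
write.csv(country_est, "results/country_estimates.csv", row.names = FALSE)

pooled <- do.call(rbind, lapply(c(components, "delivery_care"),
                                function(i) pooled_estimate(scored, i)))
write.csv(pooled, "results/pooled_estimates.csv", row.names = FALSE)
cat("pooled coverage (%, inverse-proportion country weighting):\n")
print(as.data.frame(pooled[, c("indicator", "point")]), row.names = FALSE,
      digits = 3)

summ <- country_summary(care$point)
write.csv(summ, "results/country_summary.csv", row.names = FALSE)
cat(sprintf("country delivery-care coverage: median %.1f%% [IQR %.1f-%.1f%%] over %d countries\n",
            summ$median, summ$q1, summ$q3, summ$n_countries))
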