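#!/usr/bin/env Rscript
# Stage 2: score every birth.
#
# Applies the additive 0-5 delivery-care score (hospital 2 / lower-level 1 /
# home 0, plus one point each for skilled attendance, a 24+ hour facility
# stay and a postnatal check within 48 hours; missing responses imputed as
# zero), rescales to 0-100, and reports the imputation audit and the pooled
# score distribution.

suppressPackageStartupMessages(library(delivcare))

dir.create("results", showWarnings = FALSE)

women <- read.csv("scratch/data/women.csv", stringsAsFactors = FALSE)
women <- drop_single_psu_strata(women)
scored <- score_women(women)
write.csv(scored, "scratch/data/scored_women.csv", row.names = FALSE)

cat(sprintf("%d of %d women (%.1f%%) had at least one component imputed as zero\n",
            sum(scored$imputed > 0), nrow(scored),
            100 * mean(scored$imputed > 0)))

dist <- score_distribution(scored, pooled = TRUE)
write.csv(dist, "results/score_distribution_pooled.csv", row.names = FALSE)
cat("pooled score distribution (proportion of births at each score 0-5):\n")
print(as.data.frame(dist), row.names = FALSE, digits = 3)
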