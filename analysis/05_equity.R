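#!/usr/bin/env Rscript
# Stage 5: equity gaps.
#
# Q5-Q1 wealth gaps in delivery-care coverage per country, averaged within
# obstetric-transition phases, and the facility-delivery vs delivery-care
# gap per country (negative where skilled home care is common).

suppressPackageStartupMessages(library(delivcare))

dir.create("results", showWarnings = FALSE)

scored <- read.csv("scratch/data/scored_women.csv", stringsAsFactors = FALSE)
mmr <- read.csv("scratch/data/mmr.csv", stringsAsFactors = FALSE)

gaps <- quintile_gaps(scored)
write.csv(gaps, "results/wealth_gaps.csv", row.names = FALSE)

phase_gaps <- phase_average_gap(gaps, mmr)
write.csv(phase_gaps, "results/wealth_gaps_by_phase.csv", row.names = FALSE)
cat("mean Q5-Q1 delivery-care gap (pp) by MMR phase:\n")
print(as.data.frame(phase_gaps), row.names = FALSE, digits = 3)

fc <- facility_vs_care_gap(scored)
write.csv(fc, "results/facility_vs_care_gaps.csv", row.names = FALSE)
cat(sprintf("facility-vs-care gap: mean %.1f pp; %d of %d countries positive\n",
            mean(fc$gap_pp), sum(fc$gap_pp > 0), nrow(fc)))
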