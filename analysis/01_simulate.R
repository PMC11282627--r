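#!/usr/bin/env Rscript
# Stage 1: simulate the study population.
#
# Draws the default 71-country synthetic survey programme (stratified
# two-stage cluster design, wealth-graded facility delivery, MCAR item
# missingness) together with its closed-form truth table and linked country
# maternal mortality ratios, and writes the microdata for later stages.

suppressPackageStartupMessages(library(delivcare))

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = 20260928L)
gen <- generate_population(cfg)
mmr <- generate_mmr(gen$truth, cfg)

write.csv(gen$women, "scratch/data/women.csv", row.names = FALSE)
write.csv(gen$truth, "scratch/data/truth.csv", row.names = FALSE)
write.csv(mmr, "scratch/data/mmr.csv", row.names = FALSE)

cat(sprintf("simulated %d women in %d countries (%d strata x %d PSUs each)\n",
            nrow(gen$women), cfg$n_countries, cfg$n_strata_per_country,
            cfg$n_psu_per_stratum))
cat(sprintf("true delivery-care coverage spans %.1f%% to %.1f%%\n",
            min(gen$truth$true_score), max(gen$truth$true_score)))
cat(sprintf("MMR spans %.0f to %.0f deaths per 100,000 live births\n",
            min(mmr$mmr), max(mmr$mmr)))
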