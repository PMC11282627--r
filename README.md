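# delivcare

Measuring **effective coverage of delivery care** from household-survey
microdata.

Facility delivery alone is a contact indicator: it says a woman reached a
health facility, not that she received the care recommended around
childbirth. `delivcare` implements a composite delivery-care measure over
four interventions that DHS/MICS-style surveys collect for every recent
birth, and the full analysis pipeline around it, for maternal-health
researchers and survey analysts working with woman-level records from
stratified two-stage cluster samples.

## The measure

Each woman with a live birth in the two years before the survey receives an
additive score

```
D = place + sba + stay24 + pnc48,   D in {0, ..., 5}
```

where `place` is 2 for a hospital delivery (private hospitals and clinics
included), 1 for a lower-level facility, 0 for home; `sba` is 1 for a
skilled birth attendant (per each survey's country definition); `stay24` is
1 for a post-delivery facility stay of at least 24 hours; and `pnc48` is 1
for a first postnatal check within 48 hours. A missing response is imputed
as zero — a woman is assumed not to have received an intervention she did
not report. Scores are rescaled to 0–100 (`D/5 × 100`), and delivery-care
coverage is the survey-weighted mean rescaled score, an approximation of
quality-adjusted coverage.

On top of the score the package provides:

* **survey-weighted country estimates** with stratified cluster-bootstrap
  (Rao–Wu) 95% confidence intervals;
* **pooled multi-country estimates** with inverse-proportion country
  weights, so every country contributes equally regardless of sample size;
* the five-level **effective-coverage cascade** (population in need →
  facility → + skilled attendant → + 24 h stay → + postnatal check),
  stratified by facility type or by obstetric-transition MMR phase
  (≥700, 300–699, 100–299, 20–99, <20 deaths per 100,000 live births);
* **wealth-equity gaps** (Q5–Q1 coverage difference, averaged within MMR
  phase) and the facility-delivery vs delivery-care gap per country;
* the cross-country **OLS association** between the maternal mortality
  ratio and delivery-care coverage;
* a **synthetic microdata generator** (stratified two-stage design, planted
  component coverages, wealth gradients, item missingness, and an MMR
  linked linearly to true coverage) with a closed-form truth table, so the
  whole pipeline is testable without access-restricted survey files;
* **harmonization** of raw survey dialects via a YAML code-mapping config
  (place/attendant code maps, hour/day unit conversions, the 24 h and 48 h
  thresholds, eligibility filtering, single-PSU stratum dropping).

## Worked example

```r
library(delivcare)

cfg <- generator_config(n_countries = 8, women_per_country = 2000, seed = 42)
gen <- generate_population(cfg)
scored <- score_women(gen$women)

pooled_estimate(scored, "delivery_care")
#>   indicator     point     n n_countries
#> 1 delivery_care  68.1 16000           8

build_cascade(scored, pooled = TRUE)
#>   level label                     percent
#> 1     1 population_in_need          100
#> 2     2 facility                     73.7
#> 3     3 facility_sba                 70.1
#> 4     4 facility_sba_stay24          61.5
#> 5     5 facility_sba_stay24_pnc48    58.5

mmr <- generate_mmr(gen$truth, cfg)
phase_average_gap(quintile_gaps(scored), mmr)
#>   phase   mean_gap_pp n_countries
#> 1 300-699        22.1           4
#> 2 100-299        18.8           4
```

Pooled delivery-care coverage is 68.1%: on average women received about
two-thirds of the scored care around their most recent birth. The cascade
shows the drop-off pattern — 73.7% of women delivered in a facility but only
58.5% received all four interventions — and the Q5–Q1 wealth gap is wider in
the higher-mortality phase (22.1 vs 18.8 percentage points).

## Analysis workflow

The numbered drivers under `analysis/` run the full study sequence on the
default 71-country synthetic population and write their tables under
`results/` (bulky intermediates go to `scratch/`):

```sh
Rscript analysis/01_simulate.R     # population + truth + MMR
Rscript analysis/02_score.R        # scores, imputation audit, distribution
Rscript analysis/03_estimate.R     # country / pooled estimates, median-IQR
Rscript analysis/04_cascade.R      # pooled and stratified cascades
Rscript analysis/05_equity.R       # wealth and facility-vs-care gaps
Rscript analysis/06_association.R  # MMR ~ coverage OLS
```

`run_pipeline(run_config(...))` performs the same sequence as one call, for
either a generator configuration or real input files (raw microdata CSV +
YAML mapping config + MMR table; see `inst/extdata/` for a worked example of
the formats), and writes a JSON manifest with seed, versions, checksums and
per-stage record counts.

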