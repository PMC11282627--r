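---
title: "Measuring delivery-care coverage: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring delivery-care coverage: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delivcare)
```

## The measurement problem

Contact indicators such as facility delivery overstate effective coverage:
reaching a facility does not guarantee a skilled attendant, a long enough
postpartum stay, or a timely postnatal check. `delivcare` measures delivery
care as an additive composite over the four interventions that household
surveys of the DHS/MICS family record for every woman aged 15–49 whose most
recent live birth fell in the two years before interview:

| Component | Categories | Points |
|---|---|---|
| Place of delivery | hospital (incl. private hospitals/clinics) / lower-level facility / home | 2 / 1 / 0 |
| Skilled attendant at birth | skilled / unskilled | 1 / 0 |
| Facility stay after delivery | 24+ hours / under 24 hours | 1 / 0 |
| First postnatal check | within 48 hours / later or none | 1 / 0 |

A missing component response scores zero: the woman is assumed not to have
received an intervention she did not report. This keeps every eligible
birth in the denominator rather than listwise-deleting partially observed
records; `score_women()` counts how many records had at least one imputed
component so the reliance on this assumption is auditable. Totals (0–5) are
rescaled to 0–100, and coverage is the survey-weighted mean rescaled score.
Because the score is linear in its components, the population mean rescaled
score is identically `(2·P(hospital) + P(lower) + P(sba) + P(stay24) +
P(pnc48)) / 5 × 100` for *any* weighting — an exact identity the test suite
exercises to 1e-9, and a useful internal consistency check for any dataset.

## Harmonization conventions

Raw survey dialects are recoded through a YAML mapping config (per-survey
code maps; unmapped codes become missing and are counted, never silently
dropped). Three boundary conventions are deliberate choices where the
international indicator definitions leave room:

* **Stay threshold, inclusive:** exactly 24 hours counts as a 24+ hour
  stay. Durations reported in days are converted at 24 h/day first, so a
  reported "1 day" qualifies.
* **Postnatal-check threshold, inclusive:** a check at exactly 48 hours
  counts as within two days; 49 hours does not. An explicit "none" response
  scores zero rather than missing.
* **Eligibility, strict:** `months_since_birth < 24` — a birth exactly 24
  months before interview is outside the two-year window.

A home birth that nonetheless reports a facility-stay duration is logically
inconsistent; it is recoded `stay24 = "no"` (the structural value for home
births) with a warning. Strata left with a single primary sampling unit
carry no design-based variance information and are dropped whole, with the
dropped strata reported.

## Estimation

Point estimates are ratio estimators `Σwᵢyᵢ / Σwᵢ` on the survey weights.
Confidence intervals use a **stratified cluster bootstrap** with Rao–Wu
rescaling: within each design stratum of *m* PSUs a replicate resamples
*m − 1* PSUs with replacement and rescales their totals by *m/(m − 1)*;
the 2.5th/97.5th percentiles over B replicates (default B = 1000, seeded)
form the interval. The resampling method was an open choice — the
alternative would be Taylor linearization — and the bootstrap was chosen
for transparency: it is a few lines over PSU totals, makes no linearization
approximation, and its calibration is itself testable (the suite checks
empirical 95% coverage over 200 simulated surveys of 1,000 women each,
requiring coverage in [0.90, 0.99]). Point estimates are identical under
either method. Degenerate inputs collapse gracefully: if every observation
agrees, the interval has zero width at the point estimate.

**Pooling.** Multi-country estimates weight each woman by her survey weight
(first normalized within country to sum to the country sample size n_c)
times N/n_c, the inverse of her country's share of the pooled sample. Under
this convention the pooled estimate equals the unweighted mean of country
estimates exactly, and is invariant to replicating any one country's
records k-fold — both properties are tested as identities, not
approximations. The cross-country median and IQR use linear-interpolation
quantiles (`stats::quantile` type 7); the convention matters only at small
country counts and is stated here because no standard fixes it.

## Cascades

The effective-coverage cascade reports, as percentages of the population in
need, the nested conjunctions: facility delivery; + skilled attendant;
+ 24 h stay; + postnatal check. All levels share the population-in-need
denominator (so drop-offs read in percentage points of the whole
population), and a missing component fails its condition, consistent with
missing-as-zero scoring; monotone non-increase is therefore structural.
Two stratifications are built in:

* **Facility type** restricts to facility births and *rebases* each
  stratum's cascade to its own births (level 2 becomes 100% by
  construction). Rebasing was a genuine choice — the alternative keeps the
  whole-population denominator — and is preferred because it makes hospital
  and lower-level drop-off patterns directly comparable; the
  share-weighted rebased bars still recombine exactly to the pooled bars,
  which the suite verifies to 1e-9.
* **MMR phase** groups countries by obstetric-transition band and pools
  within phase with inverse-proportion weights.

Note one arithmetic subtlety: the cascade endpoint (all four conditions) is
*not* in general the share scoring 5, because a lower-level facility birth
with every other component scores 4. Only when all facility births are
hospital births do the two coincide; the tests pin the tie-out in exactly
that configuration.

## Equity and the MMR association

The wealth gap is the Q5 − Q1 difference in delivery-care coverage,
computed per country (women with a missing quintile are excluded from gaps
but kept everywhere else) and averaged *unweighted* across countries within
each MMR phase. Gaps keep their sign by default — in practice the richest
quintile leads, and signed means preserve cancellation where it occurs — with
an `absolute = TRUE` option. Phases with no contributing country are absent
from the output, not reported as zero. The facility-vs-care gap
(facility-delivery coverage minus delivery-care coverage) is bounded by
score arithmetic to [−60, +80] percentage points and is negative where
skilled home care is common.

Phase boundaries are half-open: [700, ∞), [300, 700), [100, 300),
[20, 100), [0, 20) deaths per 100,000 live births, so integer boundary
values (700, 300, 100, 20) belong to the band whose printed range starts
there, and a non-integer such as 699.5 falls in 300–699. Every non-negative
MMR maps to exactly one phase.

The association module fits unweighted OLS of MMR on coverage (slope in
deaths per 100,000 per percentage point, so −8 reads as "80 fewer deaths
per 10-point gain"). Weighting countries (by births, say) was the open
alternative; unweighted is kept because the cross-country relation is
descriptive, each country being one observation of the coverage–mortality
pattern. Heteroskedasticity-robust (HC1) standard errors accompany the
classical ones as auxiliary output. The fit refuses fewer than 3 countries
or a constant-coverage design.

## What the synthetic generator does and does not emulate

`generate_population()` draws a multi-country programme with the design
features the pipeline's correctness depends on: strata and PSUs with
PSU-level log-normal weight variation (weights normalized within country to
the sample size, which makes the pooling identity exact); a uniform wealth
quintile; facility delivery following a logistic wealth gradient
(`wealth_gradient` log-odds per quintile step); hospital vs lower-level
drawn among facility births; skilled attendance and postnatal checks with
facility- and home-specific probabilities; a structural zero for 24 h
facility stays after home births; and independent MCAR missingness per
component. Component correlation is induced hierarchically by conditioning
on facility status rather than via a latent copula — simpler, and
sufficient to reproduce the cascade's drop-off structure; the conditional
probabilities are the natural extension point if richer dependence is ever
needed. The closed-form truth table (`true_values()`) gives each country's
expected component coverages, mean rescaled score and Q5–Q1 gap, enabling
parameter-recovery tests rather than mere smoke tests.

Defaults describe a 71-country study population: country facility-delivery
probabilities spread as Beta(3.8, 1.2) quantiles (pooled mean ≈ 0.76,
range ≈ 0.25–0.99), an even hospital/lower split, conditional probabilities
chosen so pooled skilled attendance ≈ 78%, 24 h stay ≈ 68% and postnatal
check ≈ 91%, a 0.5 log-odds wealth gradient, 2% item missingness, and
`MMR = max(0, 900 − 8·coverage + ε)`, ε ~ N(0, 190) — a noise level that
leaves the linear signal clearly present but far from deterministic
(r² well below 0.5 at 71 countries).

The generator deliberately does **not** emulate: informative (non-MCAR)
missingness, survey non-response weighting or post-stratification,
within-PSU outcome correlation beyond shared weights, country-specific
attendant definitions, or measurement error in reported durations. Passing
tests therefore demonstrate the pipeline's estimators are correct and
calibrated under a clean complex-survey design — not that real DHS/MICS
recodes are free of the harmonization hazards those features create.

## Problem sizes and numerical tolerances

Exact identities (linearity, pooling, cascade recombination) are asserted
to 1e-9. Monte-Carlo comparisons use 3 standard errors at the stated sizes:
component convergence at 20,000 women; cascade structure at 50,000 women
across 5 countries; equity recovery at 10,000 women per country across 10
countries; bootstrap calibration over 200 surveys of 1,000 women (B = 200);
slope recovery over 200 replicates of 71 countries. These sizes keep each
statistical check's false-alarm probability small while the full suite runs
in well under a minute.

## Known limitations

The score weights place of delivery at 2 of 5 points by construction and
offers no re-weighting; alternative index constructions (multiplicative,
IRT-based) are out of scope. Quality of care beyond the four contact/timing
conditions is not measured. MMR values are inputs, not estimates, and the
coverage–MMR fit is descriptive, not causal. Reading native labelled survey
formats is an extension point; the pipeline starts from delimited text plus
a mapping config.
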