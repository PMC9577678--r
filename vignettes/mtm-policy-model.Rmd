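---
title: "Modeling national coverage of medically tailored meals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling national coverage of medically tailored meals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmsim)
```

## The policy question and the model

Medically tailored meals (MTMs) are dietitian-designed, home-delivered
meals for people living with advanced diet-sensitive illness — diabetes,
heart failure, myocardial infarction and other heart disease, stroke,
cancer, emphysema, chronic kidney disease, HIV — who also have limitations
in instrumental activities of daily living (IADLs) that make preparing
healthy food difficult. `mtmsim` implements a population-level cohort
policy simulation of what national insurance coverage of MTMs (Medicare,
Medicaid, dual-eligible and private payers) would do to hospitalizations,
health-care expenditures and net costs, from the insurer perspective.

The accounting is deliberately simple and transparent. For payer stratum
$s$ with eligible weighted population $N_s$, baseline mean annual
expenditures $\bar{x}_s$ and mean annual hospitalizations $\bar{h}_s$,
coverage fraction $c$, effect sizes $\rho_e$ (fractional reduction in
annual expenditures) and $\rho_h$ (fractional reduction in annual
hospitalizations), and program costs of $m$ dollars per person-month over
$T$ treated months plus a one-time screening cost $u$:

$$
\begin{aligned}
\text{averted hospitalizations}_s &= c\, N_s \bar{h}_s \rho_h \\
\text{averted expenditures}_s &= c\, N_s \bar{x}_s \rho_e \\
\text{program cost}_s &= c\, N_s (T m + u) \\
\text{net savings}_s &= \text{averted expenditures}_s -
  \text{program cost}_s
\end{aligned}
$$

Totals are sums over strata. The net-savings identity holds exactly in
every Monte Carlo replicate, which the test-suite asserts.

All dollars are 2019 USD; rates are per person-year. Benefits accrue only
in the treated year (no carryover) unless the carryover sensitivity
scenario is enabled.

## Inputs and their uncertainty

* **Effect sizes.** A five-study literature yields pooled reductions of
  19.7% (95% CI 6.9–32.4%) in annual expenditures and 47.0% (31.7–62.3%)
  in annual hospitalizations; `pool_random_effects()` implements the
  DerSimonian–Laird inverse-variance random-effects estimator used for such
  pooling, with hospitalization relative risks pooled on the log scale
  (`pool_hospitalization_rr()`) and reported as $1-\mathrm{RR}$. Because the
  study-level rows live in supplementary material, the shipped defaults
  (`default_pooled_effects()`) pin the published pooled values and a
  fill-in study template is provided under `inst/extdata/`.
* **Duration.** The participant-weighted mean duration of MTM receipt is
  8 months per patient per year (`weighted_mean_duration()`); it is the
  default `months_of_meals`.
* **Costs.** Screening is one 15-minute medical-nutrition-therapy
  assessment per person per year, drawn Uniform($27.34, $35.17), the
  published reimbursement range across localities. The monthly
  meal-contract cost is drawn Normal($487.60, $18.70) truncated at zero.
  The $487.60 anchor is *calibrated*: it back-solves the published total
  program cost ($24.8B for 6,309,998 people, 8 months, ~$31 screening),
  and the SD reproduces the published program-cost uncertainty half-width
  (~7.5% of the mean). Note the tension this calibration exposes: $9.30
  per meal times "10 weekly meals" for 8 months is roughly $3,225 per
  person-year, which does not reproduce $24.8B (~$3,900 per person-year
  implied). We adopt the contract-level anchor as authoritative and record
  the discrepancy rather than resolving it; the same tension is why the
  break-even meal price under linear scaling (~$14.6) differs from the
  published $18.89, whose derivation basis is not recoverable.
* **Baseline utilization.** From the synthetic population described next.

## The synthetic population

The model's person table emulates the MTM-eligible population of a
national expenditure survey; no survey microdata are read.
`default_population_spec("primary_2019")` encodes the calibration targets:
weighted N = 6,309,998 split across private (1,485,365), Medicare
(2,571,562), Medicaid (697,292) and dual-eligible (1,555,779) strata;
overall mean (SD) annual expenditures $31,134 ($34,749); overall mean (SD)
annual hospitalizations 0.54 (0.94); and the published diagnosis
prevalences (44.9% diabetes, 26.8% CHF, ...). Two published count tables
give slightly inconsistent stratum populations (totalling 6,310,000 vs
6,309,998); we use the set that sums exactly to the published total.

Per-stratum baseline means are not published, so they are back-derived
from the published per-payer central results (stratum averted amount ÷
pooled effect ÷ stratum N) and rescaled by a common factor so the
weighted aggregate reproduces the published overall means exactly. Stratum
SDs use the overall coefficients of variation. The same construction
calibrates the food-insecure (2017), diabetes-only and CHF-only
populations; for the 2017 population the back-derived aggregate sits ~4%
above the published overall mean (plausibly an unstated inflation
adjustment), and the published overall moments take precedence.

Distributional choices, where the sources state only moments:

* **Expenditures**: lognormal per stratum, moment-matched. The implied
  median, $\bar{x}/\sqrt{1+\mathrm{CV}^2} \approx \$20{,}776$, falls
  within 3.3% of the published median $20,107 — the reason lognormal was
  chosen over gamma (available via
  `expenditure_distribution = "gamma"`).
* **Hospitalizations**: negative binomial moment-matched to mean 0.54, SD
  0.94 (variance greatly exceeds the mean, ruling out Poisson).
* **Joint structure**: a Gaussian copula with rank correlation 0.5 links
  expenditures and hospitalization counts within person — high-utilization
  patients drive both — but no published value exists, so
  `utilization_correlation` is an explicit configuration knob, not an
  inferred fact.
* **Diagnosis flags**: independent Bernoulli draws with a rejection step
  forcing ≥1 diagnosis per record. Naive rejection would inflate every
  marginal prevalence by ~7%, so the draw probabilities are pre-adjusted
  by a fixed-point calibration making the *post-rejection* marginals equal
  the published prevalences. Comorbidity correlation is not modeled.
* **Weights**: uniform within stratum and scaled so they sum exactly to
  the stratum population — weight conservation is exact by construction,
  not asymptotic.

What the generator does *not* emulate: survey design effects and
replicate-weight variance, comorbidity clustering, within-stratum
demographic-utilization dependence, and institutionalized or uninsured
populations. Tests passing against this generator therefore validate the
simulation machinery and its calibration, not survey-methodology fidelity.

## Uncertainty propagation

`run_monte_carlo()` runs 1000 replicates (default). Per replicate:

1. **Effects**: truncated-normal draws (bounds [0, 1], inverse-CDF
   truncation) around each pooled estimate, drawn *independently per payer
   stratum*. This is a deliberate design decision: with a single shared
   national draw per replicate, the total averted-expenditure uncertainty
   interval would be as wide (±65%) as the pooled CI itself and the
   cost-saving probability would be ~86%; the published results show
   per-stratum intervals of roughly that width but a much narrower total
   (±37%) and cost savings in >97% of simulations — the signature of
   stratum-level draws whose variance partially cancels in the sum
   (the total's relative SD shrinks by
   $\sqrt{\sum_s w_s^2} \approx 0.53$). Independent stratum draws
   reproduce all three published signatures; a shared draw provably cannot.
2. **Costs**: one screening and one monthly-contract draw, shared across
   strata (a national contract).
3. **Baseline**: within-stratum bootstrap of the person table (weights
   rescaled), a pragmatic stand-in for design-based survey variance.
   Disable with `baseline_uncertainty = "none"`.

Draws are mutually independent within a replicate; nothing in the sources
specifies a joint structure. Summaries are the replicate mean and the
2.5th/97.5th empirical percentiles (`quantile()` type 7, linear
interpolation — pinned by tests). Coverage enters as a pure multiplier,
so 50% coverage halves every replicate exactly, a property the paired-seed
scenario machinery relies on.

## Ten-year projection

`simulate_multi_year()` models an open cohort over 2019–2028: stratum
populations grow at 1.0/2.1/3.0/5.7% per year (private / Medicare /
Medicaid / dual) and per-capita inflation-adjusted expenditures at
1.5/1.7/3.5/3.9%, the published rates estimated from historical series by
log-linear regression — `fit_loglinear_growth()` implements that
estimator (OLS of log value on year, growth $e^{\beta}-1$) and is
validated by parameter recovery on `simulate_expenditure_history()`
series. Hospitalization rates per person are held constant; expenditure
SDs grow with their means (constant CV — unstated in the sources, chosen
for scale invariance). Each year gets fresh draws; dollar flows are
discounted at 3% (0% and 5% as sensitivities) with the base year
undiscounted, a convention the sources do not state; hospitalization
counts are never discounted. Cumulative totals are replicate-wise sums,
so their uncertainty intervals reflect summed simulations. The optional
carryover scenario (15% published sensitivity) adds that fraction of the
previous year's averted expenditures, discounted, with no meal or
screening cost, to each year after the first.

The projection reproduces the published 10-year hospitalization total to
+0.03% when run from the published year-1 per-payer values and +0.5% from
the fully calibrated engine (whose year-1 level is the closed form
$0.47 \times 0.54 \times N = 1{,}601{,}477$ against a published Monte
Carlo mean of 1,594,000). The published 10-year *dollar* totals sit ~9%
above what the published year-1 values and growth rates imply under any
per-year engine of this form; their projection basis lives only in
supplementary material, so we document the gap instead of fitting to it.

## Numerical and degenerate-input behaviour

* Zero-variance inputs (point CIs, `sd = 0`, `baseline_uncertainty =
  "none"`) collapse every uncertainty interval to the deterministic
  central value; degenerate multi-year runs close the geometric series to
  machine precision.
* `n_records = 0` returns a valid empty table; `coverage = 0` returns
  exact zeros; filters are idempotent and order-preserving.
* All randomness flows through R's global RNG seeded once per run, with a
  documented draw order, so equal seeds give bit-identical result tables;
  the multi-year engine consumes draws in the same order as the 1-year
  engine, making `years = 1` an exact identity.
* Negative-binomial moment matching requires variance > mean and fails
  loudly naming the offending field.

## Problem sizes

The shipped configurations use 50,000 synthetic records and 1000
replicates — a full 1-year Monte Carlo takes a few seconds on one core,
and these sizes leave calibration error (±3 standard errors on every
moment, asserted at exactly these sizes in the test-suite) well inside the
tolerances of the reproduction checks. Module tests use smaller cohorts
(2,000–4,000 records) since the properties they check are
size-independent.

## Known limitations

Beyond the generator caveats above: no ED-visit, nursing-home, mortality
or quality-of-life outcomes (the underlying effect literature is too thin
to pool them); effect sizes assumed stable over 10 years and transferable
across payers; meal-contract costs assumed geography-free beyond the
screening range; and the per-meal/contract-cost inconsistency inherited
from the sources, handled by calibration as described.
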