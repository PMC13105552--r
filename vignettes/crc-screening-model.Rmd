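---
title: "A Markov cohort model of risk-stratified colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of risk-stratified colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
library(dplyr)
```

## The model

crcscreen implements a deterministic state-transition (Markov cohort) model
of the colorectal adenoma-carcinoma sequence, with a two-step risk-stratified
screening overlay: an initial screen combining a risk-score questionnaire
with a faecal immunochemical test (FIT), and diagnostic colonoscopy for
positives. It is built around the design of China's first province-wide
risk-stratified screening programme (Zhejiang, 2020-2024, the PCCSP) and
ships that programme's base-case parameter table, published aggregate cascade
counts and published strategy-comparison table.

The state space has 21 states (`health_states()`): normal epithelium;
non-advanced adenoma (NAA), advanced adenoma (AA) and preclinical colorectal
cancer (CRC) stages I-IV, each in three compartments — undiagnosed,
diagnosed-and-treated (under surveillance/follow-up), and
diagnosed-but-untreated (treatment declined; treatment compliance is well
below 1 for adenomas) — plus CRC death and other-cause death. Disease
progression is irreversible along normal → NAA → AA → CRC I → II → III → IV
within the undiagnosed and diagnosed-untreated compartments. Recurrence after
treatment routes a treated state back to the *undiagnosed* state of the same
class: a recurrent lesion must be re-detected (and re-treatment then incurs
its cost again), which is how post-treatment surveillance naturally re-enters
the screening cascade.

A closed cohort of 100,000 enters at a mean age of 42, 47, 52, 57, 62, 67 or
72 and is cycled annually until mean age 82 (the life expectancy anchoring
the horizon). Within a cycle the order of events is: scheduled screening
round; symptom-driven detection (split by treatment compliance); natural
history progression and recurrence; mortality. Background mortality is
applied first as a competing risk and every other transition is conditioned
on surviving it — the standard cohort-model convention. Stage-specific CRC
mortality, `1 - s5^(1/5)` from five-year survival `s5`
(`annual_mortality_from_survival()`), applies to *diagnosed* CRC only
(treated or untreated alike), because five-year survival is measured from
diagnosis; undiagnosed preclinical CRC faces background mortality only.
Utilities and state-based costs accrue on the half-cycle mean of the start-
and end-of-cycle distributions; accruals in cycle `t` are discounted by
`(1 + r)^(-t)` with `r = 0.03` by default.

## Parameters

`load_parameter_table()` returns the packaged base case: screening
performance (initial-screen sensitivity 0.5476 for adenomas and 0.7778 for
CRC, specificity 0.7170; colonoscopy sensitivity 0.85/0.95/1.00 for NAA/AA/
CRC, specificity 0.95), adherence (participation 0.5829, colonoscopy
compliance 0.3892), age-banded onset and progression probabilities, stage
progression (0.30/0.45/0.50), symptom-detection rates, treatment compliance,
recurrence, utilities, five-year survival by stage, background mortality and
2023-USD unit costs, each with a 95% uncertainty interval and a distribution
family for probabilistic sensitivity analysis. Currency is USD throughout
(the programme's costs were converted upstream at 7.0467 CNY/USD).

For PSA, families are parameterised from base case and interval only:
triangular uses (min = interval low, mode = base, max = interval high);
uniform uses the interval; gamma and beta are fitted by method of moments
with mean = base and sd = interval width / 3.92 (the interval read as a
±1.96-sd range); background mortality is fixed. Parameters are sampled
independently — no correlation structure is stated for them — and age-banded
families are drawn independently per band.

## The entering cohort

A design question with real leverage: what disease does the cohort carry at
entry? An all-`normal` entering cohort makes a single screen at entry
worthless (there is nothing to find) and, at late entry ages, can make
screening look *harmful*, because detecting preclinical CRC starts the
diagnosed-state mortality clock that preclinical states do not carry. Real
screening-naive populations carry decades of accumulated lesions. The
default entering distribution (`entering_distribution()`) is therefore the
model's own unscreened state mix at the entry age, accumulated over a
22-year run-in (an entry cohort of mean age 42 accumulates from about age
20; ages below 40 reuse the youngest band's transition rates), conditioned
on being alive and free of a CRC diagnosis — the programme excluded
residents with diagnosed colorectal malignancy. The run-in length was fixed
at 22 years a priori as the span over which adenoma risk becomes
non-negligible; with it, every strategy in the base-case grid averts deaths,
and more frequent screening always averts more, the ordering the programme
evaluation reports. `run_cohort(init = "normal")` restores the all-normal
variant for diagnostics.

## Screening rounds

`apply_screening_round()` moves proportional flows: a participation fraction
of every eligible state takes the initial screen (cost 3.26 USD); positives
(true positives via class-specific sensitivity, false positives via
1 − specificity for lesion-free states) reach colonoscopy at the compliance
rate (cost 95.80 USD); colonoscopy true positives are diagnosed and split by
treatment compliance into treated (treatment cost charged on entry) versus
diagnosed-untreated; everyone else returns unchanged. Lesion-free
colonoscopies are false positives: cost only, no utility decrement (none is
listed among the utilities), with the share colonoscopy itself mis-calls
(1 − 0.95) accruing one extra follow-up visit. Eligible states are all alive
states except diagnosed CRC, which is in clinical care. Rounds fall at entry
and every `f` years thereafter while the cohort's mean age is at most the
stop age (74, the programme's upper eligibility); an optional multiplicative
per-round adherence decay implements the screening-fatigue scenario.

Strategy grids drop frequencies whose schedule collapses to an
already-present one (from entry 72, "every 10/5/3 years" all mean a single
round — identical to "once"), matching how such rows are reported.

## Costs

Treatment costs are charged once on entry to a treated state (by class and
stage); the diagnosis work-up cost (86.43 USD) is charged at symptom-driven
detections (screen-detected diagnosis is already covered by the colonoscopy
cost); every treated state accrues an annual follow-up cost (86.43 USD) on
half-cycle membership; the fixed programme preparation cost (13,572 USD,
training, education and system set-up) is charged once per screening
strategy at entry, the one defensible reading of a cost stated without a
denominator. Death states accrue nothing. Utilities: age-specific
general-population values for normal, all NAA compartments, treated AA
(treatment restores an adenoma-free colon) and undiagnosed preclinical CRC
(asymptomatic by definition); 0.83 for untreated AA; stage-specific values
for diagnosed CRC.

## Economics

`rank_and_compare()` orders one entry age's strategies by ascending QALYs
and attaches incremental costs, QALYs and ICERs versus the no-screening
baseline and versus the next-most-effective strategy (the predecessor in
QALY order, the baseline for the least effective). No dominance pruning is
applied in that table — mirroring how the published comparison reports
every strategy against its QALY-predecessor — while `ce_frontier()`
provides strict and extended dominance for general use.
`classify_against_threshold()` compares against three times per-capita GDP
(53,235 USD/QALY, 2023) and the chronic-disease threshold (1.76 × GDP),
with ≤ counted as cost-effective. `icer_consistency()` audits a printed
comparison table against its own printed increments: cells that cannot be
reproduced to within ±1 USD/QALY are flagged, never silently matched — 4 of
the 38 rows of the packaged comparison deviate by 2-4 USD/QALY because
printed increments are rounded to 1 QALY and 1,000 USD.

## Programme yield

`yield_report()` recomputes the cascade percentages, detection rates,
per-10,000 yields (the stated product formulas), colonoscopies per lesion
(ceiling quotient — the only rounding that reproduces the printed 6/11/108),
cost per lesion and number needed to screen (half-up rounding) from
aggregate counts, and lists every printed cell that is not arithmetically
consistent with the printed counts. For the packaged programme counts the
per-10,000-participants row, the detection-rate percentages and both NNS
values are irreconcilable with the printed inputs; they are reported in the
discrepancy listing, not patched.

## Calibration and validation

`calibrate_transitions()` adjusts only the calibration-sourced rows
(age-banded onset, NAA→AA and AA→CRC progression) to minimise the summed
squared difference between the unscreened model's age-banded prevalence of
undiagnosed NAA/AA/CRC and supplied targets, holding literature-sourced
parameters fixed; bounded L-BFGS-B from the base point inside each row's
uncertainty interval, with small finite-difference steps (1e-6) because the
objective lives on a 1e-4 scale. On self-generated targets it recovers
generating probabilities to within 10% per band; the last band of the
AA→CRC family is the least identified (its signal is confined to the tail
of the target window). `goodness_of_fit()` returns R² (about the reference
mean) and RMSE, erroring on a constant reference where R² is undefined.

## Synthetic data

The programme's age-specific initial state distribution, registry reference
curves and individual-level cascade are not published; `synth_*` generators
emulate them as pure functions of (seed, configuration), shipping their
generating parameters for recovery-style tests. The initial-distribution
generator enforces two structural properties for any seed — prevalence
non-decreasing with age and decreasing with severity — by clamping; with the
base-case rates the clamp binds above age 65, where the slowly-draining AA
pool overtakes NAA point prevalence (the severity ordering of *incidence
flows* holds at all ages). Registry curves are the model's own incidence and
mortality per 100,000 plus additive Gaussian noise (default sd 15, the
magnitude of the discrepancies registry comparisons show), clamped
non-negative and mortality ≤ incidence. The cascade generator draws
binomial counts with probabilities either supplied or derived from the
unscreened 50-74 state mix and the test characteristics.

What passing tests on these generators do *not* show: that the model
reproduces any real registry's curves, the real programme's detection rates,
or individual-level behaviour (participation is modelled as exchangeable
proportions, not correlated individual adherence).

## Numerical choices and problem sizes

Row-stochasticity is enforced to 1e-12 and cohort mass conservation to
1e-10 per cycle. The engine is deterministic; all randomness (PSA, synthetic
data) flows from explicit seeds, with per-draw PSA seeds derived from the
master seed so draw `i` is invariant to the number of draws. The test-suite
and acceptance analyses use the full 7-age × 6-frequency grid, a 500-draw
PSA over the entry-42 grid (the published analysis used 10,000 draws; 500
is ample for the >90% probability statements checked here) and three-band
calibration windows (nine free parameters), keeping the whole suite around
two minutes.

## Known limitations

No serrated-pathway states; no stage shift at detection (lesions are found
in their current stage); static transition probabilities (no secular
trends); adenoma and CRC recurrence is modelled as a return to the
undiagnosed compartment of the same class, an explicit reading of
"recurrence after treatment" that the source figure does not pin down;
parameters are sampled independently in PSA; and the deaths-averted and
QALY magnitudes depend materially on the entering distribution, for which
only a model-generated stand-in is available.
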