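---
title: "Developing a claims-based phenotype for problem prescription opioid use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing a claims-based phenotype for problem prescription opioid use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surveillance of problem prescription opioid use — the spectrum of clinically
documented behaviors and symptoms of unhealthy opioid use, broader than a
formal use-disorder diagnosis — is limited by the poor sensitivity of simple
ICD-9 code lists (dependence 304.\*, abuse 305.5x, poisoning 965.0x
excluding heroin). A computable phenotype built from structured EHR/claims
data promises scalable case identification: candidate predictors are
operationalized from demographics, enrollment, encounters, diagnoses,
procedures and pharmacy dispensings over a fixed observation window, a
sparse classifier is trained against a chart-review reference standard, and
risk-score cut points are chosen for the performance profile an application
needs.

`probuse` implements that full development pipeline for long-term
extended-release/long-acting (ER/LA) opioid recipients, together with a
seeded synthetic claims simulator so every stage is testable without access
to patient data.

```{r, eval = FALSE}
library(probuse)
pl <- run_pipeline(config = sim_config(n_patients = 2000, seed = 1), seed = 1)
pl$report
```

## Cohort definition

A patient is study-eligible when they

* are at least 18 years old at the study start,
* have no nursing-home/hospice exclusion flag,
* have a qualifying ER/LA *index date*: the first ER/LA dispense date `d`
  such that the summed ER/LA days' supply dispensed in the closed 90-day
  window `[d, d + 89]` reaches 60 days (buprenorphine-class products are
  OUD-treatment medications and never qualify),
* have continuous enrollment covering 6 months before through 18 months
  after the index date (24 months total; gaps up to a configurable
  tolerance, default 0 days, are bridged), and
* have encounters in at least 8 distinct calendar quarters.

The observation window is 36 months: 12 months before through 24 months
after the index date (`observation_end = index + 24 months − 1 day`). The
reference-standard outcome is operationalized against this window: a member
is positive when their documented onset falls on or before the window end —
onsets *before* the window count as positive — and negative otherwise.

Interpretation choices the data model does not pin down, made once and
exposed as configuration: the 90-day window is a closed run of calendar
days; days' supply counts toward a window by dispense date rather than by
coverage-day attribution (the eligibility criterion reads as dispensed
quantity); candidate windows are anchored at fill dates, which the test
suite proves equivalent to a daily-grid search via a brute-force oracle;
months are calendar-month offsets with end-of-month clamping; study
quarters are calendar quarters. Incident-versus-prevalent user distinctions
are out of scope: the cohort is a prevalent-user cohort by construction.

## Sampling design and weights

The analysis sample is an enriched stratified sample crossing two axes:
age 18–34 at the index date, and any dependence/abuse/poisoning code during
the study period (heroin-specific codes excluded). Enriched strata are
sampled completely and the remainder proportionally
(`enrichment_fractions()`); each patient carries
`design_weight = 1 / selection probability`. Design weights are used *only*
to re-weight prevalence estimates back to the eligible pool
(`weighted_prevalence()`, a Horvitz–Thompson ratio) — not in model fitting,
where the estimand is the classifier itself. The sample splits 70/30 into
training and validation (2,000 → exactly 1,400/600).

## Predictor engine

Every predictor is a `predictor_spec(name, family, params)` evaluated over
the member's observation window. Two primitives do most of the work:

* `daily_meq_series()` expands opioid fills into a per-day
  morphine-equivalent dose: each fill covers
  `[dispense_date, dispense_date + days_supply − 1]` (closed) and
  contributes `quantity × mg_per_unit × meq_factor / days_supply` per
  covered day; overlapping fills add. The series conserves total dispensed
  morphine equivalents, which the tests assert as a mass-balance property.
* `detect_overlap_events()` finds chains of partially overlapping fills: a
  fill overlaps another when its dispense date falls within the other's
  coverage. The detector flags a connected chain of ≥ 3 qualifying fills
  (drug class, maximum days' supply, day-of-week filters) within a rolling
  3-calendar-month span — the canonical instance being ≥ 3 overlapping IR
  fills of ≤ 14 days' supply on a Saturday, Sunday or Monday. A brute-force
  coverage-day oracle verifies the chain logic on random fill sets.

The shipped library (`default_predictor_library()`, ~110 specs) spans every
candidate-variable family — diagnosis flags/counts/percent-of-quarters for
pain, mental-health, substance-use, sleep, trauma and comorbidity code
groups; days'-supply aggregates with excess-supply variants; MEQ summaries
with high-dose thresholds at 50/90/120 MEQ/day and consecutive-quarter
percent-change triggers at 33/50/75%; overlap variants; concomitant
opioid/benzodiazepine–psychoactive coverage days; ER encounters during
opioid coverage, overlap, and high-MEQ periods; urine-drug-screen counts
and proximity (±7 days) to risk indicators; OUD-treatment medication use; a
simplified 17-category Charlson index; demographics; and age-18–34
interaction terms. Coverage is deliberately by *family*, not a
reconstruction of any particular health system's 1,126-variable catalog;
the high-MEQ thresholds and dichotomization cut-points are stated
assumptions, configurable per spec. `risk_ratio_screen()` implements the
univariate screening statistic
`RR = % of outcome-positives with the predictor TRUE / % of
outcome-negatives with it TRUE`, with zero-denominator cases flagged
undefined rather than infinite.

## Adaptive LASSO

The classifier is adaptive LASSO logistic regression: minimize

$$\sum_i \big[\log(1 + e^{\eta_i}) - y_i \eta_i\big]
  + \lambda \sum_j w_j |\beta_j|, \qquad
  w_j = 1 / |\hat\beta^{\text{ridge}}_j|^{\gamma},$$

with an unpenalized intercept. The ridge step makes the weights well
defined when predictors are many relative to events; γ controls how
strongly those initial associations steer the penalty and λ the overall
sparsity. Numerical choices:

* Solver: iteratively reweighted least squares with cyclic coordinate
  descent and soft-thresholding (compiled path solver, warm starts,
  active-set sweeps). Zero coefficients are *exact* zeros. The objective is
  verified against glmnet as an independent convex solver to 10⁻⁴ relative
  tolerance; λ = 0 reproduces the unpenalized MLE and a saturating λ the
  null model.
* Predictors are standardized to unit variance before penalization
  (population s.d., denominator *n*); coefficients are reported on the
  original scale. Ridge magnitudes below 10⁻⁶ are clamped before inversion.
* Grids: γ ∈ {0.5, 1, 2}; λ descends log-spaced in 50 steps from
  `lambda_max` (the smallest λ zeroing every coefficient) across four
  orders of magnitude.
* (γ, λ) are chosen by 8-fold cross-validation minimizing the held-out sum
  of squares `Σ (y_i − ŷ_i)²` with ŷ on the probability scale (the natural
  reading of "predicted value" for a fitted probability). Folds are
  stratified by outcome so no fold lacks events; adaptive weights are
  re-estimated inside each training fold, the conservative choice that
  avoids leaking held-out outcomes into the penalty. Ties break toward
  larger λ (sparser), then smaller γ.
* The ridge penalty for weight estimation defaults to 10 on the summed
  log-likelihood scale — mild shrinkage whose purpose is stabilization, not
  selection; it is a config knob.
* Design weights are not used in the likelihood; a sensitivity analysis
  with weighted likelihood would be a one-line extension but is not the
  primary estimand.

Post-selection interaction refitting ("selected interactions between
retained terms") has no stated selection rule and is not implemented;
age-group interactions are instead offered as first-class candidate
predictors.

## Evaluation

Classification is *at or above* the cut point. `select_cutpoint()` chooses
cuts on training data only, under four schemes: target sensitivity, target
specificity, or target PPV at excellent/good/acceptable levels
(0.90/0.80/0.75), each maximizing the complementary metric among feasible
cuts (sensitivity targets maximize PPV; specificity and PPV targets
maximize sensitivity — an interpretation of "optimize performance with
desirable X", documented as such); and a balanced scheme minimizing
|sensitivity − PPV|. Ties resolve to the higher cut. Unattainable targets
raise an error reporting the best attainable value. `cutpoint_report()`
assembles the 10 scheme rows plus an ICD-9 comparator row, reporting
sensitivity, specificity, PPV, NPV and predicted prevalence on both splits
at the training-chosen cuts; undefined ratios surface as `NA`.
`binomial_ci()` reproduces the design's power arithmetic (Wald by default,
whole-percent display; an exact method flag is provided). ROC construction
and the trapezoidal AUC follow the same tie convention.

## The synthetic claims simulator

`generate_population()` emulates the *structure* the analysis assumes, not
any particular health system: no marginal stream distributions are
published for the source setting, so all generator defaults are
assumptions, stated here and in `?sim_config`.

* Streams are piecewise-constant-rate Poisson processes within enrollment
  spans; enrollment is one long span occasionally split by gaps
  (exercising the continuous-enrollment filter).
* ER/LA episodes refill sequentially with days' supply in {28, 30, 90};
  refills arrive early by an exponential number of days (mean 1.5),
  producing the overlap/early-fill phenomena the predictors target. IR
  fills ({5, 7, 10, 14, 30} days) arrive as a Poisson stream concentrated
  in the episode.
* A latent problem-use trait (default prevalence 0.25, between the 36-month
  and study-period weighted prevalences typical of such cohorts) multiplies
  configured stream intensities for trait-positives — early fills ×3,
  high-strength (high-MEQ) products ×3, OUD-diagnosis hazard ×20 after the
  latent onset, ER visits ×3, benzodiazepine/psychoactive fills ×2.5,
  OUD-treatment medication probability ×10. A latent onset time is drawn
  for *both* trait groups and anchors OUD-related stream timing, so unit
  multipliers make the groups exactly exchangeable — the null-effect
  property the tests exploit.
* The documented onset lags the latent onset by a geometric delay (mean
  60 days), generating before/within/after-window outcome cases.
* MEQ conversion factors live in a small replaceable drug dictionary;
  they are plausible values, not a published conversion table.

What passing tests on these data do and do not show: the simulator's
defaults give a *strong, learnable* signal, so end-to-end runs demonstrate
that the machinery — eligibility, features, selection, cut points — is
correct, with near-perfect AUC. They do not show that real claims data
carry such signal — structured claims streams may well lack the nuance to
separate problem use from complex but unproblematic long-term therapy —
and nothing here bears on that empirical question.

## Problem sizes and determinism

The shipped test suite and acceptance script use: 2,000 simulated patients
for the end-to-end chain; 20 replicates of n = 1,400 × p = 100 (8 true
effects of standardized magnitude 0.5, the weakest magnitude in the stated
condition) for support recovery; 1,000 random record sets per brute-force
oracle; and 500 stratified draws for design-weight unbiasedness. All
randomness flows from explicit integer seeds; identical configuration and
seed reproduce every table byte-for-byte.

## Known limitations

* The generator does not model death, disenrollment-by-outcome, seasonal
  utilization, coding drift, or ICD-10; calibration to any real system is a
  non-goal.
* The comparator treats the opioid-abuse family as 305.5x; a literal
  "any 305.\*" reading would sweep in non-opioid abuse codes (e.g. tobacco
  305.1) and is deliberately not used.
* Variance estimation for weighted prevalence, chart-abstraction protocols,
  and multi-site transport are out of scope.
* One power-statement interval (sensitivity, 71–89%) is not reproducible by
  standard binomial formulas under the stated assumptions; only the
  specificity interval (76–84%), which Wald arithmetic reproduces exactly,
  is asserted.
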