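---
title: "Methods: instruments, tailoring, minimization, device metrics and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instruments, tailoring, minimization, device metrics and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftrialkit)
```

`hftrialkit` implements the computational layer of a patient-centered
mobile-health (mHealth) heart-failure (HF) self-care trial: a two-arm
pilot in which intervention patients use connected devices (weight
scale, blood-pressure cuff, wrist activity tracker) and receive
individually tailored SMS messages, and outcomes are
patient-reported-outcome (PRO) instruments plus device-measured
adherence. Every stage is implemented as a tested function and exercised
end to end on a synthetic cohort with embedded ground truth, because the
motivating kind of pilot never deposits raw patient data.

This vignette records the models, the tunable parameters and their
defaults, the design decisions taken where published descriptions are
silent, and what the synthetic generator does and does not emulate.

## Instrument scoring

PRO scales are declared as `scale_definition()` objects: ordered items
with per-item response ranges and reverse-scoring flags. Scoring sums
the reverse-corrected responses; scales flagged `standardize` map the
raw sum affinely onto 0–100:

$$\mathrm{score} = 100\,\frac{\text{raw} - \text{min sum}}
{\text{max sum} - \text{min sum}}.$$

The self-care index subscales (maintenance, 10 items; symptom
perception, 9; self-care management, 10) and the 10-item self-care
self-efficacy scale use this standardization, with scores below 70
flagged as clinically insufficient (strict inequality: exactly 70 is
sufficient) and changes of at least 8 standardized points flagged as
clinically important (MCID). The 12-item health-status short form
(KCCQ-12) is summarized as the arithmetic mean of its four 0–100
subscales, MCID 5 points; the knowledge test is the count of correct
answers out of 15 and is never standardized.

**Missing items.** A score with more than 50% of items missing is
itself missing; below that the raw sum is prorated (the mean of
answered items carried to the full item count). Proration is the common
PRO convention and is isolated in one function; between-patient
imputation is deliberately deferred to the multiple-imputation stage.

**Belief scales.** Perceived benefit and barrier scales for medication,
diet and self-monitoring adherence are reported as raw sums, not
standardized. The published instruments are described as 12-item
scales, but the subscale score ranges seen in practice (benefit means
above 31, barrier means above 25 on 1–5 items) are only attainable with
roughly 7 benefit and 6 barrier items, so the shipped defaults use that
7 + 6 split. These definitions are editable fixtures — stand-ins with
the right scoring behavior, not reproductions of the licensed
instruments (whose item wording is copyrighted and out of scope).

## Tailored-message engine

Each tailoring rule inspects one assessment item. On the 5-point
agreement scale (1 = strongly disagree, 5 = strongly agree):

| rule kind | fires when | rationale |
|---|---|---|
| benefit | response ≤ 3 | patient does not yet perceive the benefit |
| barrier | response ≥ 3 | patient endorses the barrier |
| efficacy | response ≤ 3 | low confidence in self-care |
| knowledge | wrong option chosen | education message needed |

Both thresholds are inclusive, so a response of exactly 3 fires a
benefit *and* a barrier rule on paired items — that is what the decision
table prescribes, and the test suite pins the full 5 × 2 truth table.
Unanswered items skip their rules (logged), never fire them.

Fired messages are scheduled at 4 per week on the patient's preferred
weekday and time. When more messages fire than a week holds, selection
is round-robin across intervention targets (medication → diet →
self-monitoring → self-efficacy → knowledge, then rule order) so each
week mixes topics; multi-message sequences stay contiguous and count as
N sends. Both conventions are package decisions — the source material
gives the rate and the preference but not an ordering — and unsent
messages roll forward. Remaining slots are filled from an editable
general-education pool. The week-4 reassessment rebuilds weeks 5–8 from
scratch (`retailor()`), so resolved barriers stop messaging. Delivery
is simulated only: the schedule is an output artifact, not an SMS
gateway.

## Minimization randomization

Arms are assigned by Pocock–Simon biased-coin minimization balancing
age, sex and NYHA class with equal weights. For each candidate arm the
imbalance score adds, over factors, the range (max − min) of the
patient's level count across arms after a hypothetical assignment; the
score-minimizing arm is chosen with base probability 0.7 (ties: fair
coin). With base probability 1 and no ties the rule is deterministic —
a degenerate limit the tests exercise.

Age must be discretized to serve as a minimization factor and the
original strata are unpublished; the default splits at 60 years
(roughly the median of a 41–72 cohort) and is configurable
(`default_allocation_factors(age_cut = )`). Every decision is logged
with both scores and the uniform draw, giving a replayable audit trail.
Simulation tests confirm the method beats simple 1:1 randomization on
marginal covariate balance over 1,000 simulated 27-patient trials.

## Device metrics

* **Wear time** is the count of minutes carrying a heart-rate sample; a
  **valid day** has ≥ 600 wear minutes (10 hours).
* **Weekly activity** means (steps, moderate-to-vigorous physical
  activity [MVPA] minutes, sedentary minutes, wear time) are computed
  over valid days within consecutive 7-day windows; weeks with fewer
  than 3 valid days are excluded. The source material states both a
  4-valid-day definition and a 3-valid-day analysis rule; the package
  defaults to 3 (the rule the analysis actually uses) and exposes the
  threshold. MVPA is operationalized as minutes labelled moderate or
  vigorous in the stream; proprietary vendor intensity algorithms are
  out of scope.
* **Self-monitoring adherence** is the percentage of protocol-required
  days with at least one measurement of the modality, with in-hospital
  days removed from the denominator. It is invariant to duplicate
  same-day measurements, and a weekly series feeds the trajectory
  models. Day boundaries are patient-local calendar days.
* **Blood pressure** readings map to guideline bands — normal
  (<120/<80), elevated (120–129 and <80), stage 1 (130–139 or 80–89),
  stage 2 (140–179 or 90–119), crisis (≥180 or ≥120) — with the more
  severe band winning when the two readings disagree, and an emergency
  flag above 180/110.
* **Weight alerts** fire on a day-over-day gain of at least 3 lb
  (≈1.36 kg); gains across longer gaps are reported as
  change-since-last-measurement without a daily flag.

## Trial statistics

**Effect sizes.** For change scores summarized per arm as
$(n_i, m_i, s_i)$, the package computes Cohen's
$d = (m_1 - m_2)/s_p$ with the pooled SD
$s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}$, the standard
error $\mathrm{se}_d = \sqrt{\frac{n_1+n_2}{n_1 n_2} +
\frac{d^2}{2(n_1+n_2)}}$, and the interval
$d \pm t_{0.975,\,n_1+n_2-2}\,\mathrm{se}_d$. The t-quantile interval
is the default because it reproduces published pilot-trial intervals at
these sample sizes where a normal-quantile interval does not; the
normal variant sits behind `ci_method = "normal"`. No Hedges
small-sample correction is applied, matching the uncorrected convention
of the tables this mirrors. The accompanying test is the
pooled-variance two-sample t test; no multiplicity adjustment is
applied anywhere, since reporting focuses on estimates and intervals
rather than p values.

**Multiple imputation.** `mi_impute()` is a compact
chained-equations engine: each incomplete outcome column is regressed
on the complete predictors plus the other outcome columns, coefficients
and residual variance are drawn from the Bayesian posterior of the
normal linear model, and missing cells are redrawn each sweep
(default 5 sweeps, m = 20 datasets; a predictive-mean-matching variant
draws from the 5 nearest observed donors). Estimates are combined with
Rubin's rules: pooled estimate = mean; total variance = within +
(1 + 1/m) × between. The engine is hand-implemented because no
chained-equations package is available in the build environment; an
MCAR simulation with a known linear model verifies pooled-slope
recovery to within 5%.

**Trajectory models.** Weekly adherence and activity trajectories use
a linear mixed model with a fixed week slope and a patient random
intercept, fitted by REML through `nlme::lme` behind the
`fit_random_intercept_lmm()` surface. Wald t statistics use the
within-subject denominator df convention
$N_\mathrm{obs} - N_\mathrm{subjects} - 1$; the exact df conventions of
any specific published analysis are not recoverable without raw data,
so the convention is documented rather than matched. Degenerate inputs
(one observation per subject) pin the random-intercept variance to zero
with a warning and fall back to ordinary least squares, and the test
suite checks the REML optimum against an independent closed-form
restricted-likelihood grid and against an `lme4` refit.

**Feasibility.** The screening-log metrics are plain arithmetic:
recruitment fraction = 100 × enrolled / screened (reported to 1
decimal), retention per visit among randomized patients, and enrolled
per month.

## The synthetic cohort: a stated world

The generator's defaults are fixed, documented choices calibrated to
the motivating cohort, not tuning knobs:

* arm sizes 11 vs 14; age truncated-normal with the location solved so
  the post-truncation (≥ 40 years) mean is 56 with SD 8.3; sex 56/44%,
  race 92/8%, NYHA 24/60/16%, ejection-fraction categories 60/20/20%;
* baseline scale means/SDs per instrument taken from the corresponding
  published baseline tables, with item responses back-solved from the
  target score (raw sum distributed as evenly as possible with random
  remainders) and then *re-scored*, so recorded scores are exactly what
  the scoring engine produces;
* follow-up change scores are normal with arm-specific means: an
  injected standardized effect $d$ on a (scale, visit) shifts the
  intervention arm's mean change by $d \times \mathrm{change\ SD}$;
* visit-level missingness is completely at random at 15% for week 4 and
  0% for week 8, mirroring the 85%/100% visit-completion pattern;
* daily measurement events are Bernoulli with per-patient propensities
  drawn from a beta distribution matched to cohort mean 86.4% and SD
  11.16% (an `adherence_sd = 0` degenerate case supports exact
  propensities, including 1.0); wear minutes are truncated-normal
  (1031, 421) in [0, 1440]; steps lognormal matched to mean 5480, SD
  3904; MVPA gamma matched to mean 22.2, SD 18.7; no within-patient
  day-to-day adherence correlation is modelled (a deliberate
  simplification);
* the screening funnel is fixed at 504 screened / 29 enrolled / 27
  randomized over 10 months.

What a green test does and does not establish: the generator reproduces
*marginals and injected effects*, so recovery tests demonstrate that
the analysis pipeline is unbiased against its own stated world. It does
not emulate item-level response psychology, informative missingness,
illness-driven adherence collapse, or physiological waveforms — results
on real cohorts can differ for all of those reasons.

## Numerical choices and edge cases

* Zero pooled SD: $d$ is 0 when the means agree and an error otherwise.
* Bayesian imputation draws floor the residual sum of squares at
  $10^{-10}$ so an exactly collinear complete-case fit still yields a
  proper (near-degenerate) posterior.
* `distribute_sum()` clamps infeasible raw-sum targets to the scale's
  range; follow-up scores are clamped to the instrument range before
  back-solving, which slightly attenuates injected effects near the
  bounds (the recovery tests use scales whose targets stay interior).
* Minimization ties break by fair coin; the drawn uniform is logged.
* Schedules are deterministic given their inputs; all pipeline
  randomness flows from the single configured seed.

## Reproducing a run

```{r, eval = FALSE}
res <- run_pipeline(run_config(seed = 1))
res$results_table          # per-scale, per-visit effect sizes
res$adherence_lmm$bp       # weekly BP-adherence trajectory model
res$feasibility            # screening funnel metrics
```

`scripts/acceptance.R --seed <int> --out <path>` performs exactly this
demo run from a fresh session and writes its JSON summary; reruns with
the same seed are identical, including the output manifest hash.

## Known limitations

* The shipped scale definitions and message bank are fixtures; real
  deployments must supply licensed instrument metadata and a curated
  message bank.
* The imputation engine covers normal-model and PMM chained equations
  only — no categorical-outcome imputation.
* Denominator df for mixed-model t statistics follow one documented
  convention; software packages differ here and so do published tables.
* Only two-arm trials are supported by the minimization module.
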