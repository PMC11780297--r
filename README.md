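# hftrialkit

Computational machinery for patient-centered mHealth heart-failure (HF)
self-care trials, built as a reusable, tested R pipeline. Pilot trials
of this kind — connected weight scales, blood-pressure cuffs and wrist
activity trackers plus individually tailored SMS messages, with
patient-reported self-care instruments as outcomes — rarely deposit raw
data, yet their methods are highly reusable. This package implements
each stage as a plain function and ships a synthetic-cohort generator
with embedded ground truth, so the whole analysis can be exercised and
validated end to end without patient data.

It is aimed at biostatisticians and trialists designing or re-analyzing
small behavioral mHealth trials.

## What is implemented

* **Instrument scoring** — scale definitions with per-item ranges and
  reverse scoring; raw sums standardized to 0–100 via
  `100·(raw − min)/(max − min)`; insufficiency flags (score < 70) and
  MCID change flags (≥ 8 standardized points; ≥ 5 for the KCCQ-12
  summary, which is the mean of its four 0–100 subscales); a 15-item
  knowledge test scored as the number correct; eligibility screening
  (age ≥ 40, NYHA I–III, MoCA ≥ 22, exclusion flags).
* **Tailored-message engine** — rules that fire on benefit answers ≤ 3,
  barrier answers ≥ 3, low confidence ≤ 3, or incorrect knowledge
  answers; delivery at 4 messages/week at the patient's preferred
  day/time with round-robin target mixing; week-4 retailoring.
* **Minimization randomization** — Pocock–Simon biased-coin
  minimization (base probability 0.7) balancing age, sex and NYHA
  class, with a full audit log.
* **Device metrics** — wear time from heart-rate minutes, the
  600-minute valid-day rule, ≥ 3-valid-day analysis weeks,
  self-monitoring adherence with hospital-day adjustment, guideline
  blood-pressure bands with an emergency flag above 180/110, and
  3-pound daily weight-gain alerts.
* **Trial statistics** — change scores; Cohen's
  *d* = (m₁ − m₂)/s_p with pooled SD, se_d = √((n₁+n₂)/(n₁n₂) +
  d²/(2(n₁+n₂))) and t-quantile confidence intervals; pooled-variance
  two-sample t tests; chained-equations multiple imputation (m = 20)
  with Rubin pooling; random-intercept REML mixed models for weekly
  trajectories; screening-funnel feasibility metrics.
* **Synthetic cohort + pipeline** — a generator calibrated to a
  realistic 25-patient two-arm cohort (adherence mean 86.4%, SD
  11.16%; 5480 steps/day; …) with injectable arm effects, and
  `run_pipeline()` to run simulate → randomize → tailor → metrics →
  analyze reproducibly from one seed.

## Worked example

Effect size from per-arm change summaries (n, mean change, SD change):

```r
library(hftrialkit)
es <- cohen_d_from_summary(group_summary(11, 4.91, 4.35),
                           group_summary(14, 1.43, 3.11))
es
#> Cohen d = 0.94 (95% CI 0.06 to 1.82), t(23) = 2.33, p = 0.029
```

The standardized mean difference is 0.94 pooled SDs — a large effect —
and the t-based interval excludes zero at these small sample sizes.

A full pipeline run on the calibrated synthetic world:

```r
res <- run_pipeline(run_config(seed = 1))
res$feasibility$recruitment_fraction_pct
#> [1] 5.8
subset(res$results_table, scale_id == "benefits_self_monitoring")
#>                  scale_id visit n_intervention n_control    d ci_low ci_high    p_value
#>  benefits_self_monitoring week4             12         9 0.66  -0.29    1.61 0.15135488
#>  benefits_self_monitoring week8             13        12 1.12   0.23    2.01 0.01001444
mean(res$adherence$weight_pct)
#> [1] 91.5
```

The demo truth injects a standardized effect of 0.94 on perceived
benefits of self-monitoring at week 8; this single seed-1 replicate
estimates 1.12 (single small trials are noisy — the test suite shows
the estimator is centered on 0.94 across 200 replicates). The
recruitment fraction comes from the generated screening funnel
(29 enrolled of 504 screened), and the adherence column summarizes
each intervention patient's percentage of eligible days with a weight
measurement.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the complete demo pipeline from scratch against the installed
package — synthetic cohort, minimization, tailoring, device metrics,
imputation, outcome tables, feasibility — prints a one-line summary of
the run, and writes its JSON output to `--out`. Reruns with the same
seed are identical.

## Layout

```
R/                  instruments, tailoring, randomization,
                    device_metrics, trial_stats, synthetic_cohort,
                    pipeline
inst/extdata/       editable message bank (YAML)
inst/cli/hftrial.R  thin CLI (simulate | demo | analyze)
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, defaults, limitations)
scripts/            acceptance runner
```
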