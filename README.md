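# rdmprec

Personalized action recommendations for remote diabetes monitoring
programs, via doubly robust heterogeneous treatment effect estimation and
uplift evaluation.

## What it does

Members of a remote diabetes monitoring program can engage in five action
categories — coaching, blood-glucose monitoring, physical activity,
nutrition, and educational content. Engagement is self-selected, so naive
comparisons of engaged vs non-engaged members confound the effect of an
action with who chooses it. `rdmprec` implements the full observational
causal workflow:

1. **Outcome** — estimated A1c from SMBG readings via the ADAG relation
   `eA1c = (mean BG + 46.7) / 28.7`; the outcome is
   `Y = eA1c(month 4) − eA1c(month 1)` (negative = improvement), behind a
   study-style eligibility funnel (4 months enrolled, type 2, no CGM, ≥5
   valid readings in months 1 and 4, baseline eA1c ≥ 7.5%).
2. **Treatments** — per-category binary treatment flags from 90-day
   engagement thresholds (e.g. ≥3 coaching sessions, ≥70 SMBG-check days),
   plus a sweep that selects thresholds trading off model error, effect
   size and cohort balance.
3. **CATE estimation** — a doubly robust learner: cross-fitted
   gradient-boosted nuisances for the outcome regression `g(T, X)` and the
   propensity `f(X)`, the pseudo-outcome
   `ψ = (g1 − g0) + T(Y − g1)/f − (1 − T)(Y − g0)/(1 − f)`,
   and a random-forest regression of ψ on X giving per-member `τ̂(x)`,
   with a 65:35 train/validation split.
4. **Evaluation** — uplift-by-decile cumulative gain curves and normalized
   AUUC (random ranking = 0.5) against a seeded random-permutation
   baseline.
5. **Recommendation** — each member's argmin-`τ̂` action (or "none" when
   nothing is predicted to help), the recommendation distribution, and the
   matched-vs-unmatched outcome analysis quantifying the personalization
   benefit.

Because member-level program data is proprietary, the package includes a
synthetic cohort generator with confounded engagement and known
ground-truth effects; every estimator is validated against that ground
truth. See the methods vignette (`vignettes/rdmprec-methods.Rmd`) for the
model, its assumptions, and all design choices.

## Worked example

```r
library(rdmprec)

cfg <- run_config(sim = sim_config(n_members = 1500), seed = 42)
report <- run_pipeline(cfg, "pipeline_out")
```

The pipeline logs one line per stage:

```
[simulate] generated 1500 members, 106553 SMBG readings
[outcomes] 1123 of 1500 members eligible
[cohorts] treatment sizes: coaching=468, monitoring=579, physical_activity=461, nutrition=525, content=503
[fit] coaching: n_t=468 mse=6.297 auuc=0.618 (random 0.501)
[fit] monitoring: n_t=579 mse=10.935 auuc=0.601 (random 0.500)
[fit] physical_activity: n_t=461 mse=7.927 auuc=1.449 (random 0.502)
[fit] nutrition: n_t=525 mse=7.942 auuc=0.590 (random 0.503)
[fit] content: n_t=503 mse=16.807 auuc=0.613 (random 0.501)
[recommend] distribution: coaching=0.51, monitoring=0.27, physical_activity=0.11, nutrition=0.02, content=0.09
```

Reading the numbers: of 1500 synthetic members, 1123 survive the
eligibility funnel. For every category the model-ranked AUUC exceeds the
random-ranking baseline of ≈0.5, i.e. ranking members by predicted benefit
concentrates real outcome gains in the top deciles. Coaching and
monitoring dominate the recommendation mix, and the matched-vs-unmatched
analysis shows the personalization gap:

```r
ma <- report$matched_vs_unmatched
ma[ma$category == "pooled", ]
#>   category n_matched n_unmatched mean_y_matched mean_y_unmatched difference
#> 6   pooled       183         189      -2.323972       -0.9525411  -1.371431
```

Validation-split members who received their recommended action improved
their estimated A1c by about 1.37 percentage points more than treated
members who received a different action (on this synthetic cohort, whose
effect sizes are configured, not estimated from real members).

All stage artifacts (`members.csv`, `outcomes.csv`, `funnel.csv`,
`cohorts.csv`, `cate_<category>.csv`, `uplift_<category>.csv`,
`recommendations.csv`, `matched_analysis.csv`, `report.json`, …) are
written to the output directory. A YAML-driven command line is available
too:

```sh
Rscript scripts/run_pipeline.R --config inst/extdata/run_default.yaml --out pipeline_out
```

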