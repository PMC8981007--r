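---
title: "Methods: doubly robust uplift modeling for engagement recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubly robust uplift modeling for engagement recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rdmprec)
```

## The problem

Remote diabetes monitoring programs offer members several ways to engage —
talking to a coach, checking blood glucose on a connected meter, tracking
physical activity, logging food and responding to nutrition nudges, and
reading educational content. Engagement and glycemic improvement are
correlated, but members self-select into activities, so a raw comparison of
engaged versus non-engaged members mixes the causal effect of the activity
with who chooses it. `rdmprec` implements an observational causal workflow
that (i) turns engagement into per-category binary treatments via
thresholds, (ii) estimates each member's conditional average treatment
effect (CATE) per category with a doubly robust learner, (iii) evaluates the
rankings those estimates induce with cumulative-gain / AUUC curves, and
(iv) recommends for each member the action with the most negative predicted
effect on estimated A1c.

Because member-level program data is proprietary, the package ships a
synthetic cohort generator with known ground truth. Every estimator is
validated against that ground truth; nothing in the package depends on real
member data being available.

## Outcome: estimated A1c

Glycemic state is summarized by estimated A1c computed from self-monitored
blood glucose (SMBG) via the A1c-derived average glucose (ADAG) relation

$$\mathrm{eA1c} = \frac{\overline{\mathrm{BG}}_{30d} + 46.7}{28.7},$$

with $\overline{\mathrm{BG}}_{30d}$ the mean of valid readings
(50–400 mg/dL) over a 30-day window. The intervention outcome is
$Y = \mathrm{eA1c}_{\text{month 4}} - \mathrm{eA1c}_{\text{month 1}}$;
negative $Y$ is clinical improvement. Month $k$ is the half-open day window
$(30(k-1),\, 30k]$ with day 0 at enrollment — the source material never
defines the window boundaries, so the trailing 30-day window ending at day
$30k$ is a package choice. A window with fewer than five valid readings
raises a classed insufficient-data condition rather than silently returning
a value; eligibility filtering later converts that condition into exclusion.

Eligibility mirrors a typical study funnel, applied in a fixed order with
each member counted at its first failing rule: four months of enrollment,
self-reported type 2 diabetes, no continuous glucose monitor, at least five
valid readings in months one and four, and baseline eA1c (month one) of at
least 7.5%.

## Treatments from engagement thresholds

Each action category becomes a binary treatment through a 90-day engagement
threshold (defaults: 70 SMBG-check days; 3 coaching sessions, scheduled or
chat; 30 days with 2000+ steps; 2 food logs *or* 50% yes-responses to
nutrition nudges; 50% yes-responses to content nudges). "Higher engagement
than the threshold" is implemented inclusively (`>=`), matching the
threshold table's own notation. A member can be in several treatment
cohorts at once; members below all five thresholds form the control-only
"other" group.

`threshold_sweep()` refits the learner along a grid of candidate thresholds
and records validation MSE, mean predicted effect and cohort sizes.
`select_threshold()` operationalizes the informal "lower MSE while
optimizing treatment effect" rule: among non-degenerate records whose MSE
is within a relative band (default 10%) of the minimum, take the most
negative average effect, breaking ties toward the smaller threshold. The
band rule is one deliberate reading of an under-specified criterion; both
the band and the minimum-cohort guard (default 50 per arm) are exposed as
parameters.

## The doubly robust CATE learner

With covariates $X$, treatment $T \in \{0,1\}$ and outcome $Y$, the learner
assumes unconfoundedness given $X$ and models
$g(T, X) = E[Y \mid T, X]$ and $f(X) = P(T = 1 \mid X)$. The per-row
doubly robust pseudo-outcome is

$$\psi = \big(g_1 - g_0\big) + T\,\frac{Y - g_1}{f} -
  (1 - T)\,\frac{Y - g_0}{1 - f},$$

whose conditional mean equals $\tau(x)$ if *either* nuisance is correct.
The fitting procedure in `fit_dr_learner()`:

1. split members 65:35 into training and validation sets (seeded);
2. cross-fit the nuisances on the training set in $K = 5$ folds — a
   gradient-boosted regressor of $Y$ on $(T, X)$, evaluated at $T = 1$ and
   $T = 0$ for the counterfactual pair $(g_1, g_0)$, and a gradient-boosted
   classifier of $T$ on $X$, clipped into $[0.01, 0.99]$;
3. form $\psi$ per training row;
4. regress $\psi$ on $X$ with a random forest — the CATE model
   $\hat\tau(x)$;
5. refit the nuisances on the full training set, compute $\psi$ on the
   validation rows, and report
   $\mathrm{MSE} = \overline{(\hat\tau(X) - \psi)^2}$ on validation.

Design notes, made explicit because the source description leaves them
open:

* **Learner roles.** The narrative description pairs a classifier with the
  continuous outcome and a regressor with the propensity, which cannot be
  taken literally; the package uses the statistically coherent assignment
  (regressor for $g$, classifier for $f$) and keeps the forest as the final
  CATE stage.
* **Cross-fitting** is not mentioned in the narrative but is required to
  avoid own-observation overfitting bias in $\psi$; $K$ is configurable.
* **Propensity clipping** at $[0.01, 0.99]$ bounds the inverse-propensity
  weights; overlap enforcement is otherwise not addressed in the source.
* **Validation target.** True $\tau$ is unobservable, so validation MSE is
  measured against $\psi$ computed from validation-row nuisance
  predictions. This is what the threshold sweep minimizes.
* The outcome model is a single regressor with $T$ as a feature (S-learner
  form for the nuisance only); the debiasing step, not the outcome model's
  functional form, carries the causal claim.

## Evaluation: uplift, cumulative gain, AUUC

True effects are unobservable on real data, so models are evaluated by
ranking. With members ranked by predicted benefit (most negative
$\hat\tau$ first), the uplift at fraction $f$ is the treated-minus-control
difference of mean $-Y$ within the top $f$; cumulative gain is uplift
times members covered, $\mathrm{gain}(f) = \mathrm{uplift}(f) \cdot f
\cdot n$, anchored at $(0,0)$. AUUC is the trapezoidal area under the gain
curve divided by the total gain, so the straight line — and, in
expectation, any uninformative ranking — scores exactly 0.5. The division
by total gain (rather than by the straight-line area) is what pins the
random baseline at 0.5; the unnormalized area is attached as an attribute
for transparency. Quantile bins whose top subset lacks one cohort have
undefined uplift; they are counted, skipped, and linearly interpolated
across during integration. Ties in scores are broken by stable input
order, so AUUC is invariant to strictly monotone score transformations.

A caveat worth knowing: when a category's overall uplift (the total gain)
is near zero, the normalization is unstable and AUUC values far from 0.5
can appear; the random-baseline comparison in `random_auuc_baseline()` is
the robust way to read the curves.

## Recommendation policy

`recommend_action()` returns the category with the most negative
$\hat\tau$, or `"none"` when no category is predicted to help; exact ties
break in the fixed order coaching, monitoring, physical activity,
nutrition, content. The recommendation distribution is reported over
members with a non-`"none"` recommendation. The matched-versus-unmatched
analysis (validation split only) compares mean outcomes of treated members
whose received category matches the recommendation against those whose
does not, per category and pooled; the pooled row uses simple means over
members in at least one treatment cohort, since no pooling weights are
canonically defined. `personalization_effect()` contrasts the mean
as-received $\hat\tau$ with the mean per-member minimum — the latter
dominates by construction, and the gap is the predicted value of
personalization. Propensity to engage is deliberately excluded from the
ranking; a production recommender would have to re-weight by the
likelihood of uptake.

## The synthetic cohort generator

`generate_cohort()` draws, per member: twelve covariates (four demographic,
six self-reported medical, two preference) from configurable
distributions; latent per-category engager indicators from logit-linear
propensities in standardized covariates; engagement counters from
overlapping "high"/"low" binomial and Poisson regimes given the indicator;
and an SMBG stream of daily readings. The month-one glucose level anchors
at the member's baseline; untreated drift accrues linearly over months
two to four; the treatment effects of every category whose counter clears
its threshold are added — together with member-level noise
(`noise_sd`, default 0.3 eA1c points) — to the month-four level only,
after the 90-day engagement window. Injecting effects on the eA1c scale
and converting through the inverse ADAG relation
($\Delta \mathrm{BG} = 28.7\,\Delta \mathrm{eA1c}$) keeps ground truth in
the outcome's units, and confining them to month four keeps the month-2/3
eA1c covariates from becoming mediators (a ramping effect would bias every
downstream estimator toward zero by construction). Per-reading noise
(`bg_noise_sd`, default 25 mg/dL) propagates into the outcome through the
30-day means.

Default magnitudes, chosen once for the package's study conditions: mean
effects between −0.45 (content) and −0.9 (coaching) eA1c points with
per-category heterogeneity of comparable scale (sd ≈ 0.6–0.8), each
category's heterogeneity loading on a different covariate so the optimal
action varies across members and most — but not all — predicted effects
are negative; propensity coefficients spanning uptake probabilities of
roughly 0.1–0.9; and a drift model sharing covariates (baseline HbA1c,
self-efficacy, insulin use) with the propensities so that the naive
treated-minus-control contrast is biased by about 0.2 eA1c points — far
beyond sampling error at the cohort sizes used — and the doubly robust
machinery is genuinely necessary. Reproducibility is per member: every
member draws from RNG substreams keyed by `seed + index`, so cohorts are
bitwise reproducible and extending a cohort never reshuffles existing
members.

What the generator does *not* emulate: nudge delivery timing and content,
attrition dynamics beyond a crude dropout fraction, measurement error
structure of real meters, dependence *between* categories' effects
(effects are additive and separately assigned), or the covariate
distributions and effect sizes of any real program population. Passing
tests on synthetic cohorts therefore demonstrate the estimator's
correctness under the stated generative assumptions — unconfoundedness
given the recorded covariates above all — not fidelity to any particular
real cohort's numbers.

## Numerical choices and degenerate inputs

* Propensity clipping bounds, the MSE band, the minimum cohort guard and
  all learner hyperparameters are configuration, not constants.
* Sporadic missing feature values (e.g. an undefined month-two eA1c) are
  median-imputed; an entirely missing column is a configuration error.
* All-constant features collapse $\hat\tau$ to the DR average-effect
  estimate (the forest has nothing to split on).
* Zero total gain makes normalized AUUC undefined and is raised as a
  classed error, never returned as `NaN`.
* Empty matched/unmatched partitions are reported as `NA`, not errors.
* Categorical covariates are one-hot encoded with one column per observed
  level in sorted order, so the feature layout is a pure function of the
  input schema; prediction refuses mismatched columns.

## Problem sizes used by the test suite

The suite validates statistical properties at sizes chosen for
resolution: constant-effect recovery and nuisance-misspecification checks
on a 5000-member cohort (the recovery tolerance is ±0.15 eA1c points);
null-effect confidence-interval coverage over 50 replicate 900-member
cohorts; the model-beats-random ranking property on a 3000-member cohort
against 200 random permutations per category; and the matched-versus-
unmatched direction over 20 replicate 1200-member cohorts with a sign
test. Unit-level oracles (the ADAG grid, the eight-member uplift table,
the pseudo-outcome identity, the designed 50-member eligibility fixture)
are exact to 1e-12 or to integer counts.

## Known limitations

* Unconfoundedness is assumed, not tested; no sensitivity analysis or
  instrumental-variable machinery is provided.
* No confidence intervals on $\hat\tau$; the forest's point predictions
  feed the policy directly.
* Categories are modeled independently; interactions between concurrent
  treatments are additive in the generator and ignored by the estimators.
  A joint (e.g. Bayesian) treatment model is out of scope.
* eA1c is a population-level proxy for laboratory HbA1c; the package makes
  no attempt to calibrate between the two.
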