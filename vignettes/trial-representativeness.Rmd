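---
title: "Assessing trial representativeness from serious adverse event rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing trial representativeness from serious adverse event rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the estimator

Randomised trials routinely under-enrol older people and people with
multimorbidity, so their serious adverse event (SAE) experience may not
reflect the population that will eventually receive the treatment. A
serious adverse event is, by regulatory definition, any event that is
life-threatening, causes or prolongs hospitalisation, causes death or
lasting disability — reportable regardless of attribution. That
definition overlaps almost entirely with *urgent hospitalisation or
death*, which is observable in routine healthcare data. This package
turns that overlap into a single representativeness metric: the
**observed/expected SAE ratio**, an analogue of the standardized
incidence ratio.

For each trial we ask: *if the trial's participants had experienced the
routine-care hospitalisation/death rates for their age, sex (and
optionally multimorbidity count), how many SAEs would we have expected,
and how does the observed count compare?*

The workflow is classical indirect standardization:

1. **Reference rates.** Sex-stratified Poisson models of the
   first urgent hospitalisation or death in a routine-care cohort with
   the same index condition, with `log(person-days)` as offset. Age
   enters through up to two fractional polynomial (FP) terms.
2. **Trial structure.** For aggregate (registry-level) trials, the
   per-sex one-year age-band composition is reconstructed from the
   four reported statistics (mean, SD, min, max) via a moment-matched
   truncated normal. For individual-participant-data (IPD) trials the
   composition is observed directly.
3. **Expected count.** Reference rates applied to the trial's
   person-time, cell by cell.
4. **Inference.** Per-trial ratio `O/E` with a sampling-based 95%
   interval; per-condition pooling with a random-effects Poisson model
   using `log(E)` as offset.

A ratio below 1 means the trial population experienced fewer SAEs than
routine-care rates predict for its demographic profile — the signature
of a healthier-than-routine-care (unrepresentative) trial population.

## Model components and their assumptions

### Rate models (`fit_rate_model`)

The outcome is the *first* event (0/1) with person-time to event or
censoring, matching the first-hospitalisation/death framing; the
Poisson likelihood with an offset is then the standard
piecewise-constant-hazard approximation. Age is scaled to decades
(`age/10`, strictly positive) before FP transforms; the multimorbidity
count is shifted by +1 because zero is a valid count and FP bases
require a positive argument.

FP powers come from the conventional set
{−2, −1, −0.5, 0, 0.5, 1, 2, 3}; power 0 denotes `log`, a repeated
power `p` contributes `(x^p, x^p log x)`. Power selection
(`select_fp_powers`) is an exhaustive search over all FP1 and FP2
candidates with a closed deviance test at α = 0.05 and 2 df per stage
(FP2 vs FP1, then FP1 vs straight line); strata with fewer than 50
events fall back to a linear term with a warning. The α, the df
convention, and the fallback threshold are configurable; they are
choices, not estimates, and are recorded in model metadata.

Predictions outside the fitted age support (±5 years) are clamped with
a warning rather than extrapolated: FP curves can be badly behaved far
outside the data.

### Reconstruction of trial age structure (`reconstruct_age_distribution`)

Registries report age as mean, SD, minimum and maximum. We fit the
(unique) normal distribution truncated to `[min, max]` whose truncated
moments match the reported mean and SD — a minimal assumption that uses
exactly the four reported numbers. The solver profiles out the location
parameter (for fixed σ the truncated mean is strictly increasing in μ)
and solves two nested 1-D root-finding problems to |Δmean|, |Δsd| <
1e−6 years. Far-tail truncations are evaluated through a
tilted-exponential asymptotic expansion because the textbook formulas
cancel catastrophically there.

Not every (mean, SD, min, max) quadruple is attainable: the truncated
normal SD on an interval is bounded by the uniform SD
`(max−min)/√12`, and with the mean held off-centre the bound is lower
still (the family degenerates to a tilted exponential as σ → ∞). When
no solution exists — which happens for genuinely non-normal, e.g.
bimodal, trial populations — the maximum-entropy fallback (uniform on
`[min, max]`) is used and flagged in the output.

One age distribution is shared by both sexes within a trial, split by
percent female, because registries report age unstratified by sex; this
is a documented limitation, not an assumption we defend.

### Expected counts (`expected_events_aggregate`, `expected_events_ipd`)

For IPD trials, expected = Σ over participants of
`rate(age, sex[, mm]) × followup_days`; exposure is exact, so no
person-time approximation is involved.

For aggregate trials total person-time uses the standard approximation
`FU × N − 0.5 × FU × events` (each incident event contributes on
average half the follow-up). Within the trial, full follow-up
(`FU × N`) is apportioned across (sex, age-band) cells by the
reconstructed weights, and the event-driven deficit
(`0.5 × FU × events`) is apportioned proportionally to each cell's
*expected event share* rather than its population share. The reason is
mechanical: events concentrate in high-rate (older) cells, which
therefore lose more exposure to early events than low-rate cells. Flat
apportionment systematically overstates person-time in exactly the
cells with the highest rates and inflated our expected counts by ~5%
at the event proportions the generator produces; share-based
apportionment reduces the aggregate-vs-IPD gap to well under 3% while
leaving the trial-level person-time total exactly equal to the formula
above. Mid-band ages (`a + 0.5`) are used for rate lookup.

### Per-trial intervals (`oe_ratio`)

The 95% interval composes two independent uncertainty sources by Monte
Carlo: the observed count is drawn from its Jeffreys Poisson posterior
`Gamma(O + 0.5, 1)` (proper at `O = 0`, where the ratio's point
estimate is 0 but the upper limit is positive), and the expected count
from multivariate-normal draws of the rate-model coefficients. The
interval is the 2.5–97.5 percentile range of the sampled ratios. This
is standard objective-Bayes sampling machinery; with 10,000 draws the
Monte-Carlo error on the limits is negligible relative to their width,
and every draw stream is seeded.

### Pooling (`pool_oe`)

Condition-level pooling fits `O_i ~ Poisson(E_i · exp(θ_i))`,
`θ_i ~ N(θ, τ²)` by maximum marginal likelihood. The integral is
evaluated by adaptive Gauss–Hermite quadrature (default 32 nodes,
recentred per trial at the conditional mode and rescaled by the local
curvature), so the fit is deterministic and testable against a dense
grid search of the same likelihood — one of the package's acceptance
oracles. τ = 0 lies on the boundary; the boundary fit (a plain Poisson
margin) is compared explicitly against the interior optimum. The
pooled ratio is `exp(θ̂)` with a Wald interval on the log scale; a
parametric bootstrap interval is available. We use quadrature rather
than MCMC because the model has one linear parameter and one variance
component: quadrature is exact to machine precision at this size,
reproducible, and fast enough to rerun hundreds of times in the
calibration studies.

### Multimorbidity (`count_comorbidities`, `mm_sae_association`)

Multimorbidity is counted from concomitant medications mapped to 21
broad chronic-condition categories, because medical history is often
redacted in shared trial data while medication lists are not. The
mapping is a user-supplied TSV (token → category, with an exclusion
list for drugs whose indications are too diverse to be informative,
e.g. tricyclic antidepressants); the package ships a *synthetic* map —
the real drug-code lists live behind governed data access and are not
reproduced. The count is the number of distinct categories, excluding
the index condition by default (a comorbidity is a condition *other*
than the one under trial); a flag includes it for sensitivity analyses,
since reasonable people disagree.

Within-trial multimorbidity–SAE associations are Poisson regressions of
the first-SAE indicator on the count, adjusted for linear age
(within-trial age ranges are narrow; FP flexibility is unnecessary and
unstable at trial sizes), with `log(time at risk)` offset, fitted per
sex and only where the sex stratum has ≥ 20 SAEs — the filter is per
sex, never per trial. Trial coefficients are pooled by REML
random-effects meta-analysis.

## The synthetic-data generator

There is no public cohort or trial IPD at desk scale: the routine-care
data sit in a governed safe haven and trial IPD behind repository
agreements. The generator therefore emulates the *statistical
structure* the method assumes, with known ground truth, and all
validation is against that truth.

* **Event process**: constant per-person hazard, exponential event
  times, censoring at a fixed horizon (182 days — six months, matching
  the typical 26-week trial follow-up). This matches the Poisson
  person-time analysis model, so parameter recovery is interpretable.
* **Hazard**: log-linear in age (log RR 0.405 per decade, i.e. RR 1.5),
  sex (female log RR log 0.85) and multimorbidity count (log RR 0.2 per
  condition), anchored at 0.30 events/person-year for a 70-year-old man
  with no comorbidities — a realistic urgent-admission/death rate for a
  COPD register.
* **Ages**: truncated normal on [18, 100], rounded to integer years,
  with condition profiles mirroring a real national register (COPD:
  mean 69.1, SD 11.6; type 2 diabetes 65.3/13.0; hypertension
  67.0/12.9; asthma 45.6/22.9; dementia 82.1/9.0) and prevalences set
  from register sizes relative to a 2.3M population.
* **Multimorbidity**: Poisson with mean `1.5 + 0.4·(age−50)/10`,
  floored at 0 — this creates the age–multimorbidity confounding that
  the dual standardization must disentangle. Each count materialises as
  medication tokens consistent with the shipped synthetic map.
* **Trial selection**: eligibility bounds on age, inclusion weight
  `exp(mm_penalty × mm)`, and a planted hazard multiplier θ applied to
  enrolled participants — θ is the ground-truth O/E ratio the inference
  must recover. Only one index condition per trial; cohort members may
  hold several condition flags.

What the generator does **not** emulate: diagnostic coding noise,
deprivation and ethnicity gradients, non-proportional hazards, seasonal
admission patterns, within-trial dropout beyond censoring, and
between-person frailty beyond the multimorbidity count. Passing the
validation studies therefore shows the *estimators* are correct and
calibrated under the stated model, not that the model captures every
feature of real routine-care data.

## Validation studies and problem sizes

The replicated studies (exported as `simulate_oe_study`,
`simulate_dual_study`, summarised by `summarize_oe_study`) run on a
100,000-person single-condition (COPD-profile) cohort:

* **Null calibration** — 200 replicates of 20 representative trials of
  250 participants, aggregate route with 1,000 interval draws: the
  pooled 95% interval covers 1 in 92–98% of replicates and per-trial
  intervals cover the truth at close to nominal rate.
* **Recovery** — planted θ = 0.5 and θ = 0.85 across 50 trials of 500:
  the pooled ratio lands within ±0.05 of truth, and θ = 0.85 is
  distinguished from 1 (interval excludes 1) in essentially all
  replicates at this size.
* **Decomposition** — 60 replicates of 12 trials of 400 under
  multimorbidity-biased selection (`mm_penalty = −0.5`): with θ = 1 the
  age/sex-standardized pooled ratio falls to ~0.84 while the
  multimorbidity-adjusted ratio returns to ~1; with θ = 0.8 the
  adjusted ratio recovers ~0.8 with the age/sex ratio below it. This is
  the package's central qualitative property: selection on
  multimorbidity masquerades as a low O/E ratio, and conditioning on
  the count removes exactly that component.
* **Model recovery** — fitted FP age-curves within 0.05 log-RMSE of the
  generating marginal hazard over ages 40–90; trial-pooled
  multimorbidity coefficients within 2 pooled SE of the planted 0.2 and
  of the cohort-fitted coefficient.

These sizes keep each study in the minutes range on a single CPU while
leaving Monte-Carlo error well inside the tested bands.

## Numerical choices, degenerate inputs, tie-breaks

* Zero events in a rate-model stratum is an explicit error, never a
  silent zero rate; all-censored strata likewise.
* `expected = 0` makes the O/E ratio undefined and errors with
  guidance.
* A single trial "pools" to its own ratio with τ = 0 and a flag.
* Zero arm counts get a 0.5 continuity correction on both arms,
  flagged; the two-group SE is `sqrt(1/O₁ + 1/O₂)`.
* Degenerate age bounds (min = max) give a point-mass band; a missing
  age SD is imputed as `(max − min)/4` and flagged.
* FP candidates that fail to converge are skipped, never fatal; ties in
  the deviance search resolve to the first (lowest-power) candidate.
* All Monte-Carlo streams take explicit seeds; replicate r of a study
  derives its seed as `seed + r`, so studies are reproducible and
  individually re-runnable.

## Known limitations

* The aggregate route inherits everything the four summary statistics
  cannot express (bimodality, skew); the uniform fallback flags the
  detectable cases.
* Person-time apportionment within aggregate trials is an
  approximation; IPD trials bypass it entirely.
* Wald intervals on the pooled log-ratio approximate the credible
  intervals a fully Bayesian treatment would give; with very few trials
  per condition (k ≤ 3) they can be anti-conservative when τ > 0.
* The medication-based multimorbidity count is a surrogate; its
  measurement error attenuates the adjusted standardization, so "the
  ratio moved toward 1 after adjustment" is a lower bound on the
  multimorbidity contribution.
* Treatment arms are combined by default (appropriate when arm effects
  on SAEs are small, as the arm-level comparison machinery lets you
  check); for toxic interventions restrict to control arms via the
  pipeline flag.
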