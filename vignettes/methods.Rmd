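---
title: "Building and validating synthetic CVD risk-factor populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating synthetic CVD risk-factor populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National CVD risk-management policy questions — who would cross a treatment
threshold under a risk-based rule versus an age-based rule, and how many
events would treatment avert — require individual-level data carrying the
*joint* distribution of all the risk factors that enter a CVD risk
equation: age, sex, ethnicity, deprivation, smoking, diabetes, prior CVD,
lipid- and blood-pressure-lowering treatment, systolic blood pressure
(SBP), the total:HDL cholesterol ratio and family history of premature
CVD. No single dataset holds all of these for a whole country, and the
datasets that hold parts of them cannot be freely shared. `cvdsynth`
implements a pipeline that builds a *synthetic* national adult population
from data that can be obtained in practice:

1. an aggregated census cross-tabulation (age x sex x ethnicity x
   deprivation quintile, with per-smoking-category counts and small cells
   suppressed for disclosure control),
2. individual-level linked administrative records carrying disease and
   medication flags,
3. a large individual-level primary-care cohort with the measured
   biological variables, and
4. external stratum-level reference estimates with 95% confidence
   intervals.

Because the real national sources are access-restricted, the package also
ships a ground-truth world generator that emulates all four inputs from a
configurable known truth, so every run of the pipeline can be scored as a
parameter-recovery experiment.

## The procedure

**Demographic framework.** The census cross-tab is walked row by row.
Suppressed cells (counts 1-5 replaced by a sentinel) are resolved either
by a uniform draw on {1,...,5} — the censoring rule bounds the truth, and
with no further information a bounded uniform draw is the
least-assumption choice — or, when row totals are known, by a draw from
the feasible fill combinations (`total_constrained`). Rows with Unknown
ethnicity or deprivation are removed and their counts reallocated to the
known categories of the same age-band x sex margin proportionally to the
known counts, with largest-remainder rounding so all totals are conserved
exactly. Each counted individual then becomes one synthetic person: age
is drawn uniformly on the one-year band `[Y, Y+1)` (bands span 30-84;
the top band is `[84, 85)`), and sex, ethnicity and quintile are copied
deterministically. The resulting demographic margins equal the resolved
cross-tab cell for cell.

**Smoking.** Although smoking is part of the cross-tab, the default mode
redraws it per person by Monte Carlo from the stratum's smoking
proportions: smoking self-report is noisier and less stable over time
than the other census variables, so treating it as a sampled rather than
copied attribute is the more honest model. A `deterministic` mode copies
the counts instead and is the mode under which the marginal-exactness
property is asserted.

**Categorical risk factors.** Diabetes and prior CVD are strongly
associated, so they are sampled *jointly* from a four-category
conditional probability table (CPT: neither / diabetes only / CVD only /
both) estimated from the linked administrative records conditional on age
band, sex and ethnicity; the sampled category is then decoded into the
two booleans. Medication status (LL x BPL, four categories) is sampled
the same way conditional on age band, sex, ethnicity and prior CVD — so
disease assignment must precede medication assignment. A configuration
switch adds diabetes to the medication conditioning; the default follows
the narrower set because that is the conditioning the assignment step
actually needs, and the wider set thins the strata. CPT rows supported by
fewer than `min_cell = 20` records are re-estimated after dropping the
last conditioning variable, recursively, with the pooling depth recorded
per row; combinations never seen in the records resolve through the same
pooled hierarchy at assignment time. Sampling is inverse-CDF on a single
uniform per person with a fixed category order, which makes runs
reproducible seed-for-seed.

**Imputation synthesis.** SBP, TC:HDL and family history are transferred
from the donor cohort by chained-equations imputation: the cohort is
appended to the synthetic population, the three targets are declared
missing on the synthetic rows, and the chain iterates over the targets in
a fixed order (SBP, TC:HDL, family history) for `n_iterations = 10`
passes. Continuous targets use predictive mean matching (PMM) with
Bayesian parameter draws and `k = 5` donors, so every imputed value is a
real observed value and the synthetic support never leaves the observed
support; the binary target uses logistic draws from the posterior of a
logistic fit (with a ridge-penalised fallback under separation). Because
missingness lives only on synthetic rows, every model is fit on the
cohort rows alone; sharding the synthetic rows for prediction is
therefore exact and bounds the working set by shard + cohort. Ten
iterations with no formal convergence diagnostic is a deliberate fixed
budget: the chain's only coupling is through the targets predicting one
another, and in practice the completed distributions are stable after a
few passes. `m > 1` returns independently completed tables; the intended
use is one imputation per replicate population rather than pooled
inference, so `m = 1` is the default and no Rubin's-rules pooling is
provided.

**Post-hoc adjustment.** Where independent reference sources disagree
with the imputed stratum means (the donor cohort is risk-biased, and its
blood pressures show digit preference), the per-stratum (age band x sex)
mean is shifted additively onto the reference target. An additive shift
preserves the within-stratum spread exactly, which is the point: the
variability developed during imputation is retained. A physiological
floor (60 mmHg for SBP, 1.0 for TC:HDL) clamps impossible values after
large negative shifts, with clamped counts reported; multiplicative or
higher-moment re-shaping is deliberately out of scope. Both adjusted and
unadjusted populations are returned so downstream sensitivity analyses
can use either.

**Validation.** Internal validation compares the synthetic population
against the sources that generated it: deterministic stages must agree
exactly (zero absolute difference), Monte Carlo stages within four
binomial/normal standard errors — the sources validate such comparisons
visually, but automated tests need a numeric criterion, and 4 SE is a
strict one. External validation compares stratum values against
independent reference estimates and flags 95%-CI membership, with
explicit re-aggregation maps (e.g. Chinese + OtherAsian -> "Asian")
where the reference uses coarser categories. Ethnic contrasts are
summarised as age- and sex-adjusted odds ratios from logistic regression;
with no adjusters this reduces exactly to the 2x2 cross-product ratio,
which the tests exploit as a closed-form oracle. Replicate populations
built from derived seeds quantify the Monte Carlo uncertainty of any
summary; relative spread shrinks with stratum size.

## The ground-truth world

`world_config()` defaults to the packaged national marginal tables
(`nz_margins_2013`): five age bands (30-44, 45-54, 55-64, 65-74, 75-84)
with their published sizes, percent male, ethnicity and deprivation
composition, smoking categories, diabetes, prior-CVD, LL and BPL
prevalences, SBP and TC:HDL means/SDs and family-history prevalence, plus
adjusted prior-CVD odds ratios by ethnicity. Joint structure that
marginal tables cannot identify is set by explicit association
parameters, chosen once as epidemiologically plausible values: diabetes x
prior-CVD odds ratio 3, LL x BPL odds ratio 4, and treatment-given-CVD
odds multipliers of 6. Baseline logits are solved numerically so the
configured band marginals still hold exactly in expectation after these
offsets are mixed in. The donor cohort is drawn with weights favouring
older bands (0.4 to 2.0 across the five bands), diabetes (x2) and
Maori/Pacific/Indian ethnicity (x1.5), and 30% of its SBP readings are
rounded to the nearest 10 mmHg, emulating the selection bias and digit
preference of a real risk-assessment cohort.

What the generator does *not* emulate: within-band age gradients of the
binary risk factors (prevalences are constant within a band, stepping at
band boundaries), sex gradients in SBP (default gap 0, configurable),
household/geographic clustering, and measurement error other than SBP
digit preference. Passing recovery tests therefore demonstrate that the
pipeline preserves the statistical structure it is given — not that real
national data have that structure.

## Numerical choices

* Largest-remainder integer allocation resolves proportional
  reallocation; ties break by canonical category order, so conservation
  is exact and deterministic.
* Joint 2x2 probabilities from two margins and an odds ratio use the
  Plackett quadratic root, clamped to the Frechet bounds.
* PMM matching sorts donor predictions once and samples one of the `k`
  nearest within a `2k` window located by `findInterval`; this is O(n)
  per target and keeps 200,000-person imputations in seconds.
* Degenerate predictors (constant columns) are dropped with a message;
  rank-deficient fits zero the aliased coefficients.
* Suppressed census cells are carried as `NA`, never as zero; writing
  restores the sentinel string.
* All stochastic stages consume a single seeded RNG stream in documented
  order (strata in file order, persons in id order); identical seeds give
  byte-identical outputs.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so a
full check completes in about a minute on one core: 100,000-person
single-band recoveries for the categorical prevalences, a 200,000-person
population with a 20,000-record cohort for the imputation/adjustment
recovery, and 200,000 persons for the odds-ratio recovery. The pipeline
itself scales linearly and handles full national sizes (a few million)
via the sharded imputation path.

## Known limitations

* Suppressed-cell resolution is unbiased only if true suppressed counts
  are uniform on 1-5; if the truth skews low the resolved population
  slightly overcounts (the `total_constrained` strategy removes this when
  row totals are available).
* The adjusted odds ratio is fitted with a linear age term; because the
  generator's baselines step at band boundaries, a small residual
  confounding bias (a few percent) relative to the embedded conditional
  effect is expected.
* Strata with no cohort donors at all inherit donors through the model's
  covariate structure rather than from like-for-like strata; such strata
  are surfaced by a warning at stacking time and should be read with the
  external validation, not in spite of it.
* The engine assumes the three imputation targets are the only missing
  fields; it is a synthesis tool, not a general missing-data imputer.
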