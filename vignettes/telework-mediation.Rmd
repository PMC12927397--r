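---
title: "Interventional-effects mediation for telework and mental health: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional-effects mediation for telework and mental health: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(telemediate)
```

## The estimands and why interventional effects

The scientific question is how telework frequency affects four mental-health
outcomes, and how much of that effect runs through six job characteristics.
With multiple mediators, the classic natural (pure) effects require knowing
the causal ordering among the mediators — whether workload drives emotional
load or vice versa — which is exactly what is unknown here. Interventional
(in)direct effects sidestep this: the indirect effect through mediator
$M_s$ is defined by shifting the *marginal* distribution of $M_s$ from its
no-telework to its telework-level form, and the joint indirect effect by
shifting the joint mediator distribution. No structure among the mediators
is assumed; in exchange, per-mediator indirect effects do not generally sum
to a "remainder-free" decomposition under interactions — which is why the
fitted models contain none (see below).

Under linearity these estimands reduce to products of regression
coefficients. Writing $A_z$ for the dummies of exposure level
$z \in \{1,2,3\}$ (monthly, weekly, daily vs none), $M_s$ for the six
mediators and $C_j$ for the eight confounders, the package fits by OLS, on
one common set of complete-case rows:

$$E(Y_q \mid A, C) = \delta_{0q} + \textstyle\sum_z \delta_{1zq} A_z + \sum_j \delta_{2jq} C_j$$
$$E(Y_q \mid A, M, C) = \beta_{0q} + \textstyle\sum_z \beta_{1zq} A_z + \sum_s \beta_{2sq} M_s + \sum_j \beta_{3jq} C_j$$
$$E(M_s \mid A, C) = \theta_{0s} + \textstyle\sum_z \theta_{1zs} A_z + \sum_j \theta_{2js} C_j$$

giving direct $= \beta_{1zq}$, indirect through $M_s$
$= \theta_{1zs}\beta_{2sq}$, joint indirect $= \sum_s \theta_{1zs}\beta_{2sq}$
and total $= \delta_{1zq}$.

**Assumptions.** The usual mediation conditions: no unmeasured
exposure–outcome, exposure–mediator or mediator–outcome confounding given
$C$; exposure precedes mediators precede outcomes; and correctly specified
linear models without exposure–mediator or mediator–mediator interactions.
None of these is verifiable from the data, and the cross-sectional origin
of the survey makes temporality an assumption, not an observation.

**Binary outcomes.** Anxiety and depression are fitted by the same OLS
machinery (a linear probability model), so every coefficient is a risk
difference; the reporting layer renders them additionally as percentages
($100\times$). The linear probability fit is deliberately unweighted: its
model-based standard errors would be wrong under heteroskedasticity, but
all inference here comes from the bootstrap, which is valid regardless.

## The decomposition identity as a correctness oracle

For nested OLS fits on identical rows, omitted-variable algebra makes

$$\delta_{1zq} = \beta_{1zq} + \sum_s \theta_{1zs}\beta_{2sq}$$

*algebraically exact*, not approximate: regressing the omitted block
($M$) on the included regressors and substituting recovers the short-model
coefficients. `verify_decomposition_identity()` checks
$\max_{q,z} |\delta_{1zq} - \beta_{1zq} - \sum_s \theta_{1zs}\beta_{2sq}|$
after every fit against a tolerance of `1e-8` (observed gaps are of order
`1e-16` on the study scales; the tolerance leaves five orders of headroom
for ill-conditioned designs). A violation means the three model sets were
not fitted on the same rows or regressor sets — a bug, not a statistical
finding — and is raised as an error.

```{r identity}
rows <- simulate_analysis_rows(generator_config(n = 800), seed = 1)
fits <- fit_path_models(rows)
verify_decomposition_identity(fits)
```

## Survey coding and scoring

* **Telework**: seven questionnaire answer strings map onto levels 0–3;
  matching is exact after trimming and case-folding, and an unrecognised
  string is an error rather than a guess.
* **GAD-7 / PHQ-9**: items arrive coded 1–4 on file and are recoded to 0–3
  (`recode_offset = -1`, configurable for files already coded 0–3), summed,
  and dichotomised at sum ≥ 10. The GAD-7 threshold is the instrument's
  published screening cut-off; the PHQ-9 threshold is not fixed by the
  study's variable table, so the same widely used ≥ 10 cut-off is the
  default and is configurable in `inst/extdata/scales.yaml`. The
  `sensitivity = TRUE` mode carries the raw 0–21 / 0–27 sum scores through
  the pipeline as additional continuous outcomes.
* **BAT-12, UWES-3, SIMPH subscales**: item means on the 1–5 response
  scale. Instruments are data, not code: every scale is defined in a YAML
  document (items, range, scoring rule, threshold).
* **Work skill**: the six job categories collapse to three levels
  ({1,2}, {3,4}, {5,6}); the default binary coding (level 3 vs below)
  matches the published descriptive table and keeps the confounder vector
  at eight columns; a three-level dummy mode exists for sensitivity.
* **Inclusion**: employed respondents aged 18–64, bounds inclusive and
  configurable (the source describes the range as "between 18 and 64
  years"; its flow diagram says "outside 18–65" — we follow the text).
  The exclusion tally is sequential and mutually exclusive (employment
  first, then age), because the published flow counts overlap and cannot
  be reproduced exactly.
* **Missingness**: complete-case only. Any missing analysis variable —
  including a single item inside a multi-item scale — drops the row; no
  imputation anywhere.
* **Reliability**: standardised Cronbach's alpha
  $k\bar r/(1+(k-1)\bar r)$ from mean pairwise inter-item correlations is
  descriptive output only; no item is dropped on its basis.

## Bootstrap inference

The resampling unit is the respondent (no strata or clusters are described
for this design). Per replicate, all three model sets are refitted and all
estimands recomputed, so every CI reflects the full estimation pipeline.
Defaults follow the study protocol: `B = 1000`.

Numerical and procedural choices, each configurable:

* **CI**: percentile method (2.5th/97.5th replicate percentiles, linear
  interpolation between order statistics — R's type-7 quantile). A
  normal-approximation interval (estimate ± 1.96·SE) is available by flag,
  since SEM tooling commonly defaults to z-intervals and the source does
  not say which was used.
* **p-values**: two-sided normal approximation from `z = estimate / SE`
  by default; a percentile-based p (twice the smaller tail proportion
  beyond 0) by flag. Both constructions are recorded in the output
  attributes rather than silently chosen.
* **Degenerate replicates**: a resample that loses an exposure level or
  produces a singular design is *redrawn*, not dropped, keeping B fixed;
  each replicate slot owns a deterministic chunk of 50 seeds from the root
  seed, so results are independent of execution order and bit-identical
  across runs. Exhausting a slot's budget is an error reporting the
  failure rate (it signals data too sparse to bootstrap, e.g. a handful of
  daily teleworkers).
* **Holm families**: "per outcome" is read as all 27 estimands of one
  outcome (9 effect types × 3 contrasts) forming one family; a
  per-outcome-per-contrast family is available because the source does not
  enumerate the family. Adjusted significance uses α = 0.05.

## What the synthetic generator emulates — and what it does not

`generator_config()` defines a population whose *estimable structure is
exactly the fitted model*: confounders from the published sample marginals
(65.3% female, 83.6% bachelor+, 94.4% permanent, 66.4% chronic illness,
79.6% functional limitation, 39.3% high work skill, support quality with
mean 2.10/SD 0.70, age uniform on the observed 23–64 range), exposure from
a multinomial logit on the confounders calibrated to the observed telework
shares (≈37/10/50/3%), mediators and outcomes from the linear models run
forward. Default effect magnitudes echo the order of the published
estimates (continuous direct effects ≈0.1–0.2, per-mediator indirect
effects ≈0.01–0.05), so recovery tests run at realistic signal-to-noise.
These marginals describe the analysed complete-case sample, not the
Belgian source population.

Two generation modes differ in one deliberate way:

* `simulate_analysis_rows()` emits the *exact* structural draws (Gaussian
  mediators, unbounded). This is the mode for parameter recovery and
  coverage validation: the configured coefficients are the exact truth.
* `simulate_survey()` writes a raw survey file with item-level responses.
  A continuous mean cannot be reproduced by integer items, so scores are
  snapped to the attainable grid (multiples of $1/k$, clamped to the
  response range) *before* outcome generation; the emitted items then
  reproduce every score exactly, and the binary outcome draws decide
  whether the emitted GAD-7/PHQ-9 sums land above or below the threshold.
  Snapping perturbs the mediator scale by at most $1/(2k)$, so the truth
  table for this mode is flagged approximate.

Binary outcomes are generated under the same linear probability structure
the estimator assumes, with probabilities clipped to [0.01, 0.99]; default
coefficients keep the realised clipping rate near $10^{-5}$, and a rate
above 0.1% is an error because it would silently bias the configured
truth. Confounders are sampled independently (only marginals are
published); consequently the generator does not emulate real-world
covariate correlation, nor attrition, recruitment waves, or informative
nonresponse — a passing recovery test shows the estimator is correct under
its own assumptions, not that those assumptions hold in any real cohort.
An optional uniform `missing_rate` blanks item cells to exercise the
complete-case filter.

## Validation design and problem sizes

The test suite validates in four tiers, with all simulation sizes chosen to
keep Monte-Carlo error well below the tolerances being asserted:

1. **Exact oracles**: exhaustive enumeration of all $4^7 = 16384$ GAD-7
   response patterns against a brute-force accumulator; Holm against a
   literal sequential-rejection oracle on 1000 random families (size ≤ 12);
   OLS against an independent SVD pseudo-inverse solve (tolerance 1e-10).
2. **Analytic identities**: the decomposition identity on every generated
   dataset (tolerance 1e-8); location invariance of effects under
   confounder shifts; exact ×100 scaling of risk differences.
3. **Stochastic recovery**: at n = 5000 and B = 200 over 100 repetitions,
   the pooled share of (repetition × estimand) checks with
   |estimate − truth| ≤ 3 bootstrap SEs must reach 0.99 (nominal content of
   a 3-SE band is 0.997; the pooled form is used because requiring ≥99/100
   *per estimand simultaneously* across 108 estimands has only a few
   percent probability even for a perfect estimator).
4. **Coverage**: under a null-effect configuration at n = 2000, B = 200,
   500 repetitions, the 95% percentile CI for the weekly joint indirect
   effect must cover 0 within 3 binomial SEs of 0.95.

`scripts/acceptance.R` re-runs scaled versions of these (30 recovery and
200 coverage repetitions) plus a full B = 1000 pipeline at n = 2323 — the
published sample size — and writes the resulting numbers as JSON.

## Known limitations

* Percentile and normal intervals only; no BCa or studentised bootstrap.
* No exposure–mediator or mediator–mediator interactions; adding them
  changes the estimands and the product-of-coefficients form.
* The linear probability model can in principle predict outside [0,1] for
  covariate patterns far from the bulk; effects remain valid risk
  differences, but individual fitted probabilities should not be
  interpreted at the extremes.
* No survey weights, calibration, or multiple imputation: estimates
  describe the complete-case analysed sample.
* Covariates enter on their raw scales (slopes, and hence all reported
  effects, are invariant to location shifts; intercepts are not
  interpreted).
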