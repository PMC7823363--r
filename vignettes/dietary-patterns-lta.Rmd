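---
title: "Deriving dietary patterns and their usual prevalence from two-day recalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving dietary patterns and their usual prevalence from two-day recalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short-term dietary instruments such as 24-hour recalls capture a single
day of intake, but dietary *patterns* are habitual constructs. With two
recall days per person, any pattern classification based on one day
mixes true between-person differences with large day-to-day
(within-person) variability: for most food groups the intra-class
correlation across two recall days sits well below 0.7, meaning more
than 30% of the observed variation is within-person. `dietlta`
implements two complementary model-based answers:

1. a **latent class model (LCA)** on intakes averaged over the two
   days, and
2. a **latent transition model (LTA)** that keeps both days, models the
   day-1 pattern and the day-1 to day-2 transition explicitly, and from
   the transition probabilities derives the **usual prevalence** of each
   pattern as the stationary distribution of the implied Markov chain.

Both models take age and sex as *concomitant variables*: class
membership (and transition) probabilities are multinomial-logistic
functions of the covariates, not constants.

## Data preparation

Food-group intakes (grams/day) are prepared as follows, in
`filter_rare_food_groups()`, `average_days()`, `categorize_intake()`
and `compute_icc()`:

* **Rare-group exclusion.** A group whose fraction of person-days with
  zero intake is at least the threshold (default 0.95) is excluded. The
  boundary counts as rare: nil on exactly 95% of days means exclusion.
* **Ordinal coding.** Each retained group is coded 0 (nil), 1 (positive
  but at or below the consumer median) or 2 (above it). The median is
  computed over positive amounts only ("among the consumers"), pooling
  both recall days so day-1 and day-2 indicators share one cutoff — a
  prerequisite for the measurement-invariance constraint below. Ties at
  the median code as category 1 ("equal or below"). For the LCA branch,
  the averaged amounts are re-coded against medians of the averaged
  consumer amounts (a separate median map), mirroring the same rule on
  the averaged data.
* **ICC.** Day-to-day variability is summarized per group by the
  one-way random-effects ANOVA ICC with two measurements per subject,
  `(MSB - MSW) / (MSB + MSW)`, floored at zero. No estimator is imposed
  by the data themselves; this is the standard choice for replicate
  recalls and is documented so users can compare with alternatives.
* **Complete cases.** Subjects must have both recall days; there is no
  imputation. Missing (subject, day, group) records are treated as
  explicit zeros, the natural encoding for episodically consumed foods.

## The latent class model

With `K` classes, `J` items and `C = 3` ordinal categories, subject `i`
with covariates `x_i` contributes

    L_i = sum_k P(C = k | x_i) * prod_j rho[j, k, y_ij]

where `rho[j, k, c]` are class-conditional category probabilities and
`P(C = k | x)` is a softmax of `beta (1, x)'` with class `K` as
reference. The indicators are three-category ordered variables; with
three categories a per-class cumulative-threshold parameterization is
saturated and equivalent to the unrestricted categorical `rho` used
here, so nothing is lost by parameterizing `rho` directly.

`lca_em_fit()` runs EM: the E-step computes posterior class
probabilities; the M-step updates `rho` by posterior-weighted category
proportions (closed form) and `beta` by a warm-started BFGS
maximization of the expected complete-data log-likelihood. Because the
`beta` update only needs to *improve* its objective, each iteration is
a generalized-EM step and the log-likelihood is monotone.

## The latent transition model

The LTA keeps both days and adds a first-order Markov structure: the
day-2 class depends on the day-1 class and the covariates,

    L_i = sum_k sum_l P(C1 = k | x_i) P(C2 = l | C1 = k, x_i)
          * prod_j rho[j, k, y_ij1] * rho[j, l, y_ij2]

with three structural choices:

* **Measurement invariance.** One `rho` array serves both days — the
  patterns mean the same thing on day 1 and day 2. This is enforced
  structurally (the M-step pools category counts over both days), not
  merely tested.
* **Constrained concomitant effects** (default). The covariate slopes
  of the day-1 membership logit and the destination slopes of the
  transition logit are one shared block, maximized jointly — the effect
  of age and sex is the same on both days. The transition intercepts
  `a[k, l]` remain free per prior state. The unconstrained variant
  (separate `gamma`) is available via `constrain_covariates = FALSE`
  and costs `(K - 1) * p` extra parameters. "Effects equal across
  days" admits more than one formalization (equality of the
  destination slopes with the day-1 membership slopes, as here, or
  equality constraints across transition rows); the shared slope block
  is the default and the alternative is reachable through the flag,
  and the constrained maximized log-likelihood can never exceed the
  unconstrained one.
* **Exhaustive path enumeration.** With two occasions the E-step
  enumerates all `K^2` (day-1, day-2) paths directly; no
  forward-backward recursion is needed, and the joint posteriors
  `q_i(k, l)` are exact.

Labels are aligned across random starts and relabeled canonically by
decreasing day-1 class size; the reference class of every logit is the
last (smallest) class after relabeling. Age is standardized internally
for optimizer stability and all coefficients are reported back on the
years scale. `membership_odds_ratios()` reports `exp(beta1)` with Wald
intervals from the observed information matrix (a central-difference
Hessian over the full packed parameter vector, item-response
probabilities included as logits); if that matrix is singular the
function falls back to a nonparametric bootstrap (default 200
replicates) with a warning.

Relative entropy for the LTA is computed on the joint posterior over
the `K^2` latent paths, normalized by `N log K^2`.

## Usual prevalence

Writing `P(x)` for the covariate-conditional transition matrix and
`S_1` for the day-1 prevalence vector, day-`d` prevalence follows
`S_d = S_1 P^(d-1)` (`propagate()`). If `P` is **regular** — some power
of it is strictly positive, checked up to the Wielandt bound
`(K - 1)^2 + 1` — the chain has a unique stationary vector
`S_inf = S_inf P`, interpreted as the prevalence of habitually followed
patterns once day-to-day noise has been integrated out
(`stationary()`, power iteration cross-checked against the left
eigenvector).

Because transitions are covariate-conditional, there are two defensible
cohort summaries and the averaging order is a genuine choice:

* **individual** (default): solve each subject's `S_inf,i` from
  `P(x_i)` and average — this respects per-subject chains;
* **aggregate**: form the cohort-level matrix first (rows averaged with
  day-1 posterior weights, `aggregate_transition_matrix()`) and take
  its stationary vector.

`usual_prevalence()` reports either, next to `S_1` and `S_2`. The two
orders agree exactly on covariate-homogeneous cohorts and differ in
general; a cohort-level printed matrix need not have the
covariate-averaged stationary vector as its own stationary vector, so
the two summaries should be read as answering slightly different
questions. In the pipeline's prevalence table the `s2` column is the
model-implied `S_1 P_agg` (so the report is internally consistent with
the propagation identity), and the measurement-updated day-2 posterior
prevalence is reported separately as `s2_posterior`.

Logit-parameterized transition matrices have strictly positive entries,
so per-subject regularity holds automatically at power 1; the check is
still enforced, and matrix-only inputs (e.g. a published transition
table) are validated before `stationary()` will touch them.

## Model selection

`fit_grid()` sweeps a class range under a shared multiple-start
protocol and tabulates log-likelihood, parameter count, AIC
(`-2LL + 2p`), BIC (`-2LL + p log N`) and relative entropy per `K`. The
automatic flag is minimum BIC; the full table is returned because the
number of patterns is usually chosen by weighing BIC against
interpretability and entropy rather than by a single number.
Non-convergence is reported per row, never silently dropped. Parameter
counts are asserted against the length of the packed free-parameter
vector actually optimized: `J K (C-1) + (K-1)(1+p)` for the LCA, plus
`K (K-1)` transition intercepts (plus `(K-1) p` if unconstrained) for
the LTA.

## The synthetic-data generator

No survey data ship with the package; `generator_config()` /
`generate_population()` produce cohorts with known truth that exercise
every assumption the models make: uniform ages 18–84, a configurable
male proportion (default 0.473), day-1 classes from a multinomial logit
with age and sex effects, day-2 classes from covariate-conditional
transition rows, and class-conditional item responses identical on both
days. `true_usual_prevalence()` integrates the stationary vector of the
true transition matrix over the covariate distribution (trapezoid rule
on a 201-point age grid crossed with sex) — the recovery target for the
whole pipeline.

The default configuration (`default_config()`) uses 28 items with nil
propensities spanning roughly 10–90%, per-year age log-odds of -0.052
and -0.083 and male log-odds near 1.8 for the two less-healthy patterns
against the healthier reference (so older women concentrate in the
reference class), day-1 shares (0.40, 0.27, 0.33) at the covariate
mean, and a transition matrix with diagonal (0.85, 0.80, 0.90) at the
covariate mean. The smallest transition entries are kept at 0.04–0.08
by design: per-subject stationary vectors are extremely sensitive to
near-zero transition rates, and rates an order of magnitude smaller are
not identifiable from two occasions at cohort sizes in the low
thousands — a limitation of the two-day design itself that users should
keep in mind when reading published near-zero transition estimates.

The optional continuous layer generates gram amounts rather than
categories: per (item, class) a consumption probability and a gamma
amount distribution, plus two persistence components — a per-subject
log-normal intake level held fixed across days (`subject_sd`) and a
probit correlation between the two days' consumption indicators
(`consume_icc`). Without these, amounts are conditionally independent
across days given the class and no parameterization can push the
two-day ICC much above 0.2; with them the default items span ICCs of
roughly 0.05–0.7, comparable to published recall data, while marginal
nil fractions stay at their targets. What the generator does *not*
emulate: survey design (strata, clusters, weights), seasonality,
weekday/weekend structure, misreporting, and item-level correlations
beyond those induced by the latent class — so passing recovery tests
demonstrates correctness of the estimation machinery under the model's
own assumptions, not robustness to violations of them.

## Numerical choices

* EM convergence: relative log-likelihood change below `1e-8`
  (`|ll - ll_old| <= tol (|ll_old| + 1)`), capped at 1000 iterations;
  non-convergence flags the result.
* Random starts: `rho` from flat Dirichlet draws, logit coefficients
  from N(0, 0.2); default 20 starts (within the conventional 10–100
  range for these models), all seeds derived reproducibly from one
  master seed; per-start log-likelihoods are kept in the fit.
* Probability floor `1e-6` on `rho` during EM, applied as the *exact*
  constrained M-step maximizer (water-filling), so monotonicity
  survives the floor; reported estimates are the un-floored
  posterior-weighted proportions.
* Modal assignment breaks posterior ties toward the lowest class index
  and logs the count.
* Label alignment between solutions minimizes the total absolute
  difference of `rho` over all class permutations — the exact
  assignment optimum at these sizes (`K <= 7`).
* Stationary distributions: power iteration from uniform, tolerance
  `1e-12`, cross-checked against the eigenvector route; per-subject
  chains use an equivalent direct linear solve for speed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script work at deliberately modest,
fixed sizes chosen once as realistic desk-scale study conditions:
recovery cohorts of N = 3000 with J = 10 items and K = 3 classes,
confidence-interval coverage over 100 replicates of N = 400 two-class
cohorts, BIC selection over 20 replicates of N = 2000, and brute-force
likelihood oracles on instances of up to 6 subjects and 2 items where
exhaustive enumeration is exact.

## Known limitations

* Two occasions only; longer panels (general hidden-Markov structure)
  and mover–stayer variants are out of scope.
* No survey weights or design-based variance; published survey numbers
  derived under complex sampling are not reproducible here, and the
  package makes no attempt to.
* One-step (joint) estimation of the concomitant model; three-step
  bias-adjusted classification approaches are not implemented.
* Small transition probabilities are weakly identified from two days,
  as discussed above; treat per-subject stationary vectors accordingly.
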