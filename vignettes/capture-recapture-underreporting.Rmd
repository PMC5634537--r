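---
title: "Methods: two-list capture-recapture for underreported law-enforcement-related deaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-list capture-recapture for underreported law-enforcement-related deaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crvital)
```

## The estimation problem

Official US mortality statistics identify deaths caused by law-enforcement
agents through the ICD-10 "legal intervention" codes. A death only receives
such a code if the certifier's narrative makes police involvement visible to
the coder; when it does not, the record is coded to assault, undetermined
intent, accident or a natural cause, and the death cannot be found by a
registry query. News-media-derived registries capture a different, also
incomplete, subset of these deaths. `crvital` treats the two sources as a
two-list capture-recapture system: the overlap pattern identifies the number
of deaths missed by both.

## The model

For stratum $s$ (calendar quarters by default) let $n_{10}$, $n_{01}$,
$n_{11}$ be the counts captured by the media list only, the registry only,
and both. The three observed cells are modelled as independent Poisson
counts with

$$\log \mu = \gamma_s + \beta_1 [\text{in media}] + \beta_2 [\text{in registry}]
  + \alpha\, [\text{in both}],$$

with list effects $\beta_1,\beta_2$ shared across strata and
stratum-specific intercepts $\gamma_s$ (the minimal identifiable stratified
model). $\alpha$ is the log cross-ratio between the two list memberships,
held fixed rather than estimated — with two lists it is not identifiable
from data, which is precisely why it enters as a sensitivity parameter. The
unobserved cell in stratum $s$ is $\hat n_{00,s} = \exp(\gamma_s)$ and the
population estimate is the observed total plus $\sum_s \hat n_{00,s}$.

Under $\alpha = 0$ and a single stratum the model is saturated and
reproduces the Lincoln–Petersen closed form $n_{10}n_{01}/n_{11}$; with a
nonzero offset the single-stratum solution scales by $e^{\alpha}$. Both
identities are enforced to $10^{-6}$ relative tolerance in the test suite,
with the closed form serving as an independent oracle for the model-based
fit.

**Intervals.** The 95% interval for $\sum_s \hat n_{00,s}$ is a Wald
interval on the log scale, with the variance obtained by the delta method
from the Poisson-fit coefficient covariance; the interval for the total adds
the observed count to each bound. In the single-stratum case this reduces to
$\hat n_{00}\exp(\pm 1.96\sqrt{1/n_{10}+1/n_{01}+1/n_{11}})$. This is the
only interval construction we found that reproduces the published
asymmetric intervals from the aggregate cells; the published totals' upper
bounds can differ from the aggregate closed form by one unit because the
original stratified fit is not fully specified, and the acceptance checks
carry that one-unit tolerance.

**Coverage.** Each list's coverage is its documented count divided by the
estimated total, with interval bounds order-reversed. Coverages are quoted
against the integer-rounded estimate and bounds — the scale on which results
are reported; this convention reproduces all published coverage figures
exactly.

## Cell construction and redistribution

Incidents that fail to link to any mortality record have unknown
classification status. They are assumed classified at the same rate as
linked incidents: `redistribute_unmatched(u, c, m)` adds
$\mathrm{round}(u\,c/m)$ (half-up) of them to the both-lists cell and the
remainder to the media-only cell. With the published tallies (95 unlinked,
444 classified of 991 linked) this gives the 43/52 split. Across quarters
the both-lists share is apportioned proportionally to quarterly unlinked
counts by largest remainders (ties to the earlier quarter), so the quarterly
cells always reconcile exactly with the media-list size and the registry's
annual total; a quarter whose registry total falls below its both-lists
cell raises a data-consistency error.

## Exclusion rules

The media list uses a broader definition than the ICD-10 category, so a
rule cascade trims it: deaths occurring the year after injury, friendly
fire, domestic violence by officers, vehicle deaths outside pursuit or
intentional transport injury, and custody deaths without a clear causal
mechanism (chokehold/Taser, withheld essential care) that were not ruled
homicides. The sources list these criteria without precedence; the cascade
order (year boundary → friendly fire → domestic violence → vehicle →
custody) is this package's convention so that every record gets one
canonical reason. The order cannot change *which* records are excluded,
only the reason label on records triggering several rules. Whether a
homicide ruling should override the vehicle rule is genuinely open; the
cascade applies the vehicle rule first. Narrative free text is never
parsed — flags must arrive as precomputed columns, keeping the engine
deterministic.

## Linkage conventions

Candidate pairs need an exact (case-insensitive) first name, surname
Levenshtein distance ≤ 2, and birth year within ±1 of `study_year − age`.
The national death index's proprietary "near match" is not public;
Levenshtein ≤ 2 is our configurable default, wide enough for the single
typos and transpositions the noise model produces. Among candidates, a
death date within 0–4 days after injury in the same state auto-matches; a
death more than 4 days *before* injury rejects the candidate; anything else
(later deaths, small pre-injury discrepancies, cross-state deaths) matches
only when the incident carries an external-confirmation flag, mirroring the
manual news-article verification step in the original workflow. Ties are
broken by minimal death-date distance and otherwise reported unmatched —
conservative, like manual review. On noise-free synthetic data with unique
names, linkage is exact; with default noise the truth-table sensitivity
exceeds 0.99.

## Misclassification analysis

A record is *misclassified* when none of its (up to 20) multiple-cause
codes falls in the legal-intervention set; the underlying cause is grouped
into the standard external-cause ranges (assault X95–Y09, undetermined
Y10–Y34/R99, suicide X60–X84, accident V01–X59, circulatory/respiratory
I00–J99, mental/behavioural F00–F99), evaluated in that order on the
normalized three-character category. Stratified tables use Clopper–Pearson
intervals and chi-squared tests without continuity correction, excluding
missing-covariate strata from the test.

Correlates are modelled by logistic regression with random intercepts for
counties nested in states, fitted by Laplace-approximate maximum likelihood
through `lme4::glmer` (adaptive quadrature is not available for
multi-grouping models there; the zero-variance limit, where the fit must
collapse onto ordinary logistic regression within $10^{-3}$, and parameter
recovery on synthetic data define correctness). Average marginal predicted
probabilities fix the focal variable at each level for every record,
average the inverse-logit of the fixed-effect linear predictor over the
observed covariate distribution with random intercepts set to zero (the
original post-estimation behaviour is unspecified; setting them to zero is
this package's documented choice), and attach delta-method intervals.

## The synthetic generator

`sim_cohort()` emulates the study conditions: 1,166 true deaths in one
year, media capture probability 1086/1166 ≈ 0.931, and a misclassification
process $\mathrm{logit}^{-1}(\beta_0 + \beta'x + u_{county} + v_{state})$
with $u \sim N(0, 7.1)$, $v \sim N(0, 2.7)$, baseline
$\beta_0 = \mathrm{logit}(0.486)$ (the reported firearm-death predicted
probability), non-firearm log-odds $\log 68.24$ and income-quintile
log-odds from the published multivariable model. Covariate mixes follow the
observed margins (e.g. 92.8% firearm; mechanism detail uses the linked-case
composition because cause assignment needs it). Geography defaults to 40
states × 12 counties ≈ the 491 counties with observed deaths; the
mixed-model recovery tests use 50 states × 10 counties, matching the 51
independent reporting areas. Injury dates are uniform over the year (the
within-year timing distribution is not reported). Death dates equal injury
dates with probability 0.8 — the reported fraction dying immediately — with
a geometric tail (mean 4 days) otherwise; quarters are assigned from death
dates because public registry counts are death-date based. Identifier noise
applies 5% single-character surname edits and 5% ±1 birth-year shifts.
Late deaths carry an external confirmation with probability 1 by default
(every late death is assumed news-verifiable).

List dependence is induced at the individual level: for each death,
`solve_joint_capture_probs` solves the 2×2 joint distribution with the
configured marginals and log cross-ratio $\alpha$ (a monotone
one-dimensional root find in $q_{11}$ on its Fréchet interval, residual
tolerance $10^{-14}$), making the generator exactly self-consistent with
the estimator's offset parameterization. Because the media-capture
probability is constant while only classification varies, the independence
estimator remains unbiased under $\alpha = 0$ heterogeneity, which the
200-replicate recovery test (estimate within 3 SE of the true total in ≥
90% of replicates) exercises end to end through filtering, linkage, cell
construction and fitting.

What the generator does **not** emulate: media-coverage heterogeneity by
rurality (beyond an optional per-urbanicity capture override), cross-state
hospital transfers, seasonal death patterns, name-frequency skew, and
certifier-level coding behaviour. Passing recovery tests therefore show the
pipeline is correct under the stated generating process, not that real
registries satisfy its assumptions — in particular, real list dependence is
unidentifiable from two lists, which is why $\alpha$ is a sensitivity
parameter rather than an estimate.

## Numerical choices and degenerate inputs

* Poisson fits use IRLS to $10^{-12}$ with at most 100 iterations;
  non-convergence is an error.
* Zero observed cells are fitted with a warning (the MLE may sit on the
  boundary); an optional +0.5 continuity flag exists and is off by default.
* A zero `n11` makes the closed form unbounded and is an error.
* Redistribution rounding is half-up; quarterly apportionment uses largest
  remainders with positional tie-break.
* Fisher exact tests are exhaustive up to table total 2,000 and
  seed-pinned Monte-Carlo (10^5 draws) beyond; the mixed model uses the
  `bobyqa` optimizer.
* Estimates are reported rounded to integers; all internal arithmetic is
  unrounded.

## Problem sizes used in validation

The test suite validates estimator recovery on 200 replicates of the
default 1,166-death cohort and mixed-model recovery on five replicates of
20,000 deaths across 500 counties (5-seed medians: non-firearm odds ratio
within ±25%, variance components within ±40% of the generating values) —
sizes chosen to make Monte-Carlo error small relative to those bands.

## Known limitations

* Two lists identify the unobserved cell only under an assumed dependence;
  the sensitivity scan brackets, not removes, that assumption.
* The linkage tie-break and the custody/vehicle rule precedence are
  documented conventions, not reconstructions of the original manual
  adjudication.
* Mixed-model variance components from Laplace approximation are mildly
  attenuated at large variances with binary outcomes; the recovery bands
  account for this.
* Marginal predicted probabilities condition random intercepts to zero and
  are population-averaged only over fixed effects.
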