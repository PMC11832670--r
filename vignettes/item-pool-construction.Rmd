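---
title: "Building and administering Rasch-calibrated item pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and administering Rasch-calibrated item pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschpool)
```

## The measurement model

`raschpool` works with dichotomous checklist data: persons (rows) by items
(columns), each cell 0/1. The Rasch model ties every response to a single
latent ability $\theta_p$ through the item characteristic curve

$$P(y_{pi} = 1 \mid \theta_p) =
  \frac{\exp(\theta_p - \alpha_i)}{1 + \exp(\theta_p - \alpha_i)},$$

where $\alpha_i$ is the item difficulty: the ability at which the
endorsement probability is exactly one half. All items share the same slope,
so the curves are parallel, the raw sum score is a sufficient statistic for
ability, and items differ only in where along the trait they measure. The
two-parameter logistic (2PL) model relaxes this by giving each item its own
discrimination $a_i$, the slope of its curve at the inflection point. The
whole pool-construction pipeline exists to find a subset of items for which
the restrictive Rasch assumptions actually hold, because those assumptions
are what make sum scoring and adaptive administration legitimate.

### Estimation

Both models are calibrated by marginal maximum likelihood (Bock–Aitkin EM):
the latent ability is integrated out over a standard normal distribution
using Gauss–Hermite quadrature with 61 nodes — enough that quadrature error
is negligible against sampling error at any realistic sample size. The scale
is identified by fixing the latent distribution to $N(0, 1)$; difficulties
live on that scale, which is also the scale the adaptive-testing
conventions (the $\pm 10$ placeholder abilities, SE thresholds of 0.2–0.5)
presuppose.

Numerical choices:

* The EM M-step uses Newton refinement in the slope–intercept
  parametrization, where the expected complete-data log-likelihood is
  concave. Iteration stops when the largest parameter update falls below
  $10^{-6}$ logits; the fit records the infinity norm of the marginal score
  at the solution and only reports `converged` when it is small.
* Constant item columns (all 0 or all 1) carry no information about a
  finite difficulty. They are excluded up front, counted in
  `n_excluded_degenerate`, and named in `excluded_items` — never silently
  fitted at an infinite estimate.
* 2PL discriminations are capped to $[0.05, 10]$; a binding cap is reported
  with a warning and negates the convergence flag.
* Per-item standard errors come from the outer-product (BHHH) estimate of
  the marginal information matrix, which respects cross-item correlations
  induced by the shared latent trait.
* Person abilities from a calibration are EAP estimates (posterior means)
  with posterior standard deviations as their errors. Ability estimation
  for a *fixed, known* bank — the adaptive-testing case — is maximum
  likelihood via damped Newton iteration on the concave log-likelihood,
  stopping at a gradient below $10^{-12}$, which pins the maximizer far
  beyond the five-decimal agreement checked against a brute-force grid
  search.

## Item fit: Infit, Outfit, and modification indices

For person $p$ and item $i$, the squared standardized residual is
$z^2_{pi} = (y_{pi} - P_{pi})^2 / (P_{pi}(1 - P_{pi}))$. Outfit is the
plain mean of $z^2$ over persons (sensitive to surprising responses from
persons far from the item's difficulty); Infit weights the squared raw
residuals by the item information $P(1-P)$, concentrating on persons near
the difficulty. Both have expectation about 1 when the model holds, and the
screening step drops items with either index strictly below 0.7 or strictly
above 1.3 (boundary values are kept).

A design decision worth spelling out: the residual probabilities are, by
default, averaged over each person's ability *posterior* from the marginal
fit rather than plugged in at the EAP point. The point plug-in uses
shrunken abilities and systematically biases both mean squares a few
percent below 1 (we measured ~0.92 for Outfit at 1000 persons × 30 items),
which eats into the distance between a well-fitting item and the 0.7
cut-off. The posterior-expected version is calibrated at 1.000 under the
model. `method = "point"` restores the plug-in formula.

The modification index asks, for each item, how much the fit would improve
if that item's slope were freed from the common Rasch value. It is computed
as an efficient score (Lagrange-multiplier) statistic: the per-person score
for the slope, with the difficulty-score directions projected out, on the
1-df chi-square scale. This is asymptotically equivalent to a
likelihood-ratio refit with the slope freed (the test suite checks
correlation > 0.9 against exactly that refit) at a fraction of the cost.

## Pool assembly

The subset objective combines four components, each entering negatively so
that 0 is the unattainable ideal:

$$S = -\tfrac{1}{3}\,\mathrm{sd}(\text{adjacent gaps})
      - 4\,\overline{|\text{Infit} - 1|}
      - 2\,\overline{|\text{Outfit} - 1|}
      - \tfrac{1}{100}\,\overline{\text{MI}}.$$

The spacing term is the sample standard deviation of the gaps between
difficulty-sorted adjacent items — zero for perfectly even coverage of the
trait. The weights 1/3, 4, 2, 1/100 bring the components onto a comparable
scale while emphasizing fit over spacing. For the fit terms we aggregate
*deviations from the ideal value 1* rather than raw sums: raw sums would
reward Infit values below 1 (overfit) as much as they penalize values above
1, and would scale with subset size, distorting comparisons across sizes.
The literal raw-sum reading remains available via
`selection_weights(aggregation = "raw_sum")`.

Subsets are searched by simulated annealing: item exchanges between the
subset and the remainder, Metropolis acceptance $\exp(\Delta/T)$ for
worsening moves, geometric cooling. The schedule defaults —
$T: 1 \to 10^{-3}$, factor 0.95, 200 proposals per temperature, swaps of
1–3 items — are unexceptional choices that reproduce exhaustive search on
every enumerable test pool; nothing in the pipeline is sensitive to them as
long as the search is given a fair budget. The best subset ever visited is
returned, so the result can never be worse than the search trace. Because
annealing is stochastic, `sa_consensus_select()` repeats the search
(default 20 restarts) and keeps the items returned most often; frequency
ties at the boundary are broken greedily by objective value and then by
bank order, making the consensus deterministic given the seed.

### Choosing the pool size: Rasch vs 2PL

For each candidate size the selected subset is submitted to a person-level
5-fold cross-validation: both models are calibrated on the training folds
and each held-out person's complete response vector receives a predictive
log density with the ability integrated over $N(0,1)$. The summed
difference (ELPD, positive favoring the 2PL) and its standard error
$\sqrt{n \,\mathrm{var}}$ feed the decision rule: the models are
*equivalent* until the difference exceeds twice its standard error, and the
pipeline keeps the largest size still equivalent (or Rasch-preferred).

Two implementation choices matter here, both measured during development:

* **The Rasch side has a free common slope.** A fixed-scale Rasch and a 2PL
  differ by *two* things: slope heterogeneity and the overall latent scale.
  Only the first is the scientific question. Giving the Rasch side a single
  shared discrimination (equivalent to a free latent variance, which
  hierarchical Bayesian Rasch fits have through the person-SD parameter)
  cancels scale-estimation noise from the comparison.
* **The 2PL slopes are partially pooled.** Unpooled ML slopes overfit, and
  cross-validation bills that overfitting to the 2PL: on Rasch-generated
  data the literal comparison reads "Rasch preferred by > 3 SE" — a
  conclusion about estimator noise, not about the data. We therefore treat
  the log-slopes as exchangeable normal draws, estimate their between-item
  variance by the method of moments, gate it on a 1% homogeneity chi-square
  (heterogeneity must be supported before slopes may differ), and shrink
  accordingly, refitting intercepts with slopes held fixed. Under Rasch
  data the two sides then collapse onto each other and the verdict is
  equivalence; under genuinely varying slopes the gate opens immediately
  and the 2PL wins by a wide margin. `shrink_slopes = FALSE` exposes the
  literal unpooled route.

## DIF screening

Differential item functioning is screened by calibrating each group
separately on the candidate pool, equating the two difficulty scales by
their means over the commonly estimable items, and flagging items whose
95% Wald intervals do not overlap. Interval non-overlap is a conservative
criterion (pointwise type I error well below 5%), which suits a final
screen whose false positives permanently discard items. Groups must number
exactly two, each with at least two persons; items degenerate in either
group are reported as untested rather than silently passed.

## Reliability

`kr20()` is the classical Kuder–Richardson formula 20 on the raw 0/1
matrix, with the sample ($n-1$) variance of total scores. Persons whose
ability carries the `convention` tag (the $\pm 10$ placeholders for uniform
response patterns) are excluded from `andrich_reliability()` — their
pseudo-values and infinite standard errors would corrupt both the observed
ability variance and the mean error variance. The index is floored at 0.

## Adaptive administration

A session starts at ability 0. While the response pattern is uniform the ML
estimate diverges, so the conventional values −10 (all "no") / +10 (all
"yes") stand in — and, by design, a convention-valued ability can never
satisfy the stopping rule, because the standard error is undefined there.
The convention is often stated for the first item only, but ML is
undefined for *any* uniform pattern, so we apply it throughout, as common
CAT implementations do. Each next item is the unadministered one with difficulty nearest the
current ability — under the Rasch model exactly the maximum-information
choice (verified in the tests against an information oracle). Equidistant
candidates resolve to the lower difficulty, then to bank order: any
deterministic rule would do, reproducibility is the point. The session ends
when the ability SE reaches the configured threshold (evaluated only once
the estimate is finite), when the pool is exhausted, or at the `max_items`
safety cap (not part of the original design; it exists so that harnesses
terminate on pathological banks). With an 89-item bank spanning ±3 logits,
a threshold of 0.2 lies below the information ceiling at the scale centre,
so such sessions typically administer the whole pool — the test suite
asserts this phenomenology.

## What the synthetic generator does and does not emulate

`generator_config()` defaults replicate the statistical skeleton of a large
parent-report vocabulary calibration study: 1190 respondents × 379 words
(197 nouns, 92 verbs, 90 adjectives); item difficulties strictly increasing
in a simulated age-of-acquisition grade, mapped affinely onto $[-4, 4]$
logits; child ages uniform on 3–8 years; abilities
$\theta = -5.5 + 1.0\,\mathrm{age} + N(0, 1)$, so that the mid-age child
sits near the scale origin, older children endorse more words, and the
marginal ability SD (~1.8) resembles a wide developmental range. The
sources report only the qualitative age trend and the AoA–difficulty
association, not these coefficients; the values above are one-time choices
of a plausible developmental gradient, not quantities fitted to anything.
Misfit injection (`misfit_fraction`, discriminations 0.3/3) and DIF
injection (`dif_items`) give the screening procedures known targets.

The generator does **not** emulate: real lexical content, caregiver
response biases (social desirability, recency), local dependence between
semantically related words, missingness, or non-uniform age recruitment.
Passing tests on synthetic data therefore demonstrate that the machinery
recovers the structures it is designed for — not that any particular field
instrument satisfies the Rasch model.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run at sizes chosen to make
sampling error small relative to the asserted tolerances while keeping a
full run in minutes on one CPU: difficulty recovery at 2000 persons × 40
items; fit-statistic calibration at 1000 × 30; model-comparison behaviour
over 20 replicates of 1000 × 30; DIF null rates over 20 replicates of
1000 × 20; 100+ adaptive sessions against the grid-search oracle; 500
sessions for coverage. Annealing is checked against exhaustive enumeration
on all pools with $\binom{n}{k} \le 1000$.

## Known limitations

* Estimation is frequentist ML throughout; no posterior distributions,
  priors, or MCMC. Absolute difficulty values from a Bayesian refit of the
  same data can differ by an affine transformation of the scale, so
  cross-implementation comparisons should allow location/scale alignment.
* Only dichotomous, unidimensional models; no polytomous or
  multidimensional extensions, no person-fit statistics.
* The DIF screen handles exactly two groups.
* The CAT engine has no exposure control or content balancing; item choice
  is purely information-driven.
* Word types are carried as metadata and reported, but the selection
  objective does not constrain their proportions.
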