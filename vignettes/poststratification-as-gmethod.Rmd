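---
title: "Poststratification as a g-method: model, assumptions, and the simulation laboratory"
author: "poststrat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poststratification as a g-method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poststrat)
```

## The problem

Most epidemiological samples are nonprobability samples: the probability
that a population member ends up in the study is unknown and usually
related to who they are. A cohort that over-recruits older women will
misstate any outcome that varies with age and sex. Poststratification
corrects this when the joint distribution of a set of categorical
auxiliary variables $X$ (the *poststratifiers*) is known both in the
sample and in the target population, typically from a census.

Write $\delta_i \in \{0,1\}$ for sample inclusion, $n_j$ and $N_j$ for the
sample and population counts of covariate cell $j = 1,\dots,J$, and
$\bar Y_j$ for the sample outcome mean in cell $j$. The package implements
the two classical estimators of the population mean $E[Y]$:

* **individual-level weighting**: each unit in cell $j$ gets weight
  $w_j = N_j / n_j = 1/\hat P(\delta = 1 \mid X = x_j)$ and
  $\hat\mu_w = \sum_j \sum_i Y_{ij} w_j \big/ \sum_j N_j$;
* **stratum aggregation**:
  $\hat\mu_s = \sum_j N_j \bar Y_j \big/ \sum_j N_j$.

The two are algebraically identical, and that identity is the package's
central organizing fact: the first form is inverse probability weighting
(IPW) with a saturated, nonparametrically estimated inclusion propensity,
and the second is standardization (the g-formula) of the sampled units to
the external covariate distribution. The test suite asserts both
equivalences to $10^{-12}$ on a thousand randomly generated studies rather
than trusting the algebra once.

Validity rests on three assumptions, each with an exact causal-inference
counterpart:

1. **Conditional independence** $Y \perp \delta \mid X$ (the analogue of
   conditional exchangeability). If inclusion depends on the outcome even
   within cells — all obese people refuse — no reweighting can help.
2. **Positivity for inclusion** $P(\delta = 1 \mid X = x) > 0$: every
   population cell needs at least one sampled unit. Only the $\delta = 1$
   level is needed, since nothing is estimated for the unsampled.
3. **Consistency** $Y = Y^{\delta=0} = Y^{\delta=1}$: being sampled must
   not change the outcome (no weight loss in anticipation of a health
   screening). This is *stronger* than the treatment-effect version — the
   price paid for the relaxed positivity condition.

## The containers and estimators

`microdata()` holds unit-level records (categorical covariates, numeric or
binary outcome, optional categorical treatment); `population_table()`
holds cell counts $N_j$, optionally entered as proportions with a
separate total, because censuses publish both. Levels are compared as
exact strings after trimming surrounding whitespace and are never
case-folded: silently merging `"Men"` and `"men"` would collapse strata
that the user declared distinct. Cells are ordered by covariate name and
then level so every output is deterministic. Missing values are rejected
outright — the cell estimators assume complete cells and imputation is
out of scope.

```{r worked}
koges <- koges_sample()          # 10,030-person cohort, reconstructed
census <- koges_census()         # six 2001 census age-sex cells
wt <- compute_cell_weights(crosstab(koges), census)
wt
weighted_mean(koges, wt)
crude_mean(koges)
```

The cohort's crude smoking prevalence of ~25.6% rises to 26.5% after
weighting to the census age-sex distribution, because the cohort
over-represents older adults, who smoke less. Note the reconstruction
caveat: the published illustration reports stratum *rates* rounded to one
decimal of a percent, and the packaged unit-level fixture expands each
stratum to `round(n_j * rate_j)` positive outcomes. That rounding
convention is ours, and it is why the fixture's crude rate (25.6%)
differs in the last digit from the published 25.7%, which was computed on
unrounded microdata. The package documents the discrepancy instead of
forcing agreement.

Positivity failures are never silent. A population cell with no sampled
units raises a structured error naming the cells, or — under the explicit
`on_empty = "drop_and_renormalize"` policy — the cell is dropped and the
remaining $N_j$ rescaled multiplicatively to preserve the population
total, with a warning quantifying the dropped share. Collapsing adjacent
cells was deliberately not implemented: there is no principled collapsing
rule to encode, and the multiplicative rescale at least keeps the weight
accounting exact. Sampled cells *absent from the population table* are
always an error under every policy; they indicate a coding mismatch
between the two sources, not a statistical condition.

## G-methods on the same cells

With a declared treatment, `estimate_propensity()` estimates
$\hat P(A = a \mid X = x_j)$ by within-cell frequencies — saturated by
design, matching the contrast with model-based propensity estimation;
parametric (logistic) propensities are an explicit non-goal. `ipw_mean()`
and `standardized_mean()` estimate counterfactual means $E[Y^a]$, and
`ate()` their difference. Standardization accepts either the sample's own
covariate distribution or an external `population_table`; called with
`a = NULL` and an external reference it *is* the stratum-aggregation
poststratification estimator, which is how the package states the
"poststratification is IPW of the inclusion arm" identity as a testable
property. Treatment is any finite categorical (the ATE needs exactly two
named levels, defaulting to the two observed levels in descending order);
the generalization beyond binary costs nothing and changes no formula.

`twostage_compare()` implements the comparison procedure for two exposure
groups from nonprobability samples: stage 1 poststratifies each group to
its own population over the selection covariates $W$; stage 2
standardizes both groups to one common distribution over the confounders
$Z$. $W$ and $Z$ may differ. We allow this deliberately: when $W = Z$,
within-cell reweighting cannot change cell means, so stage 1 provably
cancels from the final estimate and only rescales — the package emits a
note in that case, and the collapse is asserted in the tests. Stage-2
cell means are stage-1-weighted means (the natural composition;
unweighted cell means would discard stage 1 entirely).

## Diagnostics

`weight_summary()` reports the Kish effective sample size
$(\sum w)^2 / \sum w^2$ and the design effect $n/\mathrm{ESS}$ — the
squared-sum ratio is a survey convention, chosen here as the standard
heuristic, not a quantity with a stated formula in the framework.
`balance_table()` compares sample covariate distributions before and
after weighting against the target, per covariate margin and for the full
joint; on the poststratifiers the after-weighting joint matches the
target to $10^{-12}$ by construction, and the tests assert exactly that.
`positivity_report()` augments the cell-alignment report with the
per-cell inclusion fractions $\hat p_j = n_j/N_j$.

## The simulation laboratory

`sim_config()` specifies a finite population cell by cell: joint
proportion `prop`, Bernoulli outcome probability `q`, and base inclusion
probability `s`. `generate_population()` draws each unit's cell and its
outcome **once**; afterwards $X$ and $Y$ are fixed and only inclusion is
random, encoding the sampling-theory stance that outcomes are fixed
quantities while inclusion is the random element. Two knobs violate one
assumption each:

* `outcome_dependence` $d$ adds to the inclusion probability of units
  with $Y = 1$ (breaking $Y \perp \delta \mid X$). It enters additively on
  the probability scale because that is the simplest analytically
  tractable form; a logistic-scale version would be a reasonable
  alternative but is not implemented.
* `reactivity` $r$ adds to the *observed* outcome of included units
  (breaking consistency). The framework's reactive-sampling example gives
  no functional form, so this additive shift is our minimal encoding.

Configurations whose shifted probabilities leave $[0,1]$ are rejected,
never clipped — clipping would silently change the violation being
studied. Replication seeds derive from the master seed by a fixed counter
(`seed + rep`), so studies are reproducible and parallelizable by
replication.

`run_bias_study()` compares the crude and poststratified estimators over
replications against the realized population mean, excluding (and
reporting the rate of) replications with empty strata. Its independent
yardstick is `analytic_expectations()`: conditional on the realized
population (cell sizes $M_j$, positives $K_j$), the large-sample
expectation of the crude estimator is

$$
E[\hat\mu_{crude}] \approx
\frac{\sum_j K_j (s_j + d)(1 + r) + (M_j - K_j)\, s_j\, r}
     {\sum_j K_j (s_j + d) + (M_j - K_j)\, s_j},
$$

and the poststratified expectation replaces the global ratio by the
population-share-weighted sum of per-cell ratios. With $d = r = 0$ the
poststratified expectation equals the truth *exactly* (within-cell
samples are exchangeable draws), which is the clean statement of "under
the three assumptions, poststratification works". The closed form is
evaluated on the realized population rather than the configured
probabilities so that Monte-Carlo means can be compared to it at
$3\times$ their standard error without absorbing the population-sampling
noise.

```{r sim}
cells <- data.frame(sex = c("men", "women"), prop = c(0.5, 0.5),
                    q = c(0.3, 0.1), s = c(0.4, 0.6))
run_bias_study(sim_config(cells, population_size = 20000,
                          seed = 7, replications = 100))
```

Selection here depends on sex only, so the crude estimator is pulled
toward the over-sampled women's lower rate (expectation 0.18 against a
truth near 0.20) while the poststratified estimator is unbiased. Setting
`outcome_dependence = 0.2` reverses the verdict: the poststratified
estimator converges to its (biased) closed form, demonstrating that
reweighting on $X$ cannot repair outcome-dependent selection.

Problem sizes: the packaged studies use populations of $10^4$–$10^5$
units and a few hundred replications, which puts Monte-Carlo standard
errors near $10^{-4}$ — small enough to separate "unbiased" from the
built-in violations by an order of magnitude, while a full study still
runs in well under a minute on a laptop core.

## What the generator does and does not emulate

The generator reproduces the structural features the estimators care
about: a finite population with a known cell structure, Bernoulli
selection with cell-constant base rates, and the two named assumption
violations. It does not emulate continuous covariates (calibration
territory, out of scope), cluster or multi-stage designs, measurement
error, or missing data — so passing simulation tests says nothing about
those features of real data. Likewise the package offers no variance or
confidence-interval estimation for poststratified estimates, no raking to
margins, no entropy balancing and no doubly robust estimators; those are
documented boundaries, not omissions.

## Numerical conventions

Estimates are carried at full floating precision; the one-decimal
percentages shown in summaries are presentation rounding only. Weight
tables default to the population scale ($\sum_j n_j w_j = N$);
`normalize_weights()` rescales to mean weight one, and every estimator is
invariant to the choice (tested). Equivalence theorems are asserted at
$10^{-12}$ absolute, comfortably above accumulated rounding at the
problem sizes involved and far below any substantive difference.
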