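---
title: "Ranking risk factors with machine learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking risk factors with machine learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem riskrank addresses

Descriptive epidemiology frequently asks: *among dozens of candidate
predictors, which are most strongly associated with a binary outcome?*
The common answer — fit one multivariable logistic regression and read
every coefficient off the output table — is statistically incoherent for
that purpose: each covariate's coefficient is conditional on a different
implicit adjustment set, so the coefficients are not comparable and not
interpretable as importance.  riskrank implements the alternative: fit a
small set of flexible classifiers, tune them honestly, and rank the
predictors with model-agnostic importance scores, with uncertainty from
the bootstrap and effect shapes from partial dependence.

## The procedure

1. **Models.** Four tunable families plus a reference: LASSO and
   elastic-net logistic regression (`glmnet`), a probability random
   forest (`ranger`), a single-hidden-layer neural network with logistic
   activations and weight decay (`nnet`), and plain logistic regression.
   All families consume one shared dummy-coded model matrix (each
   L-level categorical becomes L−1 indicators, reference level dropped —
   by default the first level in sorted order).  Penalized and network
   families see the matrix standardized with sample (n−1) statistics,
   because their fits are scale-sensitive; the forest sees it raw.
2. **Nested cross-validation.** Hyperparameters are drawn by random
   search (defaults: penalty on a log scale over 1e−4..1, mixing uniform
   on \[0, 1\], `mtry` over 1..p with 500 trees, hidden units 1..20 with
   log-scale decay 1e−4..1e−1) and scored by mean AUC over the inner
   folds of each outer-training set.  Defaults are 10 outer and 5 inner
   folds, stratified by outcome.  The parameters of the single best
   outer fold are then refit on **all** rows to give the final model.
   That selection rule is deliberate: it maximises sample-size
   efficiency for a descriptive analysis, at the price of an optimistic
   headline metric.  The conventional rule (inner search on all data,
   outer folds used only for performance estimation) is available via
   `selection = "full_data"`.
3. **Performance reporting.** The headline AUC is the best outer fold's
   test AUC.  The accompanying bounds are 2.5th/97.5th type-7
   percentiles *across outer folds*, labelled as such — they are a
   spread of fold performance, not a sampling CI — and the full per-fold
   table is always emitted so any other convention can be recomputed.
   Sensitivity and specificity use a 0.5 cutoff by default
   (configurable); the cutoff is reported alongside.
4. **Variable importance.** Two model-agnostic definitions are
   implemented and stamped on every output row:
   * `pdp_variance` (FIRM, the default): the dispersion of the 1-D
     partial dependence curve — sample sd over the grid for continuous
     variables, (max − min)/4 over the levels for categorical ones.
   * `permutation` (model reliance): baseline AUC minus mean AUC after
     permuting the variable, averaged over seeded permutations.  A
     categorical's indicator block is permuted jointly, since permuting
     indicators independently would create impossible rows.  Negative
     raw scores are kept (they are informative about noise) but flagged.
   Scores are scaled so the best variable in each model is 100; scaling
   is per model, which makes rankings — not raw magnitudes — the
   comparable quantity across models.  Dummy columns can be ranked
   individually (`per_column = TRUE`, matching how penalized models see
   the matrix) or aggregated per source feature (`top_k(aggregate =
   TRUE)`).
5. **Bootstrap intervals.** B = 100 resamples with replacement by
   default; each refit with the *fixed* NCV-selected parameters,
   importance recomputed and rescaled **within** the replicate, and
   percentile bounds taken per variable.  Single-class resamples are
   redrawn (at most 10 attempts).  Percentile intervals need not contain
   the full-data point estimate; such rows are flagged rather than
   adjusted.
6. **Partial dependence and interactions.** PDPs substitute grid values
   into every evaluation row and average predictions, on the
   probability scale (a `logit` scale would change additivity
   properties; see the caveat below).  Continuous grids are 20 equally
   spaced sample quantiles trimmed to the 1st–99th percentile, so
   outliers cannot stretch the curve; categorical grids enumerate the
   levels.  Two-way interaction strength follows the PDP-dispersion
   recipe: for each grid value of one variable, take the dispersion of
   the conditional curve of the other, then take the sample sd of those
   conditional dispersions, and average the two orderings.  An additive
   surface scores exactly zero.  Screening defaults to demographic
   pairs plus demographic-by-top-10 pairs; `all_pairs` and (for
   penalized models) full two-way product expansion are alternatives.

**A caveat on scales.** Because PDPs are computed on the probability
scale, a model that is purely additive on the *logit* scale has a small
nonzero interaction strength induced by the sigmoid's curvature.  The
exact-zero property therefore holds on the prediction scale itself, and
the package's exact-zero tests use identity-scale models.  Reported
strengths are raw, in probability units, and are labelled with their
scale rather than normalised.

## The synthetic survey generator

`generate_survey()` draws continuous features standard normal (optionally
correlated; an exchangeable ρ = 0.3 block is a useful stress test for
importance under collinearity), categorical features multinomial, and
the outcome Bernoulli(sigmoid(η)) with η assembled from planted linear,
quadratic and product terms.  When a target prevalence is requested, the
intercept is solved by bisection to tolerance 1e−4 on the mean
probability.

`paper_like_scenario()` is the package's reference condition: 1414 rows,
70 mixed-type predictors, target prevalence 0.4, and planted structure
chosen to exercise every stage — three strong categorical main effects
(`cannabis` 1.2, `cocaine` 1.0, one `orientation` level 0.9 logit
units), one U-shaped continuous effect (`ace`, quadratic coefficient
0.5), and one sign-flip interaction (`suicidality` × `cannabis`,
coefficient −1.6 against a main slope of 0.8, so the suicidality slope
is +0.8 for non-users and −0.8 for users).  Effect sizes sit in the
0.5–1.5 logit-unit band: strong enough to be recoverable at n ≈ 1000,
weak enough that the ranking is not trivial.  The scenario also declares
a screening set (`age`, `gender`, `education`, `suicidality`): in a real
analysis the screening set is the analyst's demographic variables, and
the scenario includes the continuous interactor in it so that the
planted pair is reachable through the same demographic-by-top-predictor
route that screening uses in practice.

What the generator does *not* emulate: real survey marginals, item
missingness (the package's contract is complete-case input —
imputation, if needed, happens upstream), measurement error, or sampling
weights.  Passing the recovery tests therefore demonstrates that the
machinery ranks genuinely predictive variables highly under known
truth — not that any particular real-world ranking is correct.

## Numerical and design choices

* **Schema inference**: a numeric column with more than 10 distinct
  values is treated as continuous, otherwise categorical; an explicit
  schema always wins, and inference is logged.
* **Penalized fits**: `glmnet` is run along a log-spaced path that
  terminates exactly at the requested penalty (no path interpolation),
  with convergence threshold 1e−7.  The LASSO is literally the
  elastic net restricted to mixing = 1 and shares its code path, which
  makes their equivalence structural.
* **Neural network**: at most 500 epochs, seeded initial weights, so
  refits are bit-reproducible.
* **Ties** break to the earliest index everywhere (candidate draw
  order, fold order, variable name order in rankings) — determinism
  over optimism.
* **Seed discipline**: one master seed; every stage derives its own
  seed through a fixed hash of (master, stage label, index), so stages
  can be re-run independently and bootstrap replicates can in principle
  be parallelised with serial-identical results.
* **Degenerate inputs**: single-class outcomes refuse to fit; constant
  columns under user-requested standardization are an error (inside
  model fitting a constant column passes through with unit scale, which
  matters for resamples and product columns); single-point grids refuse
  an interaction strength.
* **Memory**: stacked PDP evaluation predicts in row chunks so the
  two-way product expansion cannot materialise oversized matrices; row
  subsampling of the PDP evaluation set is available (`subsample`) and
  used in the heavier simulation tests.

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` run everything
at desk scale, chosen so the full battery completes on one CPU in tens
of minutes: null calibration at n = 300, p = 10 over 50 runs; signal
recovery on the reduced scenario (n = 1000, p = 20, 100 runs in the
tests, 25 in the acceptance script); interaction ranking at n = 2000
with the expansion model (100 and 25 runs respectively); bootstrap-width
comparison at n = 1000 versus 250 with B = 50; and an end-to-end
three-family pipeline at n = 500 with 5 outer × 3 inner folds and
B = 25.  The framework defaults (10 outer, 5 inner, B = 100, top 10)
remain the package defaults for real analyses, and every configured
deviation from them is written to the run log.

## Known limitations

* The headline "best outer fold" metric is optimistic by construction;
  use the emitted per-fold table for an honest spread.
* Percentile bootstrap intervals for *scaled* importance are wide at
  survey sample sizes, and that is the finding, not a defect: the
  width itself is diagnostic of ranking instability (the package's
  tests verify widths grow as n shrinks).
* Importance scores share the usual caveats under strong collinearity:
  correlated predictors split credit.
* PDP averages extrapolate into regions of feature space with no data
  support when variables are strongly dependent; grids are trimmed to
  observed quantiles, which limits but does not remove this.
* Nothing here is causal.  The output is a ranked description of
  associations.
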