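---
title: "Structured-output PLS for factorial metabolomics designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured-output PLS for factorial metabolomics designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metabolomics experiments rarely vary a single factor. A typical GC-MS
study crosses bacterial strains with inducer conditions, or strains with
drug dosages and sampling times, with a handful of biological replicates
per cell. Treating such data as a flat multi-class classification problem
(one class per factor combination) throws away the design structure: two
cells that share a strain are not "as different" as two cells that share
nothing, and ordinal factors such as dosage have an ordering a one-of-k
coding cannot express. Treating them as a pure regression problem fails
for the categorical factors.

`structpls` takes the middle road: the response matrix **Y** is built
block-wise from the design of experiment. Each categorical factor
contributes a one-of-k sub-matrix (an `off`/`on` code per column); each
ordinal factor contributes a single column holding a coded value per
level. A multi-response PLS (PLS2) model is then fitted to this structured
target, and raw predictions are *crisped* back into factor levels:
arg-max within each categorical block, nearest coded value for each
ordinal block. Model quality is judged by the *error set* — the number of
blocks misassigned per sample, 0..B for B blocks — rather than a single
regression or 0/1 classification loss.

```{r}
library(structpls)
scheme <- packaged_scheme("propranolol")
scheme
encode_sample(c("S1", "D2", "T2"), scheme)
crisp(c(6, 0, 0, 2.5, 0.8), scheme)
```

## The regression engine

`fit_pls()` implements classic NIPALS PLS2 with deflation of both X and
Y. Only mean centring is applied — no unit-variance or Pareto scaling —
so the coded Y values carry their intended relative weight. The weight
vector of each component is the NIPALS fixed point, i.e. the dominant
eigenvector of $X_c' Y_c Y_c' X_c$. Rather than cycling the u→w→t→q
inner loop until a tolerance is met, the package computes that
eigenvector exactly from the small $q \times q$ eigenproblem of $C'C$
(with $C = X_c'Y_c$): the extracted component is identical to a fully
converged inner loop, there is no iteration-count nondeterminism, and the
leave-one-out loops below run an order of magnitude faster. Each
component's sign is fixed so that the largest-magnitude weight entry is
positive, which makes repeated fits bit-identical.

Numerical edge cases: a constant X column centres to zero and contributes
nothing; when the residual X/Y covariance is numerically exhausted before
the requested number of components, extraction stops early with a message
and a smaller model (rather than an error), because downstream
cross-validation loops must survive rank-deficient training subsets.

Because the scale of a block's coded values steers the least-squares fit
towards that block, `variance_balance()` reports each block's total
column variance on the encoded design and warns when the max/min ratio
exceeds a threshold. The default threshold is 10 — an order-of-magnitude
guard. It is deliberately loose: well-constructed codings such as the
packaged propranolol scheme (strain coded 0/6, dosages 0/2/4/6, times
0/1/6) still show a ratio near 4.5 on their own design without harm, so a
tighter default would flag sensible schemes.

## Validation: replicate-aware double cross-validation

The biological replicate is the unit of train/test splitting: one
replicate from every populated design cell is drawn at random to form the
blind test set, the rest train the model (`make_split()`). On the
training set alone, the number of latent variables is chosen by
leave-one-out cross-validation (`select_n_components()`): the candidate
count with the smallest total block-error over held-out samples wins,
ties going to the smaller count (integer error totals avoid floating-tie
ambiguity). The final model is refitted on the whole training set and
applied to the test set; per-block confusion matrices are tallied as row
percentages and averaged over iterations (`double_cv()`, default 1000
iterations). Conditional CCRs — block A's accuracy within each true level
of block B — expose interactions the coding itself does not model.

The default latent-variable cap is `min(15, n_train - 2, p)`. Structured
targets genuinely need more components than a single-block PLS-DA (each
block adds response directions), but beyond ~15 the inner LOOCV on
designs of this size selects larger counts only by chance.

Statistical significance of each factor comes from a permutation test:
per iteration, the label tuples (whole design rows, replicate identity
included) are permuted across samples *before* splitting, and the same
pipeline is run on the permuted data. The empirical p-value per block is
the fraction of iterations in which the observed block error strictly
exceeded the null block error. Ties count as non-exceedances, which makes
the estimate slightly anti-conservative; the strict inequality is kept
deliberately because it is the conventional form of this test in
chemometrics validation, and the anti-conservatism is negligible whenever
the null errors are spread over several values. Permuting before rather
than after the split is a genuine choice (either reading is defensible);
permuting first keeps the null run a complete, honest replica of the
observed pipeline, including the replicate-stratified split on the
permuted labels.

Classic codings are expressible in the same machinery: `cell_coding()`
builds the all-cells one-of-k scheme (every populated factor combination
a class), so "structured vs binary" comparisons run through exactly the
same pipeline, and `recover_factor_confusion()` projects the cell-level
confusion matrix back onto any single factor.

## Variable importance

For a multi-column Y there is one VIP vector per response column
(standard Wold/Chong–Jun definition; the mean squared VIP over predictors
is exactly 1 per column). `summarize_vip_by_block()` collapses them to
one vector per factor by taking, per predictor, the maximum over the
block's columns — a disjunction: a metabolite matters for the strain
factor if it matters for *any* strain column. VIP is conventionally
computed on a final model fitted to all samples; `modal_lv()` supplies
the most frequently selected latent-variable count across double-CV
iterations as a principled component count for that final fit. Which
subset of samples the "final" model should use is genuinely open;
fitting on all samples uses the most information and is the common
practice for importance screening (the double-CV report, not the VIP
fit, carries the generalisation claim).

## The synthetic generator

`effect_spec()`/`generate()` produce samples × features tables with known
ground truth so the whole pipeline is testable without any downloads.
Features are baseline Gaussian noise (sd `noise_sd`) plus additive factor
effects on a random subset (`affected_fraction`) of features:

* categorical factor: every (level, affected feature) pair receives an
  independent shift drawn from N(0, (`effect_size` × `noise_sd`)²) —
  `effect_size` is the typical per-feature level shift in noise-sd units,
  the way per-metabolite fold changes are usually quantified;
* ordinal factor: each affected feature gets a slope on the same scale,
  multiplied by the level's standardised coded value (linear-in-code
  gradient);
* optional pairwise interactions give every level combination of a factor
  pair its own random shift.

Two presets mirror the study shapes the package targets:
`riboswitch_like()` (5 × 4 full factorial, 3 replicates, 60 samples ×
200 features; strong 2.5 sd 5-level factor, weak 0.8 sd 4-level factor,
20% of features affected each, unit noise) and `propranolol_like()`
(3 strains × 4 dosages × 3 times with the first time point only at the
control dosage — 27 populated cells × 4 replicates = 108 samples; ordinal
dosage and time gradients under the 0/2/4/6 and 0/1/6 codings; effect
sizes 2.0/1.5/1.0 chosen so the strain factor dominates, the dosage
gradient is clear, and the time effect is weakest, the typical ordering
in exposure studies).

What the generator does *not* emulate: GC-MS intensities are
heavy-tailed and correlated across co-eluting peaks, retention drift and
QC-based alignment artefacts are absent, and effects here are additive
Gaussian rather than multiplicative. Passing recovery tests on this
generator therefore demonstrates that the machinery is correct and that
the strong/weak/none factor regimes are distinguished as designed — not
that any particular real-data accuracy will be reached.

A statistical caveat for chance-level checks: across double-CV
iterations the same 60–120 samples are re-split, so the averaged CCR of a
truly null factor converges to a *dataset-specific* value that wobbles
around chance by roughly one single-split binomial standard error — and
with many latent variables a null block can also sit slightly below
chance (the familiar cross-validation "anti-learning" of overfitted null
responses). Chance-level assertions in the test suite therefore use the
binomial standard error at the split size, not at the (dependent) total
number of predictions.

Missing peak areas are handled by `knn_impute()`: Euclidean distances on
mutually observed features, rescaled by the observed fraction, and the
mean of the k nearest observing samples fills each hole (k = 5 by
default; only samples that observe the feature are candidates).

## Deterministic tie-breaking and seeds

All ties are resolved deterministically and documented: arg-max ties
within a categorical block go to the lowest-index level; an ordinal
prediction exactly midway between two codes goes to the lower coded
level; equal LOOCV errors go to the smaller component count; equal VIPs
rank by ascending variable index. Every stochastic step (splits,
permutations, the generator) is driven by an explicit integer seed, and
reports are reproducible bit for bit from
(data, scheme, `n_iterations`, `max_lv`, `rng_seed`).

## Problem sizes used by the test suite

The published workflow uses 1000 double-CV iterations; the package keeps
that default but the test-suite and the bundled acceptance script use 100
iterations on the presets (and 3–30 on small fixtures), which estimates
CCRs to ~1 percentage point and p-values to ~0.05 resolution — enough to
verify the qualitative regimes the suite asserts while keeping a full run
in minutes on one CPU.

## Known limitations

* Interactions between factors are not coded into Y; they are inferred
  post hoc from conditional confusion matrices.
* No orthogonal/sparse/kernel PLS variants, no autoscaling options.
* The permutation p-value's strict-inequality convention is
  anti-conservative when error distributions are nearly degenerate
  (e.g. a model that is perfect in both observed and null runs).
* `knn_impute()` is quadratic in the number of samples; fine for
  hundreds of samples, not for thousands.
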