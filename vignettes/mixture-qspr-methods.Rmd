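---
title: "Methods: QSPR modelling of binary-mixture properties with mixqspr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSPR modelling of binary-mixture properties with mixqspr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixqspr)
```

## The modelling problem

`mixqspr` builds linear, interpretable models of a scalar property of
binary mixtures — the canonical case being the density (g/cm³) of deep
eutectic solvents (DES), mixtures of a hydrogen-bond acceptor (HBA,
component 1) and a hydrogen-bond donor (HBD, component 2) measured over a
temperature series.  The inputs are two tables: per-chemical molecular
descriptor vectors (computed elsewhere; this package does not parse
structures or compute descriptors) and a table of data points
(components, mole fractions, temperature, halide indicators, observed
property).

## Weighted-mixture descriptors

A mixture inherits its features from its components through the mole
fractions.  For each base descriptor with component values $D_1, D_2$:

$$D_{pmix} = x_1 D_1 + x_2 D_2, \qquad D_{nmix} = |x_1 D_1 - x_2 D_2|.$$

The sum form is a composition-weighted average; the absolute-difference
form captures the asymmetry between the components and is zero for
identical components at equimolar composition.  Both forms are generated
by default (`wm_features(mode = "both")`) because final models routinely
mix them.  Three variables pass through untransformed: the measuring
temperature `T_K` and two 0/1 indicators for chloride and bromide in the
HBA — needed because descriptors are computed on the HBA's cationic part
only, so the anion must enter separately.  The indicators come from the
input file rather than being inferred from structures, since only
descriptor vectors are required of the user.

Exactly constant columns are removed before modelling
(`drop_degenerate_columns`, `variance_floor = 0` by default): they carry
no information and make correlations and least squares ill-defined.  No
other descriptor pre-cleaning is applied besides the correlation cutoff
below; the models operate on raw descriptor scales, and standardization
occurs only inside the similarity computations of the applicability-domain
and consensus modules.

## Mixtures-out and compounds-out divisions

Random point-wise splits leak information for mixtures: the same mixture
at a neighbouring temperature is almost a duplicate.  Two stricter
divisions are provided.

* **Mixtures-out (MO):** a mixture — a (component-1, component-2) pair at a
  molar ratio — lies wholly in training or wholly in test.  Mixture
  identity includes the ratio rounded to 4 decimals (configurable), so 1:1
  and 2:1 preparations of the same pair are distinct mixtures; the
  rounding precision is a documented default, not an externally mandated
  value.
* **Compounds-out (CO):** whole chemicals are held out.  Chemicals in each
  slot are ranked by record count; selected chemicals pull *all* their
  records into the test set, even records whose partner chemical was not
  selected — so a CO-trained model is scored on genuinely unseen
  chemistry.

Both strategies are driven by two integers.  Items are sorted by instance
count in descending order, ties broken by first occurrence (a stable,
reproducible choice where any order would do); the top item is always kept
in training; items at sorted 0-based positions $\mathrm{seed}+1,
\mathrm{seed}+1+\mathrm{interval}, \dots$ go to test.  The seed is defined
here as a 0-based offset applied after the protected top element; textual
descriptions of such procedures are ambiguous about indexing, so the
convention is stated prominently and the two contracts that matter are
preserved exactly: the maximum-instance item always trains, and the
selection is deterministic in (seed, interval).  Splits whose test share
falls below 20 % of the records are discarded; for CO the filter is
applied to the merged result of the two per-slot passes.  Identical
partitions arising from different (seed, interval) pairs are merged, with
all generating pairs kept as provenance.  Grid enumeration order is
seed-major, and model ids (`MO1`, `CO3`, ...) are this package's own
stable numbering — no attempt is made to reproduce any external tool's
numbering, which is not recoverable from its outputs.

## Sequential forward selection MLR

Before selection, a greedy correlation prefilter removes one member of
every descriptor pair with $|r| > 0.95$ on the training rows: columns are
scanned in order and a column is dropped as soon as it correlates beyond
the cutoff with an already retained column, so the earlier column of a
pair wins.  Which member to drop is arbitrary in principle; scanning in
column order makes the choice deterministic and documented.  The filter is
computed on the training rows of the active split, not the full dataset,
to avoid leaking test-set information into model construction.

Selection is greedy forward: at each step every remaining candidate is
scored — in-sample when `cv_folds = 0`, otherwise by the mean held-out
score over contiguous folds of a seeded permutation (the fold seed is
recorded; fold assignment details are a documented package choice) — and
the best candidate is proposed.  Three scores are implemented, all
oriented so larger is better: $R^2$, negative mean absolute error, and the
negative mean Poisson deviance
$-\frac{1}{n}\sum 2[y\ln(y/\hat y) - y + \hat y]$ (the standard deviance
form, suitable for strictly positive responses).  Ties go to the lowest
column index.

The proposal is accepted only if it reduces the leave-one-out MAE by at
least `pct_mae_reduction` percent (default 5) relative to the current
model; the first rejection stops selection.  For the first step the
reference is the intercept-only model, whose LOO prediction for each point
is the mean of the remaining responses — this makes "relative to the
existing model" well defined from step one.  Setting
`pct_mae_reduction = 0` disables the rule, reducing the procedure to plain
greedy selection truncated by `max_steps`; because selection is greedy and
deterministic, re-running with a larger `max_steps` extends the accepted
prefix without reordering it.  LOO quantities use the exact hat-matrix
identity $e_{(-i)} = e_i/(1-h_i)$, which the tests verify against naive
refit loops to $10^{-12}$.

The final model is ordinary least squares (`stats::lm`) on the accepted
descriptors, reported with standard errors, $R^2$, adjusted $R^2$, the F
statistic and the maximum absolute pairwise correlation among selected
descriptors — the latter used downstream to discard collinear models
(cutoff 0.8 in `rank_and_select`).

## Validation battery

* **LOO:** $Q^2_{LOO} = 1 - \sum e_{(-i)}^2 / \sum (y-\bar y)^2$ and
  $MAE_{LOO}$.
* **Leave-chemical-out (LCO):** every component-1 chemical is removed in
  turn with all its records, the model refit *with the same descriptors*
  on the remainder, and the removed records predicted; likewise for
  component-2.  The two passes each predict every training record once.
  $Q^2_{LCO}$ averages the two $Q^2$-style terms computed against the
  full training mean $Y_m$ (held fixed across removals), and $MAE_{LCO}$
  averages the two sums each divided by the training size $N$.  The
  descriptor set is frozen during LOO/LCO refits — a deliberate choice
  matching per-model reporting practice; full nested reselection would
  measure the selection procedure rather than the model, at much greater
  cost.  A large LOO–LCO gap flags models that lean on individual
  chemicals.
* **External:** $R^2_{pred} = Q^2_{F1} = 1 - \sum(y_{test}-\hat y)^2 /
  \sum(y_{test}-\bar y_{train})^2$ (training-mean centring makes the
  constant predictor score exactly 0), $MAE_{test}$, and
  $\%AARD = \frac{100}{n}\sum|y-\hat y|/y$ (observed value in the
  denominator; safe for positive-valued properties, which the data model
  enforces).
* **rm² metrics:** from the observed-vs-predicted regressions with and
  without intercept, $r_m^2 = r^2(1-\sqrt{r^2-r_0^2})$ in both directions;
  the average and the absolute difference $\Delta r_m^2$ are reported.
  Negative radicands (numerically possible) are clamped at zero and
  flagged.  By default the raw values are used; `scaled = TRUE`
  range-scales both vectors to [0, 1] by the observed range first, since
  both conventions circulate — the choice is reported with the result.
* **Y-randomization:** the response is shuffled (seeded, bit-reproducible)
  `n_runs` times, the model refit on the same descriptors, and
  $^cR^2_P = R\,(R^2 - \bar R_r^2)$ computed with $R=\sqrt{R^2}$ and the
  randomized coefficients aggregated by their mean (the per-run
  distribution is retained).  A square-root variant
  $R\sqrt{R^2-\bar R_r^2}$, common in the literature, is available behind
  a flag; reports always name the variant used.

## Applicability domain

Williams-plot data combine leverages $h = x(X^TX)^{-1}x^T$
(intercept-augmented, against the model's training design) with
standardized residuals $SDR = e/s$,
$s = \sqrt{\sum e^2/(n-p-1)}$.  Records with $h > h^* = 3(p+1)/n$ are
structural outliers; $|SDR| > 3$ marks response outliers.  Test and
external residuals are standardized with the *training* residual scale so
all folds share one axis; internally vs externally studentized variants
are out of scope.  The similarity threshold used by the consensus module
is the mean plus three sample standard deviations of the pairwise
Euclidean distances on z-scored features (training statistics; sample,
i.e. $n-1$, standard deviation; zero-variance columns excluded with a
note).

## Consensus prediction

Given an ensemble of fitted models, each bundled with its own training
rows (`consensus_member`), four combination rules are available: CM0
averages all members; CM1 averages the *qualified* members; CM2 weights
qualified members by the inverse of their local cross-validated MAE — the
mean absolute LOO error over the `n_similar = 10` training records nearest
to the test record in the z-scored union of all members' descriptor
spaces; CM3 picks, per record, the member with the smallest local MAE
(ties to the lower member index).  "Qualified" is implemented as: inside
the member's leverage domain ($h \le h^*$) *and* within the member's
mean + 3·SD similarity threshold of its nearest training record.  The
qualification predicate and the inverse-MAE weighting are explicit
package interpretations — the originating consensus methodology names the
concepts without fixing formulas — and both are configurable and
documented.  If no member qualifies for a record, all members are used and
the record flagged.  Local MAEs that are numerically zero (below
$10^{-12}$) share the CM2 weight evenly, avoiding floating-point-driven
weight explosions.  All consensus predictions are convex combinations of
member predictions.

## The synthetic generator

`synthetic_spec()` encodes the study conditions the package is exercised
under: 17 HBA and 42 HBD chemicals, 145 distinct mixtures at molar ratios
1:1, 2:1 and 3:1, an 8-point temperature series per mixture on a
283.15–373.15 K grid (≈1160 records), a density-like response around
1.1 g/cm³ with a negative temperature slope of $-5\times10^{-4}$ K$^{-1}$
(density falls with temperature), halide shifts of +0.04 (chloride) and
+0.09 (bromide) g/cm³, and additive Gaussian noise of 0.005 g/cm³ —
a realistic experimental scatter for density.  Descriptors are independent
Gaussians with per-descriptor random location and scale; that is
deliberately simple — real descriptor blocks are heavily intercorrelated
and non-Gaussian — so passing recovery tests demonstrate correctness of
the machinery, not performance on real chemistry.  The response is exactly
linear in three weighted-mixture features plus temperature (plus the
halide indicators), which real properties are not.

`perturb_external()` extends the same ground truth to chemicals absent
from the modelling set, mirroring how external validation sets contain new
chemistry; a `shift` parameter moves the new chemicals' descriptor
distributions outward to manufacture structural outliers.

### Problem sizes used in the shipped experiments

The parameter-recovery experiment (50 replicates) uses 12 × 14 chemicals,
10 descriptors, 70 mixtures and 4 temperatures (≈280 records).  The size
is chosen so that descriptor-level sample correlations — whose effective
sample size is the number of *chemicals*, not records — are small enough
for greedy selection to be reliable; with only a dozen chemicals in total,
decoy descriptors frequently correlate with the generating combination
and greedy forward selection (correctly, per its definition) picks them
first.  Split-contract audits run on an 8 × 7-chemical dataset over a
6 × 6 (seed, interval) grid; oracle equivalences use ≤ 30-record
fixtures, where the naive refit loops are exact and fast.

## Numerical choices and degenerate inputs

* Mole-fraction pairs within $10^{-6}$ of summing to 1 are renormalized;
  larger discrepancies are data errors (with the offending row reported),
  not silently fixed.
* Rank-deficient designs raise errors naming the collinear columns, at
  fit time and inside every LOO/LCO refit; `lco_cv(skip_unevaluable =
  TRUE)` instead reports chemicals whose removal leaves too few records
  (fewer than $p+2$) and averages over what it could predict.
* A perfect fit has zero residual scale; SDR is defined as 0 there.
* `external_metrics` refuses a test set with no variance around the
  training mean ($R^2_{pred}$ undefined).
* All stochastic steps (fold assignment, Y-randomization, synthetic
  generation) take explicit seeds and restore the caller's RNG state.

## Known limitations

* Binary mixtures only; ternary systems are out of scope.
* Descriptor computation, structure parsing and descriptor meaning are
  out of scope: the package consumes numeric descriptor tables.
* The descriptor set is frozen during LOO/LCO (no nested reselection).
* Only the three named scoring functions are implemented.
* The applicability domain is leverage-based only (no kNN, bounding-box
  or density variants), and consensus qualification is an explicit
  interpretation (see above).
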