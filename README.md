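# mixqspr

Linear, interpretable QSPR models for **binary-mixture properties** — the
motivating application is the density of deep eutectic solvents (DES),
mixtures of a hydrogen-bond acceptor (HBA, component 1; descriptors computed
on its cationic part) and a hydrogen-bond donor (HBD, component 2).

The package is aimed at cheminformaticians modelling thermophysical
properties of mixtures from *precomputed* per-component molecular
descriptors.  It covers the whole workflow:

1. **Weighted-mixture descriptors.**  For every base descriptor with
   per-component values `D1`, `D2` and mole fractions `x1`, `x2`:

   ```
   Dpmix = x1·D1 + x2·D2        (sum form)
   Dnmix = |x1·D1 − x2·D2|      (absolute-difference form)
   ```

   plus three passthrough variables: temperature `T_K` and binary
   chloride/bromide indicators describing the HBA's anion.

2. **Mixtures-out (MO) and compounds-out (CO) data divisions.**  Unique
   mixtures (or, for CO, unique chemicals per component slot) are sorted by
   instance count; two integers — *seed* and *interval* — pick the test
   items from the sorted list while the most-populated item is always kept
   in training.  Enumerating a (seed, interval) grid yields many candidate
   divisions; only those with a test share ≥ 20 % are retained.

3. **SFS-MLR.**  Sequential forward selection over the descriptor pool
   (after a |r| > 0.95 correlation prefilter), scored by R², negative MAE
   or negative mean Poisson deviance, with an acceptance rule on the
   leave-one-out MAE: a descriptor enters only if it lowers `MAE_LOO` by at
   least 5 % relative to the current model.

4. **Validation battery.**  `Q²_LOO`/`MAE_LOO`; the leave-chemical-out
   metrics `Q²_LCO`/`MAE_LCO` (every HBA, then every HBD, removed with all
   its mixtures and re-predicted); external `R²_pred` (= `Q²_F1`, centred
   on the training mean), `MAE_test`, %AARD; the rm² pair; and
   Y-randomization with `cR²_P = R·(R² − R²_r)`.

5. **Applicability domain.**  Williams-plot data: leverages against
   `h* = 3(p+1)/n` and standardized residuals against |SDR| > 3.

6. **Intelligent consensus prediction** (CM0–CM3) over a model ensemble,
   with per-record model qualification (leverage AD + mean + 3·SD Euclidean
   similarity threshold) and local cross-validated MAE over the 10 most
   similar training records.

A synthetic-data generator with known ground truth
(`synthetic_spec()` / `generate_mixture_data()` / `perturb_external()`)
makes every stage testable without external data.

## Worked example

The package ships a small **synthetic** example dataset (120 records, 5
HBAs × 4 HBDs, 6 descriptors) under `inst/extdata/`:

```r
library(mixqspr)

comp <- read_component_table(system.file("extdata", "example_components.csv",
                                         package = "mixqspr"))
ds <- read_mixture_table(system.file("extdata", "example_mixtures.csv",
                                     package = "mixqspr"), comp)
m <- drop_degenerate_columns(wm_features(ds))

splits <- mo_splits(ds, max_seed = 2, max_interval = 3)
sp <- splits[[which.min(abs(sapply(splits, `[[`, "test_fraction") - 0.3))]]

tr <- wm_subset(m, sp$train_idx); te <- wm_subset(m, sp$test_idx)
pf <- prefilter_correlated(tr$X, 0.95)
sel <- sfs_mlr(pf$X, tr$y, sfs_config(scoring = "R2", max_steps = 10))
sel$model
#> mixture MLR: 5 descriptors, n = 85
#>   y = +1.2712(±0.0130)  +0.0741(±0.0034) d01_pmix -0.0005(±0.0000) T_K
#>       +0.0392(±0.0048) d03_nmix +0.0313(±0.0040) d05_pmix -0.0382(±0.0052) d01_nmix
#>   R2 = 0.9622, adj R2 = 0.9598, max intercorrelation = 0.673

validate_model(sel$model, tr, te, skip_unevaluable = TRUE)
#> internal: Q2_LOO = 0.9555, MAE_LOO = 0.008454, Q2_LCO = 0.9168, MAE_LCO = 0.011
#>           rm2_LOO = 0.9339, delta rm2_LOO = 0.0350, %AARD_train = 0.699
#> external: R2_pred = 0.8796, MAE_test = 0.01292, rm2_test = 0.8293,
#>           delta rm2_test = 0.0628, %AARD_test = 1.135

williams_data(sel$model, tr, te)
#> applicability domain: h* = 0.2118 (n = 85, p = 5)
#>   fold n_structural n_response
#>   test           10          5
#>  train            0          0
```

Reading the output: the model equation lists each selected weighted
descriptor with its coefficient and standard error; `MAE_LOO` is in the
property's units (g/cm³ for density), so 0.0085 means the model predicts a
left-out training point to about ±0.01 g/cm³.  The gap between `Q²_LOO`
(0.956) and `Q²_LCO` (0.917) is small, i.e. predictions do not hinge on any
single chemical.  `R²_pred` is computed against the *training* mean, so the
constant predictor scores exactly 0.  Ten test records fall outside the
leverage domain `h* = 3(p+1)/n` — the MO split put unseen mixtures, some
with unusual descriptor combinations, in the test set.

`run_grid()` automates the loop over splits × scoring × CV,
`rank_and_select()` shortlists models by mean MAE after discarding
collinear ones (max pairwise |r| > 0.8), and `consensus_predict()` combines
the shortlist (see `?consensus_config` for CM0–CM3).

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mixqspr.R", package = "mixqspr"))') \
    featurize --components components.csv --mixtures mixtures.csv --out features.csv
```

Subcommands: `simulate`, `featurize`, `split`, `train`, `validate`,
`domain`, `run-grid`.

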