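# synbinder

Data-efficient binder classification and scaffold-aware library triage for
α-synuclein (αS) fibril ligands.

## The problem

Small molecules that bind αS fibrils with high affinity are candidate PET
imaging probes for Parkinson's disease and related synucleinopathies.
Radioligand displacement assays produce, per compound, a fitted inhibition
constant K<sub>i</sub> (nM) or a censored "no binding" call when no curve
fits below 1 µM. With only a few hundred measurements across three
chemotype families, the practical questions are: which new molecules are
binders (K<sub>i</sub> < 25 nM)? does a trained classifier beat simply
asking "is this similar to a known active?"? and how should a huge
purchasable library be cut down to a small, scaffold-diverse set worth
assaying?

`synbinder` implements that workflow as a tested R package:

* **Chemistry**: native SMILES parsing and canonicalization, ECFP-style
  hashed circular (Morgan) fingerprints (radius 3, 1024 bits), Tanimoto
  similarity T(A,B) = |A∩B| / |A∪B|, and a 30-descriptor 2D panel.
* **Labeling / splitting**: strict-threshold binder labels with censoring;
  stratified train/test splits with largest-remainder allocation.
* **Models**: logistic regression (glmnet), k-nearest neighbours
  (Euclidean or Tanimoto metric) and a CART decision tree, tuned by
  stratified five-fold cross-validation optimizing macro F1
  (the unweighted mean of per-class F1), with two-stage feature selection
  (near-zero-variance filter, then lasso-path ranking with the retained
  size chosen by CV) refit inside every fold.
* **Baseline**: binder iff max Tanimoto to any training binder > τ = 0.5.
* **Curation**: per-compound similarity profiles against the three
  reference chemotypes, histograms, and a 30-compound prospective
  selection (14 top-similarity picks round-robin across chemotypes + 16
  "alternative" compounds with all similarities < 0.2).
* **Synthetic benchmark**: a scaffold-decoration SMILES generator with a
  latent affinity model log₁₀K<sub>i</sub> = intercept − slope·s + ε
  (s = max Tanimoto to hidden pharmacophores), calibrated to the study
  shape: 315 compounds, 138/121/56 chemotype classes, ~20% binders,
  censoring at 1 µM.

See `vignettes/synbinder-methods.Rmd` for the full model description,
parameter table and limitations.

## Worked example

```r
library(synbinder)

ds   <- make_study_dataset(synthetic_config(seed = 7, noise_sd_log10 = 0.1))
mols <- attr(ds, "molecules")
sp   <- stratified_split(ds$id, ds$label, test_fraction = 44/315, seed = 7)
tr   <- ds$id %in% sp$train_ids
te   <- ds$id %in% sp$test_ids

fm    <- build_feature_matrix(mols[tr])
model <- tune_and_train(fm, ds$label[tr], seed = 7)
model
#> <trained_model> k_nearest_neighbors (k=5, weights=distance, metric=euclidean); 32 features; CV macro F1 0.895 +/- 0.040

classification_report(ds$label[te], predict(model, mols[te])$label)
#>              Precision    Recall        F1
#> Non-binder        0.92      0.94      0.93
#> Binder            0.75      0.67      0.71
#> Accuracy                              0.89
#> Macro             0.83      0.80      0.82
#> Weighted          0.88      0.89      0.88

baseline_evaluate(mols[tr], ds$label[tr], mols[te], ds$label[te])$report$macro[["f1"]]
#> [1] 0.4958333
```

The trained model recovers the latent structure–affinity signal (held-out
macro F1 0.82 on the 44-compound test set here; 0.89 averaged over ten
seeds by `scripts/acceptance.R`) while the τ = 0.5 similarity baseline
reaches only 0.50 (0.55 averaged over ten seeds — close to the 0.56 the
original study reports for its real-data baseline). The table layout above
is the standard classification-report format used for all written reports.

Full pipeline (dataset → split → featurize → tune/train → test report →
baseline → curation → prospective prediction and evaluation), with every
artifact and seed written to an output directory:

```r
res <- run_study(run_config(output_dir = "run1",
                            synthetic = synthetic_config(seed = 1)))
```

Command line (after install):

```sh
Rscript inst/cli/synbinder.R run-all --out-dir run1 --seed 1
Rscript inst/cli/synbinder.R simulate --n 315 --out-table study.tsv --out-library lib.smi
Rscript inst/cli/synbinder.R baseline --train train.tsv --test test.tsv --tau 0.5
```

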