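# hsifluor

Hyperspectral fluorescence analysis of 5-ALA labeled brain tumor biopsies:
spectral unmixing into fluorophore abundances, class-separation statistics,
and a balanced machine-learning classification protocol — with a synthetic
biopsy simulator so the entire chain is testable without patient data.

## The problem

After 5-aminolevulinic acid (5-ALA) administration, malignant glioma
accumulates protoporphyrin IX (PpIX) and fluoresces red under blue
excitation. Hyperspectral imaging of ex vivo biopsies records an emission
spectrum at every pixel across 420–730 nm. The analysis question is whether
those spectra carry enough information to classify tissue type, resection
margin zone (solid tumor / infiltrating zone / reactively altered brain
tissue), WHO grade, and IDH mutation status.

The core model treats each measured spectrum *y* (310 bands) as a
non-negative mixture of five fluorophore endmember spectra — the columns of
a 310 × 5 matrix *B*: the two PpIX photo-states (PpIX634, PpIX620), NADH,
lipofuscin, and flavins —

> c = argmin\_{c ≥ 0} ½ ‖y − B c‖²

solved by non-negative least squares. The 5-vector of abundances *c* is the
feature representation for all downstream statistics (PCA variance
explained, pairwise two-sample Kolmogorov–Smirnov tests) and classifiers
(random forests, KNN, SVM, MLP, AdaBoost under a balanced, cross-validated
selection protocol).

For whom: researchers in fluorescence-guided neurosurgery and biomedical
optics who need a reproducible, tested reference implementation of this
analysis chain, or a simulator to benchmark alternative unmixing and
classification strategies.

## Worked example

```r
library(hsifluor)

# five-fluorophore basis on the canonical 310-band grid
B <- synthetic_basis()
#> <fluorophore_basis> 310 bands x 5 fluorophores (peak-normalized)
#>   peak positions: PpIX634=634nm, PpIX620=620nm, NADH=460nm,
#>                   lipofuscin=570nm, flavins=525nm

# unmixing recovers a noiseless mixture exactly
y <- reconstruct_spectrum(c(40, 15, 0, 0, 12), B)
unmix_nnls(y, B)
#>    PpIX634    PpIX620       NADH lipofuscin    flavins
#>         40         15          0          0         12
#> residual_norm: 3.14278e-14

# synthetic margin dataset: 10 biopsies per class at working separation
ds <- simulate_dataset("margin", margin_preset(1),
                       n_biopsies_per_class = 10, seed = 1)
#> <simulated_dataset> task=margin: 30 biopsies, 26032 blocks, seed=1

# balanced features (3 adjacent blocks per sample -> 15 columns),
# 80/20 split, 5-fold CV over the model grid, held-out evaluation
ft <- build_feature_table(ds, pixels_per_sample = 3,
                          samples_per_class = 500, seed = 2)
res <- train_and_evaluate(ft, model_grid_default(), seed = 3)
res$report
#> <evaluation_report> random_forest(ntree=100, max_features=sqrt, nodesize=2)
#>   accuracy 0.987 on 300 test samples; macro AUC 0.999
#>   confusion matrix:
#>       predicted
#> truth  IZ RABT  ST
#>   IZ   97    1   2
#>   RABT  1   99   0
#>   ST    0    0 100

# class-separation statistics
ks_battery(ds$abundances, ds$blocks$label)
#> <ks_report> 3 classes, 15 tests at alpha=0.01: 0 exception(s)
#>   all class pairs significantly different in all fluorophores

sapply(2:5, function(n)
  pca_variance_explained(ds$abundances, n)$variance_explained)
#> [1] 0.961 0.984 0.994 1.000
```

The evaluation report reads as: the selected random forest classifies the
three margin classes of the held-out set with 98.7% accuracy; the
one-vs-rest macro AUC of 0.999 says class scores rank almost perfectly; the
confusion matrix shows the few errors sit on the ST/IZ/RABT boundaries, as
expected for a continuum of infiltration. The KS battery finds every class
pair significantly different (p < 0.01) in every fluorophore at this
sample size, and 2-component PCA already explains 96% of the abundance
variance.

A complete staged run (simulation → preprocessing → unmixing → statistics →
training → evaluation, with manifest, figures, and per-stage seeds) is one
call:

```r
m <- run_pipeline(run_config(task = "margin", seed = 1,
                             out_dir = "margin_run"))
make_report(m)   # confusion/ROC/PCA/PpIX-overlay figures + report.md
```

or, from a shell, `Rscript inst/cli/hsifluor.R demo --seed 1 --out margin_run`.

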