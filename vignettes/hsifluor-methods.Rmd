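---
title: "Methods: hyperspectral fluorescence unmixing and classification of brain tumor biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral fluorescence unmixing and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsifluor)
```

## The measurement model

5-ALA administration causes malignant glioma to accumulate protoporphyrin IX
(PpIX), which fluoresces red under blue (405 nm) excitation. The imaging
system sweeps a tunable bandpass filter across the visible range and records
one grayscale image per band, producing a hyperspectral cube in which every
pixel carries an emission spectrum. Three illumination phases are acquired
per biopsy: blue (fluorescence), no light (sensor dark level), and broadband
white (reflectance reference).

Each measured emission spectrum $y \in \mathbb{R}^{310}$ is modeled as a
non-negative linear mixture of five fluorophore endmembers collected as the
columns of $B \in \mathbb{R}^{310 \times 5}$ — the two PpIX photo-states
(emission maxima near 634 and 620 nm), NADH, lipofuscin, and flavins:

$$ c = \operatorname*{argmin}_{c \ge 0} \tfrac{1}{2} \lVert y - Bc \rVert^2 $$

solved by non-negative least squares. The abundance vector $c \in
\mathbb{R}^5_{\ge 0}$ is the feature representation used by all downstream
statistics and classifiers.

### Wavelength grid

The instrument sweeps 420–730 nm in 3–5 nm steps while the spectrum vector
has 310 entries; we therefore fix the canonical internal grid at 310 bands
of 1 nm from 420 to 729 nm, which reproduces the basis dimensions exactly,
and map coarser instrument grids onto it by linear interpolation
(`resample_to_grid()`, clipped at zero). Linear interpolation is our choice;
any monotone scheme could be substituted at the same interface.

### The fluorophore basis

Measured endmember spectra are instrument-specific and not shipped here.
`synthetic_basis()` builds a parameterized stand-in from skew-normal peaks
whose *modes* are placed exactly at the nominal emission maxima
(PpIX634: 634 nm / FWHM 20 nm; PpIX620: 620 nm / 25 nm; NADH: 460 nm /
100 nm; flavins: 525 nm / 80 nm; lipofuscin: 570 nm / 120 nm; mild red
skew). The PpIX positions are the established photo-state maxima; the
autofluorophore centers and widths are literature-typical values, not
measurements. Measured endmembers drop in via `read_basis_csv()`
(`wavelength_nm,PpIX634,PpIX620,NADH,lipofuscin,flavins`). Columns are
peak-normalized by default so abundances read as peak-equivalent
intensities; area normalization is provided.

### NNLS

`nnls_solve()` implements the Lawson–Hanson active-set method with a
scale-free KKT tolerance of $10^{-10}\,\lVert B^\top y\rVert_\infty$. The
solver is validated two ways: against exhaustive support enumeration (all
$2^5$ supports, feasible least-squares minima) on random instances, and
against an independent solver. Useful properties that hold exactly:
scaling equivariance ($\hat c(\alpha y) = \alpha\,\hat c(y)$), exact
recovery of consistent non-negative mixtures, and residual monotonicity
when columns are added.

## The synthetic data generator

Patient measurements cannot be redistributed, so the package ships a
generator whose defaults mirror the study conditions; every downstream
stage is tested against it.

* **Class-conditional abundances.** Block-level log-abundances are normal:
  class mean + biopsy-level brightness effect
  ($\mathcal N(0, \sigma_b)$, shared by all blocks of a biopsy and all five
  fluorophores) + independent block noise ($\mathcal N(0, \sigma)$), i.e.
  abundances are log-normal — strictly positive and heavy-tailed, as
  fluorescence intensities are. Defaults $\sigma = 0.3$, $\sigma_b = 0.15$
  on the log scale are our choice of a realistic within-class spread; the
  source data report no distributional form.
* **Presets and the separability knob.** The four tasks ship presets whose
  class rosters mirror the source cohorts (margin: ST 131 / IZ 57 /
  RABT 100 biopsies; analogous rosters for tissue type, WHO grade, IDH).
  Between-class log-mean offsets are scaled by a knob $\Delta$:
  $\Delta = 0$ collapses all classes onto one distribution (the null
  preset), $\Delta = 1$ is the working separation, $\Delta = 2$ a strongly
  separated regime. Offsets are hand-laid so solid tumor and high-grade
  entities are PpIX-rich and autofluorescence-poor; the ST–IZ pair
  deliberately shares its lipofuscin component so that pair can differ in
  at most four of five fluorophores, mirroring the qualitative exception
  pattern seen in practice.
* **Geometry.** A biopsy is a disk of 4–10 mm diameter (190–476 px at
  47.62 px/mm) centered in a 2048 px field (configurable), with a glass
  background. Abundances are piecewise constant over the grid-aligned
  10 × 10 px blocks tiling the disk. A 6 mm (288 px) phantom yields roughly
  600 complete blocks, inside the expected 100–1000 spectra per biopsy.
* **Acquisition noise.** Gaussian read noise plus a Gaussian approximation
  of Poisson shot noise (variance proportional to signal) plus a constant
  dark offset — the standard sCMOS model. `noiseless()` switches all of it
  off for exact-arithmetic tests.
* **Artifacts.** An optional bright fluid blob adjacent to the tissue tests
  the artifact-exclusion path of segmentation.

What the generator does **not** emulate: within-biopsy spatial correlation
beyond block granularity, scattering/absorption physics, wavelength-dependent
reflectance, inter-patient batch structure, and label noise at class
boundaries. Passing tests therefore demonstrate the correctness of the
pipeline's arithmetic and protocol, not clinical performance; the published
patient-data accuracies are not reproducible from synthetic data, and the
package makes no claim to reproduce them.

## Preprocessing

1. **Dark correction**: blue − dark, clipped at zero.
2. **Segmentation** (`segment_tumor()`): Otsu threshold on the band nearest
   634 nm, morphological opening (5 px disc), largest connected component.
   The original workflow used an unspecified interactive routine with
   manual checking; this thresholding stand-in is recorded in
   `TumorMask$method` and is swappable. With artifact exclusion on
   (default), bright components other than the largest are dropped.
3. **Block extraction** (`extract_block_spectra()`): grid-aligned,
   non-overlapping 10 × 10 px tiles fully inside the mask, anchored at the
   mask bounding-box origin (0-based, half-open coordinates); each tile is
   averaged to one spectrum, so data points are spatially independent.
4. **Dual-band normalization** (`dual_band_normalize()`): division by the
   geometric mean of the white-light reference in two bands (defaults
   460–480 nm and 620–640 nm, bracketing the autofluorescence and PpIX
   regions). The exact published formula and band choice are not public;
   this operation is a documented strategy with the key invariance — a
   uniform illumination scaling applied to both fluorescence and reference
   cancels exactly. Normalization is applied per block; per-pixel versus
   per-block application is not settled by the source description, and
   per-block is cheaper at identical results for piecewise-constant
   phantoms.

With all noise off, simulate → preprocess → unmix returns the phantom's
block abundances to machine precision (the per-block normalization factor
is returned so tests can undo the bookkeeping).

## Statistics

* **PCA variance explained**: eigendecomposition of the covariance of
  mean-centered data; variance explained of an $n$-component projection is
  the sum of the $n$ largest eigenvalues over the trace. It equals 1 at
  $n = \mathrm{rank}$ (noiseless 5-fluorophore mixtures reach 1.0 at
  $n = 5$ to $10^{-10}$) and is monotone in $n$. Constant data is a
  zero-variance error.
* **t-SNE** (`tsne_embed()`): seeded, 2-D or 3-D, for visualization only.
* **KS battery** (`ks_battery()`): for each fluorophore and unordered class
  pair, the two-sample Kolmogorov–Smirnov test at $\alpha = 0.01$.
  The default p-value uses the Kolmogorov asymptotic with the classical
  small-sample correction
  $\lambda = D(\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})$, matching common
  implementations; a permutation mode (complete enumeration when feasible)
  covers small samples. All spectra are pooled per class, as in the source
  protocol — note the independence caveat: blocks from one biopsy share a
  brightness effect, so pooled p-values are anti-conservative with few
  biopsies. No multiple-testing correction is applied by default because
  raw pairwise p-values at 0.01 are the protocol; `p_adjust` exposes
  standard corrections. Type-I calibration at $n = 200$ per class lands in
  [0.003, 0.03] at $\alpha = 0.01$.

## Classification protocol

* **Samples.** A sample concatenates the abundance vectors of
  `pixels_per_sample` (1–3) spatially adjacent blocks of one biopsy — the
  seed block plus its nearest disjoint tiles by Euclidean tile distance,
  ties broken row-major — giving 5, 10, or 15 features.
* **Balancing.** Classes with fewer candidate samples than
  `samples_per_class` are excluded; every surviving class contributes
  exactly `samples_per_class` rows, drawn without replacement.
  `samples_per_class = NULL` balances at the smallest surviving class
  ("all available"). Named classes (e.g. AE) can be excluded explicitly.
* **Relabeling.** `relabel_who2021()` maps IDH-wildtype anaplastic
  astrocytoma to glioblastoma, the 2021 WHO reclassification, leaving all
  other records (including unknown IDH) unchanged.
* **Split and selection.** Stratified 80/20 train/test split; 5-fold
  stratified cross-validation ranks the model grid by mean accuracy on the
  training side only; ties break toward fewer hyperparameters, then grid
  order. The per-spectrum split is the default (each block is an
  independent data point); a biopsy-grouped split is provided for
  leakage-free evaluation when biopsy effects matter.
* **Models.** Random forests (`randomForest`; Gini splitting), KNN with
  Minkowski $p \in \{1,2\}$ and uniform/distance weights (in-package —
  no installed engine exposes these options), SVMs with four kernels
  (`e1071`), multilayer perceptrons with 1–3 hidden ReLU layers trained by
  minibatch Adam or full-batch L-BFGS (in-package — no installed R engine
  provides multi-layer ReLU networks), and AdaBoost (SAMME.R over
  depth-1 `rpart` stumps, 50 estimators, learning rate 1; in-package).
  `model_grid_table1()` enumerates the full 90-spec published grid;
  `model_grid_default()` is a 5-spec demo grid. MLP and KNN standardize
  features internally.
* **Evaluation.** Accuracy = correct/total; K × K confusion matrix;
  one-vs-rest ROC per class from predicted class probabilities (`pROC`),
  macro-averaged AUC (the averaging scheme for the published single AUC is
  unstated; one-vs-rest macro is our choice). Test AUCs are cross-checked
  in the suite against a pairwise rank-comparison oracle.

Under the margin preset at $\Delta = 2$ with 1000 samples per class and 3
pixels per sample, the selected model reaches test accuracy ≥ 0.95 and
macro AUC ≥ 0.98; at $\Delta = 0$ test accuracy stays inside the
3-standard-error binomial band around 1/3. These synthetic recoveries are
the testable substitute for the non-reproducible patient-data accuracies.

## Reproducibility and the pipeline runner

`run_pipeline()` executes simulate → preprocess → unmix → stats → train →
evaluate from a serializable `run_config()`; one global seed drives every
stage through a deterministic counter scheme (`derive_seed()`), and the
manifest records per-stage seeds, timings, and artifact checksums, so a
re-run of an archived config is artifact-identical. Missing upstream
artifacts raise dependency errors naming the stage. `make_report()` renders
the confusion matrix, ROC curves, a 2-component PCA scatter, the PpIX634
abundance overlay, and the KS exception table.

Cubes travel as multi-page 32-bit float TIFFs plus a JSON sidecar; since
float TIFF storage is defined on [0, 1], counts are stored divided by a
per-cube scale factor recorded in the sidecar.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run phantoms of 90–288 px
diameter in 120–340 px fields (full 310-band grids where spectra are under
test, 4–40 bands where only geometry is), preset-roster datasets at the
block level (~250k blocks), 2000-replicate KS calibration at $n = 200$, and
classifier recovery at 3 × 1000 samples — sizes we chose so the whole suite
completes in well under a minute while every check retains its power.
Degenerate inputs are handled explicitly: empty masks warn and return
empty, tiles not fully inside a mask are dropped, constant data is a PCA
error, classes with fewer than two samples are excluded from the KS battery
with a warning, and degenerate CV folds are redrawn with a derived seed.

## Known limitations

* The synthetic basis is a parameterized stand-in; absolute abundances are
  only meaningful relative to the chosen normalization.
* Segmentation is a global-threshold stand-in; it assumes tissue is the
  largest bright object in the field.
* Pooled KS tests ignore within-biopsy correlation (flagged above).
* The random-forest engine does not expose entropy/log-loss splitting; the
  published criterion axis collapses to Gini here.
* t-SNE and PCA visualizations are qualitative; no classifier consumes
  them.
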