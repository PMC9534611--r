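---
title: "Wavelet radiomics for GBM-vs-MET discrimination: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet radiomics for GBM-vs-MET discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wavemics` implements a two-stage radiomics pipeline for separating
glioblastoma from brain metastasis on conventional MRI, with a synthetic
cohort generator in place of patient data. This vignette explains the
models and conventions stage by stage, the parameters that matter, the
numerical choices, and what the synthetic experiments do and do not show.

## Preprocessing and discretization

Volumes are resampled to 1 mm isotropic spacing (trilinear for
intensities, nearest-neighbor for masks) before anything else; feature
values therefore refer to a physically isotropic grid. Gray levels inside
the ROI are discretized with a fixed **bin width** of 64 intensity units
anchored at the ROI minimum: `level(v) = floor((v − min)/64) + 1`. The
fixed-width convention (rather than a fixed level count) means the number
of levels scales with the ROI's dynamic range, and adding a constant to
all intensities changes no texture feature — a property the test suite
asserts. Both defaults (1 mm, width 64) are exposed as arguments of
`extract_features()`.

## The 107-feature panel

Per sequence the panel is shape (14), first-order (18), GLCM (24),
GLRLM (16), GLSZM (16), GLDM (14), NGTDM (5); four sequences give the
428-column patient row. Conventions worth stating:

* **Aggregation.** All directed texture matrices (GLCM, GLRLM) use the 13
  unique 3D offsets at Chebyshev distance 1; statistics are computed per
  direction and averaged, not pooled into one merged matrix.
* **First order.** Moments, percentiles and energies use raw intensities;
  Entropy and Uniformity use the discretized histogram. Variance,
  skewness and kurtosis are population moments; kurtosis is not
  excess-corrected, and a constant ROI yields 0 under the 0/0 → 0
  convention.
* **GLCM degenerate cases.** On a single-level ROI, Correlation and MCC
  are defined as 1 (perfect association of a constant), entropies and
  contrast-type statistics as 0, JointEnergy as 1. These sentinels are
  documented behavior, not errors; an ROI with no co-occurring pair in
  any direction does error.
* **GLDM dependence.** A voxel's dependence is 1 + the number of its 26
  in-mask neighbors with equal level (α = 0), so sizes run 1–27.
* **Mesh features.** MeshVolume, SurfaceArea and Sphericity
  (`(36πV²)^{1/3}/A`) come from a triangulated iso-surface at level 0.5.
  The mask indicator is first smoothed with a Gaussian of σ = 1 voxel and
  then meshed by marching tetrahedra (6-tetrahedron cell decomposition,
  triangles oriented by the local inside/outside geometry, volume via the
  divergence theorem). Meshing the raw binary field would track the voxel
  staircase and inflate the area of a digital ball by about 9%
  (sphericity ≈ 0.91); with the smoothed indicator the area is within 2%
  and sphericity ≈ 0.995 of the analytic sphere, which is why this
  package meshes the smoothed field. Masks too small to support an
  iso-surface (e.g. a single voxel) fall back to voxel volume and summed
  exposed-face area rather than failing.
* **Diameters.** Maximum 3D and per-plane 2D diameters are maxima of
  pairwise distances over boundary voxel centers; for very large
  boundaries a hull-like pruning keeps the quadratic pass bounded.

## Reliability filtering

Each feature's reproducibility across repeated segmentations is scored
with ICC(2,1) — two-way random effects, absolute agreement, single
measurement — computed from the ANOVA mean squares. The intra-observer
stack pairs reader 1's two sessions; the inter-observer stack pairs both
readers' first sessions; these assignments are declared conventions since
any reader/session pairing is defensible. A feature is kept only if
**both** ICCs strictly exceed 0.75 ("over 0.75" read as strict
inequality). A zero-variance stack (identical measurements everywhere) is
perfect agreement on a constant and scores 1.

## Normalization and LASSO selection

Z-scores are fitted on training rows only and applied unchanged to
held-out rows; zero-variance columns are dropped with a warning. The
LASSO logistic regression runs once on the full 428-column table (all
sequences jointly), with stratified 10-fold CV over the penalty grid and
the penalty chosen at minimum mean binomial deviance — the plain minimum,
not the 1-SE rule, because it is the simpler rule to document. Features
with nonzero coefficients, in input column order, form the selection; the
assembled row is ordered sequence-major (T1W, T2W, T1C, FLAIR). The
pipeline asks for at least 4 selected features (one per matrix row of the
wavelet stage) and relaxes the penalty along the fitted path when the
deviance minimum selects fewer.

The study design this mirrors used both a 70/30 split for
normalization/selection and repeated 5-fold CV for model comparison
without stating their composition; here the declared composition is:
selection happens once on the full table, and the downstream comparison
re-fits normalization inside every CV fold, so no held-out fold ever
contributes normalization statistics.

## The wavelet profile

The selected row of length *m* is laid out row-major into a
4 × max(2, ⌈m/4⌉) matrix — one row per MRI sequence, zero-padded on the
right (padding count recorded). The choice of rows-as-sequences is the
natural reading of a "four-sequence signal"; the exact matrix shape is
otherwise unconstrained, so it is fixed here as a documented convention.

A single-level separable 2D DWT with **symmetric (half-sample) boundary
extension** produces cA, cH, cV, cD under each of the 31 filter banks
(biorthogonal: bior1.3, 1.5, 2.2, 2.4, 2.6, 3.1, 3.3, 3.5, 3.7, 4.4,
5.5; Daubechies db2–db9; symlets sym2–sym8; coiflets coif1–coif5). The
filter coefficients are the standard published values for these families.
Symmetric extension is the fixed default so profiles are bit-reproducible;
a periodization mode exists as well and is what the energy-conservation
(Parseval) tests use, since only the circular transform is exactly
orthogonal for the orthonormal families.

The 36 criteria are: 7 statistics per matrix × 4 matrices (28); slope and
slope standard error of the OLS fit of each flattened detail matrix on
flattened cA (6), with a zero-variance cA treated as a degenerate fit
(slope 0, SE 0, flagged); and whole-signal energy plus "wavelength" (2).
Two definitional choices deserve flagging:

* **Entropy of a coefficient matrix** is Shannon entropy (base 2) of the
  normalized squared coefficients `p_i = x_i²/Σx²`, since raw
  coefficients are signed and do not form a probability mass; an all-zero
  matrix has entropy 0.
* **Wavelength** is implemented as waveform length, `Σ|x_{i+1} − x_i|`, a
  standard signal criterion; the term is otherwise undefined and this
  reading is an interpretation, stated as such.

## Classifier benchmarking

Eight families with fixed, documented hyperparameters (reproducibility
over tuning): RBF SVM (cost 1, γ = 1/p, Platt-calibrated probabilities),
Gaussian Naive Bayes, single-hidden-layer MLP (8 units, decay 0.01, 200
iterations), CART decision tree (cp 0.01), discrete AdaBoost with 100
depth-1 stumps (margin mapped to probability via 1/(1+e^{−2F})), 5-NN,
logistic regression, and a 100-tree random forest. Every model emits a
positive-class probability; the positive class for F1 is GBM (the larger
class), a declared choice.

Evaluation is stratified 5-fold CV repeated 100 times (repeat *r* seeds
the fold draw with `seed + r − 1`); inside each fold, z-scores are
re-fitted on the training part only. Accuracy thresholds scores at 0.5;
AUC is the rank (Mann–Whitney) statistic. The grid covers 31 banks × 8
classifiers (248 cells) plus the plain model's 8 cells. The best cell is
the AUC argmax with ties broken by accuracy, F1, then lexicographic bank
id. Pairwise ROC comparisons use DeLong's test on the pooled out-of-fold
scores of the first repeat — the scores entering the test are a declared
convention since pooled-vs-averaged is otherwise unspecified — at
uncorrected α = 0.05, as is conventional for these comparison tables.

## The synthetic cohort

The generator emulates the study conditions: 91 patients at a 51:40
GBM:MET split by default, four co-registered sequences, one ellipsoidal
lesion per patient. Class signal enters through two channels chosen so
every feature family has something to recover: per-class radius ranges
(GBM 6–10 mm, MET 4.5–8 mm per axis) drive the shape features, and
within-ROI texture — a Gaussian random field with class-specific
correlation length (GBM 2.2 mm, MET 1.2 mm) and per-sequence mean/sd —
drives the histogram and texture families. No intensity or morphology
statistics of the original cohort are published, so these values are
field-plausible choices fixed once, not calibrations.

Repeated segmentations flip each boundary-shell voxel independently with
probability `reader_jitter` (default 0.05) and add a partial one-voxel
dilation or erosion (an extra biased flip pass on one shell), producing
an ICC spread that straddles the 0.75 threshold at moderate jitter while
keeping any two masks of a patient above 0.8 Dice at the default.

What passing tests show — and what they do not: the synthetic lesions are
smooth ellipsoids with stationary texture, no bias fields, no partial
voluming, no necrotic cores, no peritumoral edema, and a common
acquisition model across patients. Results on this cohort validate the
*machinery* (feature definitions, reliability filtering, selection,
transforms, evaluation protocol) and directional behavior, not the
patient-data effect sizes; synthetic classes are typically far more
separable than real ones, so absolute AUCs saturate quickly.

## Problem sizes and numerical notes

The package's own test and demonstration runs use reduced problem sizes
chosen to keep the full suite fast while leaving every code path
exercised: cohorts of 4–24 patients on 18³–24³ grids for image-based
stages, 16–200 patients for table-based stages, repeats 1–20, and the
reduced wavelet-vs-plain comparison at 5 repeats × 5 folds over 4 banks ×
3 classifiers. Oracle-equivalence tests run on ≤ 4×4×4 ROIs and ≤ 8×8
matrices where brute-force enumeration is exact. Seeds fan out from one
global seed via a deterministic stage-name hash, kept below 2³¹.

Degenerate inputs are handled by documented convention rather than
failure wherever a convention is defensible (constant ROIs, single-level
GLCMs, zero-variance regressors, masks too small to mesh); genuinely
uninterpretable inputs (empty masks, non-finite intensities, one-class
labels, unknown filter banks) error early with the offending item named.

## Known limitations

* The synthetic generator is not calibrated to any real cohort; absolute
  metric values on it are not comparable to patient-data results.
* GLDM's dependence definition (α = 0, center counted) and the
  first-order raw-vs-discretized split follow common extraction-tool
  conventions but other tools differ in details; cross-tool numerical
  parity is not a goal.
* ICC confidence intervals and mixed-model alternatives are out of scope;
  only the point estimate gates filtering.
* The DWT is single-level by design; multi-level and wavelet-packet
  variants are not implemented.
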