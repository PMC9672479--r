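---
title: "Time-dimension radiomics of DSC perfusion MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dimension radiomics of DSC perfusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscradiomics)
```

## The problem

Dynamic susceptibility contrast perfusion-weighted imaging (DSC-PWI)
records a 4D series: a 3D brain volume at every timepoint while a
gadolinium bolus passes through the vasculature. Well-perfused tissue
shows a deep, transient signal drop; hypoperfused tissue — the tissue at
risk in ischemic stroke — shows a much shallower drop because little
contrast reaches it. Clinical practice reduces this rich time-resolved
signal to a handful of summary parameters (most prominently Tmax); this
package instead asks what high-throughput *radiomics* features computed
per timepoint can say about the perfusion state of a region.

The pipeline has six stages, each exposed as package functions:

1. **Phantom cohort** (`generate_phantom()`, `generate_cohort()`): a
   synthetic 4D perfusion cohort with ground-truth hypoperfusion (HA)
   masks and mirrored normal-area (NA) masks.
2. **Preprocessing** (`smooth_time_series()`, `mirror_roi()`,
   `split_hemispheres()`, `normalize_features()`).
3. **Per-timepoint radiomics** (`extract_series_features()`): the 4D
   series is decomposed into T 3D images; each yields 1,316 features
   under the default configuration, 65,800 for T = 50.
4. **Significance screen** (`ttest_filter()`): per-feature two-sample
   t-test, keep p < 0.05.
5. **Selection bank** (`score_features()`, `apply_threshold()`): 13
   selectors from four families, a common thresholding rule, and a
   composite-score evaluation over ten classifiers
   (`evaluate_sets()`).
6. **Lesion-proportion experiment** (`sweep_rt()`): hemisphere samples,
   middle-S slabs, sliding lesion-fraction threshold RT, per-cell Lasso
   re-selection and cross-validation.

## The phantom: what it emulates and what it does not

Each voxel's time-intensity curve is a gamma-variate bolus passage
converted to signal loss:

$$C(t) = A\,\Big(\frac{t-t_0}{\alpha\beta}\Big)^{\alpha}
        e^{\alpha-(t-t_0)/\beta},\qquad
  I(t) = I_0\, e^{-k\,C(t)},$$

peak-normalised so the curve maximum is $A$ at $t_0 + \alpha\beta$.
Defaults: $I_0 = 100$, $t_0 = 8$ timepoints, $\alpha = 3$,
$\beta = 1.5$, $A = 1$, $k = 0.5$, i.e. a ~40% signal drop in normal
tissue. Inside the lesion the bolus is attenuated (amplitude
$\times$ 0.4) and delayed (+2 timepoints) by default, reproducing the
hallmark that hypoperfused tissue dips far less than its mirrored
normal counterpart. With attenuation 1 and delay 0 lesion voxels are
statistically indistinguishable from normal tissue — the null
configuration used for calibration tests.

Deliberate simplifications, all of which matter when reading the test
results: the brain is an axis-aligned ellipsoid (no anatomy), the lesion
is a 6-connected region grown from a random seed voxel until the target
fraction of hemisphere brain voxels is reached (realised fraction within
a voxel of the target), noise is additive Gaussian in signal units
rather than Rician, and per-voxel heterogeneity is a ±5% jitter of
arrival time and amplitude (without it, constant ROIs would make
co-occurrence-type features degenerate). Lesion volume fractions default
to uniform on [0.02, 0.5] — a stand-in for the broad lesion-volume
spread seen clinically, not a claim about any particular population.

Because the phantom's HA/NA contrast is governed by a single strong
mechanism, an 80-subject effect cohort is close to perfectly separable:
cross-validated metrics saturate near 1 and the composite scores of all
13 selectors collapse to the top of the scale. Passing tests on the
phantom therefore demonstrate that the machinery is correct and
calibrated (null cohorts stay at chance; planted features are
recovered), *not* that the method would reach any particular accuracy on
patient data, where registration error, biological variability and
pathology heterogeneity dominate.

## Feature scheme

Per timepoint the default configuration computes 107 features on the
original image — 14 shape (mask-only), 18 first-order, 24 GLCM, 16
GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM — and the 93 non-shape features again
on 5 Laplacian-of-Gaussian images (sigma 1–5 mm) and 8 one-level
undecimated 3D Haar sub-bands: $107 + 13 \times 93 = 1{,}316$. Names
follow `<filter>_<family>_<base>_<n>` with a 0-based time index, e.g.
`log-sigma-1-0-mm-3D_firstorder_Skewness_17`, and parse back exactly
(`parse_feature_name()`). Nine reporting groups are used throughout:
filtered features count toward Log-sigma or Wavelet regardless of their
texture family, giving group totals
{700, 900, 1200, 800, 800, 250, 700, 23250, 37200} at T = 50.

Numerical choices:

* **Discretization**: the ROI intensity range is divided into 25
  equal-width gray levels (bin width = range/25), making matrix sizes and
  feature counts invariant to intensity units; an absolute bin width can
  be supplied instead. A mask whose values collapse to a single level is
  rejected with an error naming the family.
* **Direction handling**: co-occurrence and run-length matrices
  accumulate all 13 unique 3D directions into one merged (symmetric)
  matrix rather than averaging per-angle features. This is a documented
  implementation choice; the package contract is counts, names,
  determinism and family semantics, not bitwise equality with any other
  radiomics implementation.
* **Filters**: LoG kernels are sampled analytic Gaussian second
  derivatives with scale normalisation ($\sigma^2$), separable
  convolution, replicate edges; the wavelet transform is undecimated so
  sub-bands keep the image size. Filtering happens on a crop of the mask
  bounding box padded by the kernel radius, which leaves masked voxels
  identical to full-image filtering away from volume borders.
* **Shape**: volumes are voxel-counting, surface area is exposed-face
  counting, axis lengths come from the PCA of voxel coordinates
  ($4\sqrt{\lambda}$), and the 2D/3D maximum diameters are exact maxima
  of pairwise distances over surface voxels.

## Preprocessing

The temporal filter is a *triple moving average*: three successive
passes of a centred 1×3 mean filter with replicate padding. The
single-pass reading was rejected as it would make "triple" redundant;
replicate padding keeps constant series invariant and conserves the
series sum exactly, which the tests assert. Feature normalisation is the
mean-centred range scaling $F^* = (F - \bar F)/(F_{max} - F_{min})$ —
deliberately *not* min-max scaling, though `method = "min_max"` is
available — so every non-constant column has range exactly 1, and
two-sample t-test p-values are unchanged (it is a per-column affine
map). Constant columns cannot be scaled and are dropped with a warning.

The NA region is the x-mirror of the HA mask about the midsagittal
plane; hemisphere splitting assigns the midline column of odd-width
grids to neither side, so 80 subjects always yield exactly 160
hemisphere samples.

## Significance screen

An independent two-sample Student t-test per feature (Welch available
via `var_equal = FALSE`), retaining raw p < 0.05 with **no**
multiple-testing correction — the screen is a deliberate liberal filter
ahead of the selection bank, and its false-positive rate is verified
(≈5% of null features retained). HA/NA pairs share a phantom, but the
test treats samples as independent, matching the evaluation design; a
paired variant would be the natural extension.

## The 13-selector bank

Four families: mutual information (MIM, MIFS, MRMR, JMI, CMIM),
similarity (Fisher, Laplacian score, ReliefF), statistics (F-score,
t-score), and sparse/streaming learning (MCFS, Alpha-investing, Lasso).
Scores are min-max normalised, features above 0.9 kept, capped at 20
(Lasso instead keeps |beta| > 0.02, same cap); ties always break
lexicographically by feature name so outputs are bit-reproducible.

Estimator and hyperparameter choices, each a `selector_config()` field:

* MI is the discrete plug-in estimator in bits over equal-frequency
  5-bin discretizations (features with ≤5 distinct values keep their own
  levels), which keeps the brute-force oracles in the test suite exact.
* The greedy methods (MIFS, MRMR, JMI, CMIM) score features in
  forward-selection order, each carrying the objective value at its
  selection step; by default only the first 50 ranks are computed —
  selection never keeps more than 20, and full greedy scoring is
  quadratic in the number of features.
* `mifs_beta = 0.5`, the middle of Battiti's classical range. With
  beta = 1 the redundancy that informative features share *through the
  class* is over-penalised: on planted-feature benchmarks MIFS then
  ranks noise above real signal, failing the recovery property the
  pipeline is expected to satisfy.
* Laplacian score and MCFS share a 5-nearest-neighbour sample graph with
  heat-kernel weights (width = mean pairwise distance); the Laplacian
  score is negated so larger is better everywhere. MCFS regresses
  spectral embedding coordinates on the features with an L1 path and
  scores each feature by its largest coefficient magnitude; it uses the
  *first non-trivial* eigenvector by default — the spectral-clustering
  convention for two classes counts the trivial constant eigenvector,
  and adding further eigenvectors demonstrably drowns the class
  structure in noise coordinates on binary benchmarks.
* ReliefF iterates over all samples with 10 neighbours per class and
  range-normalised Manhattan differences.
* Alpha-investing streams features in table order with initial wealth
  0.5, spend $\alpha_i = w_i/2i$ and payoff 0.5, testing each candidate
  by the added-variable t-test on the running least-squares model; the
  reported score is $-\log_{10} p$, which lets the streaming method
  share the common thresholding rule (the wealth-rule accept flags are
  kept as an attribute).
* Lasso is a gaussian-family L1 path with the penalty chosen by seeded
  5-fold cross-validated MSE.

## Evaluation harness

Ten classifiers: radial-kernel SVM with probability outputs, decision
tree, AdaBoost.M1 over depth-1 stumps, a single-hidden-layer perceptron
(width 40, weight decay 0.01 — the R neural-network stack does not
express the two-layer 400×100 architecture, so a single layer is used
and documented), random forest with 200 trees, 5-NN, ridge-penalised
logistic regression with cross-validated penalty, linear discriminant
analysis, gradient-boosted trees (exact split enumeration, 100 rounds,
depth 3, learning rate 0.1) and Gaussian naive Bayes. Folds are
stratified and seeded; metrics are Acc, Pre, Auc, F1 and Recall with
HA = 1 as the positive class; a fold with no positive predictions scores
precision (and F1) 0 rather than NaN; per-metric aggregation is the
unweighted mean over fold values.

The composite score multiplies a set's mean metric by its family
coefficient:

$$CS(F_{method}) = H_{type}\cdot\frac{1}{KM}\sum_{k,m}
  \mathrm{index}\big(k,\,\mathrm{model}(m, F_{method})\big),\qquad
  H_{type} = \frac{1}{KM}\sum_{k,m}
  \mathrm{index}\big(k,\,\mathrm{model}(m, F_{type})\big)$$

with K = 5 metrics and M = 10 models, so 13 method sets instantiate 130
classifiers and CS never exceeds the set's own mean metric. Samples
enter folds as ROIs, not subjects — each phantom contributes an HA and
an NA sample and the two can land in different folds. This replicates
the evaluation design the pipeline models; it is optimistic relative to
subject-level splitting, which `crossval_metrics()` callers can obtain
by passing per-subject fold assignments.

## Lesion-proportion experiment

Hemisphere samples are labelled by whether the lesion fraction of the
middle-S slab (slices $[\lfloor(Z-S)/2\rfloor,\ \lfloor(Z-S)/2\rfloor+S)$,
S ∈ {3, 4, 5}) strictly exceeds a reference threshold RT ∈
{0, 0.01, …, 0.39} — 120 configurations, with positives non-increasing
in RT by construction. The denominator is the hemisphere's slab brain
voxels. Slab features are *recomputed* on the slab mask (restricted to
the top-6 union names via `extract_named_features()`), not sliced out of
whole-brain features. Per configuration, Lasso re-selects a subset
(falling back to the full recomputed union when the penalty zeroes every
coefficient) and the classifier bank is cross-validated. The composite
score of a configuration multiplies its mean metric by an Eq-3-style
coefficient computed from the full recomputed top-6 union under the same
labels, since the family-coefficient construction does not directly
apply to a re-selected set. Configurations whose labels collapse to a
single class are flagged degenerate and reported without metrics, never
silently dropped.

As RT grows the positive class shrinks; on cohorts with lesion fractions
uniform on [0.02, 0.5] accuracy and precision stay high below RT ≈ 0.25
and the composite score falls beyond it (tested as a negative Spearman
trend, not as specific values) — the behavioural analogue of the
class-imbalance degradation expected clinically.

## Problem sizes used by the bundled analyses

The `analysis/` drivers and the acceptance script run the full-scale
feature scheme (one 64×64×20, T = 50 phantom; 65,800 features) but a
reduced cohort geometry (16×16×8, T = 12, first-order + GLCM families)
for the 80-subject experiments, chosen so a complete run stays within a
few minutes on one CPU while exercising every stage at its full logical
cardinality (13 sets, 10 models, 120 RT cells, 160 hemisphere samples).

## Known limitations

* The phantom omits Rician noise, partial-volume effects, arterial input
  function variability and anatomy; its separability saturates the
  metric grid at effect settings.
* Texture matrices merge directions instead of per-angle averaging, so
  individual feature values are not interchangeable with other radiomics
  implementations even where names coincide.
* ROI-level cross-validation (HA and NA of one subject in different
  folds) inflates absolute metrics relative to subject-level splits.
* The t-score denominator follows the standard two-sample standard
  error; published formula renderings of such scores vary in whether
  the square root is shown.
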