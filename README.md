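# dscradiomics

Time-dimension radiomics of dynamic susceptibility contrast
perfusion-weighted imaging (DSC-PWI) for ischemic stroke analysis.

DSC-PWI is a 4D MRI series: a contrast bolus transits the brain and
well-perfused tissue shows a deep transient signal drop, while
hypoperfused tissue (the tissue at risk in stroke) barely dips. This
package decomposes the 4D series into its per-timepoint 3D images,
computes a full radiomics vector for each timepoint — 1,316 features
per 3D image (shape, first-order, five texture-matrix families, and the
non-shape features recomputed on Laplacian-of-Gaussian and wavelet
sub-band images), 65,800 for a 50-timepoint series — and asks which of
those time-resolved features distinguish hypoperfused regions (HA) from
their mirrored normal counterparts (NA).

It is aimed at researchers studying perfusion-based tissue
characterisation who want a fully testable, self-contained version of
this analysis: because clinical DSC-PWI cohorts are rarely shareable,
the package includes a synthetic 4D perfusion phantom generator with
ground-truth lesion masks (gamma-variate bolus, attenuated and delayed
inside the lesion) so every stage runs and is verified without any
download.

The analysis core:

* a significance screen — per-feature two-sample t-test after the
  mean-centred range normalisation `F* = (F − F̄)/(Fmax − Fmin)`, keep
  p < 0.05;
* a bank of 13 feature selectors in four families — mutual information
  (MIM, MIFS, MRMR, JMI, CMIM), similarity (Fisher score, Laplacian
  score, ReliefF), statistics (F-score, t-score) and sparse/streaming
  learning (MCFS, alpha-investing, Lasso) — under a common rule
  (normalised score > 0.9, at most 20 features; Lasso keeps
  |β| > 0.02);
* a ten-classifier stratified tenfold cross-validation harness (SVM,
  decision tree, AdaBoost, perceptron, random forest, k-NN, penalised
  logistic regression, LDA, gradient boosting, naive Bayes) scored by
  Acc, Pre, Auc, F1 and Recall, and summarised per feature set by the
  composite score

  CS(F_method) = H_type · (1/KM) Σ_{k,m} index(k, model(m, F_method)),

  where H_type is the same mean computed on the union set of the
  method's family (K = 5 metrics, M = 10 models, so 13 sets instantiate
  130 classifiers);
* a lesion-proportion experiment: each phantom splits into two
  hemisphere samples (80 subjects → 160 samples), the middle-S slab
  (S ∈ {3,4,5}) is labelled by whether its lesion fraction exceeds a
  sliding threshold RT ∈ {0, 0.01, …, 0.39} (120 configurations), and
  per configuration the Lasso selector re-selects features and the
  classifier bank is cross-validated.

## Worked example

```r
library(dscradiomics)

# one phantom: 12 timepoints, 8 slices of 16x16, lesion on one side
ph <- generate_phantom(acquisition_spec(n_timepoints = 12, n_slices = 8,
                                        height = 16, width = 16),
                       bolus_model(),
                       lesion_spec(target_fraction = 0.3, attenuation = 0.4,
                                   delay = 2),
                       noise_sd = 0.5, seed = 3)
ph
#> <phantom4d> 12 timepoints, 8x16x16 (z,y,x)
#>   brain 728 voxels; HA 109; NA 109; lesion fraction 0.299

# full default radiomics scheme on the lesion ROI at timepoint 3
img <- decompose_4d(ph$volume)[[4]]
v <- extract_timepoint_features(img, ph$ha_mask, extraction_config(),
                                time_index = 3)
length(v)
#> [1] 1316
table(group_of(names(v)))
#> First-order        GLCM        GLDM       GLRLM       GLSZM   Log-sigma
#>          18          24          14          16          16         465
#>       NGTDM       Shape     Wavelet
#>           5          14         744
round(v[c("original_firstorder_Mean_3", "original_glcm_Contrast_3")], 3)
#> original_firstorder_Mean_3   original_glcm_Contrast_3
#>                    100.033                     55.307
```

The mean ROI intensity sits at the 100-unit baseline at timepoint 3
(the bolus has not arrived), and the contrast value reflects the ±5%
per-voxel heterogeneity the phantom injects so that texture features
are non-degenerate.

A small end-to-end run (8 phantoms → 16 HA/NA samples, three of the ten
models, threefold CV):

```r
res <- run_pipeline(pipeline_config(n_subjects = 8,
                                    models = c("SVM", "DT", "NB"),
                                    cv_folds = 3, RT_grid = NULL, seed = 1))
res$summary$n_significant
#> [1] 161
round(unlist(res$summary$cs), 3)
#>    CMIM     JMI    MIFS     MIM    MRMR  Fisher     Lap ReliefF      FS
#>   0.523   0.523   0.526   0.538   0.523   0.538   0.538   0.538   0.538
#>      TS    MCFS   Alpha   Lasso
#>   0.538   0.526   0.538   0.538
```

161 of the 504 extracted features pass the t-test screen; the composite
scores are compressed at this tiny demonstration scale (16 samples,
3 models). The `analysis/` drivers run the same stages on an 80-subject
cohort — `01_simulate.R` through `06_proportion_sweep.R`, each writing
its tables under `results/` — where the effect cohort separates almost
perfectly and the proportion experiment reproduces the expected
behaviour (stable accuracy below RT ≈ 0.25, composite score declining
beyond it).

## Layout

* `R/`, `src/` — package implementation (phantom, preprocessing,
  feature extraction with compiled texture kernels, significance,
  selection, evaluation, proportion experiment, pipeline driver)
* `analysis/` — numbered narrative drivers over the package functions
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
* `vignettes/time-dimension-radiomics.Rmd` — the methods vignette:
  model assumptions, parameter choices, numerical decisions and known
  limitations
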