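test_that("gamma-variate curve is zero before arrival and peaks at t0 + alpha*beta", {
  m <- bolus_model(arrival_t0 = 8, shape_alpha = 3, scale_beta = 1.5,
                   amplitude = 2)
  t <- seq(0, 49, by = 0.5)
  C <- gamma_variate_curve(t, m)
  expect_length(C, length(t))
  expect_true(all(C[t <= 8] == 0))
  expect_true(all(C >= 0))
  # analytic mode at 12.5; on the integer grid the argmax is adjacent
  expect_lte(abs(t[which.max(C)] - 12.5), 0.5)
  expect_equal(max(C), 2, tolerance = 1e-12)  # peak-normalised amplitude
  expect_equal(gamma_variate_curve(t, bolus_model(amplitude = 0)),
               rep(0, length(t)))
  expect_error(bolus_model(shape_alpha = -1), "shape_alpha")
})

test_that("signal-loss relation maps concentration to an attenuated signal", {
  m <- bolus_model(baseline = 100, contrast_k = 0.5)
  C <- gamma_variate_curve(0:30, m)
  I <- signal_from_concentration(C, m)
  expect_equal(signal_from_concentration(rep(0, 10), m), rep(100, 10))
  expect_equal(signal_from_concentration(C, bolus_model(contrast_k = 0)),
               rep(100, 31))
  expect_true(all(I <= 100))
  expect_identical(which.min(I), which.max(C))
  m2 <- bolus_model(baseline = 100, contrast_k = 1)
  expect_lt(min(signal_from_concentration(C, m2)), min(I))
  expect_error(signal_from_concentration(c(-1, 0), m), ">= 0")
})

test_that("phantom geometry honours the lesion fraction and mirror contract", {
  ph <- tiny_phantom(seed = 3, fraction = 0.3)
  expect_s3_class(ph, "phantom4d")
  expect_gte(ph$achieved_fraction, 0.25)
  expect_lte(ph$achieved_fraction, 0.35)
  expect_identical(ph$na_mask, mirror_roi(ph$ha_mask))
  expect_identical(sum(ph$ha_mask), sum(ph$na_mask))
  expect_identical(sum(ph$ha_mask & ph$na_mask), 0L)
  expect_true(all(ph$brain_mask[ph$ha_mask]))
  expect_true(all(is.finite(ph$volume)))
  expect_true(all(series_matrix(ph$volume, ph$brain_mask) > 0))
})

test_that("a null lesion is statistically indistinguishable from normal tissue", {
  ph <- generate_phantom(tiny_acq(), bolus_model(),
                         lesion_spec(target_fraction = 0.4, attenuation = 1,
                                     delay = 0),
                         noise_sd = 1, seed = 9)
  expect_gte(sum(ph$ha_mask), 100)
  minima_ha <- apply(series_matrix(ph$volume, ph$ha_mask), 2, min)
  minima_na <- apply(series_matrix(ph$volume, ph$na_mask), 2, min)
  expect_gt(t.test(minima_ha, minima_na)$p.value, 0.01)
})

test_that("attenuation creates and monotonically deepens the HA/NA contrast", {
  mean_min_gap <- function(att) {
    ph <- generate_phantom(tiny_acq(), bolus_model(),
                           lesion_spec(target_fraction = 0.3,
                                       attenuation = att, delay = 2),
                           noise_sd = 0, seed = 5)
    ha_curve <- rowMeans(series_matrix(ph$volume, ph$ha_mask))
    na_curve <- rowMeans(series_matrix(ph$volume, ph$na_mask))
    min(ha_curve) - min(na_curve)  # positive when NA drops deeper
  }
  g06 <- mean_min_gap(0.6)
  g04 <- mean_min_gap(0.4)
  g02 <- mean_min_gap(0.2)
  expect_gt(g06, 0)
  expect_gt(g04, g06)
  expect_gt(g02, g04)
})

test_that("cohorts are reproducible and sized as requested", {
  c1 <- generate_cohort(3, tiny_acq(), seed = 11)
  c2 <- generate_cohort(3, tiny_acq(), seed = 11)
  expect_length(c1, 3)
  expect_identical(c1[[2]]$volume, c2[[2]]$volume)
  expect_identical(c1[[3]]$ha_mask, c2[[3]]$ha_mask)
  expect_length(generate_cohort(1, tiny_acq(), seed = 1), 1)
  # different seeds change the volumes
  c3 <- generate_cohort(3, tiny_acq(), seed = 12)
  expect_false(identical(c1[[1]]$volume, c3[[1]]$volume))
})

test_that("phantoms round-trip through NIfTI with masks intact", {
  ph <- tiny_phantom(seed = 4)
  dir <- tempfile("nifti")
  man <- write_phantom_nifti(ph, dir)
  expect_true(all(file.exists(unlist(man$files))))
  vol <- RNifti::readNifti(man$files$volume)
  expect_equal(dim(vol), c(16, 16, 8, 12))
  expect_equal(aperm(vol, c(4, 3, 2, 1)), ph$volume, ignore_attr = TRUE)
  ha <- RNifti::readNifti(man$files$ha)
  expect_equal(sum(ha), sum(ph$ha_mask))
  unlink(dir, recursive = TRUE)
})
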