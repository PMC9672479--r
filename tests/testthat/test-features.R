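test_that("feature names render and parse as exact inverses", {
  nm <- render_feature_name("log-sigma-1-0-mm-3D", "firstorder", "Skewness", 17)
  expect_identical(nm, "log-sigma-1-0-mm-3D_firstorder_Skewness_17")
  p <- parse_feature_name(nm)
  expect_identical(p$filter_tag, "log-sigma-1-0-mm-3D")
  expect_identical(p$family, "firstorder")
  expect_identical(p$base, "Skewness")
  expect_identical(p$time_index, 17L)
  expect_identical(group_of(nm), "Log-sigma")
  expect_identical(group_of("original_glcm_Contrast_0"), "GLCM")
  expect_identical(group_of("wavelet-HLL_gldm_GrayLevelVariance_3"),
                   "Wavelet")
  expect_error(parse_feature_name("no_underscores"), "unparseable")
  expect_error(parse_feature_name("original_bogus_X_1"), "invalid")
})

test_that("default extraction yields 1,316 features per timepoint", {
  ph <- tiny_phantom(seed = 3)
  img <- decompose_4d(ph$volume)[[4]]
  v <- extract_timepoint_features(img, ph$ha_mask, extraction_config(),
                                  time_index = 3L)
  expect_length(v, 1316)
  expect_true(all(is.finite(v)))
  expect_identical(anyDuplicated(names(v)), 0L)
  counts <- table(group_of(names(v)))
  expect_identical(as.integer(counts[c("Shape", "First-order", "GLCM",
                                       "GLRLM", "GLSZM", "NGTDM", "GLDM",
                                       "Log-sigma", "Wavelet")]),
                   c(14L, 18L, 24L, 16L, 16L, 5L, 14L, 465L, 744L))
  sh <- extract_timepoint_features(img, ph$ha_mask,
                                   extraction_config(families = "shape",
                                                     log_sigmas = NULL,
                                                     wavelet = FALSE))
  expect_length(sh, 14)
})

test_that("shape features are intensity-free and extraction is deterministic", {
  ph <- tiny_phantom(seed = 3)
  imgs <- decompose_4d(ph$volume)
  cfg <- extraction_config(log_sigmas = 1:2, wavelet = FALSE)
  v1 <- extract_timepoint_features(imgs[[2]], ph$ha_mask, cfg)
  v2 <- extract_timepoint_features(imgs[[9]], ph$ha_mask, cfg)
  shape_names <- grep("_shape_", names(v1), value = TRUE)
  expect_identical(v1[shape_names], v2[shape_names])
  expect_false(identical(v1, v2))
  v1b <- extract_timepoint_features(imgs[[2]], ph$ha_mask, cfg)
  expect_identical(v1, v1b)
})

test_that("series extraction concatenates timepoints with index suffixes", {
  ph <- tiny_phantom(seed = 5, Tn = 12L)
  cfg <- extraction_config(families = "firstorder", log_sigmas = NULL,
                           wavelet = FALSE)
  sub <- ph$volume[1:2, , , , drop = FALSE]
  v <- extract_series_features(sub, ph$ha_mask, cfg)
  expect_length(v, 36)  # 18 first-order x 2 timepoints
  p <- parse_feature_name(names(v))
  expect_identical(sort(unique(p$time_index)), 0:1)
  expect_identical(names(v),
                   render_feature_name(p$filter_tag, p$family, p$base,
                                       p$time_index))
  imgs <- decompose_4d(sub)
  expect_length(imgs, 2)
  restack <- aperm(simplify2array(imgs), c(4, 1, 2, 3))
  expect_identical(restack, sub)
})

test_that("first-order features are invariant to joint image/mask translation", {
  ph <- tiny_phantom(seed = 8)
  img <- decompose_4d(ph$volume)[[3]]
  cfg <- extraction_config(families = "firstorder", log_sigmas = NULL,
                           wavelet = FALSE)
  dm <- dim(img)
  img_shift <- array(0, dm)
  mask_shift <- array(FALSE, dm)
  img_shift[, , 3:dm[3]] <- img[, , 1:(dm[3] - 2)]
  mask_shift[, , 3:dm[3]] <- ph$ha_mask[, , 1:(dm[3] - 2)]
  stopifnot(sum(mask_shift) == sum(ph$ha_mask))  # shift stays in bounds
  v0 <- extract_timepoint_features(img, ph$ha_mask, cfg)
  v1 <- extract_timepoint_features(img_shift, mask_shift, cfg)
  expect_equal(v0, v1, tolerance = 1e-12)
})

test_that("degenerate masks raise errors naming the problem", {
  img <- array(7, dim = c(6, 6, 6))  # constant image
  mask <- array(FALSE, dim = c(6, 6, 6))
  mask[2:4, 2:4, 2:4] <- TRUE
  cfg <- extraction_config(families = "glcm", log_sigmas = NULL,
                           wavelet = FALSE)
  expect_error(extract_timepoint_features(img, mask, cfg), "degenerate")
  tiny <- array(FALSE, dim = c(6, 6, 6))
  tiny[1, 1, 1] <- TRUE
  expect_error(extract_timepoint_features(img, tiny, cfg), "2 voxels")
})

test_that("extract_named_features reproduces the full-extraction values", {
  ph <- tiny_phantom(seed = 4)
  cfg <- extraction_config(families = c("firstorder", "glcm"),
                           log_sigmas = 1, wavelet = FALSE)
  full <- extract_series_features(ph$volume[1:3, , , , drop = FALSE],
                                  ph$ha_mask, cfg)
  pick <- full[c(3, 40, 97, length(full))]
  sub <- extract_named_features(ph$volume[1:3, , , , drop = FALSE],
                                ph$ha_mask, names(pick), cfg)
  expect_equal(sub, pick, tolerance = 1e-12)
})
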