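test_that("middle slab selects the central S slices", {
  m <- array(0, dim = c(20, 2, 2))
  m[, 1, 1] <- 1:20
  s4 <- middle_slab(m, 4)
  expect_identical(dim(s4), c(4L, 2L, 2L))
  expect_equal(s4[, 1, 1], 9:12, ignore_attr = TRUE)   # 0-based slices 8..11
  s3 <- middle_slab(m, 3)
  expect_equal(s3[, 1, 1], 9:11, ignore_attr = TRUE)   # 0-based slices 8..10
  expect_identical(middle_slab(m, 20), m)
  expect_error(middle_slab(m, 21), "exceeds")
  v4 <- array(seq_len(3 * 20 * 2 * 2), dim = c(3, 20, 2, 2))
  expect_identical(middle_slab(v4, 4), v4[, 9:12, , , drop = FALSE])
})

test_that("proportion labels apply a strict threshold", {
  brain <- array(TRUE, dim = c(2, 5, 10))   # 100 voxels
  ha <- array(FALSE, dim = c(2, 5, 10))
  ha[, , 1:3] <- TRUE                        # 30 voxels -> fraction 0.30
  expect_identical(proportion_label(ha, brain, 0.25), 1L)
  expect_identical(proportion_label(ha, brain, 0.39), 0L)
  expect_identical(proportion_label(ha, brain, 0.30), 0L)  # strict >
  none <- array(FALSE, dim = dim(brain))
  expect_identical(proportion_label(none, brain, 0), 0L)
  expect_identical(proportion_label(ha, brain, 0), 1L)
  expect_error(proportion_label(ha, none, 0.1), "empty")
})

test_that("the RT grid yields 120 configurations with monotone positives", {
  cohort <- generate_cohort(4, tiny_acq(), fraction_range = c(0.05, 0.5),
                            seed = 21)
  sw <- sweep_rt(cohort, "original_firstorder_Mean_0",
                 S_values = c(3, 4, 5), RT_grid = seq(0, 0.39, by = 0.01),
                 label_only = TRUE)
  expect_identical(nrow(sw), 120L)
  expect_identical(sum(sw$n), 120L * 8L)  # 4 phantoms -> 8 hemisphere samples
  for (S in c(3, 4, 5)) {
    pos <- sw$n_pos[sw$S == S]
    expect_true(all(diff(pos) <= 0))
  }
  # RT = 0 labels every hemisphere with any lesioned voxel positive
  expect_gte(sw$n_pos[sw$S == 3 & sw$RT == 0], 4L)
})

test_that("the sweep re-selects features and reports metrics per configuration", {
  cohort <- generate_cohort(8, tiny_acq(), fraction_range = c(0.05, 0.5),
                            noise_sd = 0.5, seed = 22)
  top6 <- c("original_firstorder_Minimum_6", "original_firstorder_Mean_6",
            "original_firstorder_RootMeanSquared_8",
            "original_glcm_JointAverage_6",
            "original_firstorder_Median_4", "original_glcm_Contrast_2")
  cfg <- extraction_config(families = c("firstorder", "glcm"),
                           log_sigmas = NULL, wavelet = FALSE)
  sw <- suppressWarnings(sweep_rt(
    cohort, top6, S_values = 4, RT_grid = c(0.05, 0.2, 0.6),
    extraction = cfg, models = model_bank()[c("DT", "NB")], k = 3L,
    seed = 1L))
  expect_identical(nrow(sw), 3L)
  expect_identical(sw$n, rep(16L, 3))
  ok <- !sw$degenerate
  expect_true(any(ok))
  expect_true(all(sw$n_selected[ok] >= 1))
  expect_true(all(sw$cs[ok] >= 0 & sw$cs[ok] <= 1))
  expect_true(all(is.na(sw$cs[sw$degenerate])))
  # RT = 0.6 exceeds every feasible slab fraction -> single class
  expect_true(sw$degenerate[sw$RT == 0.6])
  sel <- attr(sw, "selected")
  expect_true(all(unlist(sel) %in% top6))
  mets <- attr(sw, "metrics")
  expect_true(all(mets$Acc >= 0 & mets$Acc <= 1))
})
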