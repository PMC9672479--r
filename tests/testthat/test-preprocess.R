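as_series_volume <- function(x) array(x, dim = c(length(x), 1, 1, 1))

test_that("triple moving average matches the hand-rolled convolution oracle", {
  x <- c(0, 0, 3, 0, 0)
  one_pass <- smooth_time_series(as_series_volume(x),
                                 smoothing_config(passes = 1))
  expect_equal(as.numeric(one_pass), c(0, 1, 1, 1, 0))
  # independent oracle: repeated explicit convolution with repeat padding
  oracle <- x
  for (p in 1:3) {
    padded <- c(oracle[1], oracle, oracle[length(oracle)])
    oracle <- vapply(seq_along(x), function(i) mean(padded[i:(i + 2)]),
                     numeric(1))
  }
  expect_equal(oracle, c(4 / 9, 2 / 3, 7 / 9, 2 / 3, 4 / 9))
  three_pass <- smooth_time_series(as_series_volume(x))
  expect_equal(as.numeric(three_pass), oracle)
})

test_that("smoothing leaves constants fixed and conserves the series sum", {
  const <- as_series_volume(rep(5, 7))
  expect_equal(smooth_time_series(const), const)
  set.seed(1)
  x <- rnorm(40)
  sm <- smooth_time_series(as_series_volume(x))
  expect_equal(sum(sm), sum(x))  # replicate padding conserves mass
  expect_error(smooth_time_series(as_series_volume(c(1, 2))), "timepoints")
})

test_that("mirroring reflects about the mid-x plane and is an involution", {
  m <- array(FALSE, dim = c(4, 5, 64))
  m[2, 3, 11] <- TRUE  # 0-based x = 10
  mm <- mirror_roi(m)
  expect_true(mm[2, 3, 54])  # 0-based x = 63 - 10 = 53
  expect_identical(sum(mm), sum(m))
  expect_identical(mirror_roi(mm), m)
  sym <- array(FALSE, dim = c(4, 5, 8))
  sym[1, 1, c(3, 6)] <- TRUE  # symmetric about the midline
  expect_identical(mirror_roi(sym), sym)
})

test_that("hemisphere split partitions the brain with midline exclusion when odd", {
  brain <- array(TRUE, dim = c(4, 6, 64))
  vol <- array(1, dim = c(3, 4, 6, 64))
  hs <- split_hemispheres(vol, brain)
  expect_true(all(which(apply(hs$left$mask, 3, any)) <= 32))
  expect_true(all(which(apply(hs$right$mask, 3, any)) >= 33))
  expect_identical(sum(hs$left$mask) + sum(hs$right$mask), sum(brain))
  expect_identical(sum(hs$left$mask & hs$right$mask), 0L)
  brain_odd <- array(TRUE, dim = c(4, 6, 9))
  hs_odd <- split_hemispheres(vol, brain_odd)
  covered <- hs_odd$left$mask | hs_odd$right$mask
  expect_identical(sum(brain_odd) - sum(covered), sum(brain_odd[, , 5]))
  expect_false(any(covered[, , 5]))
  # a lesion entirely on one side leaves the other hemisphere clean
  ph <- tiny_phantom(seed = 6)
  hsp <- split_hemispheres(ph$volume, ph$brain_mask)
  left_lesion <- sum(ph$ha_mask & hsp$left$mask)
  right_lesion <- sum(ph$ha_mask & hsp$right$mask)
  expect_identical(min(left_lesion, right_lesion), 0L)
  expect_gt(max(left_lesion, right_lesion), 0L)
})

test_that("mean-centred range normalisation matches the printed formula", {
  m <- cbind(a = c(0, 1), b = c(2, 6))
  out <- normalize_features(m)
  expect_equal(out[, "a"], c(-0.5, 0.5), ignore_attr = TRUE)
  m2 <- cbind(a = c(2, 4, 6))
  expect_equal(normalize_features(m2)[, 1], c(-0.5, 0, 0.5),
               ignore_attr = TRUE)
  set.seed(2)
  m3 <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, letters[1:6]))
  out3 <- normalize_features(m3)
  expect_equal(unname(apply(out3, 2, function(v) diff(range(v)))),
               rep(1, 6))
  # min-max variant maps onto [0, 1]
  mm <- normalize_features(m3, method = "min_max")
  expect_equal(unname(apply(mm, 2, min)), rep(0, 6))
  expect_equal(unname(apply(mm, 2, max)), rep(1, 6))
})

test_that("constant columns are dropped with a warning", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(out <- normalize_features(m), "constant")
  expect_identical(colnames(out), "a")
})

test_that("t-test p-values are invariant under the normalisation", {
  set.seed(7)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[, 1:2] <- x[, 1:2] + y
  p_raw <- ttest_filter(x, y)$p_value
  p_norm <- ttest_filter(normalize_features(x), y)$p_value
  expect_equal(p_raw, p_norm, tolerance = 1e-10)
})
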