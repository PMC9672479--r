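test_that("separated features are retained and single-class input errors", {
  set.seed(1)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(sig = y + rnorm(n, sd = 0.05), noise = rnorm(n))
  rep <- ttest_filter(x, y)
  expect_true(rep$retained[rep$name == "sig"])
  expect_lt(rep$p_value[rep$name == "sig"], 1e-10)
  expect_error(ttest_filter(x, rep(1L, n)), "class")
})

test_that("the filter retains about alpha of null features", {
  set.seed(2)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 1000), n, 1000,
              dimnames = list(NULL, paste0("f", 1:1000)))
  rep <- ttest_filter(normalize_features(x), y)
  frac <- mean(rep$retained)
  expect_gte(frac, 0.037)
  expect_lte(frac, 0.064)
})

test_that("p-values decrease monotonically with the class-mean gap", {
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  base <- sin(seq_len(n))  # deterministic within-class spread
  p_at_gap <- vapply(c(0.5, 1, 2, 4), function(gap) {
    ttest_filter(cbind(f = base + gap * y), y)$p_value
  }, numeric(1))
  expect_true(all(diff(p_at_gap) < 0))
})

test_that("group statistics match an order-statistics oracle", {
  set.seed(3)
  nm <- c(paste0("original_glcm_Contrast_", 0:9),
          paste0("original_firstorder_Mean_", 0:9),
          paste0("wavelet-LLL_glcm_Contrast_", 0:4))
  rep <- data.frame(name = nm, p_value = runif(25, 0, 0.2),
                    stringsAsFactors = FALSE)
  rep$retained <- rep$p_value < 0.05
  class(rep) <- c("significance_report", "data.frame")
  stats_tab <- group_pvalue_stats(rep)
  for (g in stats_tab$group) {
    p <- rep$p_value[group_of(rep$name) == g & rep$retained]
    row <- stats_tab[stats_tab$group == g, ]
    if (length(p) == 0) {
      expect_identical(row$n, 0L)
      expect_true(is.na(row$mean))
    } else {
      sorted <- sort(p)  # brute-force order statistics
      expect_identical(row$n, length(p))
      expect_equal(row$mean, sum(p) / length(p), tolerance = 1e-12)
      expect_equal(row$min, sorted[1], tolerance = 1e-12)
      expect_equal(row$max, sorted[length(sorted)], tolerance = 1e-12)
      med <- if (length(sorted) %% 2 == 1) {
        sorted[(length(sorted) + 1) / 2]
      } else {
        mean(sorted[length(sorted) / 2 + 0:1])
      }
      expect_equal(row$median, med, tolerance = 1e-12)
    }
  }
  one <- rep[rep$retained, ][1, ]
  single <- group_pvalue_stats(one, grouping = "G", groups = "G")
  expect_equal(single$min, one$p_value)
  expect_equal(single$median, one$p_value)
  expect_equal(single$max, one$p_value)
  expect_equal(single$std, 0)
})
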