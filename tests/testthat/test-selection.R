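test_that("mutual information matches hand summation on a contingency table", {
  # counts {(0,0):30, (0,1):10, (1,0):10, (1,1):30}
  x <- rep(c(0L, 0L, 1L, 1L), times = c(30, 10, 10, 30))
  y <- rep(c(0L, 1L, 0L, 1L), times = c(30, 10, 10, 30))
  hand <- 2 * (30 / 80) * log2((30 / 80) / 0.25) +
    2 * (10 / 80) * log2((10 / 80) / 0.25)
  expect_equal(mutual_information(x, y), hand, tolerance = 1e-12)
  expect_equal(mutual_information(x, y), 0.188721875540867, tolerance = 1e-12)
  # identical balanced binary variables carry exactly one bit
  yy <- rep(c(0L, 1L), each = 20)
  expect_equal(mutual_information(yy, yy), 1)
  # independence: non-negative and small for a large sample
  set.seed(4)
  xi <- sample(1:5, 4000, replace = TRUE)
  yi <- sample(0:1, 4000, replace = TRUE)
  expect_gte(mutual_information(xi, yi), 0)
  expect_lt(mutual_information(xi, yi), 0.01)
})

test_that("greedy MI selectors match the brute-force objective evaluation", {
  set.seed(10)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[, 1] <- x[, 1] + 2 * y
  x[, 2] <- x[, 1] + rnorm(n, sd = 0.1)
  x[, 3] <- x[, 3] + 1.2 * y
  cfg <- selector_config(max_rank = 8L)
  D <- apply(x, 2, discretize_ef, bins = cfg$mi_bins)
  colnames(D) <- colnames(x)
  for (m in c("MIM", "MIFS", "MRMR", "JMI", "CMIM")) {
    got <- score_features(m, x, y, cfg)
    want <- if (m == "MIM") {
      vapply(seq_len(ncol(D)), function(i) naive_mi(D[, i], y), numeric(1))
    } else {
      naive_greedy_scores(D, y, m, beta = cfg$mifs_beta)
    }
    expect_equal(unname(got), unname(want), tolerance = 1e-10,
                 label = paste(m, "scores"))
  }
})

test_that("MRMR prefers a fresh informative feature over a duplicate", {
  set.seed(11)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  f1 <- y + rnorm(n, sd = 0.1)
  x <- cbind(f1 = f1, f2 = f1, f3 = 1.5 * y + rnorm(n, sd = 0.4),
             f4 = rnorm(n))
  s <- score_features("MRMR", x, y, selector_config(max_rank = 4L))
  ranked <- names(sort(s, decreasing = TRUE))
  expect_identical(ranked[1], "f1")
  expect_lt(match("f3", ranked), match("f2", ranked))
})

test_that("Fisher score is invariant to positive affine feature rescaling", {
  set.seed(12)
  n <- 50
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 4) + y, n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  s1 <- score_features("Fisher", x, y, selector_config())
  s2 <- score_features("Fisher", sweep(x * 3.7, 2, c(1, -2, 0, 5), `+`), y,
                       selector_config())
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("a perfect predictor is ranked first by every method", {
  d <- toy_table()
  for (m in names(selector_types())) {
    s <- score_features(m, d$x, d$y, selector_config(seed = 1))
    best <- names(sort(s[!is.na(s)], decreasing = TRUE))[1]
    expect_identical(best, "lab", label = paste(m, "top pick"))
  }
})

test_that("threshold rules keep high scorers, cap at 20 and break ties by name", {
  cfg <- selector_config()
  s <- c(a = 1.0, b = 0.95, c = 0.89, d = 0)   # already spans [0, 1]
  fs <- apply_threshold(s, cfg, "MIM")
  expect_identical(fs$members$name, c("a", "b"))
  many <- c(setNames(rep(1, 30), sprintf("f%02d", 30:1)), low = 0)
  capped <- apply_threshold(many, cfg, "MIM")
  expect_identical(nrow(capped$members), 20L)
  expect_identical(capped$members$name, sprintf("f%02d", 1:20))
  lasso <- c(w = 0.5, x = 0.021, y = 0.02, z = 0.019)
  fl <- apply_threshold(lasso, cfg, "Lasso")
  expect_identical(fl$members$name, c("w", "x"))
  expect_warning(empty <- apply_threshold(c(a = 1, b = 1, c = 1), cfg, "MIM"),
                 "equal")
  expect_identical(nrow(empty$members), 0L)
})

test_that("feature attributes match direct-formula oracles", {
  y <- rep(c(0L, 1L), each = 4)
  att <- feature_attributes(as.numeric(y), y)
  expect_equal(att$r_squared, 1)
  expect_equal(att$gain, 1)  # H(C) = 1 bit for balanced classes
  expect_equal(att$p_value, 0)
  f <- c(1.2, 0.4, 0.8, 0.1, 2.3, 1.9, 2.8, 1.5)
  got <- feature_attributes(f, y, mi_bins = 2L)
  # oracle: explicit formulas
  r <- sum((f - mean(f)) * (y - mean(y))) /
    sqrt(sum((f - mean(f))^2) * sum((y - mean(y))^2))
  expect_equal(got$r_squared, r^2, tolerance = 1e-12)
  expect_equal(got$p_value, t.test(f[y == 1], f[y == 0],
                                   var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  fb <- as.integer(f > median(f))
  hy <- -sum(c(0.5, 0.5) * log2(c(0.5, 0.5)))
  hygf <- 0
  for (b in unique(fb)) {
    sel <- fb == b
    pc <- table(factor(y[sel], levels = 0:1)) / sum(sel)
    pc <- pc[pc > 0]
    hygf <- hygf + mean(sel) * (-sum(pc * log2(pc)))
  }
  hf <- -sum((table(fb) / length(fb)) * log2(table(fb) / length(fb)))
  expect_equal(got$gain, hy - hygf, tolerance = 1e-12)
  expect_equal(got$gain_ratio, (hy - hygf) / hf, tolerance = 1e-12)
  expect_error(feature_attributes(rep(1, 8), y), "constant")
})

test_that("set unions deduplicate, keep order and the type partition is exact", {
  mk <- function(method, nms) {
    structure(list(method = method,
                   type = unname(selector_types()[method]),
                   members = data.frame(name = nms,
                                        score = seq_along(nms),
                                        stringsAsFactors = FALSE)),
              class = "feature_set")
  }
  a <- mk("MIM", paste0("f", 1:4))
  b <- mk("CMIM", paste0("f", 5:10))
  u <- union_sets(list(a, b), "type")
  expect_identical(nrow(u$members), 10L)
  expect_identical(u$members$name, paste0("f", 1:10))
  expect_identical(union_sets(list(a, a), "type")$members$name,
                   a$members$name)
  types <- selector_types()
  expect_length(types, 13)
  expect_identical(sort(unique(unname(types))),
                   c("FI", "SIF", "SSL", "STF"))
  expect_identical(sum(types == "FI"), 5L)
  expect_identical(sum(types == "SIF"), 3L)
  expect_identical(sum(types == "STF"), 2L)
  expect_identical(sum(types == "SSL"), 3L)
})

test_that("stochastic selectors reproduce identical sets under a fixed seed", {
  set.seed(20)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  x[, 1:3] <- x[, 1:3] + 1.5 * y
  xn <- normalize_features(x)
  for (m in c("ReliefF", "MCFS", "Lasso")) {
    cfg <- selector_config(seed = 7L)
    s1 <- select_features(m, xn, y, cfg, attributes = FALSE)
    s2 <- select_features(m, xn, y, cfg, attributes = FALSE)
    expect_identical(s1$members, s2$members, label = paste(m, "determinism"))
  }
})
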