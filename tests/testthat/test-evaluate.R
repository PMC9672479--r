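test_that("all ten models score perfectly on a separable toy problem", {
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = y + 0.01 * sin(seq_len(n)), f2 = 0.5 * y + 0.02 * cos(seq_len(n)))
  mm <- suppressWarnings(crossval_metrics(colnames(x), x, y,
                                          models = model_bank(),
                                          k = 10L, seed = 1L))
  expect_identical(dim(mm), c(10L, 5L))
  expect_true(all(mm == 1))
})

test_that("label-independent features give chance-level AUC", {
  set.seed(30)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  mm <- suppressWarnings(crossval_metrics(colnames(x), x, y,
                                          models = model_bank()[c("DT", "KNN",
                                                                  "NB")],
                                          k = 10L, seed = 2L))
  auc <- mean(mm[, "Auc"])
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("H_type and CS match a flat-loop oracle over the metric grid", {
  set.seed(31)
  methods <- names(selector_types())
  models <- paste0("m", 1:10)
  metrics <- c("Acc", "Pre", "Auc", "F1", "Recall")
  sets <- c(methods, c("FI", "SIF", "STF", "SSL"), "all")
  g <- array(runif(length(sets) * 10 * 5), dim = c(length(sets), 10, 5),
             dimnames = list(sets, models, metrics))
  grid <- structure(list(
    metrics = g,
    h_type = vapply(c(FI = "FI", SIF = "SIF", STF = "STF", SSL = "SSL"),
                    function(ty) mean(g[ty, , ]), numeric(1)),
    cs = vapply(methods, function(m) {
      mean(g[selector_types()[[m]], , ]) * mean(g[m, , ])
    }, numeric(1)),
    methods = methods, n_classifiers = 130L), class = "evaluation_grid")
  # flat-loop oracle for H_type
  for (ty in c("FI", "SIF", "STF", "SSL")) {
    acc <- 0
    for (k in metrics) for (m in models) acc <- acc + g[ty, m, k]
    expect_equal(h_type(grid, ty), acc / 50, tolerance = 1e-12)
  }
  # CS is the product of H_type and the method's own flat mean
  for (m in methods) {
    acc <- 0
    for (k in metrics) for (mo in models) acc <- acc + g[m, mo, k]
    expect_equal(composite_score(grid, m),
                 h_type(grid, selector_types()[[m]]) * acc / 50,
                 tolerance = 1e-12)
    expect_lte(composite_score(grid, m), acc / 50)
  }
  expect_error(h_type(grid, "XX"), "missing")
  expect_error(composite_score(grid, "Nope"), "unknown")
})

test_that("degenerate H_type grids reproduce the trivial coefficients", {
  g <- array(1, dim = c(2, 10, 5),
             dimnames = list(c("FI", "MIM"), paste0("m", 1:10),
                             c("Acc", "Pre", "Auc", "F1", "Recall")))
  grid <- structure(list(metrics = g, h_type = c(FI = mean(g["FI", , ])),
                         cs = c(MIM = mean(g["FI", , ]) * mean(g["MIM", , ]))),
                    class = "evaluation_grid")
  expect_equal(h_type(grid, "FI"), 1)
  g[] <- 0.5
  grid$h_type <- c(FI = mean(g["FI", , ]))
  expect_equal(h_type(grid, "FI"), 0.5)
})

test_that("top-k ranking is CS-descending with lexicographic ties", {
  cs <- c(B = 0.9, A = 0.9, C = 0.95, D = 0.1, E = 0.5, F = 0.4, G = 0.3)
  expect_identical(rank_top_k(cs, 6), c("C", "A", "B", "E", "F", "G"))
  all_equal <- setNames(rep(0.5, 7), c("g", "a", "c", "b", "f", "e", "d"))
  expect_identical(rank_top_k(all_equal, 6), c("a", "b", "c", "d", "e", "f"))
  expect_identical(rank_top_k(cs, 7), c("C", "A", "B", "E", "F", "G", "D"))
  expect_error(rank_top_k(cs, 8), "exceeds")
})

test_that("undefined precision scores zero instead of propagating NaN", {
  y <- c(rep(0L, 8), rep(1L, 2))
  score <- rep(0.1, 10)  # never predicts the positive class
  m <- dscradiomics:::classification_metrics(y, score)
  expect_identical(unname(m["Pre"]), 0)
  expect_identical(unname(m["Recall"]), 0)
  expect_identical(unname(m["F1"]), 0)
})

test_that("stratified folds preserve class proportions", {
  y <- rep(c(0L, 1L), times = c(60, 40))
  fold <- dscradiomics:::stratified_folds(y, 10L, seed = 3L)
  for (f in 1:10) {
    expect_identical(sum(y == 0 & fold == f), 6L)
    expect_identical(sum(y == 1 & fold == f), 4L)
  }
})
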