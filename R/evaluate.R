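#' The ten-classifier bank
#'
#' Builds the ten supervised models used to validate feature sets: radial
#' SVM with probability outputs, decision tree, AdaBoost.M1 over stumps,
#' a multilayer perceptron, random forest (200 trees), k-nearest
#' neighbours, cross-validated (ridge-penalised) logistic regression,
#' linear discriminant analysis, gradient-boosted trees and Gaussian naive
#' Bayes. Each entry has `fit(x, y)` and `prob(fit, x)` functions, where
#' `prob` returns the positive-class score.
#'
#' @param nn_size Hidden-layer width of the perceptron (default 40).
#' @param nn_maxit Perceptron iteration cap (default 300).
#' @return Named list of 10 model specifications.
#' @export
model_bank <- function(nn_size = 40L, nn_maxit = 300L) {
  list(
    SVM = list(
      fit = function(x, y) e1071::svm(x, factor(y, levels = c(0, 1)),
                                      kernel = "radial", probability = TRUE),
      prob = function(fit, x) {
        pr <- attr(stats::predict(fit, x, probability = TRUE),
                   "probabilities")
        pr[, "1"]
      }),
    DT = list(
      fit = function(x, y) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), x)
        rpart::rpart(y ~ ., data = df, method = "class")
      },
      prob = function(fit, x) {
        stats::predict(fit, data.frame(x), type = "prob")[, "1"]
      }),
    Ada = list(
      fit = function(x, y) adaboost_fit(x, y, n_rounds = 50L),
      prob = function(fit, x) adaboost_prob(fit, x)),
    NN = list(
      fit = function(x, y) {
        nnet::nnet(x, y, size = nn_size, decay = 0.01, maxit = nn_maxit,
                   entropy = TRUE, trace = FALSE, MaxNWts = 100000)
      },
      prob = function(fit, x) as.numeric(stats::predict(fit, x))),
    RF = list(
      fit = function(x, y) {
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = 200)
      },
      prob = function(fit, x) stats::predict(fit, x, type = "prob")[, "1"]),
    KNN = list(
      fit = function(x, y) list(x = x, y = y),
      prob = function(fit, x) {
        pr <- class::knn(fit$x, x, factor(fit$y, levels = c(0, 1)), k = 5,
                         prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }),
    LR = list(
      fit = function(x, y) {
        foldid <- sample(rep_len(seq_len(5L), length(y)))
        glmnet::cv.glmnet(pad_glmnet(x), y, family = "binomial", alpha = 0,
                          nfolds = 5, foldid = foldid)
      },
      prob = function(fit, x) {
        as.numeric(stats::predict(fit, pad_glmnet(x), s = "lambda.min",
                                  type = "response"))
      }),
    DA = list(
      fit = function(x, y) MASS::lda(x, grouping = factor(y, levels = c(0, 1))),
      prob = function(fit, x) stats::predict(fit, x)$posterior[, "1"]),
    GBDT = list(
      fit = function(x, y) {
        dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = 3, eta = 0.1,
                                         tree_method = "exact", nthread = 1),
                           data = dtrain, nrounds = 100, verbose = 0)
      },
      prob = function(fit, x) {
        stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
      }),
    NB = list(
      fit = function(x, y) e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
      prob = function(fit, x) {
        stats::predict(fit, x, type = "raw")[, "1"]
      })
  )
}

# glmnet requires >= 2 predictor columns; pad single-feature designs with
# an all-zero column (its coefficient is always 0).
pad_glmnet <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `..pad..` = 0)
}

# AdaBoost.M1 with depth-1 rpart stumps.
adaboost_fit <- function(x, y, n_rounds = 50L) {
  n <- nrow(x)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(y = factor(yy, levels = c(-1, 1)), x)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err <= 0) {
      stumps[[m]] <- fit; alphas[m] <- 10; break
    }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- a
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (!length(stumps)) {   # degenerate: constant majority vote
    stumps[[1]] <- NULL
    return(list(stumps = list(), alphas = numeric(0),
                default = mean(y == 1)))
  }
  list(stumps = stumps, alphas = alphas, default = mean(y == 1))
}

adaboost_prob <- function(fit, x) {
  if (!length(fit$stumps)) return(rep(fit$default, nrow(x)))
  df <- data.frame(x)
  score <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(stats::predict(fit$stumps[[m]], df,
                                  type = "class") == "1", 1, -1)
    score <- score + fit$alphas[m] * pred
  }
  1 / (1 + exp(-2 * score))   # logistic link on the additive margin
}

# Stratified k-fold assignment (seeded): fold ids 1..k per sample.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Area under the ROC curve from scores (positive class = 1).
auc_score <- function(y, score) {
  if (length(unique(y)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

classification_metrics <- function(y, score, cutoff = 0.5) {
  pred <- as.integer(score > cutoff)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  c(Acc = mean(pred == y), Pre = pre, Auc = auc_score(y, score), F1 = f1,
    Recall = rec)
}

#' Stratified tenfold cross-validation of one feature set
#'
#' Restricts the table to the set's features, runs seeded stratified
#' k-fold cross-validation for every model in the bank, and reports the
#' fold-mean of the five metrics (Acc, Pre, Auc, F1, Recall) per model.
#' The positive class is HA (label 1); undefined precision (no positive
#' predictions in a fold) scores 0.
#'
#' @param feature_set A `feature_set` (or character vector of names).
#' @param table A [feature_table()] or named matrix.
#' @param labels Binary labels.
#' @param models A [model_bank()] (or subset of one).
#' @param k Number of folds (default 10).
#' @param seed Fold/model seed.
#' @return Matrix models x metrics of fold means.
#' @export
crossval_metrics <- function(feature_set, table, labels, models = model_bank(),
                             k = 10L, seed = 1L) {
  nms <- if (inherits(feature_set, "feature_set")) {
    feature_set$members$name
  } else {
    as.character(feature_set)
  }
  if (!length(nms)) stop("empty feature set")
  x <- ft_values(table)[, nms, drop = FALSE]
  y <- as.integer(labels)
  if (min(table(y)) < k) stop(sprintf("each class needs >= %d samples", k))
  fold <- stratified_folds(y, k, seed)
  metric_names <- c("Acc", "Pre", "Auc", "F1", "Recall")
  acc <- array(0, dim = c(length(models), length(metric_names), k),
               dimnames = list(names(models), metric_names, NULL))
  for (f in seq_len(k)) {
    tr <- fold != f
    for (m in names(models)) {
      set.seed(seed * 1000L + f)
      fit <- models[[m]]$fit(x[tr, , drop = FALSE], y[tr])
      score <- models[[m]]$prob(fit, x[!tr, , drop = FALSE])
      acc[m, , f] <- classification_metrics(y[!tr], score)
    }
  }
  apply(acc, c(1, 2), mean)
}

#' Evaluate the full bank of feature sets
#'
#' Cross-validates every method set, the four family unions (F_FI, F_SIF,
#' F_STF, F_SSL) and the overall union F_all, then derives each family
#' coefficient H_type and each method's composite score CS.
#'
#' @param sets Named list of 13 `feature_set` objects (one per method).
#' @param table,labels Data and binary labels.
#' @param models A [model_bank()].
#' @param k,seed Cross-validation folds and seed.
#' @return An `evaluation_grid`: list with `metrics` (set x model x metric
#'   array over methods, unions and "all"), `h_type`, `cs`, `n_classifiers`.
#' @export
evaluate_sets <- function(sets, table, labels, models = model_bank(),
                          k = 10L, seed = 1L) {
  types <- selector_types()
  methods <- names(sets)
  nonempty <- methods[vapply(sets, function(s) nrow(s$members) > 0, TRUE)]
  unions <- list()
  for (ty in unique(types)) {
    mem <- intersect(nonempty, names(types)[types == ty])
    if (length(mem)) unions[[ty]] <- union_sets(sets[mem], "type", label = ty)
  }
  all_set <- union_sets(sets[nonempty], "all", label = "all")
  eval_list <- c(sets[nonempty], unions, list(all = all_set))
  metric_names <- c("Acc", "Pre", "Auc", "F1", "Recall")
  grid <- array(NA_real_,
                dim = c(length(eval_list), length(models),
                        length(metric_names)),
                dimnames = list(names(eval_list), names(models),
                                metric_names))
  for (nm in names(eval_list)) {
    grid[nm, , ] <- crossval_metrics(eval_list[[nm]], table, labels, models,
                                     k = k, seed = seed)
  }
  h <- vapply(names(unions), function(ty) mean(grid[ty, , ]), numeric(1))
  cs <- vapply(nonempty, function(m) {
    ty <- unname(types[m])
    if (!ty %in% names(h)) return(NA_real_)
    unname(h[ty]) * mean(grid[m, , ])
  }, numeric(1))
  structure(list(metrics = grid, h_type = h, cs = cs,
                 methods = nonempty,
                 n_classifiers = length(nonempty) * length(models),
                 sets = eval_list),
            class = "evaluation_grid")
}

#' Family coefficient H_type
#'
#' The mean of the five metrics over the ten models for the family union
#' set: `H_type = (1 / (K * M)) * sum index(k, model(m, F_type))`.
#'
#' @param grid An [evaluate_sets()] result.
#' @param type One of `"FI"`, `"SIF"`, `"STF"`, `"SSL"`.
#' @return Scalar in \[0, 1].
#' @export
h_type <- function(grid, type) {
  if (!type %in% names(grid$h_type)) stop("missing cells for type ", type)
  unname(grid$h_type[type])
}

#' Composite score of a method's feature set
#'
#' `CS(F_method) = H_type * mean(index(k, model(m, F_method)))`; since
#' `H_type <= 1`, CS never exceeds the method's own mean metric.
#'
#' @param grid An [evaluate_sets()] result.
#' @param method Method name.
#' @return Scalar in \[0, 1].
#' @export
composite_score <- function(grid, method) {
  if (!method %in% names(grid$cs)) stop("unknown method ", method)
  unname(grid$cs[method])
}

#' Rank the top-k feature sets by composite score
#'
#' @param cs_values Named CS vector (e.g. `grid$cs`).
#' @param k Number of sets to keep (default 6).
#' @return Character vector of method names, descending CS, ties broken
#'   lexicographically.
#' @export
rank_top_k <- function(cs_values, k = 6L) {
  cs_values <- cs_values[!is.na(cs_values)]
  if (k > length(cs_values)) stop("k exceeds number of scored methods")
  names(cs_values)[order(-cs_values, names(cs_values))][seq_len(k)]
}

#' Union of the top-k sets' members
#'
#' @param sets Named list of `feature_set`s.
#' @param cs_values Named CS vector.
#' @param k Number of top sets (default 6).
#' @return A `feature_set` labelled `"top6"` (or `"top<k>"`).
#' @export
top_k_union <- function(sets, cs_values, k = 6L) {
  top <- rank_top_k(cs_values, k)
  union_sets(sets[top], "all", label = paste0("top", k))
}
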