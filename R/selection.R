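#' The 13 feature-selection methods and their families
#'
#' Four families: mutual-information methods (FI), similarity methods
#' (SIF), statistical scores (STF), and sparse-learning / streaming
#' methods (SSL).
#'
#' @return Named character vector mapping method to family.
#' @export
selector_types <- function() {
  c(CMIM = "FI", JMI = "FI", MIFS = "FI", MIM = "FI", MRMR = "FI",
    Fisher = "SIF", Lap = "SIF", ReliefF = "SIF",
    FS = "STF", TS = "STF",
    MCFS = "SSL", Alpha = "SSL", Lasso = "SSL")
}

#' Configuration of the feature-selection bank
#'
#' Holds the shared thresholding rules (normalised score > 0.9, at most 20
#' features; Lasso keeps coefficients with |beta| > 0.02) and per-method
#' hyperparameters that the originating descriptions leave open.
#'
#' @param max_features Cap on selected features (default 20).
#' @param score_threshold Normalised-score cut for non-Lasso methods (0.9).
#' @param lasso_coef_threshold Absolute-coefficient cut for Lasso (0.02).
#' @param mi_bins Equal-frequency bins for mutual-information estimation.
#' @param mifs_beta Redundancy weight of MIFS (default 0.5, the middle of
#'   the classical \[0.5, 1] range; 1 over-penalises the mutual redundancy
#'   that informative features share through the class).
#' @param knn_k Neighbours for the Laplacian-score / MCFS sample graph.
#' @param relieff_k Neighbours per class in ReliefF (default 10).
#' @param mcfs_eigvecs Number of non-trivial spectral eigenvectors in MCFS
#'   (default 1: with two classes the cluster structure lives in the first
#'   non-trivial eigenvector, the spectral-clustering convention).
#' @param alpha_wealth,alpha_delta Initial wealth and payoff of
#'   alpha-investing (defaults 0.5, 0.5).
#' @param max_rank Greedy MI methods rank at most this many features in
#'   forward-selection order (default 50); features beyond it are unranked.
#' @param seed Seed for the stochastic methods (Lasso CV folds).
#' @return An object of class `selector_config`.
#' @export
selector_config <- function(max_features = 20L, score_threshold = 0.9,
                            lasso_coef_threshold = 0.02, mi_bins = 5L,
                            mifs_beta = 0.5, knn_k = 5L, relieff_k = 10L,
                            mcfs_eigvecs = 1L, alpha_wealth = 0.5,
                            alpha_delta = 0.5, max_rank = 50L, seed = 1L) {
  if (max_features < 1L) stop("max_features must be >= 1")
  structure(list(max_features = as.integer(max_features),
                 score_threshold = score_threshold,
                 lasso_coef_threshold = lasso_coef_threshold,
                 mi_bins = as.integer(mi_bins), mifs_beta = mifs_beta,
                 knn_k = as.integer(knn_k), relieff_k = as.integer(relieff_k),
                 mcfs_eigvecs = as.integer(mcfs_eigvecs),
                 alpha_wealth = alpha_wealth, alpha_delta = alpha_delta,
                 max_rank = as.integer(max_rank), seed = as.integer(seed)),
            class = "selector_config")
}

#' Equal-frequency discretization
#'
#' @param x Numeric vector.
#' @param bins Target number of bins (ties can merge bins).
#' @return Integer vector of bin indices starting at 1.
#' @export
discretize_ef <- function(x, bins = 5L) {
  ux <- sort(unique(x))
  if (length(ux) <= bins) return(match(x, ux))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Plug-in mutual information in bits
#'
#' Mutual information of two discrete variables from their empirical joint
#' distribution, `I(X;Y) = sum p(x,y) log2(p(x,y) / (p(x) p(y)))`.
#'
#' @param x,y Integer/factor vectors of equal length.
#' @return Non-negative scalar, in bits.
#' @export
mutual_information <- function(x, y) {
  x <- as.integer(as.factor(x)); y <- as.integer(as.factor(y))
  nx <- max(x); ny <- max(y)
  joint <- tabulate(x + (y - 1L) * nx, nbins = nx * ny) / length(x)
  px <- tabulate(x, nbins = nx) / length(x)
  py <- tabulate(y, nbins = ny) / length(y)
  pq <- as.vector(outer(px, py))
  pos <- joint > 0
  sum(joint[pos] * log2(joint[pos] / pq[pos]))
}

# I(X;Y | Z) = sum_z p(z) I(X;Y | Z=z), plug-in, bits.
cond_mutual_information <- function(x, y, z) {
  z <- as.integer(as.factor(z))
  out <- 0
  for (zv in seq_len(max(z))) {
    sel <- z == zv
    pz <- mean(sel)
    if (pz > 0 && sum(sel) > 1L) {
      out <- out + pz * mutual_information(x[sel], y[sel])
    }
  }
  out
}

# ---- individual scorers ------------------------------------------------

score_mim <- function(D, y) apply(D, 2, mutual_information, y = y)

# Greedy forward selection for the redundancy-aware MI methods. Each
# selected feature carries the objective value at its selection step;
# unranked features get NA.
score_greedy_mi <- function(D, y, method, cfg) {
  p <- ncol(D)
  nm <- colnames(D)
  rel <- apply(D, 2, mutual_information, y = y)
  scores <- rep(NA_real_, p)
  names(scores) <- nm
  n_rank <- min(p, cfg$max_rank)
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)                # sum over selected of I(f_i; f_s)
  cmi_list <- NULL                     # per remaining: running min / sum CMI
  cmi_sum <- numeric(p)
  cmi_min <- rep(Inf, p)
  for (step in seq_len(n_rank)) {
    obj <- switch(method,
      MIFS = rel[remaining] - cfg$mifs_beta * red_sum[remaining],
      MRMR = rel[remaining] -
        if (length(selected)) red_sum[remaining] / length(selected) else 0,
      JMI = if (length(selected)) cmi_sum[remaining] / length(selected)
            else rel[remaining],
      CMIM = if (length(selected)) cmi_min[remaining] else rel[remaining])
    ord <- order(-obj, nm[remaining])
    pick <- remaining[ord[1]]
    scores[pick] <- obj[ord[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (!length(remaining)) break
    if (method %in% c("MIFS", "MRMR")) {
      red_sum[remaining] <- red_sum[remaining] +
        apply(D[, remaining, drop = FALSE], 2, mutual_information,
              y = D[, pick])
    } else {
      cmi <- apply(D[, remaining, drop = FALSE], 2, cond_mutual_information,
                   y = y, z = D[, pick])
      cmi_sum[remaining] <- cmi_sum[remaining] + cmi
      cmi_min[remaining] <- pmin(cmi_min[remaining], cmi)
    }
  }
  scores
}

score_fisher <- function(x, y) {
  apply(x, 2, function(f) {
    mu <- mean(f)
    num <- 0; den <- 0
    for (c in unique(y)) {
      fc <- f[y == c]
      num <- num + length(fc) * (mean(fc) - mu)^2
      den <- den + length(fc) * stats::var(fc)
    }
    ratio_score(num, den)
  })
}

# Variance-ratio scores blow up on perfectly separated features (zero
# within-class variance); cap them at a large finite value so min-max
# normalisation stays well defined.
ratio_score <- function(num, den) {
  if (den > 0) num / den else if (num > 0) 1e12 else 0
}

# Sample kNN graph with heat-kernel weights; shared by Lap and MCFS.
sample_graph <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  width <- mean(d[upper.tri(d)])
  if (width <= 0) width <- 1
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:min(k + 1L, n)]
    W[i, nb] <- exp(-d[i, nb]^2 / (2 * width^2))
  }
  pmax(W, t(W))  # symmetrize (union of neighbourhoods)
}

score_lap <- function(x, y, cfg) {
  W <- sample_graph(x, cfg$knn_k)
  ddiag <- rowSums(W)
  Dsum <- sum(ddiag)
  apply(x, 2, function(f) {
    ft <- f - sum(f * ddiag) / Dsum
    den <- sum(ft^2 * ddiag)
    if (den <= 0) return(-Inf)           # worst possible after negation
    num <- sum(ft * (ddiag * ft - W %*% ft))
    -(num / den)                          # lower raw score = better
  })
}

score_relieff <- function(x, y, cfg) {
  n <- nrow(x); p <- ncol(x)
  rngs <- apply(x, 2, function(f) diff(range(f)))
  rngs[rngs == 0] <- 1
  xn <- sweep(x, 2, rngs, `/`)
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  diag(d) <- Inf
  priors <- table(y) / n
  k <- cfg$relieff_k
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    hits <- same[order(d[i, same])][seq_len(min(k, length(same) - 1L))]
    for (cls in names(priors)) {
      if (cls == as.character(y[i])) next
      other <- which(as.character(y) == cls)
      miss <- other[order(d[i, other])][seq_len(min(k, length(other)))]
      wt <- priors[[cls]] / (1 - priors[[as.character(y[i])]])
      w <- w + wt * colMeans(abs(sweep(xn[miss, , drop = FALSE], 2, xn[i, ])))
    }
    w <- w - colMeans(abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ])))
  }
  w / n
}

score_fs <- function(x, y) {
  pos <- y == 1; neg <- !pos
  apply(x, 2, function(f) {
    mu <- mean(f)
    num <- (mean(f[pos]) - mu)^2 + (mean(f[neg]) - mu)^2
    den <- stats::var(f[pos]) + stats::var(f[neg])
    ratio_score(num, den)
  })
}

score_ts <- function(x, y) {
  pos <- y == 1; neg <- !pos
  n1 <- sum(pos); n0 <- sum(neg)
  apply(x, 2, function(f) {
    se <- sqrt(stats::var(f[pos]) / n1 + stats::var(f[neg]) / n0)
    ratio_score(abs(mean(f[pos]) - mean(f[neg])), se)
  })
}

score_mcfs <- function(x, y, cfg) {
  W <- sample_graph(x, cfg$knn_k)
  dd <- rowSums(W)
  dd[dd <= 0] <- 1e-12
  Dh <- 1 / sqrt(dd)
  Lsym <- diag(nrow(W)) - (Dh * W) * rep(Dh, each = nrow(W))
  eg <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  K <- min(cfg$mcfs_eigvecs, nrow(W) - 1L)
  # smallest non-trivial eigenvalues
  take <- seq.int(nrow(W) - 1L, by = -1L, length.out = K)
  scores <- matrix(0, ncol(x), K)
  for (kk in seq_len(K)) {
    target <- Dh * eg$vectors[, take[kk]]
    fit <- glmnet::glmnet(x, target, family = "gaussian", standardize = TRUE)
    nz <- fit$df
    want <- min(ncol(x), cfg$max_features)
    idx <- which(nz >= want)[1]
    if (is.na(idx)) idx <- length(fit$lambda)
    scores[, kk] <- abs(as.numeric(stats::coef(fit)[-1, idx]))
  }
  out <- apply(scores, 1, max)
  names(out) <- colnames(x)
  out
}

# Streaming alpha-investing over the feature sequence: each candidate is
# tested for the error reduction it adds to the running least-squares
# model (added-variable t-test on orthogonalized residuals); the wealth
# rule adapts the acceptance threshold as features stream by.
score_alpha_investing <- function(x, y, cfg) {
  n <- nrow(x); p <- ncol(x)
  w <- cfg$alpha_wealth
  Q <- matrix(1 / sqrt(n), n, 1)       # orthonormal basis incl. intercept
  ry <- y - Q %*% crossprod(Q, y)
  pvals <- numeric(p)
  sel_flag <- logical(p)
  for (i in seq_len(p)) {
    alpha_i <- max(w, 0) / (2 * i)
    xi <- x[, i] - Q %*% crossprod(Q, x[, i])
    nrm2 <- sum(xi^2)
    dfres <- n - ncol(Q) - 1L
    pv <- 1
    if (nrm2 > 1e-12 && dfres > 0) {
      beta <- sum(xi * ry) / nrm2
      rss_new <- sum(ry^2) - beta^2 * nrm2
      if (rss_new <= 0) {
        pv <- 0
      } else {
        tt <- beta * sqrt(nrm2) / sqrt(rss_new / dfres)
        pv <- 2 * stats::pt(-abs(tt), dfres)
      }
    }
    pvals[i] <- pv
    if (pv < alpha_i) {
      sel_flag[i] <- TRUE
      w <- w + cfg$alpha_delta - alpha_i
      Q <- cbind(Q, xi / sqrt(nrm2))
      ry <- ry - Q[, ncol(Q)] * sum(Q[, ncol(Q)] * ry)
    } else {
      w <- w - alpha_i / (1 - alpha_i)
    }
  }
  out <- -log10(pmax(pvals, 1e-300))
  names(out) <- colnames(x)
  attr(out, "accepted") <- colnames(x)[sel_flag]
  out
}

score_lasso <- function(x, y, cfg) {
  set.seed(cfg$seed)
  n <- nrow(x)
  p <- ncol(x)
  foldid <- sample(rep_len(seq_len(5L), n))
  xx <- if (p >= 2L) x else cbind(x, `..pad..` = 0)
  cv <- glmnet::cv.glmnet(xx, y, family = "gaussian", nfolds = 5,
                          foldid = foldid, standardize = TRUE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  out <- abs(beta)[seq_len(p)]
  names(out) <- colnames(x)
  out
}

#' Score all features with one selection method
#'
#' Dispatches to one of the 13 scorers. Greedy mutual-information methods
#' (MIFS, MRMR, JMI, CMIM) return the forward-selection objective at each
#' feature's selection step (later unranked features are `NA`); the
#' Laplacian score is negated so that larger is always better; Lasso
#' scores are `|beta|` at the cross-validated penalty.
#'
#' @param method One of `names(selector_types())`.
#' @param table A [feature_table()] or named numeric matrix (normalised).
#' @param labels Binary labels (1 = positive class).
#' @param cfg A [selector_config()].
#' @return Named numeric score vector (may carry an `accepted` attribute
#'   for the streaming Alpha-investing method).
#' @export
score_features <- function(method, table, labels, cfg = selector_config()) {
  method <- match.arg(method, names(selector_types()))
  x <- ft_values(table)
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (method %in% c("MIM", "MIFS", "MRMR", "JMI", "CMIM")) {
    D <- apply(x, 2, discretize_ef, bins = cfg$mi_bins)
    colnames(D) <- colnames(x)
    if (method == "MIM") return(score_mim(D, y))
    return(score_greedy_mi(D, y, method, cfg))
  }
  switch(method,
         Fisher = score_fisher(x, y),
         Lap = score_lap(x, y, cfg),
         ReliefF = score_relieff(x, y, cfg),
         FS = score_fs(x, y),
         TS = score_ts(x, y),
         MCFS = score_mcfs(x, y, cfg),
         Alpha = score_alpha_investing(x, y, cfg),
         Lasso = score_lasso(x, y, cfg))
}

#' Threshold scores into a feature set
#'
#' Non-Lasso methods: scores are min-max normalised to \[0, 1], features
#' with normalised score > `score_threshold` are kept, and the list is
#' truncated to the top `max_features` (descending score, ties broken
#' lexicographically by name). Lasso keeps `|beta| >
#' lasso_coef_threshold` with the same cap. All-equal scores yield an
#' empty set with a warning.
#'
#' @param scores Named score vector from [score_features()].
#' @param cfg A [selector_config()].
#' @param method Method name (determines the rule).
#' @return An object of class `feature_set`.
#' @export
apply_threshold <- function(scores, cfg = selector_config(), method = "MIM") {
  method <- match.arg(method, names(selector_types()))
  s <- scores[!is.na(scores)]
  if (!length(s)) stop("no scored features")
  if (method == "Lasso") {
    keep <- s[abs(s) > cfg$lasso_coef_threshold]
  } else {
    rng <- range(s)
    if (diff(rng) == 0) {
      warning("all scores equal; empty feature set")
      keep <- s[0]
    } else {
      norm <- (s - rng[1]) / diff(rng)
      keep <- s[norm > cfg$score_threshold]
    }
  }
  ord <- order(-keep, names(keep))
  keep <- keep[ord]
  if (length(keep) > cfg$max_features) keep <- keep[seq_len(cfg$max_features)]
  structure(list(method = method,
                 type = unname(selector_types()[method]),
                 members = data.frame(name = names(keep),
                                      score = unname(keep),
                                      stringsAsFactors = FALSE)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> F_%s (%s): %d features\n", x$method, x$type,
              nrow(x$members)))
  invisible(x)
}

#' Run one selection method end to end
#'
#' @inheritParams score_features
#' @param attributes Attach per-feature attributes ([feature_attributes()]).
#' @return A `feature_set`.
#' @export
select_features <- function(method, table, labels, cfg = selector_config(),
                            attributes = TRUE) {
  scores <- score_features(method, table, labels, cfg)
  fs <- apply_threshold(scores, cfg, method)
  if (attributes && nrow(fs$members)) {
    x <- ft_values(table)
    att <- t(vapply(fs$members$name, function(nm) {
      unlist(feature_attributes(x[, nm], labels, cfg$mi_bins))
    }, numeric(4)))
    fs$members <- cbind(fs$members, as.data.frame(att))
  }
  fs
}

#' Per-feature attributes: R squared, p-value, gain and gain ratio
#'
#' `r_squared` is the squared Pearson correlation with the label; the
#' p-value comes from the two-sample t-test; `gain` is the information
#' gain `H(C) - H(C | f)` with `f` discretized into equal-frequency bins;
#' `gain_ratio` divides the gain by the entropy of the binned feature.
#'
#' @param feature Numeric vector (non-constant).
#' @param labels Binary labels.
#' @param mi_bins Bins for the discretization (default 5).
#' @return List with `r_squared`, `p_value`, `gain`, `gain_ratio`.
#' @export
feature_attributes <- function(feature, labels, mi_bins = 5L) {
  if (diff(range(feature)) == 0) stop("constant feature has no attributes")
  y <- as.integer(labels)
  r2 <- stats::cor(feature, y)^2
  m <- matrix(feature, ncol = 1, dimnames = list(NULL, "f"))
  p <- ttest_filter(m, y)$p_value
  if (!is.finite(p)) p <- 1
  fb <- discretize_ef(feature, mi_bins)
  hy <- entropy_bits(tabulate(y + 1L) / length(y))
  gain <- mutual_information(fb, y)  # = H(C) - H(C|f)
  hf <- entropy_bits(tabulate(fb) / length(fb))
  list(r_squared = r2, p_value = p, gain = gain,
       gain_ratio = if (hf > 0) gain / hf else 0)
}

#' Union of feature sets
#'
#' Duplicate-free union preserving first-seen order, used to build the
#' family-level sets `F_type` (FI, SIF, STF, SSL) and the overall `F_all`.
#'
#' @param sets List of `feature_set` objects.
#' @param level `"type"` or `"all"` (controls the label only).
#' @param label Optional explicit label for the union set.
#' @return A `feature_set` whose `method` is the label.
#' @export
union_sets <- function(sets, level = c("type", "all"), label = NULL) {
  level <- match.arg(level)
  if (!length(sets)) stop("need >= 1 input set")
  nm <- unlist(lapply(sets, function(s) s$members$name))
  sc <- unlist(lapply(sets, function(s) s$members$score))
  keep <- !duplicated(nm)
  if (is.null(label)) {
    label <- if (level == "all") "all" else unique(vapply(sets, `[[`,
                                                          "", "type"))[1]
  }
  structure(list(method = label, type = label,
                 members = data.frame(name = nm[keep], score = sc[keep],
                                      stringsAsFactors = FALSE)),
            class = "feature_set")
}
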