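#' Per-feature two-sample t-test filter
#'
#' Runs an independent two-sample t-test on every feature column
#' (HA = 1 vs NA = 0) and retains features with `p < alpha`. No
#' multiple-testing correction is applied; the filter is a deliberate
#' raw-p screen ahead of the feature-selection bank. The classical
#' equal-variance (Student) test is the default; Welch is available.
#'
#' @param table A [feature_table()] or named numeric matrix (samples x
#'   features), already normalised with [normalize_features()].
#' @param labels Binary vector (1 = HA, 0 = NA), one per sample.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance Student test (default TRUE);
#'   `FALSE` gives Welch.
#' @return An object of class `significance_report`: a data frame with
#'   columns `name`, `p_value`, `retained`, plus attributes `alpha`.
#' @export
ttest_filter <- function(table, labels, alpha = 0.05, var_equal = TRUE) {
  x <- ft_values(table)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels must match sample count")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L) stop("each class needs >= 2 samples")
  x1 <- x[labels == 1L, , drop = FALSE]
  x0 <- x[labels == 0L, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, ncol(x))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  rep <- data.frame(name = colnames(x), p_value = unname(p),
                    retained = unname(p < alpha), stringsAsFactors = FALSE)
  attr(rep, "alpha") <- alpha
  class(rep) <- c("significance_report", "data.frame")
  rep
}

#' Per-group p-value statistics of retained features
#'
#' Summarises the retained (significant) features per radiomics group:
#' count, mean, standard deviation, minimum, median and maximum of their
#' p-values. Groups with no retained feature are reported with count 0 and
#' blank statistics.
#'
#' @param report A [ttest_filter()] result.
#' @param grouping Character vector of group labels per feature; defaults
#'   to [group_of()] applied to the feature names.
#' @param groups Group levels to report (default [radiomics_groups()]
#'   intersected with those present).
#' @return Data frame with one row per group.
#' @export
group_pvalue_stats <- function(report, grouping = group_of(report$name),
                               groups = NULL) {
  if (is.null(groups)) {
    groups <- intersect(radiomics_groups(), unique(grouping))
    if (!length(groups)) groups <- sort(unique(grouping))
  }
  rows <- lapply(groups, function(g) {
    p <- report$p_value[grouping == g & report$retained]
    if (!length(p)) {
      data.frame(group = g, n = 0L, mean = NA_real_, std = NA_real_,
                 min = NA_real_, median = NA_real_, max = NA_real_)
    } else {
      data.frame(group = g, n = length(p), mean = mean(p),
                 std = if (length(p) > 1) stats::sd(p) else 0,
                 min = min(p), median = stats::median(p), max = max(p))
    }
  })
  do.call(rbind, rows)
}
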