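#!/usr/bin/env Rscript
# Cross-validate every feature set on the ten-classifier bank (stratified
# tenfold), derive the family coefficients H_type and each method's
# composite score CS, and rank the top six sets.

library(dscradiomics)

feats <- read.csv("results/features.csv", check.names = FALSE, na.strings = "")
labels <- as.integer(feats$role == "HA")
x <- as.matrix(feats[, -(1:2)])
xn <- suppressWarnings(normalize_features(x))
report <- read.csv("results/significance.csv")
xs <- xn[, report$name[report$retained], drop = FALSE]

cfg <- selector_config(seed = 1L)
sets <- list()
for (m in names(selector_types())) {
  sets[[m]] <- suppressWarnings(select_features(m, xs, labels, cfg,
                                                attributes = FALSE))
}

grid <- suppressWarnings(evaluate_sets(sets, xs, labels, model_bank(),
                                       k = 10L, seed = 1L))

cs_tab <- data.frame(method = names(grid$cs),
                     type = unname(selector_types()[names(grid$cs)]),
                     mean_metric = vapply(names(grid$cs), function(m) {
                       mean(grid$metrics[m, , ])
                     }, numeric(1)),
                     cs = unname(grid$cs))
cs_tab <- cs_tab[order(-cs_tab$cs), ]
write.csv(cs_tab, "results/cs_table.csv", row.names = FALSE)

long <- do.call(rbind, lapply(dimnames(grid$metrics)[[1]], function(s) {
  do.call(rbind, lapply(dimnames(grid$metrics)[[2]], function(m) {
    data.frame(set = s, model = m, metric = dimnames(grid$metrics)[[3]],
               value = grid$metrics[s, m, ])
  }))
}))
write.csv(long, "results/metric_grid.csv", row.names = FALSE)

top6 <- rank_top_k(grid$cs, 6L)
jsonlite::write_json(
  list(h_type = as.list(grid$h_type), cs = as.list(grid$cs), top6 = top6,
       top6_union = top_k_union(sets, grid$cs, 6L)$members$name,
       n_classifiers = grid$n_classifiers),
  "results/evaluation_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("%d classifiers fitted (13 sets x 10 models)\n",
            grid$n_classifiers))
cat("family coefficients H_type:\n"); print(round(grid$h_type, 3))
cat("composite scores:\n"); print(cs_tab, digits = 3, row.names = FALSE)
cat("top six sets:", paste(top6, collapse = ", "), "\n")
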