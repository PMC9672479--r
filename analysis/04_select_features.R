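#!/usr/bin/env Rscript
# Run the 13-method selection bank on the significant features and report
# each set with its per-feature attributes (R squared with the label,
# t-test p, information gain and gain ratio).

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
  sets[[m]] <- suppressWarnings(select_features(m, xs, labels, cfg))
}

summary_tab <- do.call(rbind, lapply(names(sets), function(m) {
  mem <- sets[[m]]$members
  data.frame(method = m, type = sets[[m]]$type, n = nrow(mem),
             r_squared = mean(mem$r_squared), p_value = mean(mem$p_value),
             gain = mean(mem$gain), gain_ratio = mean(mem$gain_ratio))
}))
write.csv(summary_tab, "results/feature_set_attributes.csv",
          row.names = FALSE)
jsonlite::write_json(lapply(sets, function(s) s$members),
                     "results/feature_sets.json", dataframe = "rows",
                     digits = NA, pretty = TRUE)

cat("features selected per method:\n")
print(summary_tab[, c("method", "type", "n")], row.names = FALSE)
cat(sprintf("union over all 13 methods: %d distinct features\n",
            nrow(union_sets(sets, "all")$members)))
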