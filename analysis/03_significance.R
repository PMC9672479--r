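#!/usr/bin/env Rscript
# Normalise the feature table (mean-centred range scaling) and screen
# features with the per-column two-sample t-test (HA vs NA, p < 0.05).
# Writes the per-feature report and the per-group p-value statistics.

library(dscradiomics)

feats <- read.csv("results/features.csv", check.names = FALSE, na.strings = "")
labels <- as.integer(feats$role == "HA")
x <- as.matrix(feats[, -(1:2)])
rownames(x) <- feats$sample

xn <- suppressWarnings(normalize_features(x))
report <- ttest_filter(xn, labels)
groups <- group_pvalue_stats(report)

write.csv(report, "results/significance.csv", row.names = FALSE)
write.csv(groups, "results/significant_groups.csv", row.names = FALSE)

cat(sprintf("%d of %d features significant at p < 0.05 (%.1f%%)\n",
            sum(report$retained), nrow(report),
            100 * mean(report$retained)))
print(groups, digits = 3)
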