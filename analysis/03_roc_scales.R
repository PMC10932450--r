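#!/usr/bin/env Rscript

# Stage 3: pairwise diagnostic accuracy and the Ca/K metric scales.
#
# For each of the six tissue pairs and each element: oriented Mann-Whitney
# AUC with DeLong 95% CI and p-value against AUC = 0.5, plus the
# Youden-optimal cutoff with its sensitivity and specificity. Then the two
# four-class metric scales: classes ordered by element median, one Youden
# cutoff between each median-adjacent pair, partitioning the peak-area axis.

suppressMessages(library(libstissue))

features <- read_features("scratch/features.csv")
study <- features[features$tissue %in% study_classes(), ]
dir.create("results", showWarnings = FALSE)

roc <- pairwise_roc_report(study)
write.csv(roc, "results/table3_roc.csv", row.names = FALSE)
best <- roc[which.max(roc$auc), ]
message(sprintf("best pairwise discrimination: %s vs %s by %s, AUC %.4f",
                best$positive_class, best$negative_class, best$element,
                best$auc))

scale_rows <- list()
for (el in c("Ca", "K")) {
  sc <- build_metric_scale(study, el)
  print(sc)
  bounds <- c(0, sc$cutoffs)
  scale_rows[[el]] <- data.frame(
    element = el, class = sc$ordered_classes, lower = bounds,
    upper = c(sc$cutoffs, Inf), median = unname(sc$medians))
}
scales <- do.call(rbind, scale_rows)
rownames(scales) <- NULL
write.csv(scales, "results/fig5_scales.csv", row.names = FALSE)
message("wrote results/table3_roc.csv and results/fig5_scales.csv")
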