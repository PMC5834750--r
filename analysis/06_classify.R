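#!/usr/bin/env Rscript
# Stage 6: boosted-tree group classification from the four global AUC
# metrics, evaluated by leave-one-out cross-validation; per-group
# sensitivity and specificity from the pooled confusion matrix.

library(sivdnet)

meta <- read.csv("results/cohort/metadata.csv")
groups <- factor(meta$group, levels = c("NC", "SIVCIND", "SIVaD"))
auc <- read.csv("results/metrics/auc_global.csv")

res <- loocv_adaboost(auc[, c("Cp", "Lp", "Eg", "Eloc")], groups,
                      n_rounds = 100, tree_depth = 1)
cat(sprintf("LOOCV accuracy: %.1f%%\n", 100 * res$accuracy))
cat("confusion matrix (rows = true, columns = predicted):\n")
print(res$confusion)

dir.create("results/classify", recursive = TRUE, showWarnings = FALSE)
write.csv(as.data.frame.matrix(res$confusion),
          "results/classify/confusion_matrix.csv")
write.csv(data.frame(subject_id = meta$subject_id, true = groups,
                     predicted = res$predictions),
          "results/classify/predictions.csv", row.names = FALSE)

perf <- do.call(rbind, lapply(levels(groups), function(g) {
  ss <- sensitivity_specificity(res$confusion, g)
  data.frame(group = g, sensitivity = ss$sensitivity,
             specificity = ss$specificity)
}))
print(perf, digits = 3)
write.csv(perf, "results/classify/sensitivity_specificity.csv",
          row.names = FALSE)
cat("written to results/classify/\n")
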