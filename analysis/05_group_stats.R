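#!/usr/bin/env Rscript
# Stage 5: group statistics and brain-behaviour correlation.
#
# Demographic checks (chi-squared gender, Welch ANOVA age/education,
# two-sample t on clinical scales), Welch ANOVA + Games-Howell on the
# global AUC metrics (BH-adjusted as a 4-test family), Welch ANOVA per
# region on nodal efficiency AUCs (BH within each 90-test family), and
# Spearman correlations of the four metrics with MMSE/MoCA in the pooled
# patient sample (BH over the 8-test family).

library(sivdnet)

meta <- read.csv("results/cohort/metadata.csv")
groups <- factor(meta$group, levels = c("NC", "SIVCIND", "SIVaD"))
auc <- read.csv("results/metrics/auc_global.csv")
nodal_g <- read.csv("results/metrics/auc_nodal_global.csv", check.names = FALSE)
nodal_l <- read.csv("results/metrics/auc_nodal_local.csv", check.names = FALSE)
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

cat("== demographics ==\n")
cs <- chisq_gender(table(meta$gender, meta$group))
cat(sprintf("gender: X2 = %.3f, p = %.3f\n", cs$statistic, cs$pvalue))
for (v in c("age", "education")) {
  w <- welch_anova(meta[[v]], groups)
  cat(sprintf("%s: Welch F = %.3f, p = %.3f\n", v, w$statistic, w$pvalue))
}
for (sc in c("HIS", "GDS", "CDR", "ADL")) {
  tt <- two_sample_t(meta[[sc]][meta$group == "SIVCIND"],
                     meta[[sc]][meta$group == "SIVaD"])
  cat(sprintf("%s (SIVCIND vs SIVaD): t = %.3f, p = %.3g\n",
              sc, tt$statistic, tt$pvalue))
}

cat("== global AUC metrics ==\n")
global <- compare_groups(auc, groups, ks_seed = 20260905)
print(global$omnibus, digits = 4)
write.csv(global$omnibus, "results/stats/global_omnibus.csv", row.names = FALSE)
for (me in names(global$posthoc)) {
  cat("Games-Howell for", me, ":\n")
  print(global$posthoc[[me]], digits = 4)
  write.csv(global$posthoc[[me]],
            file.path("results/stats", paste0("games_howell_", me, ".csv")),
            row.names = FALSE)
}

cat("== nodal efficiencies ==\n")
ng <- compare_groups_nodal(as.matrix(nodal_g[, -1]), groups, nodal_g$region)
nl <- compare_groups_nodal(as.matrix(nodal_l[, -1]), groups, nodal_l$region)
write.csv(ng, "results/stats/nodal_global_welch.csv", row.names = FALSE)
write.csv(nl, "results/stats/nodal_local_welch.csv", row.names = FALSE)
cat("regions with FDR-significant nodal global efficiency differences:",
    sum(ng$adjusted_p < 0.05, na.rm = TRUE), "of", nrow(ng), "\n")
cat("regions with FDR-significant nodal local efficiency differences:",
    sum(nl$adjusted_p < 0.05, na.rm = TRUE), "of", nrow(nl), "\n")

cat("== brain-behaviour correlation (patients only) ==\n")
sp <- spearman_scores(auc, meta)
print(sp, digits = 3)
write.csv(sp, "results/stats/spearman_cognition.csv", row.names = FALSE)
cat("written to results/stats/\n")
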