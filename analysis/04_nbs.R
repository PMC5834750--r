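#!/usr/bin/env Rscript
# Stage 4: edge-wise inference with the network-based statistic.
#
# Omnibus one-way ANOVA across the three groups at every edge, components
# of edges surviving p < 0.005, family-wise error control by the
# permutation (10000) null of the maximum component size; post hoc
# one-tailed t contrasts restricted to the omnibus-significant network;
# hub classification (degree > mean + 1 SD) and connection typing.

library(sivdnet)

seed <- 20260904
meta <- read.csv("results/cohort/metadata.csv")
groups <- factor(meta$group, levels = c("NC", "SIVCIND", "SIVaD"))
z <- lapply(meta$subject_id, function(id) {
  as.matrix(read.csv(file.path("results/connectome", paste0(id, ".csv"))))
})
regions <- aal_regions()

omnibus <- nbs_test(z, groups, design = "anova", component_alpha = 0.005,
                    n_perm = 10000, seed = seed)
sig <- significant_edges(omnibus, 0.05)
cat("omnibus NBS:", nrow(sig), "significant edges in",
    length(unique(sig$component)), "component(s)\n")

dir.create("results/nbs", recursive = TRUE, showWarnings = FALSE)
write.csv(data.frame(max_component_size = omnibus$null_distribution),
          "results/nbs/null_distribution.csv", row.names = FALSE)

if (nrow(sig) > 0) {
  sig$region_i <- regions$name[sig$i]
  sig$region_j <- regions$name[sig$j]
  sig$connection_type <- classify_connection(sig$region_i, sig$region_j, regions)
  write.csv(sig, "results/nbs/omnibus_significant_edges.csv", row.names = FALSE)
  print(table(sig$connection_type))

  hubs <- hub_nodes(sig, nrow(regions))
  write.csv(regions[hubs, ], "results/nbs/hubs.csv", row.names = FALSE)
  cat("hubs:", paste(regions$name[hubs], collapse = ", "), "\n")

  posthoc <- posthoc_pairwise(z, groups, significant_edges = sig,
                              component_alpha = 0.005, n_perm = 10000,
                              seed = seed + 1)
  for (nm in names(posthoc)) {
    ps <- significant_edges(posthoc[[nm]], 0.05)
    cat("post hoc", nm, ":", nrow(ps), "decreased connection(s)\n")
    if (nrow(ps) > 0) {
      ps$region_i <- regions$name[ps$i]
      ps$region_j <- regions$name[ps$j]
      ps$connection_type <- classify_connection(ps$region_i, ps$region_j,
                                                regions)
      fname <- paste0("posthoc_", gsub(" > ", "_gt_", nm), ".csv")
      write.csv(ps, file.path("results/nbs", fname), row.names = FALSE)
    }
  }
}
cat("written to results/nbs/\n")
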