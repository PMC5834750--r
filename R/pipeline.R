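#' Read per-subject time-series files from a directory
#'
#' Expects one tab-separated file per subject, named `<subject_id>.tsv`,
#' with a header row of region names matching the region table order.
#' Subjects are returned in metadata order.
#'
#' @param path Directory containing the files.
#' @param metadata Metadata data frame with a `subject_id` column.
#' @param regions Region table, see [aal_regions()].
#' @return Named list of T x N matrices.
#' @export
read_timeseries_dir <- function(path, metadata, regions = aal_regions()) {
  out <- vector("list", nrow(metadata))
  names(out) <- metadata$subject_id
  for (id in metadata$subject_id) {
    f <- file.path(path, paste0(id, ".tsv"))
    if (!file.exists(f)) stop_sivd("missing time-series file: ", f)
    ts <- tryCatch(as.matrix(read.table(f, header = TRUE, sep = "\t",
                                        check.names = FALSE)),
                   error = function(e) stop_sivd("unreadable file ", f, ": ",
                                                 conditionMessage(e)))
    if (ncol(ts) != nrow(regions)) {
      stop_sivd("file ", f, " has ", ncol(ts), " columns; expected ",
                nrow(regions))
    }
    if (!identical(colnames(ts), regions$name)) {
      stop_sivd("header of ", f, " does not match the region table")
    }
    if (!all(is.finite(ts))) stop_sivd("non-finite values in ", f)
    out[[id]] <- ts
  }
  out
}

#' Configuration for a full pipeline run
#'
#' @param s_min,s_max,step Sparsity sweep.
#' @param distance_mode Shortest-path distance transform.
#' @param abs_weights Threshold on absolute weights.
#' @param band_pass `NULL` or `c(low_hz, high_hz)` to filter time series.
#' @param component_alpha,n_perm NBS parameters.
#' @param nbs_alpha Family-wise level for significant components.
#' @param n_rounds,tree_depth Classifier parameters.
#' @param seed Master seed (all stage seeds are derived from it).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(s_min = 0.10, s_max = 0.40, step = 0.01,
                       distance_mode = "reciprocal", abs_weights = FALSE,
                       band_pass = NULL, component_alpha = 0.005,
                       n_perm = 10000, nbs_alpha = 0.05, n_rounds = 100,
                       tree_depth = 1, seed = 1) {
  cfg <- list(s_min = s_min, s_max = s_max, step = step,
              distance_mode = distance_mode, abs_weights = abs_weights,
              band_pass = band_pass, component_alpha = component_alpha,
              n_perm = n_perm, nbs_alpha = nbs_alpha, n_rounds = n_rounds,
              tree_depth = tree_depth, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full connectome analysis pipeline
#'
#' Executes, in order: optional band-pass filtering, Pearson connectivity,
#' Fisher r-to-z, covariate regression (age, gender, education), the
#' sparsity sweep with AUC metric summaries, the omnibus NBS with pairwise
#' post hoc contrasts, group statistics on global and nodal AUC values,
#' brain-behaviour Spearman correlations, and leave-one-out boosted-tree
#' classification. Rerunning with an identical configuration and input
#' reproduces every numeric output.
#'
#' @param timeseries Named list of T x N matrices (see
#'   [read_timeseries_dir()] or [generate_cohort()]).
#' @param metadata Metadata data frame (`subject_id`, `group`, `age`,
#'   `gender`, `education`, scores).
#' @param config A [run_config()].
#' @param regions Region table.
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @return A result bundle (list); see the individual stage functions.
#' @export
run_pipeline <- function(timeseries, metadata, config = run_config(),
                         regions = aal_regions(), out_dir = NULL) {
  if (is.null(metadata) || nrow(metadata) == 0) {
    stop_sivd("pipeline validation: empty metadata")
  }
  if (!all(metadata$subject_id %in% names(timeseries))) {
    stop_sivd("pipeline validation: metadata subjects missing from time series")
  }
  timeseries <- timeseries[metadata$subject_id]
  groups <- droplevels(as.factor(metadata$group))
  seeds <- derive_seeds(config$seed, 4)

  if (!is.null(config$band_pass)) {
    timeseries <- lapply(timeseries, bandpass,
                         low_hz = config$band_pass[1],
                         high_hz = config$band_pass[2])
  }
  z <- lapply(timeseries, function(ts) fisher_z(pearson_connectivity(ts)))
  z <- regress_covariates(z, metadata[, c("age", "gender", "education")])

  metrics <- cohort_metrics(z, config$s_min, config$s_max, config$step,
                            config$distance_mode, config$abs_weights)

  omnibus_nbs <- nbs_test(z, groups, design = "anova",
                          component_alpha = config$component_alpha,
                          n_perm = config$n_perm, seed = seeds[1])
  sig <- significant_edges(omnibus_nbs, config$nbs_alpha)
  posthoc_nbs <- if (nrow(sig) > 0) {
    posthoc_pairwise(z, groups, significant_edges = sig,
                     component_alpha = config$component_alpha,
                     n_perm = config$n_perm, seed = seeds[2])
  } else list()
  hubs <- hub_nodes(sig, nrow(regions))
  conn_type <- if (nrow(sig) > 0) {
    classify_connection(regions$name[sig$i], regions$name[sig$j], regions)
  } else character(0)

  stats_global <- compare_groups(metrics$auc, groups, ks_seed = seeds[3])
  stats_nodal <- list(
    Enodal_glob = compare_groups_nodal(metrics$nodal_glob, groups, metrics$regions),
    Enodal_loc = compare_groups_nodal(metrics$nodal_loc, groups, metrics$regions))
  correlations <- if (all(c("MMSE", "MoCA") %in% names(metadata)) &&
                      any(metadata$group != levels(groups)[1])) {
    spearman_scores(metrics$auc, metadata,
                    patient_groups = setdiff(levels(groups), levels(groups)[1]))
  } else NULL

  cls <- loocv_adaboost(metrics$auc[, c("Cp", "Lp", "Eg", "Eloc")], groups,
                        config$n_rounds, config$tree_depth)
  perclass <- lapply(setNames(nm = levels(groups)), function(g) {
    sensitivity_specificity(cls$confusion, g)
  })

  bundle <- list(
    config = config, config_hash = config_hash(config),
    metrics = metrics, nbs = list(omnibus = omnibus_nbs,
                                  significant = cbind_safe(sig, conn_type),
                                  posthoc = posthoc_nbs, hubs = hubs),
    stats = list(global = stats_global, nodal = stats_nodal,
                 correlations = correlations),
    classification = c(cls, list(per_class = perclass)),
    regions = regions)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

cbind_safe <- function(sig, conn_type) {
  if (nrow(sig) > 0) cbind(sig, connection_type = conn_type) else sig
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$metrics$auc, "auc_metrics.csv")
  nod <- data.frame(region = bundle$metrics$regions,
                    bundle$metrics$nodal_glob, check.names = FALSE)
  wr(nod, "nodal_global_auc.csv")
  wr(bundle$stats$global$omnibus, "group_stats_global.csv")
  wr(bundle$stats$nodal$Enodal_glob, "group_stats_nodal_glob.csv")
  wr(bundle$stats$nodal$Enodal_loc, "group_stats_nodal_loc.csv")
  if (!is.null(bundle$stats$correlations)) {
    wr(bundle$stats$correlations, "correlations.csv")
  }
  sig <- bundle$nbs$significant
  if (nrow(sig) > 0) {
    sig$region_i <- bundle$regions$name[sig$i]
    sig$region_j <- bundle$regions$name[sig$j]
    wr(sig, "nbs_significant_edges.csv")
  }
  wr(data.frame(max_component_size = bundle$nbs$omnibus$null_distribution),
     "nbs_null_distribution.csv")
  wr(as.data.frame.matrix(bundle$classification$confusion), "confusion_matrix.csv")
  manifest <- list(
    package = "sivdnet",
    package_version = as.character(utils::packageVersion("sivdnet")),
    config = unclass(bundle$config), config_hash = bundle$config_hash,
    note = "all region indices are 1-based")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Human-readable summary of a pipeline result bundle
#'
#' @param bundle Result of [run_pipeline()].
#' @return Character vector of summary lines.
#' @export
summarize_report <- function(bundle) {
  lines <- c(paste0("sivdnet pipeline summary (config hash ",
                    bundle$config_hash, ")"))
  auc <- bundle$metrics$auc
  omn <- bundle$stats$global$omnibus
  grp <- bundle$stats$global$posthoc
  groups <- bundle$classification$predictions
  meta_groups <- rownames(bundle$classification$confusion)
  for (me in c("Cp", "Lp", "Eg", "Eloc")) {
    w <- omn[omn$metric == me, ]
    lines <- c(lines, sprintf(
      "AUC(%s): Welch F = %.3f (df %.0f, %.1f), p = %.4g, FDR p = %.4g",
      me, w$welch_F, w$df1, w$df2, w$pvalue, w$adjusted_p))
  }
  sig <- bundle$nbs$significant
  if (nrow(sig) == 0) {
    lines <- c(lines, "NBS: no significant components")
  } else {
    tt <- table(sig$connection_type)
    lines <- c(lines, sprintf(
      "NBS: %d significant edge(s) in %d component(s); connection types: %s",
      nrow(sig), length(unique(sig$component)),
      paste(names(tt), tt, sep = "=", collapse = ", ")))
    if (length(bundle$nbs$hubs) > 0) {
      lines <- c(lines, paste0("hubs: ",
                               paste(bundle$regions$name[bundle$nbs$hubs],
                                     collapse = ", ")))
    }
    for (nm in names(bundle$nbs$posthoc)) {
      ps <- significant_edges(bundle$nbs$posthoc[[nm]], bundle$config$nbs_alpha)
      lines <- c(lines, sprintf("post hoc %s: %d decreased connection(s)",
                                nm, nrow(ps)))
    }
  }
  if (!is.null(bundle$stats$correlations)) {
    co <- bundle$stats$correlations
    for (r in seq_len(nrow(co))) {
      lines <- c(lines, sprintf(
        "Spearman %s ~ %s: rho = %.3f, FDR p = %.4g",
        co$metric[r], co$score[r], co$rho[r], co$adjusted_p[r]))
    }
  }
  lines <- c(lines, sprintf("LOOCV accuracy: %.3f",
                            bundle$classification$accuracy))
  lines
}
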