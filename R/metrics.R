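#' Weighted graph container for the network metrics
#'
#' Wraps a dense symmetric non-negative weight matrix (0 = absent edge)
#' with a flag recording whether the weights have been scaled by their
#' mean, as the weighted metric formulas require.
#'
#' @param x A `sparsity_graph` (from [threshold_sparsity()]) or a dense
#'   symmetric weight matrix.
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(x) {
  if (inherits(x, "weighted_graph")) return(x)
  if (inherits(x, "sparsity_graph")) {
    w <- matrix(0, x$n_nodes, x$n_nodes)
    ij <- cbind(x$edges$i, x$edges$j)
    w[ij] <- x$edges$w
    w[ij[, 2:1, drop = FALSE]] <- x$edges$w
    if (!is.null(x$region_names)) dimnames(w) <- list(x$region_names, x$region_names)
  } else {
    w <- as.matrix(x)
    if (nrow(w) != ncol(w)) stop_sivd("weight matrix must be square")
    if (any(w < 0)) stop_sivd("edge weights must be non-negative")
    diag(w) <- 0
  }
  structure(list(n_nodes = nrow(w), w = w, scaled = FALSE),
            class = "weighted_graph")
}

#' Scale edge weights by their mean
#'
#' Divides every retained weight by the mean retained weight, so that the
#' mean edge weight is 1. This controls each subject's network cost so
#' that metric differences reflect the weight pattern, not its overall
#' level. Idempotent.
#'
#' @param g A [weighted_graph()].
#' @return The graph with `scaled = TRUE`.
#' @export
scale_weights <- function(g) {
  g <- weighted_graph(g)
  pos <- g$w[upper.tri(g$w)] > 0
  if (!any(pos)) stop_sivd("cannot scale a graph with no edges")
  mw <- mean(g$w[upper.tri(g$w)][pos])
  g$w <- g$w / mw
  g$scaled <- TRUE
  g
}

require_scaled <- function(g) {
  if (!inherits(g, "weighted_graph") || !isTRUE(g$scaled)) {
    stop_sivd("this metric requires a scaled weighted_graph; call scale_weights() first")
  }
  g
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per node, sums the cube-root triple product of scaled weights over
#' unordered neighbour pairs that are themselves connected, normalised by
#' `2 / (k_i (k_i - 1))`; nodes of degree < 2 get 0. The graph-level value
#' is the mean over all nodes.
#'
#' @param g A scaled [weighted_graph()].
#' @return List with `Cp` (mean) and `Ci` (per-node vector).
#' @export
clustering_coefficient <- function(g) {
  g <- require_scaled(g)
  ci <- onnela_clustering_ci(g$w)
  list(Cp = mean(ci), Ci = as.numeric(ci))
}

#' All-pairs shortest path lengths
#'
#' Edge distances are reciprocal scaled weights by default (strong edges
#' are short), or the literal weights in `"literal"` mode. Disconnected
#' pairs are `Inf`; the diagonal is 0.
#'
#' @param g A [weighted_graph()] (scaled for the standard pipeline).
#' @param distance_mode `"reciprocal"` or `"literal"`.
#' @return N x N matrix of shortest path lengths.
#' @export
shortest_path_lengths <- function(g, distance_mode = c("reciprocal", "literal")) {
  distance_mode <- match.arg(distance_mode)
  g <- weighted_graph(g)
  d <- ifelse(g$w > 0, if (distance_mode == "reciprocal") 1 / g$w else g$w, Inf)
  diag(d) <- 0
  fw_apsp(d)
}

#' Characteristic path length
#'
#' Mean shortest path length over connected ordered node pairs. If any
#' pair is disconnected, the mean is taken over the connected pairs only
#' and a disconnection flag is raised.
#'
#' @param lengths Matrix from [shortest_path_lengths()].
#' @return List with `Lp` and logical `disconnected`.
#' @export
characteristic_path_length <- function(lengths) {
  off <- lengths[row(lengths) != col(lengths)]
  finite <- is.finite(off)
  if (!any(finite)) stop_sivd("graph has no edges: path length undefined")
  list(Lp = mean(off[finite]), disconnected = !all(finite))
}

#' Global efficiency and nodal global efficiency
#'
#' `E_nodal_glob(i) = mean over j != i of 1 / L_ij` (0 for disconnected
#' pairs); `Eg` is the mean nodal value.
#'
#' @param lengths Matrix from [shortest_path_lengths()].
#' @return List with `Eg` and `Enodal_glob`.
#' @export
global_efficiency <- function(lengths) {
  inv <- ifelse(is.finite(lengths) & lengths > 0, 1 / lengths, 0)
  diag(inv) <- 0
  nodal <- rowSums(inv) / (nrow(lengths) - 1)
  list(Eg = mean(nodal), Enodal_glob = as.numeric(nodal))
}

#' Local efficiency and nodal local efficiency
#'
#' `E_nodal_loc(i)` is the global efficiency of the subgraph induced on
#' the neighbours of node i (node i removed), with the original scaled
#' weights and the subgraph's own node count; nodes with fewer than two
#' neighbours get 0. `Eloc` is the mean over all nodes.
#'
#' @param g A scaled [weighted_graph()].
#' @param distance_mode `"reciprocal"` or `"literal"`.
#' @return List with `Eloc` and `Enodal_loc`.
#' @export
local_efficiency <- function(g, distance_mode = c("reciprocal", "literal")) {
  distance_mode <- match.arg(distance_mode)
  g <- require_scaled(g)
  nodal <- nodal_local_efficiency(g$w, distance_mode == "reciprocal")
  list(Eloc = mean(nodal), Enodal_loc = as.numeric(nodal))
}

#' Area under a metric curve over the sparsity sweep
#'
#' Trapezoidal integration of metric values over strictly increasing
#' sparsity thresholds; exact for linear curves.
#'
#' @param thresholds Strictly increasing sparsity values (>= 2).
#' @param values Metric values, same length.
#' @return The integral as a scalar.
#' @export
metric_auc <- function(thresholds, values) {
  if (length(thresholds) < 2) stop_sivd("AUC needs at least two thresholds")
  if (length(values) != length(thresholds)) stop_sivd("length mismatch")
  if (any(diff(thresholds) <= 0)) {
    stop_sivd("thresholds must be strictly increasing")
  }
  sum(diff(thresholds) * (head(values, -1) + values[-1]) / 2)
}

#' Metric curves and AUC summary for one subject's sparsity sweep
#'
#' Scales each thresholded graph, computes Cp, Lp, Eg, Eloc and the two
#' nodal efficiency vectors at every threshold, and integrates each curve
#' over the sweep.
#'
#' @param sweep List of `sparsity_graph` objects from [sparsity_sweep()].
#' @param distance_mode `"reciprocal"` or `"literal"`.
#' @return List with `curves` (data.frame threshold, Cp, Lp, Eg, Eloc,
#'   disconnected), `auc` (named vector), `nodal_auc` (data.frame region,
#'   Enodal_glob, Enodal_loc).
#' @export
subject_metrics <- function(sweep, distance_mode = c("reciprocal", "literal")) {
  distance_mode <- match.arg(distance_mode)
  if (length(sweep) == 0) stop_sivd("empty sparsity sweep")
  svals <- vapply(sweep, function(x) x$sparsity, numeric(1))
  n <- sweep[[1]]$n_nodes
  region_names <- sweep[[1]]$region_names
  if (is.null(region_names)) region_names <- paste0("R", seq_len(n))
  k <- length(sweep)
  cp <- lp <- eg <- eloc <- numeric(k)
  disc <- logical(k)
  ng <- nl <- matrix(0, n, k)
  for (t in seq_len(k)) {
    g <- scale_weights(weighted_graph(sweep[[t]]))
    cl <- clustering_coefficient(g)
    lengths <- shortest_path_lengths(g, distance_mode)
    path <- characteristic_path_length(lengths)
    glob <- global_efficiency(lengths)
    loc <- local_efficiency(g, distance_mode)
    cp[t] <- cl$Cp; lp[t] <- path$Lp; disc[t] <- path$disconnected
    eg[t] <- glob$Eg; eloc[t] <- loc$Eloc
    ng[, t] <- glob$Enodal_glob; nl[, t] <- loc$Enodal_loc
  }
  list(
    curves = data.frame(threshold = svals, Cp = cp, Lp = lp, Eg = eg,
                        Eloc = eloc, disconnected = disc),
    auc = c(Cp = metric_auc(svals, cp), Lp = metric_auc(svals, lp),
            Eg = metric_auc(svals, eg), Eloc = metric_auc(svals, eloc)),
    nodal_auc = data.frame(
      region = region_names,
      Enodal_glob = apply(ng, 1, function(v) metric_auc(svals, v)),
      Enodal_loc = apply(nl, 1, function(v) metric_auc(svals, v)))
  )
}

#' AUC metric table for a whole cohort
#'
#' Runs the sparsity sweep and [subject_metrics()] for every subject's
#' connectivity matrix.
#'
#' @param matrices Named list of N x N weight matrices.
#' @param s_min,s_max,step Sweep parameters.
#' @param distance_mode Passed to [subject_metrics()].
#' @param abs_mode Passed to [threshold_sparsity()].
#' @return List with `auc` (data.frame subject_id, Cp, Lp, Eg, Eloc),
#'   `nodal_glob` and `nodal_loc` (region x subject matrices of nodal
#'   AUCs), and `disconnected` (any disconnected threshold per subject).
#' @export
cohort_metrics <- function(matrices, s_min = 0.10, s_max = 0.40, step = 0.01,
                           distance_mode = "reciprocal", abs_mode = FALSE) {
  ids <- names(matrices)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(matrices))
  res <- lapply(matrices, function(m) {
    subject_metrics(sparsity_sweep(m, s_min, s_max, step, abs_mode),
                    distance_mode)
  })
  auc <- do.call(rbind, lapply(res, function(r) as.data.frame(as.list(r$auc))))
  auc <- cbind(subject_id = ids, auc)
  rownames(auc) <- NULL
  list(
    auc = auc,
    nodal_glob = vapply(res, function(r) r$nodal_auc$Enodal_glob,
                        numeric(nrow(res[[1]]$nodal_auc))),
    nodal_loc = vapply(res, function(r) r$nodal_auc$Enodal_loc,
                       numeric(nrow(res[[1]]$nodal_auc))),
    regions = res[[1]]$nodal_auc$region,
    disconnected = vapply(res, function(r) any(r$curves$disconnected), logical(1))
  )
}
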