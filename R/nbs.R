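#' Edge-wise one-way ANOVA across groups
#'
#' Classical equal-variance one-way ANOVA F statistic and p-value for
#' every edge of the connectivity matrices.
#'
#' @param matrices List of N x N symmetric weight matrices, one per subject.
#' @param groups Factor of group labels, aligned with `matrices`.
#' @return List with `statistic` and `pvalue` (N x N symmetric matrices,
#'   zero diagonal), `df` (numerator, denominator), `contrast`.
#' @export
edgewise_anova <- function(matrices, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop_sivd("need at least two groups")
  if (any(table(groups) < 2)) stop_sivd("every group needs at least two subjects")
  y <- edge_matrix(matrices)
  f <- anova_f_vec(y, groups)
  n <- nrow(matrices[[1]])
  k <- nlevels(groups)
  df <- c(k - 1, length(groups) - k)
  p <- pf(f$F, df[1], df[2], lower.tail = FALSE)
  p[f$sst == 0] <- 1
  list(statistic = matrix_from_edges(f$F, n),
       pvalue = matrix_from_edges(p, n),
       df = df, contrast = paste(levels(groups), collapse = " vs "))
}

# vectorised one-way ANOVA F over columns of y (subjects x edges)
anova_f_vec <- function(y, groups) {
  n <- nrow(y)
  k <- nlevels(groups)
  ng <- as.numeric(table(groups))
  gs <- rowsum(y, groups)                       # k x edges group sums
  tot <- colSums(gs)
  ssb <- colSums(gs^2 / ng) - tot^2 / n
  sst <- colSums(y^2) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  list(F = f, sst = sst)
}

#' Edge-wise two-sample t-test
#'
#' Pooled-variance two-sample t statistic per edge, with a one-tailed
#' p-value in the stated direction (default: the first-listed group
#' greater, matching the convention of reporting connections that are
#' decreased in the more impaired group).
#'
#' @param matrices List of symmetric weight matrices.
#' @param groups Group labels aligned with `matrices`.
#' @param group_a,group_b The two groups to compare (`group_a > group_b`
#'   is the default alternative).
#' @param tail `"greater"` (A > B), `"less"` (A < B), or `"two.sided"`.
#' @return List with `statistic`, `pvalue`, `df`, `contrast`.
#' @export
edgewise_ttest <- function(matrices, groups, group_a, group_b,
                           tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  groups <- as.character(groups)
  sel <- groups %in% c(group_a, group_b)
  if (sum(groups == group_a) < 2 || sum(groups == group_b) < 2) {
    stop_sivd("both groups need at least two subjects")
  }
  y <- edge_matrix(matrices[sel])
  g <- factor(groups[sel], levels = c(group_a, group_b))
  tt <- ttest_vec(y, g)
  p <- switch(tail,
              greater = pt(tt$t, tt$df, lower.tail = FALSE),
              less = pt(tt$t, tt$df, lower.tail = TRUE),
              two.sided = 2 * pt(abs(tt$t), tt$df, lower.tail = FALSE))
  zero_var <- tt$sp2 == 0
  if (any(zero_var & tt$t == 0)) {
    p[zero_var & tt$t == 0] <- if (tail == "two.sided") 1 else 0.5
  }
  if (any(zero_var & is.na(tt$t))) {
    warning("zero pooled variance on ", sum(zero_var & is.na(tt$t)), " edge(s)")
    p[zero_var & is.na(tt$t)] <- 1
  }
  n <- nrow(matrices[[1]])
  list(statistic = matrix_from_edges(tt$t, n),
       pvalue = matrix_from_edges(p, n),
       df = tt$df, contrast = paste(group_a, ">", group_b))
}

# vectorised pooled-variance two-sample t over columns of y
ttest_vec <- function(y, g) {
  na <- sum(g == levels(g)[1]); nb <- sum(g == levels(g)[2])
  ya <- y[g == levels(g)[1], , drop = FALSE]
  yb <- y[g == levels(g)[2], , drop = FALSE]
  ma <- colMeans(ya); mb <- colMeans(yb)
  va <- (colSums(ya^2) - na * ma^2) / (na - 1)
  vb <- (colSums(yb^2) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0 & (ma == mb)] <- 0
  list(t = t, df = na + nb - 2, sp2 = sp2)
}

#' Connected components of supra-threshold edges
#'
#' Keeps edges with `p < alpha` and returns the connected components of
#' the resulting undirected graph; component size is the edge count.
#'
#' @param stat_map List with a `pvalue` matrix (as from
#'   [edgewise_anova()] / [edgewise_ttest()]).
#' @param alpha Uncorrected edge-level threshold in (0, 1).
#' @return List of components, each a list with `edges` (data.frame
#'   `i`, `j`) and `size`.
#' @export
supra_threshold_components <- function(stat_map, alpha = 0.005) {
  if (!(alpha > 0 && alpha < 1)) stop_sivd("alpha must lie in (0, 1)")
  p <- stat_map$pvalue
  n <- nrow(p)
  pairs <- ut_pairs(n)
  keep <- p[upper.tri(p)] < alpha
  edge_components(pairs[keep, , drop = FALSE], n)
}

# component decomposition of an edge list via igraph
edge_components <- function(pairs, n_nodes) {
  if (nrow(pairs) == 0) return(list())
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[pairs[, 1]]
  split_idx <- split(seq_len(nrow(pairs)), comp_of_edge)
  out <- lapply(split_idx, function(idx) {
    list(edges = data.frame(i = pairs[idx, 1], j = pairs[idx, 2]),
         size = length(idx))
  })
  out[order(-vapply(out, function(x) x$size, numeric(1)))]
}

# max component edge count of a supra-threshold edge set (fast inner loop)
max_component_size <- function(pairs, n_nodes) {
  if (nrow(pairs) == 0) return(0L)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[pairs[, 1]]))
}

#' Network-based statistic test
#'
#' Computes supra-threshold components of the observed group contrast and
#' corrects their sizes for family-wise error against the permutation null
#' distribution of the maximum component size: group labels are shuffled
#' (preserving group sizes), the edge statistics recomputed, and the
#' maximal supra-threshold component size recorded for each permutation.
#' The corrected p-value of an observed component of size M is the
#' proportion of permutations whose maximum size is `>= M` (default;
#' `tie_mode = "gt"` uses the strict inequality).
#'
#' @param matrices List of symmetric weight matrices.
#' @param groups Group labels.
#' @param design `"anova"` (omnibus F) or `"ttest"`.
#' @param contrast For `"ttest"`: `c(group_a, group_b)`.
#' @param tail Tail for the t design.
#' @param component_alpha Uncorrected edge threshold (default 0.005).
#' @param n_perm Number of permutations (>= 100; the reference analysis
#'   uses 10000).
#' @param seed Seed for the permutation stream.
#' @param mask Optional logical N x N matrix restricting the tested edges.
#' @param tie_mode `">="` convention (`"geq"`, default) or strict `"gt"`.
#' @return Object of class `nbs_result`: list with `components` (each with
#'   `edges`, `size`, `corrected_p`), `null_distribution`, `n_perm`,
#'   `component_alpha`, `design`, `contrast`, `seed`.
#' @export
nbs_test <- function(matrices, groups, design = c("anova", "ttest"),
                     contrast = NULL, tail = "greater",
                     component_alpha = 0.005, n_perm = 10000, seed = 1,
                     mask = NULL, tie_mode = c("geq", "gt")) {
  design <- match.arg(design)
  tie_mode <- match.arg(tie_mode)
  if (n_perm < 100) stop_sivd("need at least 100 permutations")
  groups <- as.factor(groups)
  n_nodes <- nrow(matrices[[1]])
  pairs <- ut_pairs(n_nodes)
  y <- edge_matrix(matrices)
  if (!is.null(mask)) {
    keep_edge <- mask[upper.tri(mask)]
    pairs <- pairs[keep_edge, , drop = FALSE]
    y <- y[, keep_edge, drop = FALSE]
    if (ncol(y) == 0) {
      warning("empty edge mask: no edges to test")
      return(structure(list(components = list(), null_distribution = integer(0),
                            n_perm = n_perm, component_alpha = component_alpha,
                            design = design, contrast = contrast, seed = seed),
                       class = "nbs_result"))
    }
  }
  if (design == "anova") {
    groups <- droplevels(groups)
    k <- nlevels(groups)
    if (k < 2 || any(table(groups) < 2)) stop_sivd("invalid group structure")
    crit <- qf(1 - component_alpha, k - 1, length(groups) - k)
    stat_fun <- function(lab) anova_f_vec(y, lab)$F
    lab0 <- groups
  } else {
    if (is.null(contrast) || length(contrast) != 2) {
      stop_sivd("ttest design needs contrast = c(group_a, group_b)")
    }
    sel <- as.character(groups) %in% contrast
    y <- y[sel, , drop = FALSE]
    lab0 <- factor(as.character(groups)[sel], levels = contrast)
    if (any(table(lab0) < 2)) stop_sivd("both groups need >= 2 subjects")
    dfree <- length(lab0) - 2
    crit <- switch(tail,
                   greater = qt(1 - component_alpha, dfree),
                   less = qt(component_alpha, dfree),
                   two.sided = qt(1 - component_alpha / 2, dfree))
    stat_fun <- function(lab) ttest_vec(y, lab)$t
  }
  exceeds <- function(stat) {
    if (design == "ttest" && tail == "less") stat < crit
    else if (design == "ttest" && tail == "two.sided") abs(stat) > crit
    else stat > crit
  }
  obs_stat <- stat_fun(lab0)
  obs_keep <- which(exceeds(obs_stat))
  comps <- edge_components(pairs[obs_keep, , drop = FALSE], n_nodes)

  set.seed(seed)
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    lab <- lab0[sample.int(length(lab0))]
    keep <- exceeds(stat_fun(lab))
    null_max[b] <- max_component_size(pairs[keep, , drop = FALSE], n_nodes)
  }
  for (ci in seq_along(comps)) {
    m <- comps[[ci]]$size
    hits <- if (tie_mode == "geq") sum(null_max >= m) else sum(null_max > m)
    comps[[ci]]$corrected_p <- hits / n_perm
  }
  structure(list(components = comps, null_distribution = null_max,
                 n_perm = n_perm, component_alpha = component_alpha,
                 design = design, contrast = contrast, seed = seed),
            class = "nbs_result")
}

#' Post hoc pairwise NBS within the omnibus-significant network
#'
#' Re-runs the network-based statistic for every pairwise contrast with a
#' one-tailed t design, restricted (by default) to the edge mask of the
#' omnibus-significant components.
#'
#' @param matrices,groups As in [nbs_test()].
#' @param significant_edges Data frame `i`, `j` of omnibus-significant
#'   edges, or `NULL` for unrestricted post hoc tests.
#' @param contrasts List of `c(group_a, group_b)` pairs; default: all
#'   ordered "earlier group > later group" pairs of the group levels.
#' @param component_alpha,n_perm,seed,tail As in [nbs_test()].
#' @return Named list of `nbs_result` objects, one per contrast.
#' @export
posthoc_pairwise <- function(matrices, groups, significant_edges = NULL,
                             contrasts = NULL, component_alpha = 0.005,
                             n_perm = 10000, seed = 1, tail = "greater") {
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  if (is.null(contrasts)) {
    contrasts <- list()
    for (a in seq_along(lev)) for (b in seq_along(lev)) {
      if (a < b) contrasts[[length(contrasts) + 1]] <- c(lev[a], lev[b])
    }
  }
  n_nodes <- nrow(matrices[[1]])
  mask <- NULL
  if (!is.null(significant_edges)) {
    if (nrow(significant_edges) == 0) {
      warning("empty significant edge set; no post hoc tests run")
      return(setNames(list(), character(0)))
    }
    mask <- matrix(FALSE, n_nodes, n_nodes)
    ij <- cbind(significant_edges$i, significant_edges$j)
    mask[ij] <- TRUE
    mask[ij[, 2:1, drop = FALSE]] <- TRUE
  }
  seeds <- derive_seeds(seed, length(contrasts))
  out <- lapply(seq_along(contrasts), function(ci) {
    nbs_test(matrices, groups, design = "ttest", contrast = contrasts[[ci]],
             tail = tail, component_alpha = component_alpha, n_perm = n_perm,
             seed = seeds[ci], mask = mask)
  })
  names(out) <- vapply(contrasts, function(ct) paste(ct[1], ">", ct[2]), "")
  out
}

#' Hub nodes of a significant-difference network
#'
#' Degree is computed over the significant edges with all `n_nodes` nodes
#' included (zero degrees count); hubs are nodes whose degree exceeds the
#' mean by strictly more than one standard deviation.
#'
#' @param significant_edges Data frame with columns `i`, `j`.
#' @param n_nodes Total number of nodes.
#' @return Integer vector of hub node indices (possibly empty).
#' @export
hub_nodes <- function(significant_edges, n_nodes) {
  deg <- numeric(n_nodes)
  if (!is.null(significant_edges) && nrow(significant_edges) > 0) {
    tab <- table(factor(c(significant_edges$i, significant_edges$j),
                        levels = seq_len(n_nodes)))
    deg <- as.numeric(tab)
  }
  which(deg > mean(deg) + sd(deg))
}

#' Collect the edges of significant NBS components
#'
#' @param result An `nbs_result`.
#' @param alpha Family-wise significance level on the corrected p-values.
#' @return Data frame `i`, `j`, `component`, `corrected_p` (possibly empty).
#' @export
significant_edges <- function(result, alpha = 0.05) {
  rows <- list()
  for (ci in seq_along(result$components)) {
    comp <- result$components[[ci]]
    if (comp$corrected_p < alpha) {
      rows[[length(rows) + 1]] <- cbind(comp$edges, component = ci,
                                        corrected_p = comp$corrected_p)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(i = integer(0), j = integer(0), component = integer(0),
                      corrected_p = numeric(0)))
  }
  do.call(rbind, rows)
}
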