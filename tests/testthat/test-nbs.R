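make_edge_mats <- function(values_by_subject, n_nodes) {
  lapply(values_by_subject, function(v) {
    m <- matrix(0, n_nodes, n_nodes)
    m[upper.tri(m)] <- v
    m + t(m)
  })
}

test_that("edge-wise ANOVA matches the from-definition oracle", {
  set.seed(21)
  n_nodes <- 4
  n_edges <- 6
  groups <- factor(rep(c("a", "b", "c"), each = 5))
  vals <- lapply(1:15, function(s) rnorm(n_edges))
  mats <- make_edge_mats(vals, n_nodes)
  res <- edgewise_anova(mats, groups)
  y <- do.call(rbind, vals)
  for (e in 1:n_edges) {
    ref <- oracle_anova_f(y[, e], groups)
    ij <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)[e, ]
    expect_equal(res$statistic[ij[1], ij[2]], ref$F, tolerance = 1e-10)
    expect_equal(res$pvalue[ij[1], ij[2]], ref$p, tolerance = 1e-10)
  }
  # identical groups: F = 0, p = 1
  same <- make_edge_mats(rep(list(c(1, 2, 3, 4, 5, 6)), 6), n_nodes)
  r0 <- edgewise_anova(same, factor(rep(c("a", "b"), each = 3)))
  expect_equal(r0$statistic[1, 2], 0)
  expect_equal(r0$pvalue[1, 2], 1)
  expect_error(edgewise_anova(mats[1:3], factor(c("a", "a", "b"))), "two subjects")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(22)
  groups <- factor(rep(c("a", "b"), each = 8))
  vals <- lapply(1:16, function(s) rnorm(3))
  mats <- make_edge_mats(vals, 3)
  fa <- edgewise_anova(mats, groups)
  tt <- edgewise_ttest(mats, groups, "a", "b", tail = "two.sided")
  expect_equal(fa$statistic[upper.tri(fa$statistic)],
               tt$statistic[upper.tri(tt$statistic)]^2, tolerance = 1e-10)
  expect_equal(fa$pvalue[upper.tri(fa$pvalue)],
               tt$pvalue[upper.tri(tt$pvalue)], tolerance = 1e-10)
})

test_that("edge-wise t-test tails behave correctly", {
  set.seed(23)
  groups <- factor(rep(c("a", "b"), each = 10))
  base <- lapply(1:20, function(s) rnorm(3))
  mats <- make_edge_mats(base, 3)
  g <- edgewise_ttest(mats, groups, "a", "b", tail = "greater")
  l <- edgewise_ttest(mats, groups, "a", "b", tail = "less")
  expect_equal(g$pvalue[1, 2], 1 - l$pvalue[1, 2], tolerance = 1e-12)
  # identical groups: t = 0, one-tailed p = 0.5
  same <- make_edge_mats(rep(list(c(1, 2, 3)), 20), 3)
  r <- suppressWarnings(edgewise_ttest(same, groups, "a", "b"))
  expect_equal(r$statistic[1, 2], 0)
  expect_equal(r$pvalue[1, 2], 0.5)
  # a 10-sigma shift is detected
  shifted <- make_edge_mats(c(lapply(1:10, function(s) rnorm(3) + 10),
                              lapply(1:10, function(s) rnorm(3))), 3)
  rs <- edgewise_ttest(shifted, groups, "a", "b")
  expect_lt(rs$pvalue[1, 2], 1e-6)
})

test_that("supra-threshold components match hand-checkable cases", {
  n <- 6
  p <- matrix(1, n, n)
  set_p <- function(p, i, j, v) { p[i, j] <- p[j, i] <- v; p }
  p <- set_p(p, 1, 2, 0.001); p <- set_p(p, 2, 3, 0.001)
  p <- set_p(p, 4, 5, 0.001)
  comps <- supra_threshold_components(list(pvalue = p), alpha = 0.005)
  expect_length(comps, 2)
  expect_equal(unname(vapply(comps, function(c) c$size, numeric(1))),
               c(2, 1))
  # no survivors
  expect_length(supra_threshold_components(list(pvalue = matrix(1, 3, 3)), 0.005), 0)
  # complete K5: one component with 10 edges
  p5 <- matrix(1e-5, 5, 5)
  comps5 <- supra_threshold_components(list(pvalue = p5), 0.005)
  expect_length(comps5, 1)
  expect_equal(comps5[[1]]$size, 10)
  expect_error(supra_threshold_components(list(pvalue = p5), 1.2), "alpha")
})

test_that("component finding agrees with a union-find oracle", {
  set.seed(24)
  for (rep in 1:25) {
    n <- 30
    n_e <- sample(5:40, 1)
    pairs <- t(replicate(n_e, sort(sample(n, 2))))
    pairs <- unique(pairs)
    p <- matrix(1, n, n)
    p[pairs] <- 1e-4
    p[pairs[, 2:1]] <- 1e-4
    comps <- supra_threshold_components(list(pvalue = p), 0.005)
    sizes <- sort(unname(vapply(comps, function(c) c$size, numeric(1))),
                  decreasing = TRUE)
    expect_equal(sizes, as.numeric(oracle_components(pairs, n)))
  }
})

test_that("NBS corrected p-values are valid proportions and deterministic", {
  set.seed(25)
  n_nodes <- 20
  groups <- factor(rep(c("a", "b"), each = 10))
  planted <- chain_pairs(1:8)
  mats <- make_planted_matrices(n_nodes, 10, 10, planted, effect = 2.5, seed = 3)
  res <- nbs_test(mats, groups, design = "ttest", contrast = c("b", "a"),
                  n_perm = 200, seed = 99)
  expect_length(res$null_distribution, 200)
  expect_gt(length(res$components), 0)
  ps <- vapply(res$components, function(c) c$corrected_p, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  # corrected p is an integer multiple of 1/n_perm
  expect_equal(ps * 200, round(ps * 200), tolerance = 1e-12)
  # determinism
  res2 <- nbs_test(mats, groups, design = "ttest", contrast = c("b", "a"),
                   n_perm = 200, seed = 99)
  expect_identical(res$null_distribution, res2$null_distribution)
  expect_identical(significant_edges(res), significant_edges(res2))
  # strict tie mode gives corrected p no larger than the >= convention
  res3 <- nbs_test(mats, groups, design = "ttest", contrast = c("b", "a"),
                   n_perm = 200, seed = 99, tie_mode = "gt")
  expect_true(all(vapply(res3$components, function(c) c$corrected_p, numeric(1))
                  <= ps))
  expect_error(nbs_test(mats, groups, n_perm = 50), "100")
})

test_that("NBS recovers a planted component and localises it", {
  planted <- chain_pairs(1:11)  # 10 connected edges
  mats <- make_planted_matrices(30, 20, 20, planted, effect = 1.5, seed = 7)
  groups <- factor(rep(c("ctrl", "pat"), each = 20))
  res <- nbs_test(mats, groups, design = "ttest", contrast = c("pat", "ctrl"),
                  n_perm = 500, seed = 1)
  sig <- significant_edges(res, 0.05)
  expect_gt(nrow(sig), 0)
  found <- paste(sig$i, sig$j)
  truth <- paste(planted[, 1], planted[, 2])
  expect_gte(mean(truth %in% found), 0.8)
})

test_that("post hoc contrasts respect the omnibus mask", {
  planted <- chain_pairs(1:9)
  mats <- make_planted_matrices(25, 15, 15, planted, effect = 2, seed = 5)
  groups <- factor(rep(c("a", "b"), each = 15))
  mask_edges <- data.frame(i = planted[, 1], j = planted[, 2])
  out <- posthoc_pairwise(mats, groups, significant_edges = mask_edges,
                          contrasts = list(c("b", "a")), n_perm = 200, seed = 2)
  expect_named(out, "b > a")
  sig <- significant_edges(out[["b > a"]])
  key <- paste(sig$i, sig$j)
  expect_true(all(key %in% paste(mask_edges$i, mask_edges$j)))
  # empty mask warns and returns nothing
  expect_warning(
    empty <- posthoc_pairwise(mats, groups,
                              significant_edges = data.frame(i = integer(0),
                                                             j = integer(0)),
                              n_perm = 200),
    "empty")
  expect_length(empty, 0)
})

test_that("hub detection follows the mean + 1 SD rule over all nodes", {
  # all degrees equal: no hubs
  ring <- data.frame(i = 1:5, j = c(2:5, 1))
  expect_length(hub_nodes(ring, 5), 0)
  # two high-degree nodes among 90
  edges <- data.frame(i = c(rep(1, 5), rep(2, 6)), j = c(3:7, 8:13))
  hubs <- hub_nodes(edges, 90)
  expect_true(all(c(1, 2) %in% hubs))
  expect_false(any(3:13 %in% hubs))
  # star on 10 of 90 nodes: centre only
  star <- data.frame(i = rep(1, 9), j = 2:10)
  expect_equal(hub_nodes(star, 90), 1)
  expect_length(hub_nodes(data.frame(i = integer(0), j = integer(0)), 90), 0)
})

test_that("connection types come from the hemisphere labels", {
  reg <- aal_regions()
  expect_equal(classify_connection("Precentral_L", "Precuneus_L", reg),
               "left_intra")
  expect_equal(classify_connection("Precentral_L", "Precentral_R", reg), "inter")
  expect_equal(classify_connection("Insula_R", "Putamen_R", reg), "right_intra")
  expect_error(classify_connection("Nonexistent_L", "Precentral_R", reg),
               "unknown region")
})
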