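test_that("Lilliefors KS statistic matches nortest and calibrates roughly", {
  skip_if_not_installed("nortest")
  set.seed(31)
  x <- rnorm(50)
  ours <- ks_normality(x, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_error(ks_normality(c(1, 2, 3)), "four")
  expect_error(ks_normality(rep(2, 10)), "constant")
  # clearly non-normal data are detected
  set.seed(32)
  expect_lt(ks_normality(rexp(100), seed = 2)$pvalue, 0.05)
  # normal data are usually not rejected
  set.seed(33)
  rejections <- sum(vapply(1:30, function(r) {
    ks_normality(rnorm(50), seed = r)$pvalue < 0.05
  }, logical(1)))
  expect_lte(rejections, 5)
})

test_that("Levene test matches the from-definition W", {
  vals <- c(1, 2, 3, 10, 12, 14)
  grp <- factor(rep(c("a", "b"), each = 3))
  ours <- levene_test(vals, grp)
  expect_equal(ours$statistic, oracle_levene_w(vals, grp), tolerance = 1e-12)
  skip_if_not_installed("car")
  ref <- car::leveneTest(vals ~ grp, center = mean)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$pvalue, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # unequal variances are detected
  set.seed(34)
  detected <- sum(vapply(1:20, function(r) {
    v <- c(rnorm(30, sd = 1), rnorm(30, sd = 5))
    levene_test(v, factor(rep(c("a", "b"), each = 30)))$pvalue < 0.01
  }, logical(1)))
  expect_gte(detected, 19)
  expect_error(levene_test(1:3, factor(c("a", "a", "b"))), "2 observations")
})

test_that("Welch ANOVA matches its oracle and the squared Welch t", {
  vals <- c(5.1, 4.8, 5.6, 6.2, 5.9, 7.7, 8.9, 8.1, 7.4, 6.5, 2.2, 3.3, 2.8, 4.1)
  grp <- factor(rep(c("a", "b", "c"), c(5, 5, 4)))
  ours <- welch_anova(vals, grp)
  ref <- oracle_welch_f(vals, grp)
  expect_equal(ours$statistic, ref$F, tolerance = 1e-10)
  expect_equal(ours$df[2], ref$df2, tolerance = 1e-10)
  expect_equal(ours$pvalue, ref$p, tolerance = 1e-10)
  # two groups: F equals squared Welch t
  a <- c(1.2, 3.1, 2.4, 4.4, 2.2); b <- c(5.5, 7.1, 6.3, 8.0)
  two <- welch_anova(c(a, b), factor(rep(c("a", "b"), c(5, 4))))
  wt <- t.test(a, b)
  expect_equal(two$statistic, unname(wt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$pvalue, wt$p.value, tolerance = 1e-10)
  expect_error(welch_anova(c(1, 1, 2, 3), factor(c("a", "a", "b", "b"))),
               "zero variance")
})

test_that("Games-Howell matches its oracle and the two-group Welch t", {
  set.seed(35)
  vals <- c(rnorm(8, 0, 1), rnorm(9, 1, 2), rnorm(7, 3, 0.5))
  grp <- factor(rep(c("a", "b", "c"), c(8, 9, 7)))
  gh <- games_howell(vals, grp)
  expect_equal(nrow(gh), 3)
  ref <- oracle_games_howell_pair(vals[grp == "a"], vals[grp == "b"], k = 3)
  row_ab <- gh[gh$group_a == "a" & gh$group_b == "b", ]
  expect_equal(row_ab$statistic, ref$t, tolerance = 1e-10)
  expect_equal(row_ab$df, ref$df, tolerance = 1e-10)
  expect_equal(row_ab$pvalue, ref$p, tolerance = 1e-10)
  # two-group case: q = t * sqrt(2) equivalence against the Welch t
  a <- vals[grp == "a"]; b <- vals[grp == "b"]
  gh2 <- games_howell(c(a, b), factor(rep(c("a", "b"), c(8, 9))))
  wt <- t.test(a, b)
  expect_equal(abs(gh2$statistic), abs(unname(wt$statistic)), tolerance = 1e-10)
  expect_equal(gh2$pvalue, wt$p.value, tolerance = 1e-8)
  # identical groups: p near 1
  same <- rep(c(1, 2, 3, 4), 3)
  gh3 <- games_howell(same, factor(rep(c("a", "b", "c"), each = 4)))
  expect_true(all(gh3$pvalue > 0.999))
  # a strongly shifted group is flagged, the null pair is not
  set.seed(36)
  v <- c(rnorm(20), rnorm(20), rnorm(20) + 5)
  g3 <- factor(rep(c("a", "b", "c"), each = 20))
  gh4 <- games_howell(v, g3)
  expect_lt(max(gh4$pvalue[gh4$group_b == "c"]), 0.001)
  expect_gt(gh4$pvalue[gh4$group_a == "a" & gh4$group_b == "b"], 0.05)
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.03), 0.03)
  set.seed(37)
  p <- runif(25)
  expect_equal(fdr_bh(p), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(fdr_bh(p) >= p))
  # idempotent on a flat already-adjusted vector
  expect_equal(fdr_bh(rep(0.04, 4)), rep(0.04, 4))
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
})

test_that("Spearman brain-behaviour correlations are rank-exact", {
  auc <- data.frame(subject_id = sprintf("S%02d", 1:12),
                    Cp = runif(12), Lp = runif(12),
                    Eg = c(1:6, 1:6) + runif(12, 0, 0.1),
                    Eloc = runif(12))
  meta <- data.frame(subject_id = auc$subject_id,
                     group = rep(c("SIVCIND", "SIVaD"), each = 6),
                     MMSE = auc$Eg * 2 + 1,   # perfectly monotone in Eg
                     MoCA = c(5, 3, 3, 8, 2, 9, 1, 4, 4, 6, 7, 2))
  res <- spearman_scores(auc, meta)
  expect_equal(nrow(res), 8)
  expect_equal(res$rho[res$metric == "Eg" & res$score == "MMSE"], 1)
  # ties handled by average ranks, matching the from-definition oracle
  moca_row <- res[res$metric == "Eloc" & res$score == "MoCA", ]
  expect_equal(moca_row$rho, oracle_spearman(auc$Eloc, meta$MoCA),
               tolerance = 1e-12)
  # z-scoring is rank-invariant: same rho as raw scores
  meta2 <- meta; meta2$MMSE <- meta$MMSE * 10 + 3
  res2 <- spearman_scores(auc, meta2)
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)
  meta3 <- meta; meta3$MMSE <- rep(7, 12)
  expect_error(spearman_scores(auc, meta3), "constant")
})

test_that("chi-squared matches the from-definition oracle", {
  tab <- matrix(c(10, 0, 0, 10), 2)
  ours <- chisq_gender(tab)
  expect_equal(ours$statistic, 20)
  expect_equal(ours$statistic, oracle_chisq(tab), tolerance = 1e-12)
  # identical columns: X^2 = 0, p = 1
  same <- matrix(c(5, 7, 5, 7, 5, 7), 2)
  r0 <- chisq_gender(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$pvalue, 1)
  set.seed(38)
  tab2 <- matrix(rpois(6, 20), 2)
  expect_equal(chisq_gender(tab2)$statistic, oracle_chisq(tab2),
               tolerance = 1e-12)
  expect_error(chisq_gender(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("two-sample t-test follows the hand formula and is antisymmetric", {
  a <- c(8.2, 7.5, 9.1, 6.8); b <- c(5.5, 6.0, 4.8, 5.9, 6.2)
  ours <- two_sample_t(a, b, equal_var = TRUE)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(ours$statistic, t_ref, tolerance = 1e-12)
  flipped <- two_sample_t(b, a, equal_var = TRUE)
  expect_equal(flipped$statistic, -ours$statistic, tolerance = 1e-12)
  expect_equal(flipped$pvalue, ours$pvalue, tolerance = 1e-12)
  # degenerate equal constants: t = 0, p = 1
  r0 <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$pvalue, 1)
})

test_that("compare_groups gates post hoc tests and adjusts within family", {
  set.seed(39)
  n <- 20
  auc <- data.frame(subject_id = sprintf("S%02d", 1:(3 * n)),
                    Cp = rnorm(3 * n),
                    Lp = rnorm(3 * n),
                    Eg = c(rnorm(n, 3, 0.8), rnorm(n, 2, 1.4), rnorm(n, 1, 0.5)),
                    Eloc = rnorm(3 * n))
  grp <- factor(rep(c("NC", "SIVCIND", "SIVaD"), each = n),
                levels = c("NC", "SIVCIND", "SIVaD"))
  res <- compare_groups(auc, grp)
  expect_equal(res$omnibus$metric, c("Cp", "Lp", "Eg", "Eloc"))
  expect_equal(res$omnibus$adjusted_p, fdr_bh(res$omnibus$pvalue))
  expect_true("Eg" %in% names(res$posthoc))         # strong effect gated in
  expect_false("Cp" %in% names(res$posthoc))        # null metric gated out
  all_gh <- compare_groups(auc, grp, posthoc = "exploratory")
  expect_equal(sort(names(all_gh$posthoc)), sort(c("Cp", "Lp", "Eg", "Eloc")))
  # nodal comparison adjusts within the region family
  nodal <- rbind(matrix(rnorm(3 * n), 1),
                 matrix(c(rnorm(n, 2), rnorm(n, 0), rnorm(n, -2)), 1))
  ndres <- compare_groups_nodal(nodal, grp, regions = c("r1", "r2"))
  expect_equal(ndres$adjusted_p, fdr_bh(ndres$pvalue))
  expect_lt(ndres$adjusted_p[2], 0.01)
})
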