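test_that("base covariance has the stated block pattern and is SPD", {
  reg <- data.frame(index = 1:4, name = paste0("r", 1:4),
                    hemisphere = c("L", "R", "L", "R"),
                    lobe = c("a", "a", "b", "b"))
  spec <- cohort_spec(n_per_group = c(NC = 2L, SIVCIND = 2L, SIVaD = 2L),
                      n_regions = 4L, regions = reg,
                      within_lobe_corr = 0.4, between_lobe_corr = 0.1,
                      planted_edges = data.frame(i = 1, j = 3, factor = 0.5),
                      backbone_edges = data.frame(i = integer(0), j = integer(0)))
  m <- make_base_covariance(spec)
  expect_equal(diag(m), rep(1, 4))
  expect_equal(m[1, 2], 0.4)
  expect_equal(m[3, 4], 0.4)
  expect_equal(m[1, 3], 0.1)
  expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)

  # degenerate case: zero correlations give the identity
  spec0 <- cohort_spec(n_per_group = c(NC = 2L, SIVCIND = 2L, SIVaD = 2L),
                       n_regions = 4L, regions = reg,
                       within_lobe_corr = 1e-12, between_lobe_corr = 0,
                       planted_edges = data.frame(i = 1, j = 3, factor = 0.5),
                       backbone_edges = data.frame(i = integer(0), j = integer(0)))
  expect_equal(make_base_covariance(spec0), diag(4), tolerance = 1e-9)
})

test_that("default 90-region base covariance is SPD", {
  m <- make_base_covariance(cohort_spec())
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(dim(m), c(90, 90))
})

test_that("subject covariance applies group and planted factors exactly", {
  base <- diag(6)
  base[base == 0] <- 0.4
  # identity case: nothing changes
  expect_equal(subject_covariance(base, 1, NULL, subject_jitter_sd = 0), base)
  # uniform group factor halves the off-diagonal
  out <- subject_covariance(base, 0.5, NULL, subject_jitter_sd = 0)
  expect_equal(out[1, 2], 0.2)
  expect_equal(diag(out), rep(1, 6))
  # planted edge gets the product of both factors: 0.4 * 0.85 * 0.5 = 0.17
  out <- subject_covariance(base, 0.85,
                            planted_edges = data.frame(i = 1, j = 5, factor = 0.5),
                            subject_jitter_sd = 0)
  expect_equal(out[1, 5], 0.4 * 0.85 * 0.5)
  expect_equal(out[5, 1], 0.17)
  expect_equal(out[1, 2], 0.4 * 0.85)
  # severity exponent: factor^0.5
  out <- subject_covariance(base, 1,
                            planted_edges = data.frame(i = 1, j = 5, factor = 0.25),
                            planted_exponent = 0.5, subject_jitter_sd = 0)
  expect_equal(out[1, 5], 0.4 * 0.5)
})

test_that("simulated time series reproduce the target covariance", {
  expect_error(simulate_timeseries(diag(3), 1), "two timepoints")
  # determinism
  s1 <- simulate_timeseries(diag(3), 50, seed = 9)
  s2 <- simulate_timeseries(diag(3), 50, seed = 9)
  expect_identical(s1, s2)
  # identity covariance: off-diagonal sample correlations are small
  big <- simulate_timeseries(diag(10), 4000, seed = 2)
  r <- cor(big)
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(4000) * 2)
  # a strong planted correlation is recovered at large T
  cv <- diag(2); cv[1, 2] <- cv[2, 1] <- 0.6
  ts <- simulate_timeseries(cv, 10000, seed = 3)
  expect_equal(cor(ts)[1, 2], 0.6, tolerance = 0.02)
})

test_that("cognitive scores are anchored and ordered in the degradation factor", {
  s <- generate_scores(1.0, "NC", score_noise_sd = 0)
  expect_equal(s$MMSE, 28.5)
  expect_equal(s$MoCA, 28.0)
  expect_true(is.na(s$HIS))
  s_mid <- generate_scores(0.85, "SIVCIND", score_noise_sd = 0, seed = 1)
  s_low <- generate_scores(0.70, "SIVaD", score_noise_sd = 0, seed = 1)
  expect_equal(s_mid$MMSE, 24.1)
  expect_equal(s_low$MMSE, 14.2)
  expect_true(s$MMSE > s_mid$MMSE && s_mid$MMSE > s_low$MMSE)
  expect_false(is.na(s_mid$HIS))
  expect_true(s_mid$CDR >= 0 && s_mid$CDR <= 0.5)
  # noisy group means stay ordered in nearly all replicates
  set.seed(42)
  ok <- 0
  for (r in 1:20) {
    m <- vapply(c(1.0, 0.85, 0.70), function(f) {
      mean(vapply(1:20, function(s) generate_scores(f, "SIVaD", 1.5)$MMSE,
                  numeric(1)))
    }, numeric(1))
    ok <- ok + (m[1] > m[2] && m[2] > m[3])
  }
  expect_gte(ok, 19)
})

test_that("generate_cohort produces a complete, reproducible cohort", {
  spec <- cohort_spec()
  cohort <- generate_cohort(spec, seed = 5)
  expect_length(cohort$timeseries, 59)
  expect_equal(dim(cohort$timeseries[[1]]), c(230, 90))
  expect_equal(as.vector(table(cohort$metadata$group)), c(19, 20, 20))
  expect_true(all(cohort$metadata$MMSE >= 0 & cohort$metadata$MMSE <= 30))
  expect_true(all(is.na(cohort$metadata$HIS[cohort$metadata$group == "NC"])))
  # determinism of the whole cohort
  cohort2 <- generate_cohort(spec, seed = 5)
  expect_identical(cohort$metadata, cohort2$metadata)
  expect_identical(cohort$timeseries[[37]], cohort2$timeseries[[37]])
  # small-group failure contract
  expect_error(cohort_spec(n_per_group = c(NC = 0L, SIVCIND = 2L, SIVaD = 2L)),
               "at least one subject")
})

test_that("population efficiency decreases over the planted severity course", {
  spec <- cohort_spec()
  cohort <- generate_cohort(spec, seed = 1)
  eg <- vapply(cohort$ground_truth$group_covariance, function(cv) {
    z <- fisher_z(cv)
    mean(vapply(seq(0.10, 0.40, 0.05), function(s) {
      g <- scale_weights(weighted_graph(threshold_sparsity(z, s)))
      global_efficiency(shortest_path_lengths(g))$Eg
    }, numeric(1)))
  }, numeric(1))
  expect_true(eg["NC"] > eg["SIVCIND"])
  expect_true(eg["SIVCIND"] > eg["SIVaD"])
})

test_that("zero covariate effects leave edges uncorrelated with age", {
  spec <- cohort_spec(n_per_group = c(NC = 10L, SIVCIND = 10L, SIVaD = 10L),
                      covariate_effect = c(age = 0, gender = 0, education = 0))
  cohort <- generate_cohort(spec, seed = 8)
  z <- lapply(cohort$timeseries, function(ts) fisher_z(pearson_connectivity(ts)))
  nc <- cohort$metadata$group == "NC"
  y <- t(vapply(z[nc], function(m) m[upper.tri(m)][1:300], numeric(300)))
  age <- cohort$metadata$age[nc]
  obs <- mean(cor(age, y))
  # permutation oracle: the observed mean edge-age correlation sits inside
  # the null spread obtained by shuffling the age labels
  set.seed(99)
  null <- vapply(1:100, function(b) mean(cor(sample(age), y)), numeric(1))
  expect_lt(abs(obs), max(abs(null)))
  expect_gt(mean(abs(null) >= abs(obs)), 0.05)
})

test_that("cohort round-trips through delimited text files", {
  spec <- cohort_spec(n_per_group = c(NC = 2L, SIVCIND = 2L, SIVaD = 2L),
                      n_timepoints = 40L)
  cohort <- generate_cohort(spec, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(meta$subject_id, cohort$metadata$subject_id)
  back <- read_timeseries_dir(file.path(dir, "timeseries"), meta)
  expect_equal(back[[1]], cohort$timeseries[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
})
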