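#' Lilliefors-type Kolmogorov-Smirnov normality test
#'
#' KS distance between the empirical distribution and a normal with mean
#' and SD estimated from the sample; because the parameters are estimated,
#' the p-value is calibrated by seeded Monte-Carlo simulation of the null
#' rather than the classical KS distribution.
#'
#' @param values Numeric vector (n >= 4, non-constant).
#' @param n_mc Number of Monte-Carlo null samples.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `statistic`, `pvalue`, `n`, `test`.
#' @export
ks_normality <- function(values, n_mc = 1999, seed = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) stop_sivd("need at least four observations")
  if (sd(values) == 0) stop_sivd("constant input")
  lillie_d <- function(x) {
    z <- sort((x - mean(x)) / sd(x))
    pz <- pnorm(z)
    i <- seq_along(z)
    max(i / length(z) - pz, pz - (i - 1) / length(z))
  }
  d <- lillie_d(values)
  set.seed(seed)
  d_null <- vapply(seq_len(n_mc), function(b) lillie_d(rnorm(n)), numeric(1))
  list(statistic = d, pvalue = (1 + sum(d_null >= d)) / (n_mc + 1),
       n = n, test = "lilliefors_ks")
}

#' Levene's test for homogeneity of variances (mean-centred)
#'
#' One-way ANOVA on the absolute deviations from the group means.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @return List with `statistic` (W), `df`, `pvalue`.
#' @export
levene_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop_sivd("need at least two groups")
  if (any(table(groups) < 2)) stop_sivd("every group needs >= 2 observations")
  centred <- abs(values - ave(values, groups))
  fit <- anova(lm(centred ~ groups))
  list(statistic = fit[1, "F value"], df = fit$Df,
       pvalue = fit[1, "Pr(>F)"], test = "levene_mean")
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch F* with Welch-Satterthwaite denominator degrees of freedom, as
#' used when Levene's test indicates unequal group variances.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List with `statistic`, `df` (numerator, denominator), `pvalue`,
#'   and per-group `summary` (n, mean, sd).
#' @export
welch_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop_sivd("need at least two groups")
  tab <- table(groups)
  if (any(tab < 2)) stop_sivd("every group needs >= 2 observations")
  vars <- tapply(values, groups, var)
  if (any(vars == 0)) stop_sivd("zero variance in a group")
  fit <- oneway.test(values ~ groups, var.equal = FALSE)
  list(statistic = unname(fit$statistic),
       df = unname(fit$parameter), pvalue = fit$p.value,
       summary = data.frame(group = levels(groups), n = as.numeric(tab),
                            mean = as.numeric(tapply(values, groups, mean)),
                            sd = sqrt(as.numeric(vars))),
       test = "welch_anova")
}

#' Games-Howell pairwise post hoc test
#'
#' Pairwise comparisons for unequal variances: Welch standard error and
#' degrees of freedom per pair, p-value from the studentized range
#' distribution with the total number of groups.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `mean_diff`, `se`, `statistic` (t), `df`, `pvalue`.
#' @export
games_howell <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2) stop_sivd("need at least two groups")
  if (any(table(groups) < 2)) stop_sivd("every group needs >= 2 observations")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  n <- tapply(values, groups, length)
  rows <- list()
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    se2 <- v[a] / n[a] + v[b] / n[b]
    se <- sqrt(se2)
    t <- (m[a] - m[b]) / se
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) + (v[b] / n[b])^2 / (n[b] - 1))
    p <- ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      group_a = lev[a], group_b = lev[b], mean_diff = unname(m[a] - m[b]),
      se = unname(se), statistic = unname(t), df = unname(df),
      pvalue = unname(p))
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone and clipped at 1, in the input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_sivd("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Spearman correlation between AUC metrics and cognitive scores
#'
#' Cognitive scores are z-scored within the pooled patient sample; the
#' Spearman rank correlation (average ranks for ties) of every metric with
#' every score forms one Benjamini-Hochberg family.
#'
#' @param auc_table Data frame with columns `subject_id`, `Cp`, `Lp`,
#'   `Eg`, `Eloc`.
#' @param metadata Data frame with `subject_id`, `group` and score columns.
#' @param scores Score column names (default MMSE and MoCA).
#' @param patient_groups Groups pooled for the analysis.
#' @return Data frame `metric`, `score`, `rho`, `pvalue`, `adjusted_p`, `n`.
#' @export
spearman_scores <- function(auc_table, metadata, scores = c("MMSE", "MoCA"),
                            patient_groups = c("SIVCIND", "SIVaD")) {
  merged <- merge(auc_table, metadata, by = "subject_id")
  merged <- merged[merged$group %in% patient_groups, ]
  if (nrow(merged) < 5) stop_sivd("need at least five paired observations")
  metrics <- c("Cp", "Lp", "Eg", "Eloc")
  rows <- list()
  for (sc in scores) {
    x <- merged[[sc]]
    if (sd(x) == 0) stop_sivd("constant score vector: ", sc)
    z <- (x - mean(x)) / sd(x)
    for (me in metrics) {
      ct <- suppressWarnings(cor.test(merged[[me]], z, method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        metric = me, score = sc, rho = unname(ct$estimate),
        pvalue = ct$p.value, n = nrow(merged))
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- fdr_bh(out$pvalue)
  out
}

#' Group comparison of global AUC metrics
#'
#' For each global metric (Cp, Lp, Eg, Eloc): Kolmogorov-Smirnov normality
#' per group, Levene's test, Welch ANOVA, and Games-Howell post hoc tests
#' where the omnibus test is significant (or always, in exploratory mode).
#' Omnibus p-values are Benjamini-Hochberg adjusted as one four-test
#' family.
#'
#' @param auc_table Data frame with `subject_id`, `Cp`, `Lp`, `Eg`, `Eloc`.
#' @param groups Group labels aligned with `auc_table` rows.
#' @param alpha Significance level gating the post hoc stage.
#' @param posthoc `"gated"` (default) or `"exploratory"`.
#' @param ks_seed Seed for the normality Monte-Carlo.
#' @return List with `omnibus` (data.frame) and `posthoc` (named list of
#'   Games-Howell tables).
#' @export
compare_groups <- function(auc_table, groups, alpha = 0.05,
                           posthoc = c("gated", "exploratory"), ks_seed = 1) {
  posthoc <- match.arg(posthoc)
  groups <- droplevels(as.factor(groups))
  metrics <- c("Cp", "Lp", "Eg", "Eloc")
  rows <- list(); gh <- list()
  for (me in metrics) {
    v <- auc_table[[me]]
    ks_p <- min(vapply(levels(groups), function(g) {
      ks_normality(v[groups == g], seed = ks_seed)$pvalue
    }, numeric(1)))
    lev <- levene_test(v, groups)
    w <- welch_anova(v, groups)
    rows[[me]] <- data.frame(
      metric = me, ks_min_pvalue = ks_p, levene_W = lev$statistic,
      levene_p = lev$pvalue, welch_F = w$statistic, df1 = w$df[1],
      df2 = w$df[2], pvalue = w$pvalue)
  }
  omnibus <- do.call(rbind, rows)
  omnibus$adjusted_p <- fdr_bh(omnibus$pvalue)
  rownames(omnibus) <- NULL
  for (me in metrics) {
    if (posthoc == "exploratory" ||
        omnibus$adjusted_p[omnibus$metric == me] < alpha) {
      gh[[me]] <- games_howell(auc_table[[me]], groups)
    }
  }
  list(omnibus = omnibus, posthoc = gh)
}

#' Group comparison of nodal efficiency AUC values
#'
#' Welch ANOVA per region for one nodal metric family (90 tests for the
#' packaged parcellation), Benjamini-Hochberg adjusted within the family.
#'
#' @param nodal_matrix Region x subject matrix of nodal AUC values.
#' @param groups Group labels aligned with columns.
#' @param regions Region names.
#' @return Data frame `region`, `welch_F`, `pvalue`, `adjusted_p`.
#' @export
compare_groups_nodal <- function(nodal_matrix, groups, regions = NULL) {
  groups <- droplevels(as.factor(groups))
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(nodal_matrix)))
  res <- apply(nodal_matrix, 1, function(v) {
    w <- tryCatch(welch_anova(v, groups),
                  error = function(e) list(statistic = NA_real_, pvalue = NA_real_))
    c(w$statistic, w$pvalue)
  })
  out <- data.frame(region = regions, welch_F = res[1, ], pvalue = res[2, ])
  ok <- !is.na(out$pvalue)
  out$adjusted_p <- NA_real_
  out$adjusted_p[ok] <- fdr_bh(out$pvalue[ok])
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' @param counts Matrix of non-negative integer counts (e.g. gender by
#'   group).
#' @return List with `statistic`, `df`, `pvalue`.
#' @export
chisq_gender <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_sivd("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_sivd("zero marginal in the contingency table")
  }
  fit <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       pvalue = fit$p.value)
}

#' Two-sample t-test on clinical scale scores
#'
#' Student (equal variance) or Welch two-sided t-test. If both groups have
#' zero variance and equal means the statistic is 0 with p = 1.
#'
#' @param group_a,group_b Numeric vectors.
#' @param equal_var Pool the variances.
#' @return List with `statistic`, `df`, `pvalue`.
#' @export
two_sample_t <- function(group_a, group_b, equal_var = FALSE) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_sivd("both groups need at least two observations")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, df = length(group_a) + length(group_b) - 2,
                  pvalue = 1))
    }
    stop_sivd("zero variance in both groups with unequal means")
  }
  fit <- t.test(group_a, group_b, var.equal = equal_var)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       pvalue = fit$p.value)
}
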