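# Brute-force reference implementations used as independent oracles.
# These deliberately use the slowest, most literal formulations.

# random connected-ish weighted graph as a dense symmetric matrix
random_weight_matrix <- function(n, density = 0.5, wmin = 0.2, wmax = 2) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) {
      w[i, j] <- w[j, i] <- runif(1, wmin, wmax)
    }
  }
  w
}

# Onnela clustering by exhaustive triple enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; l <- nb[b]
      if (w[j, l] > 0) s <- s + (w[i, j] * w[j, l] * w[l, i])^(1 / 3)
    }
    ci[i] <- 2 * s / (k * (k - 1))
  }
  list(Ci = ci, Cp = mean(ci))
}

# all-pairs shortest paths by triple-loop Floyd-Warshall
oracle_apsp <- function(w, reciprocal = TRUE) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- if (reciprocal) 1 / w[i, j] else w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_global_efficiency <- function(d) {
  n <- nrow(d)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  nodal <- rowSums(inv) / (n - 1)
  list(Eg = mean(nodal), nodal = nodal)
}

oracle_local_efficiency <- function(w, reciprocal = TRUE) {
  n <- nrow(w)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    sub <- w[nb, nb, drop = FALSE]
    nodal[i] <- oracle_global_efficiency(oracle_apsp(sub, reciprocal))$Eg
  }
  list(Eloc = mean(nodal), nodal = nodal)
}

# binary-graph metrics (unit weights) for the binary-limit check
oracle_binary_metrics <- function(adj) {
  d <- oracle_apsp(adj, reciprocal = TRUE)  # unit weights: 1/w = 1
  eg <- oracle_global_efficiency(d)
  cl <- oracle_clustering(adj)              # cube roots of 1 are 1
  el <- oracle_local_efficiency(adj)
  list(Cp = cl$Cp, Eg = eg$Eg, Eloc = el$Eloc,
       Lp = mean(d[row(d) != col(d)][is.finite(d[row(d) != col(d)])]))
}

# connected components of an edge list by union-find; returns sorted
# component edge counts
oracle_components <- function(pairs, n_nodes) {
  parent <- seq_len(n_nodes)
  find2 <- function(p, x) { while (p[x] != x) x <- p[x]; x }
  if (nrow(pairs) > 0) {
    for (e in seq_len(nrow(pairs))) {
      ri <- find2(parent, pairs[e, 1]); rj <- find2(parent, pairs[e, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n_nodes), function(x) find2(parent, x), integer(1))
  if (nrow(pairs) == 0) return(integer(0))
  edge_root <- vapply(seq_len(nrow(pairs)), function(e) find2(parent, pairs[e, 1]),
                      integer(1))
  sort(as.integer(table(edge_root)), decreasing = TRUE)
}

# from-definition one-way ANOVA on a single vector
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values); k <- nlevels(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# from-definition Welch ANOVA
oracle_welch_f <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, var)
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  a <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  f <- a / (1 + 2 * lambda * (k - 2))
  df2 <- 1 / (3 * lambda)
  list(F = f, df1 = k - 1, df2 = df2,
       p = pf(f, k - 1, df2, lower.tail = FALSE))
}

# from-definition mean-centred Levene W
oracle_levene_w <- function(values, groups) {
  groups <- as.factor(groups)
  zi <- abs(values - ave(values, groups))
  oracle_anova_f(zi, groups)$F
}

# from-definition Games-Howell for one pair within a k-group design
oracle_games_howell_pair <- function(xa, xb, k) {
  se2 <- var(xa) / length(xa) + var(xb) / length(xb)
  t <- (mean(xa) - mean(xb)) / sqrt(se2)
  df <- se2^2 / ((var(xa) / length(xa))^2 / (length(xa) - 1) +
                   (var(xb) / length(xb))^2 / (length(xb) - 1))
  p <- ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# from-definition Spearman rho with average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# from-definition chi-squared on a contingency table
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# from-definition BH step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[ord[r]] * m / r)
    adj[ord[r]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# edge matrices with a planted group difference on a connected edge set
make_planted_matrices <- function(n_nodes, n_a, n_b, planted_pairs = NULL,
                                  effect = 0, noise_sd = 1, seed = 1) {
  set.seed(seed)
  make_one <- function(shift_edges) {
    m <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(m)
    m[ut] <- rnorm(sum(ut), 0, noise_sd)
    if (!is.null(planted_pairs) && shift_edges) {
      m[planted_pairs] <- m[planted_pairs] + effect * noise_sd
    }
    m + t(m)
  }
  c(lapply(seq_len(n_a), function(s) make_one(FALSE)),
    lapply(seq_len(n_b), function(s) make_one(TRUE)))
}

# a chain of connected node pairs for planting components
chain_pairs <- function(nodes) {
  cbind(nodes[-length(nodes)], nodes[-1])
}
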