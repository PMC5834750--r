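#' Zero-phase band-pass filter for regional time series
#'
#' Frequency-domain masking with a raised-cosine taper at the band edges.
#' Column means (the DC component) are always removed; the output has the
#' same length as the input.
#'
#' @param ts T x N numeric matrix of regional signals.
#' @param low_hz,high_hz Pass band in Hz; `0 <= low < high < Nyquist`.
#' @param sampling_interval Sampling interval in seconds (default 2, i.e.
#'   a 0.25 Hz Nyquist frequency).
#' @param taper_hz Width of the cosine transition band.
#' @return Filtered matrix of the same dimensions.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08,
                     sampling_interval = 2, taper_hz = 0.004) {
  ts <- as.matrix(ts)
  nyquist <- 1 / (2 * sampling_interval)
  if (!(low_hz >= 0 && low_hz < high_hz)) {
    stop_sivd("need 0 <= low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    stop_sivd("high_hz must be below the Nyquist frequency (",
              format(nyquist), " Hz)")
  }
  n <- nrow(ts)
  freq <- seq(0, n - 1) / (n * sampling_interval)
  freq <- pmin(freq, 1 / sampling_interval - freq)  # fold to [0, Nyquist]
  cosine_ramp <- function(x) 0.5 - 0.5 * cos(pi * pmin(1, pmax(0, x)))
  up <- if (low_hz > 0) cosine_ramp((freq - (low_hz - taper_hz)) / taper_hz) else 1
  down <- cosine_ramp(((high_hz + taper_hz) - freq) / taper_hz)
  gain <- up * down
  gain[1] <- 0  # always remove DC
  centred <- sweep(ts, 2, colMeans(ts))
  out <- apply(centred, 2, function(x) Re(fft(fft(x) * gain, inverse = TRUE)) / n)
  dimnames(out) <- dimnames(ts)
  out
}

#' Pearson correlation connectivity matrix
#'
#' @param ts T x N matrix of regional signals.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
pearson_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  v <- apply(ts, 2, var)
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop_sivd("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  cor(ts)
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' `z = atanh(r)` elementwise off the diagonal; the diagonal is set to 0.
#' Correlations within `1e-7` of +/-1 are clipped before the transform.
#'
#' @param corr Correlation matrix.
#' @return Matrix of Fisher-z edge weights with zero diagonal.
#' @export
fisher_z <- function(corr) {
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(corr, -clip), clip))
  diag(z) <- 0
  z
}

# upper-triangle index helpers shared by the edge-wise modules
ut_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

edge_matrix <- function(matrices) {
  n <- nrow(matrices[[1]])
  ut <- upper.tri(matrices[[1]])
  t(vapply(matrices, function(m) m[ut], numeric(sum(ut))))
}

matrix_from_edges <- function(values, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m + t(m)
}

#' Regress nuisance covariates out of the edge weights
#'
#' For every edge, the Fisher-z weights are regressed across subjects on an
#' intercept plus the covariate columns by ordinary least squares; the
#' corrected weight is the residual plus the fitted intercept, which keeps
#' the weights on the Fisher-z scale. Constant covariates are dropped with
#' a warning.
#'
#' @param matrices List of N x N Fisher-z matrices, one per subject.
#' @param covariates Data frame row-aligned with `matrices`; all columns
#'   are used as covariates (default expectation: age, gender, education).
#' @return List of corrected matrices.
#' @export
regress_covariates <- function(matrices, covariates) {
  covariates <- as.data.frame(covariates)
  n_sub <- length(matrices)
  if (nrow(covariates) != n_sub) {
    stop_sivd("covariate table must have one row per subject")
  }
  keep <- vapply(covariates, function(x) var(as.numeric(x)) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  p <- ncol(covariates)
  if (n_sub < p + 2) stop_sivd("too few subjects for ", p, " covariates")
  n <- nrow(matrices[[1]])
  y <- edge_matrix(matrices)                       # subjects x edges
  # centre the covariates so the fitted intercept is the cohort-mean
  # prediction and the corrected weights stay on the Fisher-z scale
  x <- cbind(1, scale(as.matrix(covariates), center = TRUE, scale = FALSE))
  beta <- solve(crossprod(x), crossprod(x, y))
  corrected <- y - x %*% beta + rep(1, n_sub) %*% beta[1, , drop = FALSE]
  out <- lapply(seq_len(n_sub), function(s) {
    m <- matrix_from_edges(corrected[s, ], n)
    dimnames(m) <- dimnames(matrices[[s]])
    m
  })
  names(out) <- names(matrices)
  out
}

#' Threshold a connectivity matrix at a proportional sparsity
#'
#' Retains the `K = round(s * N(N-1)/2)` largest-weighted edges (rounding
#' half away from zero), ties at the cutoff broken by ascending `(i, j)`
#' order. In signed mode (default) a retained non-positive weight is an
#' error, because the downstream weighted metrics require positive
#' weights; absolute-value mode ranks and stores `|w|`.
#'
#' @param z N x N symmetric weight matrix with zero diagonal.
#' @param sparsity Fraction of possible edges to retain, in (0, 1].
#' @param abs_mode Rank and store absolute weights.
#' @return An object of class `sparsity_graph`: list with `sparsity`,
#'   `n_nodes`, `region_names` and `edges` (data.frame `i`, `j`, `w`).
#' @export
threshold_sparsity <- function(z, sparsity, abs_mode = FALSE) {
  if (!(sparsity > 0 && sparsity <= 1)) stop_sivd("sparsity must lie in (0, 1]")
  n <- nrow(z)
  pairs <- ut_pairs(n)
  w <- z[upper.tri(z)]
  if (abs_mode) w <- abs(w)
  k <- as.integer(round_half_away(sparsity * n * (n - 1) / 2))
  k <- max(1L, min(k, length(w)))
  ord <- order(-w, pairs[, 1], pairs[, 2])
  keep <- ord[seq_len(k)]
  if (!abs_mode && any(w[keep] <= 0)) {
    stop_sivd("non-positive weight retained at sparsity ", sparsity,
              "; use abs_mode = TRUE or a lower sparsity")
  }
  structure(list(
    sparsity = sparsity, n_nodes = n,
    region_names = rownames(z),
    edges = data.frame(i = pairs[keep, 1], j = pairs[keep, 2], w = w[keep])
  ), class = "sparsity_graph")
}

#' Sweep proportional sparsity thresholds
#'
#' @param z Weight matrix.
#' @param s_min,s_max,step Sweep bounds and increment; the defaults
#'   (10 to 40 percent in 1 percent steps) yield 31 thresholds.
#' @param abs_mode Passed to [threshold_sparsity()].
#' @return List of `sparsity_graph` objects.
#' @export
sparsity_sweep <- function(z, s_min = 0.10, s_max = 0.40, step = 0.01,
                           abs_mode = FALSE) {
  if (s_min > s_max || step <= 0) stop_sivd("invalid sweep bounds")
  n_steps <- floor((s_max - s_min) / step + 1e-9)
  svals <- round(s_min + step * (0:n_steps), 10)
  lapply(svals, function(s) threshold_sparsity(z, s, abs_mode))
}
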