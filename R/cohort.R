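#' Specify a synthetic three-group connectome cohort
#'
#' Bundles all parameters of the synthetic cohort generator. The defaults
#' describe a 59-subject study — normal controls (NC, n = 19) and two
#' progressively impaired patient groups (SIVCIND, n = 20; SIVaD, n = 20) —
#' with 90 regions in six lobe blocks and 230 retained volumes per subject
#' at a 2 s sampling interval.
#'
#' Group degradation is planted as per-edge attenuation of the population
#' correlation matrix. Each planted edge carries a full-severity factor in
#' (0, 1]; a subject at severity `t` (derived from the group attenuation
#' level, `t = (1 - attenuation) / (1 - min(attenuation))`) multiplies that
#' edge by `factor^t`. The default planted set attenuates (i) between-lobe
#' edges with at least one endpoint in the frontal, temporal or parietal
#' lobes (long-range disconnection) and (ii) all edges of a "lesion patch"
#' of every third frontal/temporal/parietal region (focal nodal
#' degradation). Severity additionally scales a symmetric jitter applied to
#' the subject covariance ("disorganisation"), which degrades local
#' neighbourhood coherence. A uniform multiplicative attenuation of all
#' edges is deliberately not part of the default degradation: the
#' downstream metrics control cost by mean-weight scaling and proportional
#' thresholding, which cancels any uniform factor.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param n_regions Number of regions (must match the region table).
#' @param n_timepoints Time series length per subject.
#' @param regions Region table, see [aal_regions()].
#' @param within_lobe_corr,between_lobe_corr Baseline correlations inside /
#'   across lobe blocks; `0 <= between < within < 1`.
#' @param group_attenuation Named vector of group attenuation levels in
#'   (0, 1], non-increasing over the group order (1 = intact).
#' @param planted_edges Data frame with columns `i`, `j`, `factor` giving
#'   region index pairs and full-severity attenuation factors, or `NULL`
#'   for the default planted set described above.
#' @param backbone_edges Data frame with columns `i`, `j` of long-range
#'   "backbone" pairs whose baseline correlation is elevated to
#'   `backbone_corr` (strong inter-lobe connections that keep the intact
#'   network integrated at low sparsity), or `NULL` for the default
#'   deterministic backbone; the default planted set attenuates these
#'   edges with staged full-severity factors (0.09 early, 0.55 late).
#' @param backbone_corr Baseline correlation of backbone pairs.
#' @param covariate_effect Named vector of additive slopes of age, gender
#'   and education on the (off-diagonal) population correlations.
#' @param score_noise_sd Gaussian noise SD added to the cognitive scores.
#' @param subject_jitter_sd Baseline SD of the symmetric covariance jitter.
#' @param disorganization_slope Additional jitter SD per unit severity.
#' @param attenuation_sd SD of the per-subject attenuation jitter.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(NC = 19L, SIVCIND = 20L, SIVaD = 20L),
                        n_regions = 90L,
                        n_timepoints = 230L,
                        regions = aal_regions(),
                        within_lobe_corr = 0.45,
                        between_lobe_corr = 0.25,
                        group_attenuation = c(NC = 1.00, SIVCIND = 0.85, SIVaD = 0.70),
                        planted_edges = NULL,
                        backbone_edges = NULL,
                        backbone_corr = 0.45,
                        covariate_effect = c(age = -0.0015, gender = 0.01, education = 0.002),
                        score_noise_sd = 1.5,
                        subject_jitter_sd = 0.01,
                        disorganization_slope = 0.04,
                        attenuation_sd = 0.02) {
  if (length(n_per_group) < 1 || any(n_per_group <= 0)) {
    stop_sivd("every group needs at least one subject")
  }
  if (!(between_lobe_corr >= 0 && within_lobe_corr > between_lobe_corr &&
        within_lobe_corr < 1)) {
    stop_sivd("need 0 <= between_lobe_corr < within_lobe_corr < 1")
  }
  if (any(group_attenuation <= 0) || any(group_attenuation > 1)) {
    stop_sivd("group attenuation levels must lie in (0, 1]")
  }
  if (is.unsorted(rev(group_attenuation))) {
    stop_sivd("group attenuation must be non-increasing over the group order")
  }
  if (nrow(regions) != n_regions) {
    stop_sivd("region table has ", nrow(regions), " rows but n_regions = ", n_regions)
  }
  if (is.null(backbone_edges)) {
    backbone_edges <- default_backbone_edges(regions)
  }
  if (is.null(planted_edges)) {
    planted_edges <- default_planted_edges(regions, backbone_edges = backbone_edges)
  }
  if (nrow(planted_edges) > 0) {
    if (!all(c("i", "j", "factor") %in% names(planted_edges))) {
      stop_sivd("planted_edges needs columns i, j, factor")
    }
    ok <- planted_edges$i >= 1 & planted_edges$i <= n_regions &
      planted_edges$j >= 1 & planted_edges$j <= n_regions &
      planted_edges$i != planted_edges$j
    if (!all(ok)) stop_sivd("planted edges reference invalid region pairs")
    if (any(planted_edges$factor <= 0 | planted_edges$factor > 1)) {
      stop_sivd("planted attenuation factors must lie in (0, 1]")
    }
  }
  if (nrow(backbone_edges) > 0) {
    okb <- backbone_edges$i >= 1 & backbone_edges$i <= n_regions &
      backbone_edges$j >= 1 & backbone_edges$j <= n_regions &
      backbone_edges$i != backbone_edges$j
    if (!all(okb)) stop_sivd("backbone edges reference invalid region pairs")
    if (backbone_corr <= between_lobe_corr || backbone_corr >= 1) {
      stop_sivd("backbone_corr must lie in (between_lobe_corr, 1)")
    }
  }
  structure(list(
    n_per_group = n_per_group, n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints), regions = regions,
    within_lobe_corr = within_lobe_corr, between_lobe_corr = between_lobe_corr,
    group_attenuation = group_attenuation, planted_edges = planted_edges,
    backbone_edges = backbone_edges, backbone_corr = backbone_corr,
    covariate_effect = covariate_effect, score_noise_sd = score_noise_sd,
    subject_jitter_sd = subject_jitter_sd,
    disorganization_slope = disorganization_slope,
    attenuation_sd = attenuation_sd
  ), class = "cohort_spec")
}

#' Default long-range backbone edge set
#'
#' A deterministic "rich club" of hub regions — a few per lobe, chosen
#' outside the lesion patch — fully interconnected across lobes. These
#' hub-to-hub edges play the role of the strong long-distance connections
#' that keep the intact connectome integrated at low sparsity; because
#' they interconnect, they carry their own triangle support and do not
#' dilute local neighbourhood coherence. The default planted degradation
#' targets them first.
#'
#' @param regions Region table.
#' @param hubs_per_affected Hub count per frontal/temporal/parietal lobe.
#' @param hubs_per_other Hub count per remaining lobe.
#' @return Data frame with columns `i`, `j` (all between-lobe hub pairs).
#' @export
default_backbone_edges <- function(regions, hubs_per_affected = 3,
                                   hubs_per_other = 2) {
  affected_lobes <- c("frontal", "temporal", "parietal")
  patch <- unlist(lapply(affected_lobes, function(l) {
    idx <- which(regions$lobe == l)
    idx[seq(1, length(idx), by = 3)]
  }))
  hubs <- unlist(lapply(unique(regions$lobe), function(l) {
    k <- if (l %in% affected_lobes) hubs_per_affected else hubs_per_other
    idx <- setdiff(which(regions$lobe == l), patch)
    idx[round(seq(1, length(idx), length.out = min(k, length(idx))))]
  }))
  hubs <- sort(unique(hubs))
  lobe <- regions$lobe
  out <- list()
  for (a in seq_along(hubs)) for (b in seq_along(hubs)) {
    if (a < b && lobe[hubs[a]] != lobe[hubs[b]]) {
      out[[length(out) + 1]] <- c(hubs[a], hubs[b])
    }
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

#' Default planted degradation edge set
#'
#' Degradation targets, each a set of edges with a full-severity
#' attenuation factor. Both the focal lesion patch (every third
#' frontal/temporal/parietal region) and the long-range backbone are
#' staged in an early and a late half, so that part of the structural loss
#' happens between the control and the intermediate stage and part only
#' between the intermediate and the full-severity stage: early patch
#' regions carry factor 0.15 and early backbone edges 0.09 (below the
#' proportional-threshold retention cutoff already at intermediate
#' severity), late patch regions 0.50 and late backbone edges 0.55
#' (crossing the cutoff only at full severity). The remaining between-lobe
#' edges touching the frontal, temporal or parietal lobes carry factor
#' 0.45. Staging by extent makes global integration decline roughly in
#' proportion to the number of lost long-range shortcuts across the whole
#' severity course instead of saturating at the intermediate stage.
#'
#' @param regions Region table.
#' @param between_factor Full-severity factor for the between-lobe edges.
#' @param patch_factor_early,patch_factor_late Full-severity factors for
#'   the early- and late-stage halves of the lesion patch.
#' @param backbone_factor_early,backbone_factor_late Full-severity factors
#'   for the early- and late-stage halves of the backbone.
#' @param backbone_edges Backbone pairs, see [default_backbone_edges()].
#' @return Data frame with columns `i`, `j`, `factor`.
#' @export
default_planted_edges <- function(regions, between_factor = 0.45,
                                  patch_factor_early = 0.15,
                                  patch_factor_late = 0.50,
                                  backbone_factor_early = 0.09,
                                  backbone_factor_late = 0.55,
                                  backbone_edges = default_backbone_edges(regions)) {
  n <- nrow(regions)
  affected_lobes <- c("frontal", "temporal", "parietal")
  affected <- regions$lobe %in% affected_lobes
  patch <- unlist(lapply(affected_lobes, function(l) {
    idx <- which(regions$lobe == l)
    idx[seq(1, length(idx), by = 3)]
  }))
  patch_early <- patch[seq(1, length(patch), by = 2)]
  patch_late <- setdiff(patch, patch_early)
  in_early <- seq_len(n) %in% patch_early
  in_late <- seq_len(n) %in% patch_late
  lobe <- regions$lobe
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  early_edge <- in_early[i] | in_early[j]
  late_edge <- (in_late[i] | in_late[j]) & !early_edge
  backbone_early <- backbone_late <- rep(FALSE, length(i))
  if (!is.null(backbone_edges) && nrow(backbone_edges) > 0) {
    key <- paste(pmin(i, j), pmax(i, j))
    b_ij <- cbind(pmin(backbone_edges$i, backbone_edges$j),
                  pmax(backbone_edges$i, backbone_edges$j))
    half <- seq_len(nrow(b_ij)) %% 2 == 1
    backbone_early <- key %in% paste(b_ij[half, 1], b_ij[half, 2])
    backbone_late <- key %in% paste(b_ij[!half, 1], b_ij[!half, 2])
  }
  between_edge <- (lobe[i] != lobe[j]) & (affected[i] | affected[j])
  fac <- rep(NA_real_, length(i))
  fac[between_edge] <- between_factor
  fac[backbone_late] <- backbone_factor_late
  fac[backbone_early] <- backbone_factor_early
  fac[late_edge] <- patch_factor_late
  fac[early_edge] <- patch_factor_early  # strongest target wins
  keep <- !is.na(fac)
  data.frame(i = i[keep], j = j[keep], factor = fac[keep])
}

#' Baseline block-structured population correlation matrix
#'
#' Unit diagonal, `within_lobe_corr` inside each lobe block and
#' `between_lobe_corr` across blocks, projected to the nearest symmetric
#' positive-definite correlation matrix if required.
#'
#' @param spec A [cohort_spec()].
#' @param lobe_assignment Optional vector of lobe labels per region;
#'   defaults to the spec's region table.
#' @return An SPD correlation matrix of size `n_regions`.
#' @export
make_base_covariance <- function(spec, lobe_assignment = NULL) {
  n <- spec$n_regions
  if (is.null(lobe_assignment)) lobe_assignment <- spec$regions$lobe
  if (length(lobe_assignment) != n) {
    stop_sivd("lobe assignment length must equal n_regions")
  }
  same <- outer(lobe_assignment, lobe_assignment, "==")
  base <- ifelse(same, spec$within_lobe_corr, spec$between_lobe_corr)
  diag(base) <- 1
  nearest_spd(base)
}

#' Project a symmetric matrix to a nearby SPD correlation matrix
#'
#' Eigenvalues are clipped at a small positive floor, the matrix is
#' reconstructed and the diagonal renormalised to 1.
#'
#' @param mat Symmetric matrix.
#' @param eig_floor Eigenvalue floor.
#' @return An SPD matrix with unit diagonal.
#' @export
nearest_spd <- function(mat, eig_floor = 1e-6) {
  mat <- (mat + t(mat)) / 2
  eig <- eigen(mat, symmetric = TRUE)
  if (min(eig$values) < eig_floor) {
    vals <- pmax(eig$values, eig_floor)
    mat <- eig$vectors %*% (vals * t(eig$vectors))
    d <- 1 / sqrt(diag(mat))
    mat <- mat * tcrossprod(d)
    mat <- (mat + t(mat)) / 2
  }
  check <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
  if (check <= 0) {
    stop_sivd("SPD repair failed; minimum eigenvalue ", format(check))
  }
  diag(mat) <- 1
  mat
}

#' Subject-level covariance with planted degradation
#'
#' Applies a uniform multiplicative group factor to the off-diagonal of the
#' base matrix, multiplies planted edges by their attenuation factor raised
#' to `planted_exponent`, adds symmetric zero-mean jitter to the
#' off-diagonal and repairs the result to SPD with unit diagonal.
#'
#' @param base SPD base correlation matrix.
#' @param group_factor Uniform attenuation in (0, 1].
#' @param planted_edges Data frame `i`, `j`, `factor` (optional).
#' @param planted_factor Scalar factor used if `planted_edges` has no
#'   `factor` column.
#' @param planted_exponent Severity exponent applied to the per-edge factors.
#' @param subject_jitter_sd SD of the symmetric jitter.
#' @param seed Seed for the jitter draw.
#' @return An SPD matrix with unit diagonal.
#' @export
subject_covariance <- function(base, group_factor = 1, planted_edges = NULL,
                               planted_factor = NULL, planted_exponent = 1,
                               subject_jitter_sd = 0, seed = NULL) {
  if (group_factor <= 0 || group_factor > 1) {
    stop_sivd("group_factor must lie in (0, 1]")
  }
  n <- nrow(base)
  out <- base
  off <- row(out) != col(out)
  out[off] <- out[off] * group_factor
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    fac <- if ("factor" %in% names(planted_edges)) planted_edges$factor else {
      if (is.null(planted_factor)) stop_sivd("no planted factor given")
      rep(planted_factor, nrow(planted_edges))
    }
    fac <- fac^planted_exponent
    ij <- cbind(planted_edges$i, planted_edges$j)
    out[ij] <- out[ij] * fac
    out[ij[, 2:1, drop = FALSE]] <- out[ij[, 2:1, drop = FALSE]] * fac
  }
  if (subject_jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    jit <- matrix(rnorm(n * n, 0, subject_jitter_sd), n, n)
    jit <- (jit + t(jit)) / 2
    diag(jit) <- 0
    out <- out + jit
  }
  diag(out) <- 1
  nearest_spd(out)
}

#' Simulate a multivariate Gaussian regional time series
#'
#' Draws `n_timepoints` i.i.d. rows from a zero-mean multivariate normal
#' with the given covariance.
#'
#' @param cov SPD covariance matrix.
#' @param n_timepoints Number of rows (>= 2).
#' @param seed Seed for reproducibility.
#' @return A `n_timepoints x n` numeric matrix.
#' @export
simulate_timeseries <- function(cov, n_timepoints, seed = NULL) {
  if (n_timepoints < 2) stop_sivd("need at least two timepoints")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cov)
  chol_f <- chol(cov)
  matrix(rnorm(n_timepoints * n), n_timepoints, n) %*% chol_f
}

# Table-1-style anchors: group mean scores at attenuation 1.00/0.85/0.70
score_anchor <- list(
  MMSE = c(28.5, 24.1, 14.2),
  MoCA = c(28.0, 17.9, 8.9)
)
anchor_attenuation <- c(1.00, 0.85, 0.70)

# clinical scale parameters for the patient groups: mean, sd, range
clinical_scales <- list(
  SIVCIND = list(HIS = c(8.5, 1.8, 7, 12), GDS = c(3.3, 0.7, 2, 5),
                 CDR = c(0.5, 0.2, 0, 0.5), ADL = c(15.0, 3.2, 12, 25)),
  SIVaD = list(HIS = c(8.9, 4.5, 8, 17), GDS = c(4.7, 1.0, 4, 7),
               CDR = c(1.5, 0.7, 1, 3), ADL = c(14.4, 2.5, 12, 19))
)

#' Cognitive and clinical scores for one subject
#'
#' MMSE and MoCA are monotone piecewise-linear functions of the subject's
#' degradation factor through the three group anchor means, plus Gaussian
#' noise, clipped to the instrument range 0-30. Clinical scales (HIS, GDS,
#' CDR, ADL) are drawn within their observed group ranges for patient
#' groups and are `NA` for controls.
#'
#' @param degradation_factor Subject attenuation level in (0, 1].
#' @param group Group label (`"NC"`, `"SIVCIND"`, `"SIVaD"`).
#' @param score_noise_sd Noise SD for MMSE/MoCA.
#' @param seed Seed.
#' @return Named list of scores.
#' @export
generate_scores <- function(degradation_factor, group, score_noise_sd = 1.5,
                            seed = NULL) {
  if (degradation_factor <= 0 || degradation_factor > 1) {
    stop_sivd("degradation factor must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  interp <- function(anchors) {
    # monotone increasing in the attenuation level; affine between anchors
    stats::approx(x = rev(anchor_attenuation), y = rev(anchors),
                  xout = degradation_factor, rule = 2)$y
  }
  clip30 <- function(x) min(30, max(0, x))
  out <- list(
    MMSE = clip30(interp(score_anchor$MMSE) + rnorm(1, 0, score_noise_sd)),
    MoCA = clip30(interp(score_anchor$MoCA) + rnorm(1, 0, score_noise_sd)),
    HIS = NA_real_, GDS = NA_real_, CDR = NA_real_, ADL = NA_real_
  )
  if (group %in% names(clinical_scales)) {
    for (sc in names(clinical_scales[[group]])) {
      p <- clinical_scales[[group]][[sc]]
      out[[sc]] <- min(p[4], max(p[3], rnorm(1, p[1], p[2])))
    }
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Produces one regional time series and one metadata record per subject,
#' plus the ground truth (per-group population covariance, planted edge
#' set, per-subject degradation factors). Fully reproducible given the
#' master seed: all randomness flows through derived sub-seeds.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed.
#' @return A list with elements `timeseries` (list of T x N matrices with
#'   region-name columns), `metadata` (data.frame), and `ground_truth`.
#' @export
#' @examples
#' \donttest{
#' spec <- cohort_spec()
#' cohort <- generate_cohort(spec, seed = 1)
#' table(cohort$metadata$group)
#' }
generate_cohort <- function(spec, seed = 1L) {
  groups <- names(spec$n_per_group)
  n_total <- sum(spec$n_per_group)
  seeds <- derive_seeds(seed, 4L * n_total + 1L)
  base <- make_base_covariance(spec)
  if (!is.null(spec$backbone_edges) && nrow(spec$backbone_edges) > 0) {
    ij <- cbind(spec$backbone_edges$i, spec$backbone_edges$j)
    base[ij] <- spec$backbone_corr
    base[ij[, 2:1, drop = FALSE]] <- spec$backbone_corr
    base <- nearest_spd(base)
  }
  att_min <- min(spec$group_attenuation)
  severity <- function(att) {
    if (att_min >= 1) 0 else max(0, (1 - att) / (1 - att_min))
  }
  # population (noise-free) covariance per group, for ground truth
  group_cov <- lapply(groups, function(g) {
    subject_covariance(base, group_factor = 1,
                       planted_edges = spec$planted_edges,
                       planted_exponent = severity(spec$group_attenuation[[g]]),
                       subject_jitter_sd = 0)
  })
  names(group_cov) <- groups

  subject_id <- sprintf("S%03d", seq_len(n_total))
  group_lab <- rep(groups, times = spec$n_per_group)
  ts_list <- vector("list", n_total)
  meta <- vector("list", n_total)
  degr <- numeric(n_total)
  k <- 0L
  for (s in seq_len(n_total)) {
    g <- group_lab[s]
    set.seed(seeds[k <- k + 1L])
    age <- min(85, max(47, rnorm(1, 67, 7)))
    gender <- rbinom(1, 1, 0.5)
    education <- min(15, max(0, rnorm(1, 8, 3.5)))
    att <- min(1, max(0.4, spec$group_attenuation[[g]] +
                        rnorm(1, 0, spec$attenuation_sd)))
    degr[s] <- att
    t_i <- severity(att)
    shift <- spec$covariate_effect[["age"]] * (age - 67) +
      spec$covariate_effect[["gender"]] * (gender - 0.5) +
      spec$covariate_effect[["education"]] * (education - 8)
    shifted <- base
    off <- row(shifted) != col(shifted)
    shifted[off] <- shifted[off] + shift
    cov_s <- subject_covariance(
      shifted, group_factor = 1, planted_edges = spec$planted_edges,
      planted_exponent = t_i,
      subject_jitter_sd = spec$subject_jitter_sd +
        spec$disorganization_slope * t_i,
      seed = seeds[k <- k + 1L])
    ts <- simulate_timeseries(cov_s, spec$n_timepoints,
                              seed = seeds[k <- k + 1L])
    colnames(ts) <- spec$regions$name
    ts_list[[s]] <- ts
    scores <- generate_scores(att, g, spec$score_noise_sd,
                              seed = seeds[k <- k + 1L])
    meta[[s]] <- data.frame(
      subject_id = subject_id[s], group = g, age = age, gender = gender,
      education = education, MMSE = scores$MMSE, MoCA = scores$MoCA,
      HIS = scores$HIS, GDS = scores$GDS, CDR = scores$CDR, ADL = scores$ADL,
      degradation_factor = att, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  metadata$group <- factor(metadata$group, levels = groups)
  names(ts_list) <- subject_id
  list(
    timeseries = ts_list,
    metadata = metadata,
    ground_truth = list(group_covariance = group_cov,
                        planted_edges = spec$planted_edges,
                        degradation_factor = setNames(degr, subject_id))
  )
}

#' Write a cohort to delimited text files
#'
#' One tab-separated time-series file per subject (T rows x N region
#' columns, header row of region names), a metadata CSV and a ground-truth
#' JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$timeseries)) {
    write.table(cohort$timeseries[[id]],
                file.path(dir, "timeseries", paste0(id, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(planted_edges = gt$planted_edges,
         degradation_factor = as.list(gt$degradation_factor)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
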