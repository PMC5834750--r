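---
title: "Methods: weighted connectome analysis of a graded vascular cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome analysis of a graded vascular cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sivdnet` implements a group-level analysis of resting-state functional
connectomes for a three-group design: normal controls (NC) and two stages
of subcortical ischemic vascular disease, cognitive impairment without
dementia (SIVCIND) and vascular dementia (SIVaD). This vignette documents
the model behind every stage, the tunable parameters and their defaults,
the synthetic cohort that stands in for (undeposited) patient data, and
the numerical choices and limitations a careful user should know about.

## From time series to weighted networks

Each subject contributes a T x N matrix of regional BOLD-like signals
(default T = 230 volumes at a 2 s sampling interval, N = 90 regions of an
automated-anatomical-labelling style parcellation; the packaged region
table assigns every region a hemisphere and one of six lobe groups:
frontal, temporal, parietal, medial temporal, occipital, subcortical).

1. **Optional band-pass** (`bandpass()`, 0.01-0.08 Hz): zero-phase
   frequency-domain masking with a raised-cosine transition band
   (default width 0.004 Hz). The DC component is always removed. The
   filter is off by default for synthetic cohorts, whose signals are
   temporally white by construction; it exists for data that still carry
   scanner drift or high-frequency physiological noise.
2. **Pearson connectivity** (`pearson_connectivity()`): the N x N
   correlation matrix of the regional signals. Zero-variance regions are
   an error, reported by name.
3. **Fisher r-to-z** (`fisher_z()`): `z = atanh(r)` off the diagonal,
   variance-stabilising the correlations; values within 1e-7 of +/-1 are
   clipped first, and the diagonal is set to 0.
4. **Covariate correction** (`regress_covariates()`): for every edge,
   ordinary least squares of the z-weights on mean-centred age, gender
   and education across all subjects in one pooled model; the corrected
   weight is the residual plus the fitted intercept. Centring makes the
   intercept the cohort-mean prediction, so corrected weights stay on the
   Fisher-z scale (a requirement of the positive-weight metrics
   downstream). The correction is an idempotent projection; constant
   covariates are dropped with a warning.

## Proportional thresholding and the sparsity sweep

`threshold_sparsity()` retains the `K = round(s * N(N-1)/2)` largest
signed weights at sparsity `s` (rounding half away from zero; at N = 90
and s = 0.10, K = 401). Ties at the cutoff are broken by ascending region
index pair, which makes the edge set deterministic and order-independent.
If a non-positive weight would be retained the function stops: the
weighted metric formulas (cube roots of weights, reciprocal-weight
distances) require positive weights. An absolute-value mode, which ranks
and stores `|w|`, is available for strongly negative matrices. The default
sweep (`sparsity_sweep()`) covers 10-40% in 1% increments — 31 nested
edge sets per subject.

## Weighted graph metrics

All metrics operate on a graph whose weights have been **scaled by their
mean** (`scale_weights()`), so that every subject's retained network has
mean edge weight 1. Together with proportional thresholding this controls
"cost": every subject contributes the same number of edges and the same
total weight, and group differences reflect the *pattern* of strong and
weak connections, not their overall level.

* **Clustering coefficient** `Cp` (Onnela form): per node,
  `C_i = 2/(k_i(k_i-1)) * sum over connected neighbour pairs {j,k} of
  (w_ij w_jk w_ki)^(1/3)`; nodes of degree < 2 contribute 0. `Cp` is the
  node average — functional segregation.
* **Shortest paths**: edge distance is the reciprocal scaled weight
  (strong connections are short). A literal mode (`distance = w`) is
  provided for comparison because the field's formula sheets sometimes
  write path length as a sum of edge weights; reciprocal distances are
  the default since summing similarity weights would make strong
  connections look distant, contradicting the efficiency interpretation.
  Paths come from Floyd-Warshall in compiled code.
* **Characteristic path length** `Lp`: mean shortest path over connected
  ordered pairs. Disconnected pairs are excluded and flagged; an edgeless
  graph is an error.
* **Global efficiency** `Eg` and nodal `E_nodal_glob(i) = mean_j 1/L_ij`
  with `1/Inf = 0` — functional integration, robust to disconnection.
* **Local efficiency** `Eloc` and nodal `E_nodal_loc(i)`: the global
  efficiency of the subgraph induced on i's neighbours (i removed),
  carrying the original scaled weights and normalised by the subgraph's
  own node count; nodes with fewer than two neighbours contribute 0.

Each metric traced over the 31 thresholds is summarised by its
**area under the curve** (trapezoidal rule, exact for linear curves),
giving one threshold-independent scalar per subject and metric
(`subject_metrics()`, `cohort_metrics()`).

A property worth knowing: adding an edge can *decrease* local efficiency
(the endpoint neighbourhoods grow without gaining internal connectivity),
so `Eloc` is not monotone under edge addition even though `Eg` is. This
neighbourhood-dilution effect is real — the synthetic degradation model
uses it — and is why the package's property tests assert edge-addition
monotonicity for `Eg` only.

## Network-based statistic

`nbs_test()` performs edge-wise inference with family-wise error control
by component size. For the omnibus design, a classical one-way ANOVA F is
computed at every edge; edges with uncorrected p < 0.005 are kept and
decomposed into connected components, whose size is their **edge count**.
Shuffling group labels (preserving group sizes) 10000 times and recording
the maximal component size per permutation yields the null distribution;
a component of size M gets corrected p = (number of permutation maxima
>= M) / n_perm. The `>=` convention is the default (a strict `>` mode is
available); corrected p-values are integer multiples of 1/n_perm.
Post hoc one-tailed t contrasts (`posthoc_pairwise()`) re-run the
procedure per group pair, by default restricted to the edge mask of the
omnibus-significant network; the unrestricted variant is a switch. The
permutation loop shuffles labels only — the covariate correction happens
once, upstream, in the pipeline's order of operations. Edge statistics
are threshold-compared on the statistic scale (F or t against the
critical value), which is equivalent to p < alpha and avoids recomputing
tail probabilities inside the loop. Hubs of the significant network are
nodes whose degree exceeds the mean by strictly more than one standard
deviation, computed over all N nodes including zero-degree ones; edges
are typed left/right-intrahemispheric or interhemispheric from the region
table.

## Group statistics

AUC metrics are compared with **Welch's heteroscedastic ANOVA** (the
design anticipates unequal group variances, which `levene_test()` —
mean-centred — checks), preceded by a **Lilliefors-type normality check**
(Kolmogorov-Smirnov distance to a normal with estimated moments; because
estimating the moments invalidates the classical KS null, the p-value is
calibrated by seeded Monte-Carlo simulation, 1999 draws by default).
Significant omnibus tests are followed by **Games-Howell** pairwise
comparisons (Welch standard error and degrees of freedom per pair,
studentized-range reference with k groups); a gated mode (default)
follows the "main effect first" convention, an exploratory mode runs all
pairs. Multiplicity is handled by Benjamini-Hochberg within explicit
families: the 4 global metrics, each 90-region nodal family, and the 8
metric-by-score correlations. **Spearman correlations** between the four
global AUCs and MMSE/MoCA are computed in the pooled patient sample, with
scores z-scored within that sample (rank-invariant, retained for
comparability of reported effect sizes).

## Classification

`adaboost_fit()` implements multiclass adaptive boosting with the SAMME
weight update over `rpart` decision trees; with two classes it reduces to
classical AdaBoost. The default weak learner is a stump (depth 1) — with
four predictors and fewer than sixty subjects, deeper trees overfit
quickly; depth is configurable. One hundred learning cycles are the
default; boosting stops early if a weak learner reaches zero weighted
error or violates the SAMME condition (error >= 1 - 1/k). Evaluation is
leave-one-out cross-validation (`loocv_adaboost()`); per-class
sensitivity and specificity are one-vs-rest readings of the pooled
confusion matrix.

## The synthetic cohort and its planted truth

No subject-level recordings are publicly available for this design, so
`generate_cohort()` simulates the study: 19 NC / 20 SIVCIND / 20 SIVaD
subjects, each a 230 x 90 Gaussian time series drawn from a subject-level
correlation matrix, plus demographics (age ~ N(67, 7^2) clipped to
47-85; gender Bernoulli(0.5); education ~ N(8, 3.5^2) clipped to 0-15)
and cognitive scores.

The population model is a six-lobe block correlation matrix (0.45 within,
0.25 between lobes) plus a deterministic **rich-club backbone**: a few
hub regions per lobe, fully interconnected across lobes at r = 0.45.
These hub-to-hub edges are the strong long-range shortcuts that keep the
intact network integrated at low sparsity; because they interconnect,
they carry their own triangle support and do not dilute local coherence.

Degradation is planted per edge. Each planted edge has a full-severity
attenuation factor f; a subject at severity t multiplies it by `f^t`,
where t maps the group attenuation level (NC 1.00, SIVCIND 0.85, SIVaD
0.70, each jittered per subject with SD 0.02) to 0, 0.5 and 1. The
default planted set stages the loss in extent as well as depth:

* half the backbone falls early (f = 0.09: below the retention cutoff
  already at SIVCIND severity) and half late (f = 0.55: lost only at
  SIVaD severity);
* a "lesion patch" — every third frontal/temporal/parietal region —
  likewise splits into an early half (all edges, f = 0.15) and a late
  half (f = 0.50);
* the remaining between-lobe edges touching the affected lobes carry
  f = 0.45.

Severity additionally scales a symmetric jitter on the subject covariance
(SD 0.01 + 0.04 t, "disorganisation"), which erodes neighbourhood
coherence and hence local efficiency. Cognitive scores are monotone
piecewise-linear functions of the subject's attenuation level through
the three group anchor means (MMSE 28.5/24.1/14.2, MoCA 28.0/17.9/8.9),
plus Gaussian noise (SD 1.5), clipped to 0-30; clinical scales
(HIS/GDS/CDR/ADL) are drawn within their observed patient-group ranges
and are absent for controls. Small additive covariate effects on the
edges (age -0.0015/y, gender 0.01, education 0.002/y) give the covariate
regression something real to remove. All randomness flows from one
master seed through derived sub-seeds; identical spec + seed reproduces
the cohort exactly.

Two design points deserve emphasis, because they are easy to get wrong:

* **Uniform attenuation is invisible.** Mean-weight scaling and
  proportional thresholding cancel any uniform multiplicative factor on
  the edges, so "multiply everything by 0.85" plants nothing the metrics
  can see. Worse, lowering all true correlations toward the sampling
  noise floor makes the thresholded graph more *random*, and random
  graphs are efficient — naive uniform degradation *raises* measured
  efficiency. The group factor therefore defaults to 1 and all
  degradation lives in the planted structure and the jitter.
* **Staging by extent, not only depth.** Because `f^t` spends most of
  its drop early (for small f, `f^0.5` is already far down) and an edge
  contributes nothing further once it leaves the retained set, a single
  deep factor saturates by mid-severity. Splitting each target into an
  early and a late tranche makes integration decline across the whole
  severity course, which is what gives the intermediate group its own
  measurable deficit.

What the generator does **not** emulate: hemodynamics and temporal
autocorrelation (rows are i.i.d.; the band-pass stage is therefore off by
default), head-motion and physiological artefacts, spatial smoothness of
the parcellation, negative-correlation structure, and subject-level
lesion geography. Passing tests on this cohort demonstrate that the
pipeline recovers a known planted degradation under realistic sampling
noise at the study's sample sizes — not that any particular clinical
effect size will replicate in real recordings.

## Numerical choices and degenerate inputs

* SPD repair (`nearest_spd()`): eigenvalues clipped at 1e-6, matrix
  reconstructed, diagonal renormalised to 1; failure to reach positive
  definiteness reports the offending eigenvalue.
* Edge-count rounding: half away from zero; cutoff ties broken
  lexicographically.
* Fisher clipping at |r| = 1 - 1e-7; correlations of constant columns
  are an error upstream.
* Degree-< 2 nodes: clustering and local efficiency 0 by definition (the
  normalisations divide by k(k-1)).
* Disconnected pairs: excluded (and flagged) in `Lp`, contribute 0 to
  efficiencies. At 10% sparsity disconnected nodes are common — this is
  a property of proportional thresholding, not an error.
* Corrected NBS p-values never fall below 1/n_perm with the default
  `>=` tie convention.
* Classifier ties in the weighted vote resolve to the first class level,
  keeping predictions deterministic.

## Problem sizes used by the packaged checks

The packaged validation suite exercises the pipeline at deliberately
modest sizes chosen to make the Monte-Carlo properties sharp without
excessive runtime: metric kernels against brute-force oracles on 200
random graphs of up to 12 nodes; NBS type-I calibration on 200 null
cohorts (two groups of 15, 90 nodes, 500 permutations); planted-component
recovery on 50 cohorts (10-edge component, standardized effect 1.5,
n = 20 + 20, 1000 permutations); and 40 full synthetic cohorts for the
end-to-end ordering check. The analysis scripts under `analysis/` run the
full study once at the reference sizes (59 subjects, 31 thresholds,
10000 permutations).

## Known limitations

* Pooled covariate regression assumes a common covariate effect across
  groups; group-specific slopes would require an interaction model the
  reference design does not use.
* The NBS component threshold (0.005) is a sensitivity parameter of the
  method itself; results at other thresholds are not nested in any
  simple way.
* Games-Howell p-values rely on the studentized-range approximation and
  are approximate for very small groups (n < 6).
* The boosted classifier reports resubstitution-free LOOCV accuracy but
  no confidence intervals; with 59 subjects a single accuracy figure has
  wide sampling error.
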