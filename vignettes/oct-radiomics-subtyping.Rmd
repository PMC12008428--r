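---
title: "Unsupervised OCT radiomics subtyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised OCT radiomics subtyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octomics)
```

## The problem

Diabetic macular edema (DME) eyes respond very unevenly to intravitreal
anti-VEGF therapy: a large fraction retain residual fluid after the loading
injections or relapse within months (RDME), and many keep poor visual acuity.
`octomics` implements an unsupervised stratification pipeline for this
setting: quantitative texture ("radiomics") features are extracted from
pre-treatment OCT B-scans inside a manually delineated inner-retina region of
interest, the feature space is reduced with permutation-calibrated PCA, eyes
are partitioned with a hybrid of Ward hierarchical clustering and K-means,
the partition's robustness is quantified by bootstrap and noise injection,
and a three-stage selection cascade plus logistic models connect individual
texture features to the two clinical endpoints (RDME; poor vision, defined
as 6-month BCVA of 20/63 or worse).

Because no patient images ship with the package, a synthetic cohort
generator (`generate_cohort()`) renders B-scan-like images with the motifs
the texture features are supposed to detect — dark cystoid ellipses, bright
hyperreflective foci, a layered reflectivity profile with smooth disruption —
so that every stage of the pipeline is exercised end to end by code alone.

## Feature extraction

`extract_features()` computes, per masked image, 18 first-order statistics,
9 two-dimensional shape descriptors (mask only) and the five matrix families
(GLCM, GLRLM, GLSZM, GLDM, NGTDM) on the original image and on filtered
derivatives: a single-level Coiflet-1 separable wavelet transform (four
subbands, upsampled back to the input shape), Laplacian-of-Gaussian at
configurable sigmas, the rescaled point maps (logarithm, exponential, square,
square root), a first-difference gradient magnitude, and a
rotation-invariant uniform local binary pattern code image (radius 1, 8
points). Column names carry full provenance
(`logarithm_gldm_DependenceVariance`, `wavelet-LH_firstorder_Mean`,
`log-sigma-3-mm-3D_glcm_Imc1`), matching the naming conventions of the
standard extraction engines so that published biomarker names map directly
onto columns. The full default schema yields 1,218 columns; published
category counts for such pipelines are internally inconsistent, so the
package guarantees schema determinism (the column set depends only on the
configuration), not any particular total.

Key conventions, all configurable:

* **Discretization** — fixed bin width (default 25 on the 8-bit scale),
  `level = floor((x - min) / bin_width) + 1`. Applied identically to
  filtered derivatives; the LBP code image (integers 0–9) uses bin width 1,
  since a width of 25 would collapse it to a single level.
* **GLCM** — distance 1, the four unique 2D directions, symmetric
  accumulation, per-direction normalization, feature values averaged over
  directions. Same aggregation for GLRLM.
* **GLSZM** — zones are 8-connected components of equal level.
* **GLDM** — `alpha = 0`, 8-neighbourhood; neighbours outside the mask are
  excluded. Dependence size is defined as 1 + the number of dependent
  neighbours (the center counts as dependent on itself), so the
  small-dependence emphasis terms are always finite.
* **GLRLM** — the full standard set of 16 run-length features.
* **Degenerate (constant) regions** — correlation-type GLCM features,
  skewness/kurtosis, and the NGTDM ratios are set to documented constants
  and flagged via the `"flagged"` attribute instead of propagating NaN into
  downstream z-scoring.
* **LoG sigma** — given in millimetres and converted through the pixel
  spacing; values below one pixel or above a quarter of the image side are
  clamped with a warning, since such kernels carry no usable band-pass
  information at the image scale.
* **Shape** — area and perimeter come from a marching-squares mesh of the
  binary mask (iso-level 0.5, edge midpoints). Binary meshing carries an
  irreducible staircase bias: the mesh perimeter of a rasterized disk of
  radius 20 px is about 5% above $2\pi r$, so the sphericity of a disk
  plateaus near 0.95 rather than 1. This is a property of meshing binary
  masks, shared by the standard engines, not an implementation error.

Every matrix-family feature is verified against an exhaustive brute-force
enumeration (explicit pair counting, line walking, flood fill, per-pixel
neighbourhood loops) on random small regions to a relative tolerance of
1e-9; the test suite runs 100 such regions per family.

## Dimensionality reduction and component retention

Features are z-scored (`zscore_features()`; zero-variance columns are
dropped with a warning) and decomposed by PCA (`fit_pca()`, SVD of the
centered matrix, sample covariance, component signs fixed so the
largest-magnitude loading is positive). The number of retained components is
chosen by Horn's parallel analysis (`parallel_analysis()`): each of
`n_perm` null tables permutes every column independently — preserving all
marginal distributions while destroying correlation — and component *k* is
retained while its observed eigenvalue exceeds the 95th percentile of the
null distribution of the *k*-th eigenvalue, stopping at the first failure
(the leading-consecutive convention). A fresh-Gaussian null is available as
an alternative (`null = "gaussian"`); column permutation is the default
because it is distribution-free. Calibration is part of the acceptance
suite: on 200 x 50 pure-noise tables the procedure retains zero components
in ≈98/100 seeds, and recovers exactly 3 planted factors in ≈100/100 seeds
at `n_perm = 200`.

## Clustering and choosing k

`hybrid_cluster()` defines the hybrid of the two parent methods
deterministically: Ward clustering (`ward.D2` on Euclidean distances) cut at
*k* provides the initial centroids for a single Lloyd K-means run, and the
converged K-means labels are reported together with the ARI between hybrid
and pure-Ward partitions as an auditable concordance. Stand-alone K-means
uses k-means++ seeding, best of `n_init` starts. Labels are canonicalized by
decreasing cluster size.

Two criteria choose *k* and must agree in `run_pipeline(k = "auto")`:

* **Elbow** (`elbow_select_k()`) — the *k* maximizing the second forward
  difference of the within-cluster sum-of-squares curve, i.e. the sharpest
  levelling-off point. Exactly tied (degenerate) curves resolve to the
  smallest candidate with a low-confidence flag.
* **Consensus CDF delta-area** (`consensus_select_k()`) — Monti-style
  consensus over subsamples (default 100 resamples at 80%, K-means with a
  single k-means++ start as the base clusterer, as in the original
  formulation; a best-of-n base clusterer makes splits of a true cluster
  artificially consistent and biases the curve toward larger k). `A(k)` is
  the area under the empirical CDF of off-diagonal consensus values and the
  chosen k is the largest candidate whose relative gain
  `delta(k) = (A(k) - A(k-1))/A(k-1)` exceeds 0.1.

## Stability validation

`bootstrap_stability()` resamples rows with replacement and refits the
entire pipeline from scratch on each replicate (z-score, PCA retaining
`n_pcs` components, K-means at *k*), comparing replicate labels with the
original partition restricted to the resampled instances, duplicates counted
with multiplicity (a flag switches to unique instances). The adjusted Rand
index is computed from the contingency-table closed form and is verified in
the tests against an explicit O(n²) pair-classification oracle and against
an independent implementation. `noise_sensitivity()` adds zero-mean Gaussian
noise either to the z-scored feature table (sigma in z-units, fast) or to
the [0,1]-scaled image intensities with full re-extraction (sigma on the
intensity scale, faithful to imaging noise but costly); the output states
its domain, since the two sigma scales are not comparable.

## Feature selection and outcome models

The cascade (`select_features()`) is: (1) greedy collinearity pruning at
|r| > 0.8 — the member of the worst offending pair with the larger mean
absolute correlation to all other retained features is dropped, ties by
column order, so the result is deterministic and pairwise-decorrelated;
(2) one-way ANOVA screening across cluster labels at P < 0.05 (raw by
default; a flag switches to Benjamini-Hochberg, since both conventions are
common); (3) Boruta against a binary endpoint — per iteration a permuted
shadow copy of every active feature is appended, a ranger random forest
(impurity importance) is fit, features beating the maximum shadow importance
score a hit, and accumulated hits are tested two-sidedly against
Binomial(iterations, 1/2) with Bonferroni correction across the undecided
features; rejected features leave the model, and leftover tentatives are
resolved at termination by comparing median importance against the median
per-iteration shadow maximum.

A known property of all-relevant selection deserves emphasis: on a fixed
finite sample, the feature with the largest *chance* association with the
outcome is genuinely informative in-sample and will beat fresh shadows
persistently, so Boruta confirms a small number of features even on pure
noise at any sample size we examined. The tests therefore assert the
realistic null behaviour (the large majority of null features rejected)
and the power behaviour (all five planted predictors confirmed and ≥ 90/95
noise features rejected at n = 300), not a zero false-positive rate.

Outcome models: `univariate_logistic()` and
`backward_stepwise_logistic()` (entry at univariate P < 0.1, backward
removal while any Wald P ≥ 0.05) with odds ratios and 95% Wald intervals;
quasi-complete separation is flagged with an infinite-OR sentinel rather
than reported as a finite estimate. `compare_clusters()` reproduces the
usual baseline table: Shapiro-Wilk, Kruskal-Wallis with Dunn's
Bonferroni-corrected post-hoc z-tests for continuous variables, chi-square
switching to Fisher's exact test when any expected cell is below 5 for
categorical ones. `icc_intra_rater()` is the two-way mixed-effects,
consistency, single-measure ICC with its F-based confidence interval.

Endpoints are encoded exactly as used clinically: residual DME is a CMT
reduction below 10/15/20/25% for baselines ≤ 400 / 401–500 / 501–600 /
> 600 µm (worsening counts as residual — the clinically forced reading),
RDME is residual OR recurrence within 6 months, and
poor vision is logMAR ≥ log10(63/20), the 20/63 boundary inclusive.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()` defaults encode the reference cohort structure the
pipeline targets: 234 eyes, four phenotypes with shares 122/45/32/35 of
234, RDME link probabilities 59.0/68.9/59.4/34.3% and poor-vision link
probabilities 57.4/60.0/65.6/28.6% per class (these counts also ship as
`inst/extdata/reference_cohort_counts.csv`). Per class the generator
controls cyst density and radius, focus density, layer-disruption
amplitude, and base reflectivity; clinical covariates are drawn around
plausible clinic values (baseline CMT lognormal around class medians of
roughly 290–540 µm), and the CMT / acuity values are synthesized to be
*exactly* consistent with the drawn endpoint labels under the rules above,
which the tests verify by round-trip.

Two presets define benchmark conditions:

* `"high_separation"` — class motifs arranged so the four phenotypes are
  essentially perfectly separable (reflectivity splits two pairs; cyst load
  and focus/disruption load split within pairs), with mildly unbalanced
  shares (35/25/20/20%): minority groups large enough for stable recovery
  without a single dominating cluster. This preset is the planted-partition
  benchmark: hybrid clustering must recover the classes at ARI ≥ 0.95 and
  both k-selection criteria must return 4.
* `"null"` — all classes share identical texture parameters; recovered-label
  ARI against the (meaningless) class labels must sit at chance.

What the generator deliberately does **not** model: OCT speckle statistics
and device optics, 3D volume context, bilateral within-patient correlation
(eyes are sampled independently, as in the eye-level analyses it emulates),
and full covariate distributions (location only). Passing tests therefore
demonstrate that the pipeline machinery is correct and well calibrated on
data with planted structure of the intended kind — not that the specific
biomarkers would validate on real OCT scans.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's own defaults for simulation studies: 64 x 64-pixel
synthetic scans with the reduced extraction preset (original + gradient +
square-root images; first-order + GLCM + GLDM families) for the 120-eye
planted-recovery benchmark; 100 seeds at `n_perm = 200` for the
parallel-analysis calibration; B = 100 bootstrap resamples; 200 Boruta
iterations with 500-tree forests; n = 5,000 for single-coefficient logistic
recovery. Full-schema extraction (1,218 features) on a 128 x 128 image takes
well under a second per eye, so cohort-scale runs with the complete filter
bank remain practical.

Reproducibility: every stochastic routine takes an explicit seed, restores
the caller's RNG state on exit, and `run_pipeline()` derives all stage
seeds from one master seed; identical configuration and seed reproduce
byte-identical outputs, which the test suite asserts.

## Known limitations

* 2D only: single B-scans, no volumetric features or resampling.
* The feature-count bookkeeping of published OCT radiomics pipelines cannot
  be reproduced exactly (their stated totals are internally inconsistent);
  the schema here is deterministic and documented instead.
* Boruta's all-relevant semantics imply a nonzero false-confirmation rate on
  finite samples (see above).
* The consensus delta-area threshold (0.1) and the elbow's second-difference
  rule are heuristics; `run_pipeline()` requires their agreement and warns
  on disagreement rather than silently trusting either.
* Eye-level analysis: no mixed-effects correction for bilateral eyes.
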