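# octomics

Unsupervised stratification of diabetic macular edema (DME) eyes from OCT
B-scan radiomics, in R.

A substantial fraction of DME eyes respond poorly to intravitreal anti-VEGF
therapy — residual or early-recurrent edema (RDME) after the loading
injections, or persistently poor visual acuity. `octomics` implements the
full unsupervised analysis that stratifies eyes into treatment-response
subtypes from *pre-treatment* imaging alone:

1. **Radiomic feature extraction** from masked B-scans: 18 first-order
   statistics, 9 2D shape descriptors, and the GLCM / GLRLM / GLSZM / GLDM /
   NGTDM texture families on the original image and on filtered derivatives
   (Coiflet-1 wavelet subbands, Laplacian of Gaussian, logarithm,
   exponential, square root, square, gradient magnitude, LBP). Fixed-bin-
   width discretization `level = floor((x − min)/w) + 1`; matrix features
   aggregated over the four 2D directions.
2. **Dimensionality reduction**: z-scoring and PCA with component retention
   by Horn's parallel analysis — component *k* is kept while its eigenvalue
   λ<sub>k</sub> exceeds the 95th percentile of eigenvalues from tables with
   independently permuted columns.
3. **Clustering**: hybrid partition (Ward's minimum-variance tree provides
   the initial centroids for Lloyd K-means), with *k* chosen jointly by the
   WSS elbow (max second forward difference) and Monti-style consensus
   clustering (largest *k* whose CDF area gain Δ(k) = (A(k) − A(k−1))/A(k−1)
   exceeds 0.1).
4. **Stability validation**: bootstrap resampling with full pipeline refit,
   agreement measured by the adjusted Rand index
   ARI = (Index − E\[Index\])/(Max − E\[Index\]), plus incremental Gaussian
   noise-injection curves.
5. **Feature selection and outcome models**: collinearity pruning
   (|r| > 0.8), one-way ANOVA screening across clusters (P < 0.05), Boruta
   shadow-feature selection per endpoint, then univariate and backward
   stepwise logistic regression (entry P < 0.1, stay P < 0.05) reporting
   OR = e<sup>β</sup> with 95% Wald intervals; cluster-comparison tables
   (Kruskal–Wallis + Dunn, chi-square/Fisher) and intra-rater ICC(3,1).

No patient data ships with the package: a synthetic cohort generator
renders B-scan-like images (dark cystoid ellipses, bright hyperreflective
foci, layered reflectivity with smooth disruption) with class-linked
clinical outcomes, so the whole pipeline is testable end to end. See the
methods vignette (`vignettes/oct-radiomics-subtyping.Rmd`) for the model
details, conventions, and design decisions.

## Worked example

```r
library(octomics)

cfg   <- cohort_preset("high_separation", n_eyes = 60,
                       image_size = c(64, 64), seed = 7)
coh   <- generate_cohort(cfg)                       # 60 synthetic eyes
feats <- extract_cohort(coh, reduced_extraction_config())
dim(feats)
#> [1]  60 168

z  <- zscore_features(feats)
pa <- parallel_analysis(z, n_perm = 200, seed = 2)
pa$n_retained
#> [1] 3

pc     <- fit_pca(z)
scores <- as.matrix(z) %*% pc$loadings[, 1:pa$n_retained]
round(100 * sum(pc$explained[1:pa$n_retained]), 1)  # cumulative variance
#> [1] 91.2

cs <- consensus_select_k(scores, seed = 3)
cs$k
#> [1] 4
cl <- hybrid_cluster(scores, cs$k, seed = 4)
table(cl$labels)
#>  1  2  3  4
#> 21 15 12 12
adjusted_rand_index(cl$labels, coh$clinical$true_class)
#> [1] 1

st <- bootstrap_stability(feats, cl$labels, n_pcs = pa$n_retained,
                          k = cs$k, B = 50, seed = 5)
sprintf("bootstrap ARI: %.2f +/- %.2f", st$mean, st$sd)
#> [1] "bootstrap ARI: 1.00 +/- 0.00"
```

Reading the output: parallel analysis keeps 3 components (91.2% of the
variance) for this strongly separated 4-class benchmark cohort; consensus
clustering picks k = 4; the hybrid Ward/K-means partition reproduces the
planted classes exactly (ARI 1 against the generator's labels), and the
partition is perfectly stable under bootstrap refitting. On weakly
structured data the same calls return fractional ARIs and smaller retained
dimensions — the point of the stability step.

`run_pipeline(coh, pipeline_config(...), out_dir = "run1/")` chains all of
the above plus feature selection, the logistic outcome models, and
cluster-wise clinical comparison tables, and writes CSV/JSON outputs with a
short markdown report.

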