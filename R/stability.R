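#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement from the contingency-table
#' closed form; permutation-invariant in the labels of either side, range
#' `[-1, 1]`, 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length (>= 2).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 items")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  npairs <- choose(length(a), 2)
  expected <- ai * bj / npairs
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (nij - expected) / (maxidx - expected)
}

#' Bootstrap stability of the clustering pipeline
#'
#' Draws `B` bootstrap resamples of the rows of a feature table; on each
#' resample the full downstream pipeline is refit from scratch (z-scoring,
#' PCA retaining `n_pcs` components, K-means at `k`) and the agreement with
#' the original partition, restricted to the resampled instances (duplicates
#' counted with multiplicity), is measured with the adjusted Rand index.
#' With `unique_instances = TRUE` duplicates are collapsed before comparison.
#'
#' @param table Raw feature table (eyes x features).
#' @param labels_orig Original cluster labels, one per row of `table`.
#' @param n_pcs Principal components retained per replicate.
#' @param k Number of clusters.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param unique_instances Collapse duplicated rows before the ARI.
#' @return `oct_stability` list: `ari` (length <= B; degenerate replicates
#'   with fewer than `k` distinct rows are skipped and counted in
#'   `n_skipped`), `mean`, `sd`, `ci` (2.5-97.5 percentile interval).
#' @export
bootstrap_stability <- function(table, labels_orig, n_pcs = 16, k = 4,
                                B = 500, seed = 1, unique_instances = FALSE) {
  if (B < 1) stop("B must be >= 1")
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < k) stop("need at least k rows")
  if (length(labels_orig) != n) stop("labels must match rows")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  aris <- numeric(0); skipped <- 0L
  for (b in seq_len(B)) {
    ix <- sample.int(n, n, replace = TRUE)
    if (length(unique(ix)) < k) { skipped <- skipped + 1L; next }
    xb <- x[ix, , drop = FALSE]
    rownames(xb) <- NULL
    zb <- suppressWarnings(zscore_features(xb))
    pc <- fit_pca(zb)
    np <- min(n_pcs, ncol(pc$loadings))
    sc <- as.matrix(zb) %*% pc$loadings[, seq_len(np), drop = FALSE]
    cl <- kmeans_cluster(sc, k, seed = sample.int(2^30, 1))$labels
    ref <- labels_orig[ix]
    if (unique_instances) {
      keep <- !duplicated(ix)
      aris <- c(aris, adjusted_rand_index(cl[keep], ref[keep]))
    } else {
      aris <- c(aris, adjusted_rand_index(cl, ref))
    }
  }
  structure(list(
    ari = aris,
    mean = mean(aris), sd = stats::sd(aris),
    ci = stats::quantile(aris, c(0.025, 0.975), names = FALSE),
    B = B, n_skipped = skipped, n_pcs = n_pcs, k = k
  ), class = "oct_stability")
}

#' Cluster stability under incremental noise injection
#'
#' Adds zero-mean Gaussian noise of increasing standard deviation and
#' measures how well the re-derived partition matches the clean one. Two
#' domains: `"feature"` perturbs the z-scored feature table directly (sigma
#' in z-units); `"image"` perturbs the \[0,1\]-scaled image intensities and
#' re-extracts features (sigma on the \[0,1\] intensity scale), which mirrors
#' imaging noise but costs a re-extraction per replicate.
#'
#' @param x For `domain = "feature"`: raw feature table. For
#'   `domain = "image"`: an `oct_cohort`.
#' @param sigma_grid Non-negative ascending noise SDs.
#' @param reps Replicates per sigma.
#' @param domain `"feature"` or `"image"`.
#' @param k Clusters; `n_pcs` components retained.
#' @param n_pcs Principal components retained.
#' @param seed Integer seed.
#' @param config Extraction configuration (image domain only).
#' @return Data frame with columns `sigma`, `mean_ari`, `sd_ari`, plus
#'   attribute `domain`.
#' @export
noise_sensitivity <- function(x, sigma_grid, reps = 20,
                              domain = c("feature", "image"), k = 4,
                              n_pcs = 16, seed = 1,
                              config = reduced_extraction_config()) {
  domain <- match.arg(domain)
  if (any(sigma_grid < 0)) stop("sigma_grid must be non-negative")
  if (is.unsorted(sigma_grid)) stop("sigma_grid must be ascending")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  feat <- if (domain == "feature") as.matrix(x) else as.matrix(extract_cohort(x, config))
  cluster_table <- function(tab, sd_seed) {
    zb <- suppressWarnings(zscore_features(tab))
    pc <- fit_pca(zb)
    np <- min(n_pcs, ncol(pc$loadings))
    sc <- as.matrix(zb) %*% pc$loadings[, seq_len(np), drop = FALSE]
    kmeans_cluster(sc, k, seed = sd_seed)$labels
  }
  clean <- cluster_table(feat, 1)

  rows <- lapply(sigma_grid, function(s) {
    aris <- vapply(seq_len(reps), function(r) {
      tab <- if (domain == "feature") {
        z <- as.matrix(suppressWarnings(zscore_features(feat)))
        z + matrix(stats::rnorm(length(z), sd = s), nrow(z))
      } else {
        noisy <- lapply(x$eyes, function(e) {
          img01 <- e$image / 255
          img01 <- pmin(pmax(img01 +
            matrix(stats::rnorm(length(img01), sd = s), nrow(img01)), 0), 1)
          e$image <- round(img01 * 255)
          e
        })
        as.matrix(extract_cohort(noisy, config))
      }
      labs <- cluster_table(tab, sample.int(2^30, 1))
      adjusted_rand_index(labs, clean)
    }, numeric(1))
    data.frame(sigma = s, mean_ari = mean(aris), sd_ari = stats::sd(aris))
  })
  out <- do.call(rbind, rows)
  attr(out, "domain") <- domain
  out
}
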