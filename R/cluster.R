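#' K-means clustering with k-means++ seeding
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ starting centers;
#' the best of `n_init` seedings by within-cluster sum of squares is kept.
#' Labels are canonicalized by decreasing cluster size (cluster 1 is the
#' largest), matching the reporting convention for patient subgroups.
#'
#' @param scores Numeric matrix (rows = eyes).
#' @param k Number of clusters (`1 <= k <= n`).
#' @param seed Integer seed.
#' @param n_init Number of independent seedings.
#' @return `oct_clusters` object: `labels`, `k`, `inertia`, `centers`,
#'   `method`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1, n_init = 10) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k > n) stop("k cannot exceed the number of rows")
  if (k < 1) stop("k must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # degenerate input: fewer distinct rows than clusters
  key <- apply(scores, 1, paste, collapse = "\r")
  ids <- match(key, unique(key))
  if (max(ids) <= k) {
    labels <- split_to_k(ids, k)
    return(new_clusters(labels, k, within_ss(scores, labels), "kmeans"))
  }
  best <- NULL
  for (i in seq_len(n_init)) {
    ctrs <- kmeanspp_centers(scores, k)
    fit <- suppressWarnings(
      stats::kmeans(scores, centers = ctrs, iter.max = 100,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  new_clusters(best$cluster, k, best$tot.withinss, "kmeans", best$centers)
}

# k-means++ seeding: weighted sampling by squared distance to nearest center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  d2 <- rep(Inf, n)
  for (j in seq_len(k - 1)) {
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
    if (all(d2 == 0)) {
      idx <- c(idx, sample.int(n, k - j))   # duplicated points: pad arbitrarily
      break
    }
    idx <- c(idx, sample.int(n, 1, prob = d2))
  }
  x[idx[seq_len(k)], , drop = FALSE] + 0  # force matrix copy
}

# grow a partition of m <= k identity groups to exactly k nonempty clusters
# by splitting the largest groups (duplicated points are interchangeable)
split_to_k <- function(ids, k) {
  labels <- ids
  nxt <- max(ids) + 1L
  while (nxt <= k) {
    big <- which.max(tabulate(labels))
    members <- which(labels == big)
    labels[members[1]] <- nxt
    nxt <- nxt + 1L
  }
  labels
}

new_clusters <- function(labels, k, inertia, method, centers = NULL) {
  labels <- canonicalize_labels(labels)
  structure(list(labels = labels, k = k, inertia = inertia,
                 method = method, centers = centers),
            class = "oct_clusters")
}

#' Renumber cluster labels by decreasing size
#' @param labels Integer vector of cluster labels.
#' @return Integer vector where label 1 is the largest cluster; ties keep
#'   the original label order.
#' @export
canonicalize_labels <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.vector(tab), names(tab))]
  as.integer(match(as.character(labels), ord))
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `ward.D2`), cut at `k`.
#'
#' @inheritParams kmeans_cluster
#' @return `oct_clusters` object.
#' @export
ward_cluster <- function(scores, k) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) stop("k cannot exceed the number of rows")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  new_clusters(labels, k, within_ss(scores, labels), "ward")
}

within_ss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(ix) {
    xx <- x[ix, , drop = FALSE]
    sum(sweep(xx, 2, colMeans(xx))^2)
  }, numeric(1)))
}

#' Choose k by the elbow (maximum-curvature) heuristic
#'
#' Computes the within-cluster sum-of-squares curve for `k = 1..k_max` and
#' returns the `k` maximizing its second forward difference
#' `WSS(k-1) - 2 WSS(k) + WSS(k+1)` over `k = 2..k_max-1` — the point where
#' the curve levels off. Ties (flat curves) resolve to the smallest `k` and
#' set `low_confidence`.
#'
#' @inheritParams kmeans_cluster
#' @param k_max Largest k evaluated (>= 3).
#' @return List: `k`, `wss`, `low_confidence`.
#' @export
elbow_select_k <- function(scores, k_max = 10, seed = 1) {
  if (k_max < 3) stop("k_max must be >= 3")
  scores <- as.matrix(scores)
  k_max <- min(k_max, nrow(scores) - 1)
  wss <- vapply(seq_len(k_max), function(k) {
    kmeans_cluster(scores, k, seed = seed + k)$inertia
  }, numeric(1))
  ks <- 2:(k_max - 1)
  d2 <- wss[ks - 1] - 2 * wss[ks] + wss[ks + 1]
  k_hat <- ks[which.max(d2)]
  spread <- max(d2) - min(d2)
  low_conf <- spread <= 1e-8 * max(wss[1], 1)
  if (low_conf) k_hat <- min(ks)
  list(k = as.integer(k_hat), wss = wss, low_confidence = low_conf)
}

#' Consensus clustering over subsamples with CDF delta-area selection
#'
#' Monti-style consensus: for each candidate `k`, items are repeatedly
#' subsampled (without replacement), clustered with K-means, and the
#' co-clustering frequency among co-sampled pairs accumulated into a
#' consensus matrix. `A(k)` is the area under the empirical CDF of the
#' off-diagonal consensus entries; the relative gain
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)` (with `delta(2) = A(2)`) levels off
#' once additional clusters stop adding stable structure. The chosen `k` is
#' the largest candidate whose relative gain exceeds `delta_threshold`.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param n_resamples Subsamples per k (default 100; 1 sets
#'   `low_confidence`).
#' @param subsample_frac Fraction of items per subsample.
#' @param delta_threshold Relative-gain cutoff (default 0.1).
#' @return List: `k`, `a` (area per k), `delta`, `consensus` (list of
#'   matrices), `low_confidence`.
#' @export
consensus_select_k <- function(scores, k_range = 2:6, n_resamples = 100,
                               subsample_frac = 0.8, seed = 1,
                               delta_threshold = 0.1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 20) stop("need at least 20 items for consensus clustering")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  m <- floor(subsample_frac * n)
  consensus <- list()
  a_vec <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n); tog <- matrix(0, n, n)
    for (r in seq_len(n_resamples)) {
      if (m < k) next
      ix <- sort(sample.int(n, m))
      cl <- kmeans_cluster(scores[ix, , drop = FALSE], k,
                           seed = sample.int(2^30, 1), n_init = 1)$labels
      tog[ix, ix] <- tog[ix, ix] + 1
      same <- outer(cl, cl, "==") * 1
      co[ix, ix] <- co[ix, ix] + same
    }
    cm <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cm) <- 1
    consensus[[as.character(k)]] <- cm
    vals <- cm[upper.tri(cm)]
    a_vec[ki] <- cdf_area(vals)
  }
  delta <- c(a_vec[1], diff(a_vec) / a_vec[-length(a_vec)])
  pass <- delta > delta_threshold
  k_hat <- if (any(pass)) k_range[max(which(pass))] else k_range[1]
  list(k = as.integer(k_hat), a = stats::setNames(a_vec, k_range),
       delta = stats::setNames(delta, k_range), consensus = consensus,
       low_confidence = n_resamples < 10)
}

# area under the empirical CDF of values in [0, 1]
cdf_area <- function(vals) {
  xs <- sort(unique(c(0, vals, 1)))
  cdf <- stats::ecdf(vals)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

#' Hybrid Ward-initialized K-means clustering
#'
#' Ward clustering at `k` provides the initial centroids for a single Lloyd
#' K-means run; the converged K-means labels are returned, together with the
#' adjusted Rand index between the hybrid result and the pure Ward cut
#' (`ward_concordance`) as an auditable agreement measure between the two
#' parent methods.
#'
#' @inheritParams kmeans_cluster
#' @return `oct_clusters` with extra field `ward_concordance`.
#' @export
hybrid_cluster <- function(scores, k, seed = 1) {
  scores <- as.matrix(scores)
  wd <- ward_cluster(scores, k)
  if (k == 1) {
    out <- new_clusters(rep(1L, nrow(scores)), 1L, within_ss(scores, wd$labels),
                        "hybrid")
    out$ward_concordance <- 1
    return(out)
  }
  ctrs <- do.call(rbind, lapply(split(seq_len(nrow(scores)), wd$labels),
                                function(ix) colMeans(scores[ix, , drop = FALSE])))
  fit <- suppressWarnings(
    stats::kmeans(scores, centers = ctrs, iter.max = 100, algorithm = "Lloyd")
  )
  out <- new_clusters(fit$cluster, k, fit$tot.withinss, "hybrid", fit$centers)
  out$ward_concordance <- adjusted_rand_index(out$labels, wd$labels)
  out
}
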