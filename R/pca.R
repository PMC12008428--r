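#' Z-score a feature table
#'
#' Centers and scales every column to mean 0, sample SD 1. Zero-variance
#' columns cannot be scaled and are dropped with a warning; the dropped names
#' plus the centering/scaling vectors are kept as attributes so new data can
#' be transformed identically.
#'
#' @param table Numeric data frame or matrix (eyes x features).
#' @return Data frame of the same rows with attributes `center`, `scale`,
#'   `dropped`.
#' @export
zscore_features <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 rows to z-score")
  sds <- apply(x, 2, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance column(s): %s", sum(drop),
                    paste(utils::head(colnames(x)[drop], 5), collapse = ", ")))
  }
  kept <- x[, !drop, drop = FALSE]
  ctr <- colMeans(kept)
  scl <- sds[!drop]
  z <- sweep(sweep(kept, 2, ctr), 2, scl, "/")
  out <- as.data.frame(z)
  rownames(out) <- rownames(table)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "dropped") <- colnames(x)[drop]
  out
}

#' Fit a principal component model
#'
#' Eigendecomposition of the sample (n-1) covariance of an already z-scored
#' table, via SVD. Component signs are fixed so the largest-magnitude loading
#' of each component is positive, making the decomposition reproducible.
#'
#' @param z Z-scored data frame/matrix (see [zscore_features()]).
#' @return `oct_pca` object: `loadings` (features x components, orthonormal),
#'   `eigenvalues` (non-increasing), `explained` (fractions of total
#'   variance), `center`, `scale` (carried from the z-table when present).
#' @export
fit_pca <- function(z) {
  x <- as.matrix(z)
  n <- nrow(x)
  sv <- svd(scale(x, center = TRUE, scale = FALSE))
  eig <- sv$d^2 / (n - 1)
  load <- sv$v
  # sign convention
  for (k in seq_len(ncol(load))) {
    m <- which.max(abs(load[, k]))
    if (load[m, k] < 0) load[, k] <- -load[, k]
  }
  total <- sum(apply(x, 2, stats::var))
  rownames(load) <- colnames(x)
  structure(list(
    loadings = load,
    eigenvalues = eig,
    explained = eig / total,
    center = attr(z, "center"),
    scale = attr(z, "scale"),
    n = n
  ), class = "oct_pca")
}

#' Horn's parallel analysis for component retention
#'
#' Compares the observed PCA eigenvalues against eigenvalues of permuted
#' null tables of identical dimensions: each permutation shuffles every
#' column independently, preserving all marginal distributions while
#' destroying inter-feature correlation. Component `k` passes when its
#' observed eigenvalue exceeds the requested percentile of the null
#' distribution of the `k`-th eigenvalue; the retained count is the leading
#' run of consecutive passing components (Horn's stopping convention).
#'
#' A Gaussian null (`null = "gaussian"`, fresh standard-normal tables) is
#' available as an alternative Monte-Carlo reference; the permutation null is
#' the default.
#'
#' @param z Z-scored table.
#' @param n_perm Number of null datasets (default 1000; below 100 a warning
#'   is emitted).
#' @param percentile Null percentile to beat (default 95).
#' @param seed Integer seed for the permutation stream.
#' @param null `"permutation"` or `"gaussian"`.
#' @return List: `n_retained`, `observed` eigenvalues, `null_quantiles`.
#' @export
parallel_analysis <- function(z, n_perm = 1000, percentile = 95, seed = 1,
                              null = c("permutation", "gaussian")) {
  null <- match.arg(null)
  x <- as.matrix(z)
  n <- nrow(x); p <- ncol(x)
  if (n_perm < 100) warning("n_perm < 100: null percentile will be unstable")
  obs <- pca_eigenvalues(x)
  m <- length(obs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nulls <- matrix(0, n_perm, m)
  for (r in seq_len(n_perm)) {
    xp <- if (null == "permutation") {
      apply(x, 2, sample)
    } else {
      matrix(stats::rnorm(n * p), n, p)
    }
    nulls[r, ] <- pca_eigenvalues(xp)[seq_len(m)]
  }
  qs <- apply(nulls, 2, stats::quantile, probs = percentile / 100, type = 7)
  pass <- obs > qs
  n_retained <- if (pass[1]) which.min(c(pass, FALSE)) - 1L else 0L
  list(n_retained = as.integer(n_retained), observed = obs,
       null_quantiles = qs, percentile = percentile, n_perm = n_perm)
}

# eigenvalues of the sample covariance, via the cheaper of the two Gram forms
pca_eigenvalues <- function(x) {
  x <- scale(x, center = TRUE, scale = FALSE)
  n <- nrow(x); p <- ncol(x)
  if (p <= n) {
    ev <- eigen(crossprod(x) / (n - 1), symmetric = TRUE,
                only.values = TRUE)$values
  } else {
    ev <- eigen(tcrossprod(x) / (n - 1), symmetric = TRUE,
                only.values = TRUE)$values
  }
  pmax(ev, 0)
}

#' Project data onto a fitted principal component model
#'
#' New rows are centered/scaled with the model's stored vectors (from the
#' training z-scoring) when available, then multiplied by the leading
#' loadings.
#'
#' @param model An [fit_pca()] object.
#' @param table Raw feature table (same columns the model was fit on) or an
#'   already z-scored table.
#' @param n_components Number of leading components to keep.
#' @param zscored Set `TRUE` when `table` is already standardized.
#' @return Numeric score matrix (rows x n_components).
#' @export
project_scores <- function(model, table, n_components, zscored = FALSE) {
  stopifnot(inherits(model, "oct_pca"))
  if (n_components > ncol(model$loadings)) {
    stop("n_components exceeds available components")
  }
  x <- as.matrix(table)
  if (!zscored && !is.null(model$center)) {
    x <- x[, names(model$center), drop = FALSE]
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  if (ncol(x) != nrow(model$loadings)) stop("feature schema mismatch")
  x %*% model$loadings[, seq_len(n_components), drop = FALSE]
}
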