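#' Gray-level run-length matrix features
#'
#' Maximal runs of equal gray level along each of the four 2D directions;
#' out-of-mask pixels break runs. One run-length matrix per direction, the 16
#' standard features computed per direction and averaged.
#'
#' @param disc An [discretize()] result.
#' @return Named numeric vector `glrlm_<Feature>` of length 16.
#' @export
glrlm_features <- function(disc) {
  check_disc(disc)
  lv <- disc$levels; ng <- disc$ng
  np <- sum(!is.na(lv))
  feats <- lapply(seq_len(4), function(d) {
    runs <- runs_in_direction(lv, d)
    glrlm_features_from_runs(runs$level, runs$length, ng, np)
  })
  out <- average_directions(feats)
  names(out) <- paste0("glrlm_", names(out))
  out
}

# maximal same-level runs along direction d (1 = rows/0deg, 2 = 45deg
# anti-diagonals, 3 = columns/90deg, 4 = 135deg diagonals)
runs_in_direction <- function(lv, d) {
  h <- nrow(lv); w <- ncol(lv)
  lines <- switch(d,
    split(lv, row(lv)),
    split(lv, row(lv) + col(lv)),
    split(lv, col(lv)),
    split(lv, row(lv) - col(lv))
  )
  # direction 2 lines need reversal so pixels are spatially consecutive?
  # order within each line is already monotone along the traversal; runs are
  # direction-symmetric so orientation does not matter.
  level <- integer(0); len <- integer(0)
  for (ln in lines) {
    r <- rle(as.vector(ln))
    keep <- !is.na(r$values)
    level <- c(level, r$values[keep])
    len <- c(len, r$lengths[keep])
  }
  list(level = level, length = len)
}

glrlm_features_from_runs <- function(level, len, ng, np) {
  nr <- length(len)
  P <- matrix(tabulate(level + (len - 1L) * ng, nbins = ng * max(len)),
              ng, max(len))
  p <- P / nr
  i <- matrix(seq_len(ng), ng, ncol(P))
  j <- t(matrix(seq_len(ncol(P)), ncol(P), ng))
  pg <- rowSums(P)   # runs per gray level
  pl <- colSums(P)   # runs per length
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(
    ShortRunEmphasis = sum(p / j^2),
    LongRunEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    RunLengthNonUniformity = sum(pl^2) / nr,
    RunLengthNonUniformityNormalized = sum(pl^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (j - mu_j)^2),
    RunEntropy = entropy2(p),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    HighGrayLevelRunEmphasis = sum(p * i^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LongRunLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LongRunHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
  attr(out, "flagged") <- character(0)
  out
}
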