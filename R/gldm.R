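#' Gray-level dependence matrix features
#'
#' For every in-mask pixel, its dependence size is 1 plus the number of
#' 8-neighbours inside the mask whose discretized level differs from the
#' center by at most `alpha` (the center counts as dependent on itself, so
#' dependence is always at least 1 and the small-dependence emphasis terms
#' are defined). The matrix counts (gray level, dependence size) pairs over
#' all in-mask pixels; the 14 standard features are returned.
#'
#' @param disc An [discretize()] result.
#' @param alpha Non-negative integer dependence tolerance (default 0:
#'   neighbours must have the identical level).
#' @return Named numeric vector `gldm_<Feature>` of length 14.
#' @export
gldm_features <- function(disc, alpha = 0) {
  check_disc(disc)
  stopifnot(alpha >= 0)
  lv <- disc$levels
  h <- nrow(lv); w <- ncol(lv)
  dep <- matrix(0L, h, w)
  offs <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
               c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dep[r1, c1] <- dep[r1, c1] + hit
  }
  inm <- !is.na(lv)
  lev <- lv[inm]
  j <- dep[inm] + 1L                      # center included
  ng <- disc$ng
  nz <- length(lev)
  P <- matrix(tabulate(lev + (j - 1L) * ng, nbins = ng * max(j)), ng, max(j))
  p <- P / nz
  i <- matrix(seq_len(ng), ng, ncol(P))
  jj <- t(matrix(seq_len(ncol(P)), ncol(P), ng))
  pg <- rowSums(P); pd <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(jj * p)
  out <- c(
    SmallDependenceEmphasis = sum(p / jj^2),
    LargeDependenceEmphasis = sum(p * jj^2),
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (jj - mu_j)^2),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * jj^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / jj^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * jj^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * jj^2)
  )
  attr(out, "flagged") <- character(0)
  names(out) <- paste0("gldm_", names(out))
  out
}
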