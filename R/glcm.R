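#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence at distance 1 over the four unique 2D directions;
#' each direction's matrix is normalized separately and the 24 feature values
#' are averaged over directions (the usual "mean" aggregation). Only pixel
#' pairs lying fully inside the mask contribute.
#'
#' Degenerate single-level regions give defined, flagged constants for the
#' correlation-type features: Correlation = 1, MCC = 1, Imc1 = 0, Imc2 = 0.
#'
#' @param disc An [discretize()] result.
#' @return Named numeric vector `glcm_<Feature>` of length 24; attribute
#'   `flagged` names any features set to their degenerate constants.
#' @export
glcm_features <- function(disc) {
  check_disc(disc)
  lv <- disc$levels; ng <- disc$ng
  feats <- list()
  for (off in texture_offsets()) {
    pr <- shifted_pairs(lv, off[1], off[2])
    if (length(pr$a) == 0) next
    M <- matrix(tabulate(pr$a + (pr$b - 1L) * ng, nbins = ng * ng), ng, ng)
    P <- M + t(M)
    P <- P / sum(P)
    feats[[length(feats) + 1]] <- glcm_features_from_p(P, ng)
  }
  if (length(feats) == 0) stop("mask supports no pixel pairs")
  out <- average_directions(feats)
  names(out) <- paste0("glcm_", names(out))
  out
}

# features from one normalized symmetric co-occurrence matrix
glcm_features_from_p <- function(P, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)                    # == colSums for symmetric P
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  flagged <- character(0)

  # diagonal-band (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)

  if (sig2 > 0) {
    correlation <- (sum(i * j * P) - mu^2) / sig2
  } else {
    correlation <- 1
    flagged <- c(flagged, "Correlation")
  }

  HX <- entropy2(px)
  HXY <- entropy2(P)
  pos <- P > 0
  lg <- outer(px, px)
  HXY1 <- -sum(P[pos & lg > 0] * log2(lg[pos & lg > 0]))
  HXY2 <- entropy2(lg)
  if (max(HX, HX) > 0) {
    imc1 <- (HXY - HXY1) / HX
    imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  } else {
    imc1 <- 0; imc2 <- 0
    flagged <- c(flagged, "Imc1", "Imc2")
  }

  # maximal correlation coefficient via the Q matrix on present levels
  keep <- px > 0
  if (sum(keep) > 1) {
    Pk <- P[keep, keep, drop = FALSE]
    pk <- px[keep]
    Q <- sweep(Pk, 1, pk, "/") %*% t(sweep(Pk, 2, pk, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(0, ev[2]))
  } else {
    mcc <- 1
    flagged <- c(flagged, "MCC")
  }

  offdiag <- i != j
  out <- c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = correlation,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offdiag] / (i - j)[offdiag]^2),
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = entropy2(p_sum),
    SumSquares = sig2
  )
  attr(out, "flagged") <- flagged
  out
}
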