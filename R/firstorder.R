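#' First-order intensity statistics over a masked region
#'
#' The 18 first-order descriptors: Mean, Median, Minimum, Maximum, Range,
#' Variance, Skewness, Kurtosis, Energy, TotalEnergy, Entropy, 10Percentile,
#' 90Percentile, InterquartileRange, MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation, RootMeanSquared, Uniformity.
#'
#' Conventions: Variance uses the population (1/N) denominator; Kurtosis is
#' the raw fourth standardized moment (not excess, so a Gaussian gives ~3);
#' Skewness and Kurtosis of a constant region are defined as 0 and flagged
#' via the `"flagged"` attribute rather than returned as NaN. Entropy (log2)
#' and Uniformity are computed on the fixed-bin-width histogram used by the
#' matrix features. TotalEnergy scales Energy by the physical pixel area.
#'
#' @param image Numeric matrix.
#' @param mask Logical/0-1 matrix, same shape.
#' @param bin_width Bin width for Entropy/Uniformity discretization.
#' @param spacing_mm (row, col) pixel spacing in mm.
#' @return Named numeric vector of length 18 with names
#'   `firstorder_<Feature>`; attribute `flagged` lists features that were
#'   assigned a defined constant on a degenerate (constant) region.
#' @export
first_order_features <- function(image, mask, bin_width = 25,
                                 spacing_mm = c(1, 1)) {
  mask <- mask_as_logical(mask, dim(image))
  if (!any(mask)) stop("empty mask")
  x <- image[mask]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  flagged <- character(0)
  if (m2 == 0) {
    skew <- 0; kurt <- 0
    flagged <- c("Skewness", "Kurtosis")
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[4]]
  lev <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  out <- c(
    Mean = mu,
    Median = stats::median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    TotalEnergy = sum(x^2) * prod(spacing_mm),
    Entropy = -sum(p * log2(p)),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2],
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("firstorder_", names(out))
  attr(out, "flagged") <- flagged
  out
}
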