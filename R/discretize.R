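#' Discretize a masked image into gray levels
#'
#' Fixed-bin-width discretization of the in-mask intensities, the scheme used
#' by all matrix-based texture families (GLCM, GLRLM, GLSZM, GLDM, NGTDM).
#' Level assignment is `floor((x - min_in_mask) / bin_width) + 1`, so the
#' darkest in-mask pixel always maps to level 1 and `ng` is the maximum level
#' observed. A constant region collapses to a single level.
#'
#' @param image Numeric matrix of intensities (any real scale; filtered
#'   derivatives are discretized the same way as raw 8-bit images).
#' @param mask Logical or 0/1 matrix of the same shape; nonzero = in ROI.
#' @param bin_width Positive bin width on the intensity scale. Default 25,
#'   intended for 8-bit (0-255) inputs.
#' @return An object of class `oct_disc`: list with `levels` (integer matrix,
#'   `NA` outside the mask), `ng`, `bin_width`, and `mask` (logical matrix).
#' @examples
#' img <- matrix(0:255, 16, 16)
#' msk <- matrix(TRUE, 16, 16)
#' d <- discretize(img, msk, 25)
#' d$ng
#' @export
discretize <- function(image, mask, bin_width = 25) {
  stopifnot(is.matrix(image))
  mask <- mask_as_logical(mask, dim(image))
  if (!any(mask)) stop("empty mask")
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive scalar")
  }
  vals <- image[mask]
  lev <- floor((vals - min(vals)) / bin_width) + 1L
  levels <- matrix(NA_integer_, nrow(image), ncol(image))
  levels[mask] <- as.integer(lev)
  structure(
    list(levels = levels, ng = max(lev), bin_width = bin_width, mask = mask),
    class = "oct_disc"
  )
}

# coerce a 0/255, 0/1 or logical mask to logical and validate the shape
mask_as_logical <- function(mask, dims = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.null(dims) && !identical(dim(mask), as.integer(dims))) {
    stop("mask shape does not match image shape")
  }
  m <- mask != 0
  m[is.na(m)] <- FALSE
  m
}
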