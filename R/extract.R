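#' Feature extraction configuration
#'
#' Controls which filters and feature families [extract_features()] computes.
#' Column names carry full provenance as `<filter>_<family>_<Feature>`
#' (e.g. `logarithm_gldm_DependenceVariance`, `wavelet-LH_firstorder_Mean`,
#' `log-sigma-3-mm-3D_glcm_Imc1`). Shape features are mask-only and computed
#' once under the `original_shape2D_` prefix.
#'
#' `bin_width` applies to every derived image except the LBP code image,
#' whose integer codes (0..9) are discretized with bin width 1.
#'
#' @param filters Character vector of filter names (see [apply_filter()]).
#' @param families Character vector among `"firstorder"`, `"shape2d"`,
#'   `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param bin_width Discretization bin width (default 25, for 8-bit input).
#' @param sigma_mm LoG sigmas in mm.
#' @param gldm_alpha GLDM dependence tolerance.
#' @return An `oct_extract_config` list.
#' @export
extraction_config <- function(filters = c("original", "wavelet", "log-sigma",
                                          "logarithm", "exponential",
                                          "gradient", "squareroot", "square",
                                          "lbp-2D"),
                              families = c("firstorder", "shape2d", "glcm",
                                           "glrlm", "glszm", "gldm", "ngtdm"),
                              bin_width = 25, sigma_mm = c(3, 5),
                              gldm_alpha = 0) {
  structure(list(filters = filters, families = families,
                 bin_width = bin_width, sigma_mm = sigma_mm,
                 gldm_alpha = gldm_alpha),
            class = "oct_extract_config")
}

#' Reduced extraction preset for fast runs
#'
#' Original, gradient and square-root images with first-order, GLCM and GLDM
#' families: a small but discriminative slice of the full schema, suitable
#' for simulation studies and examples.
#' @return An `oct_extract_config`.
#' @export
reduced_extraction_config <- function() {
  extraction_config(filters = c("original", "gradient", "squareroot"),
                    families = c("firstorder", "glcm", "gldm"))
}

#' Extract all configured radiomic features from one masked image
#'
#' Applies every enabled filter, discretizes each derived image inside the
#' mask and computes the enabled feature families. The output schema
#' (names and length) depends only on the configuration, never on the pixel
#' values, so vectors are comparable across eyes.
#'
#' @param image Numeric matrix (8-bit scale intensities).
#' @param mask Logical/0-1 matrix, same shape.
#' @param config An [extraction_config()].
#' @param spacing_mm (row, col) pixel spacing in mm.
#' @return Named numeric vector; attribute `flagged` collects
#'   `<column>` names that were assigned defined degenerate constants.
#' @export
extract_features <- function(image, mask, config = extraction_config(),
                             spacing_mm = c(1, 1)) {
  stopifnot(inherits(config, "oct_extract_config"))
  mask <- mask_as_logical(mask, dim(image))
  if (sum(mask) < 16) stop("mask must contain at least 16 pixels")
  out <- numeric(0)
  flagged <- character(0)
  if ("shape2d" %in% config$families) {
    sh <- shape2d_features(mask, spacing_mm)
    names(sh) <- paste0("original_", names(sh))
    out <- c(out, sh)
  }
  mat_fams <- intersect(config$families,
                        c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  for (f in config$filters) {
    derived <- apply_filter(image, f, spacing_mm, config$sigma_mm)
    for (nm in names(derived)) {
      img <- derived[[nm]]
      bw <- if (nm == "lbp-2D") 1 else config$bin_width
      if ("firstorder" %in% config$families) {
        fo <- first_order_features(img, mask, bw, spacing_mm)
        flagged <- c(flagged, paste0(nm, "_firstorder_", attr(fo, "flagged")))
        names(fo) <- paste0(nm, "_", names(fo))
        out <- c(out, fo)
      }
      if (length(mat_fams)) {
        d <- discretize(img, mask, bw)
        for (fam in mat_fams) {
          v <- switch(fam,
            glcm = glcm_features(d),
            glrlm = glrlm_features(d),
            glszm = glszm_features(d),
            gldm = gldm_features(d, config$gldm_alpha),
            ngtdm = ngtdm_features(d)
          )
          flg <- attr(v, "flagged")
          if (length(flg)) flagged <- c(flagged, paste0(nm, "_", fam, "_", flg))
          names(v) <- paste0(nm, "_", names(v))
          out <- c(out, v)
        }
      }
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Extract a feature table from a cohort
#'
#' @param cohort An `oct_cohort` (see [generate_cohort()]) or a list with
#'   elements having `$image`, `$mask` and `$eye_id`.
#' @param config An [extraction_config()].
#' @return Data frame of eyes x features with row names `eye_id`; attribute
#'   `provenance` is a data frame of filter/family per column.
#' @export
extract_cohort <- function(cohort, config = extraction_config()) {
  eyes <- if (inherits(cohort, "oct_cohort")) cohort$eyes else cohort
  spacing <- if (inherits(cohort, "oct_cohort")) {
    rep(cohort$config$pixel_spacing_mm, 2)
  } else c(1, 1)
  rows <- lapply(eyes, function(e) {
    extract_features(e$image, e$mask, config, spacing)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- vapply(eyes, function(e) e$eye_id, character(1))
  parts <- strsplit(colnames(tab), "_")
  attr(tab, "provenance") <- data.frame(
    column = colnames(tab),
    filter = vapply(parts, `[`, character(1), 1),
    family = vapply(parts, `[`, character(1), 2)
  )
  tab
}
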