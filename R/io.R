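#' Read an 8-bit grayscale B-scan image
#'
#' Reads a PNG and returns intensities on the 0..255 scale (the first
#' channel is used for RGB/RGBA files).
#' @param path PNG file path.
#' @return Numeric matrix, values 0..255.
#' @export
read_bscan <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  round(a * 255)
}

#' Read a raster ROI mask (nonzero = foreground)
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0
}

#' Rasterize polygon-annotation JSON into an ROI mask
#'
#' Accepts the common labeling-tool export layout: a JSON document with a
#' `shapes` list, each shape holding `points` as a list of (x, y) vertex
#' pairs in 0-based pixel coordinates (x = column, y = row). Each polygon is
#' filled by the even-odd rule evaluated at pixel centers; multiple polygons
#' are unioned. Degenerate polygons (< 3 vertices) are skipped with a
#' warning.
#'
#' @param json_doc Path to a JSON file, or an already-parsed list.
#' @param image_shape (H, W) of the target mask.
#' @return Logical matrix.
#' @export
read_mask_polygons <- function(json_doc, image_shape) {
  doc <- if (is.character(json_doc)) jsonlite::fromJSON(json_doc,
    simplifyVector = FALSE) else json_doc
  shapes <- if (!is.null(doc$shapes)) doc$shapes else doc
  h <- image_shape[1]; w <- image_shape[2]
  mask <- matrix(FALSE, h, w)
  # pixel centers in 0-based (x, y) coordinates
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), w)
  for (sh in shapes) {
    pts <- sh$points
    if (length(pts) < 3) {
      warning("skipping degenerate polygon with < 3 vertices")
      next
    }
    vx <- vapply(pts, function(p) as.numeric(p[[1]]), numeric(1))
    vy <- vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))
    inside <- point_in_polygon_evenodd(px, py, vx, vy)
    mask <- mask | matrix(inside, h, w)
  }
  if (!any(mask)) stop("polygon annotation produced an empty mask")
  mask
}

# even-odd (crossing number) point-in-polygon, vectorized over points
point_in_polygon_evenodd <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write a synthetic cohort to disk
#'
#' Writes 8-bit grayscale PNG images, 0/255 PNG masks, polygon-annotation
#' JSON masks (the rectangular band as a 4-vertex polygon), and a clinical
#' manifest CSV with one row per eye.
#'
#' @param cohort An `oct_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oct_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (e in cohort$eyes) {
    img_file <- file.path(dir, "images", paste0(e$eye_id, ".png"))
    png::writePNG(e$image / 255, img_file)
    png::writePNG(e$mask * 1, file.path(dir, "masks",
                                        paste0(e$eye_id, "_mask.png")))
    rows <- range(which(rowSums(e$mask) > 0))
    cols <- range(which(colSums(e$mask) > 0))
    poly <- list(
      imagePath = basename(img_file),
      shapes = list(list(points = list(
        # 0-based (x, y); pad by 0.5 so all masked pixel centers fall inside
        c(cols[1] - 1.5, rows[1] - 1.5), c(cols[2] - 0.5, rows[1] - 1.5),
        c(cols[2] - 0.5, rows[2] - 0.5), c(cols[1] - 1.5, rows[2] - 0.5)
      )))
    )
    jsonlite::write_json(poly, file.path(dir, "masks",
                                         paste0(e$eye_id, "_mask.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- cohort$clinical
  utils::write.csv(manifest, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
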