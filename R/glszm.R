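#' Gray-level size-zone matrix features
#'
#' Zones are 8-connected components of equal gray level inside the mask
#' (connectivity resolved with an igraph component search over the pixel
#' adjacency graph). A single size-zone matrix is built (the family is
#' direction-free) and the 16 standard features returned.
#'
#' @param disc An [discretize()] result.
#' @return Named numeric vector `glszm_<Feature>` of length 16.
#' @export
glszm_features <- function(disc) {
  check_disc(disc)
  z <- size_zones(disc$levels)
  ng <- disc$ng
  np <- sum(!is.na(disc$levels))
  nz <- length(z$size)
  P <- matrix(tabulate(z$level + (z$size - 1L) * ng, nbins = ng * max(z$size)),
              ng, max(z$size))
  p <- P / nz
  i <- matrix(seq_len(ng), ng, ncol(P))
  j <- t(matrix(seq_len(ncol(P)), ncol(P), ng))
  pg <- rowSums(P); ps <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(
    SmallAreaEmphasis = sum(p / j^2),
    LargeAreaEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    SizeZoneNonUniformity = sum(ps^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (j - mu_j)^2),
    ZoneEntropy = entropy2(p),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    HighGrayLevelZoneEmphasis = sum(p * i^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
  attr(out, "flagged") <- character(0)
  names(out) <- paste0("glszm_", names(out))
  out
}

# 8-connected equal-level zones; returns per-zone level and size
size_zones <- function(lv) {
  inmask <- which(!is.na(lv))
  nv <- length(inmask)
  vid <- rep(NA_integer_, length(lv))
  vid[inmask] <- seq_len(nv)
  h <- nrow(lv)
  edges <- integer(0)
  for (off in texture_offsets()) {
    pr <- shifted_pairs_idx(lv, off[1], off[2])
    same <- lv[pr$from] == lv[pr$to]
    if (any(same)) {
      edges <- c(edges, rbind(vid[pr$from[same]], vid[pr$to[same]]))
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  size <- as.integer(comp$csize)
  # level of each component from its first member
  first <- match(seq_len(comp$no), comp$membership)
  level <- lv[inmask[first]]
  list(level = level, size = size)
}

# in-mask neighbour index pairs under offset (dr, dc)
shifted_pairs_idx <- function(lv, dr, dc) {
  h <- nrow(lv); w <- ncol(lv)
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  from <- as.vector(outer(r1, (c1 - 1L) * h, "+"))
  to <- as.vector(outer(r1 + dr, (c1 + dc - 1L) * h, "+"))
  ok <- !is.na(lv[from]) & !is.na(lv[to])
  list(from = from[ok], to = to[ok])
}
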