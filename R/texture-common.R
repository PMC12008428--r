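# shared helpers for the matrix-based texture families

# the four unique 2D direction offsets (0, 45, 90, 135 degrees), (dr, dc)
texture_offsets <- function() {
  list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
}

# aligned pixel pairs of `lv` under offset (dr, dc); NA outside mask
shifted_pairs <- function(lv, dr, dc) {
  h <- nrow(lv); w <- ncol(lv)
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  if (length(r1) == 0 || length(c1) == 0) {
    return(list(a = integer(0), b = integer(0)))
  }
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

# entropy base 2 of a probability vector, 0 log 0 := 0
entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

check_disc <- function(disc) {
  if (!inherits(disc, "oct_disc")) stop("expected an `oct_disc` object")
  disc
}

# average a list of equally named feature vectors, propagating flags
average_directions <- function(feats) {
  vals <- do.call(rbind, feats)
  out <- colMeans(vals)
  flg <- unique(unlist(lapply(feats, attr, "flagged")))
  attr(out, "flagged") <- flg
  out
}
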