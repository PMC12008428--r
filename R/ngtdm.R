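#' Neighbouring gray-tone difference matrix features
#'
#' For each gray level `i`, `s_i` sums `|i - mean of valid 8-neighbours|`
#' over all in-mask pixels of level `i` that have at least one in-mask
#' neighbour. The five standard features (Coarseness, Contrast, Busyness,
#' Complexity, Strength) follow, with the usual degenerate-region guards:
#' a single-level region gives Contrast 0, Busyness 0, Strength 0 (flagged),
#' and a region with all `s_i = 0` caps Coarseness at 1e6.
#'
#' @param disc An [discretize()] result.
#' @return Named numeric vector `ngtdm_<Feature>` of length 5.
#' @export
ngtdm_features <- function(disc) {
  check_disc(disc)
  lv <- disc$levels
  h <- nrow(lv); w <- ncol(lv)
  ssum <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  offs <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
               c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(b)
    b[!ok] <- 0L
    ssum[r1, c1] <- ssum[r1, c1] + b
    cnt[r1, c1] <- cnt[r1, c1] + ok
  }
  valid <- !is.na(lv) & cnt > 0
  lev <- lv[valid]
  nbar <- ssum[valid] / cnt[valid]
  ng <- disc$ng
  nvp <- length(lev)
  n_i <- tabulate(lev, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - nbar[lev == i])),
                numeric(1))
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  flagged <- character(0)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6

  if (ngp > 1) {
    pij_d2 <- 0; busy_den <- 0; strength_num <- 0
    for (a in present) for (b in present) {
      pij_d2 <- pij_d2 + p_i[a] * p_i[b] * (a - b)^2
      busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
      strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
    }
    contrast <- pij_d2 / (ngp * (ngp - 1)) * sum(s_i) / nvp
    busyness <- if (busy_den > 0) coarse_den / busy_den else 0
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
    cx <- 0
    for (a in present) for (b in present) {
      cx <- cx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
    }
    complexity <- cx / nvp
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
    flagged <- c("Contrast", "Busyness", "Complexity", "Strength")
  }
  out <- c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
           Complexity = complexity, Strength = strength)
  names(out) <- paste0("ngtdm_", names(out))
  attr(out, "flagged") <- flagged
  out
}
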