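# Brute-force, loop-based reference implementations of the texture families.
# These deliberately avoid the vectorized code paths of the package: matrices
# are accumulated pixel by pixel, zones are grown by explicit flood fill, and
# feature formulas are evaluated with scalar loops.

rand_disc <- function(h, w, ng, seed, mask_frac = 0.85) {
  set.seed(seed)
  lv <- matrix(sample.int(ng, h * w, replace = TRUE), h, w)
  mask <- matrix(stats::runif(h * w) < mask_frac, h, w)
  if (!any(mask)) mask[1, 1] <- TRUE
  lv[!mask] <- NA_integer_
  structure(list(levels = lv, ng = max(lv, na.rm = TRUE), bin_width = 1,
                 mask = mask), class = "oct_disc")
}

oracle_offsets <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

in_bounds <- function(r, c, h, w) r >= 1 && r <= h && c >= 1 && c <= w

oracle_glcm_features <- function(disc) {
  lv <- disc$levels; ng <- disc$ng
  h <- nrow(lv); w <- ncol(lv)
  acc <- NULL
  for (off in oracle_offsets) {
    M <- matrix(0, ng, ng)
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (in_bounds(r2, c2, h, w) && !is.na(lv[r, cc]) && !is.na(lv[r2, c2])) {
        a <- lv[r, cc]; b <- lv[r2, c2]
        M[a, b] <- M[a, b] + 1
        M[b, a] <- M[b, a] + 1
      }
    }
    if (sum(M) == 0) next
    acc <- rbind(acc, oracle_glcm_from_p(M / sum(M), ng))
  }
  out <- colMeans(acc)
  names(out) <- paste0("glcm_", names(out))
  out
}

oracle_glcm_from_p <- function(P, ng) {
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0; for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  p_diff <- numeric(ng); p_sum <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + P[i, j]
    p_sum[i + j - 1] <- p_sum[i + j - 1] + P[i, j]
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * p_diff[k + 1]
  ent <- function(v) { s <- 0; for (x in v) if (x > 0) s <- s - x * log2(x); s }
  HX <- ent(px); HXY <- ent(as.vector(P))
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (P[i, j] > 0 && q > 0) HXY1 <- HXY1 - P[i, j] * log2(q)
    if (q > 0) HXY2 <- HXY2 - q * log2(q)
  }
  s <- list(
    Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
    ClusterTendency = 0, Contrast = 0, JointEnergy = 0, Id = 0, Idm = 0,
    Idmn = 0, Idn = 0, InverseVariance = 0, SumSquares = 0, corr_num = 0
  )
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    s$Autocorrelation <- s$Autocorrelation + i * j * p
    s$ClusterProminence <- s$ClusterProminence + (i + j - 2 * mu)^4 * p
    s$ClusterShade <- s$ClusterShade + (i + j - 2 * mu)^3 * p
    s$ClusterTendency <- s$ClusterTendency + (i + j - 2 * mu)^2 * p
    s$Contrast <- s$Contrast + (i - j)^2 * p
    s$JointEnergy <- s$JointEnergy + p^2
    s$Id <- s$Id + p / (1 + abs(i - j))
    s$Idm <- s$Idm + p / (1 + (i - j)^2)
    s$Idmn <- s$Idmn + p / (1 + ((i - j) / ng)^2)
    s$Idn <- s$Idn + p / (1 + abs(i - j) / ng)
    if (i != j) s$InverseVariance <- s$InverseVariance + p / (i - j)^2
    s$SumSquares <- s$SumSquares + (i - mu)^2 * p
    s$corr_num <- s$corr_num + i * j * p
  }
  correlation <- if (sig2 > 0) (s$corr_num - mu^2) / sig2 else 1
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- if (HX > 0) sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))) else 0
  keep <- which(px > 0)
  mcc <- if (length(keep) > 1) {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      for (kk in keep) {
        Q[a, b] <- Q[a, b] +
          P[keep[a], kk] * P[keep[b], kk] / (px[keep[a]] * px[kk])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  } else 1
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * p_sum[k - 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * p_diff[k + 1]
  c(Autocorrelation = s$Autocorrelation, JointAverage = mu,
    ClusterProminence = s$ClusterProminence, ClusterShade = s$ClusterShade,
    ClusterTendency = s$ClusterTendency, Contrast = s$Contrast,
    Correlation = correlation, DifferenceAverage = da,
    DifferenceEntropy = ent(p_diff), DifferenceVariance = dv,
    JointEnergy = s$JointEnergy, JointEntropy = HXY, Imc1 = imc1,
    Imc2 = imc2, Id = s$Id, Idm = s$Idm, Idmn = s$Idmn, Idn = s$Idn,
    InverseVariance = s$InverseVariance, MaximumProbability = max(P),
    MCC = mcc, SumAverage = sa, SumEntropy = ent(p_sum),
    SumSquares = s$SumSquares)
}

# walk every line of direction d pixel by pixel, recording maximal runs
oracle_glrlm_features <- function(disc) {
  lv <- disc$levels; ng <- disc$ng
  h <- nrow(lv); w <- ncol(lv)
  np <- sum(!is.na(lv))
  steps <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  acc <- NULL
  for (st in steps) {
    runs_level <- integer(0); runs_len <- integer(0)
    for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
      pr <- r0 - st[1]; pc <- c0 - st[2]
      has_pred <- in_bounds(pr, pc, h, w)
      if (has_pred) next   # only start walking from line beginnings
      r <- r0; cc <- c0
      cur <- NA_integer_; len <- 0L
      while (in_bounds(r, cc, h, w)) {
        v <- lv[r, cc]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1L
        } else {
          if (!is.na(cur)) { runs_level <- c(runs_level, cur); runs_len <- c(runs_len, len) }
          cur <- v; len <- if (is.na(v)) 0L else 1L
        }
        r <- r + st[1]; cc <- cc + st[2]
      }
      if (!is.na(cur)) { runs_level <- c(runs_level, cur); runs_len <- c(runs_len, len) }
    }
    acc <- rbind(acc, oracle_rl_features(runs_level, runs_len, ng, np))
  }
  out <- colMeans(acc)
  names(out) <- paste0("glrlm_", names(out))
  out
}

oracle_rl_features <- function(level, len, ng, np) {
  nr <- length(len)
  maxl <- max(len)
  P <- matrix(0, ng, maxl)
  for (q in seq_len(nr)) P[level[q], len[q]] <- P[level[q], len[q]] + 1
  s <- list(sre = 0, lre = 0, lgl = 0, hgl = 0, srl = 0, srh = 0, lrl = 0,
            lrh = 0, gv = 0, rv = 0, re = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:maxl) {
    p <- P[i, j] / nr
    mu_i <- mu_i + i * p; mu_j <- mu_j + j * p
  }
  for (i in 1:ng) for (j in 1:maxl) {
    p <- P[i, j] / nr
    s$sre <- s$sre + p / j^2; s$lre <- s$lre + p * j^2
    s$lgl <- s$lgl + p / i^2; s$hgl <- s$hgl + p * i^2
    s$srl <- s$srl + p / (i^2 * j^2); s$srh <- s$srh + p * i^2 / j^2
    s$lrl <- s$lrl + p * j^2 / i^2; s$lrh <- s$lrh + p * i^2 * j^2
    s$gv <- s$gv + p * (i - mu_i)^2; s$rv <- s$rv + p * (j - mu_j)^2
    if (p > 0) s$re <- s$re - p * log2(p)
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  rln <- 0; for (j in 1:maxl) rln <- rln + sum(P[, j])^2
  c(ShortRunEmphasis = s$sre, LongRunEmphasis = s$lre,
    GrayLevelNonUniformity = gln / nr,
    GrayLevelNonUniformityNormalized = gln / nr^2,
    RunLengthNonUniformity = rln / nr,
    RunLengthNonUniformityNormalized = rln / nr^2,
    RunPercentage = nr / np, GrayLevelVariance = s$gv, RunVariance = s$rv,
    RunEntropy = s$re, LowGrayLevelRunEmphasis = s$lgl,
    HighGrayLevelRunEmphasis = s$hgl, ShortRunLowGrayLevelEmphasis = s$srl,
    ShortRunHighGrayLevelEmphasis = s$srh,
    LongRunLowGrayLevelEmphasis = s$lrl,
    LongRunHighGrayLevelEmphasis = s$lrh)
}

# explicit flood fill, 8-connectivity
oracle_glszm_features <- function(disc) {
  lv <- disc$levels; ng <- disc$ng
  h <- nrow(lv); w <- ncol(lv)
  np <- sum(!is.na(lv))
  visited <- matrix(FALSE, h, w)
  zl <- integer(0); zs <- integer(0)
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (is.na(lv[r0, c0]) || visited[r0, c0]) next
    lev <- lv[r0, c0]
    stack <- list(c(r0, c0)); visited[r0, c0] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- cur[1] + dr; cc <- cur[2] + dc
        if (in_bounds(r, cc, h, w) && !visited[r, cc] &&
            !is.na(lv[r, cc]) && lv[r, cc] == lev) {
          visited[r, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(r, cc)
        }
      }
    }
    zl <- c(zl, lev); zs <- c(zs, size)
  }
  nz <- length(zs)
  maxs <- max(zs)
  P <- matrix(0, ng, maxs)
  for (q in seq_len(nz)) P[zl[q], zs[q]] <- P[zl[q], zs[q]] + 1
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:maxs) {
    p <- P[i, j] / nz; mu_i <- mu_i + i * p; mu_j <- mu_j + j * p
  }
  s <- list(sae = 0, lae = 0, lgl = 0, hgl = 0, sal = 0, sah = 0, lal = 0,
            lah = 0, gv = 0, zv = 0, ze = 0)
  for (i in 1:ng) for (j in 1:maxs) {
    p <- P[i, j] / nz
    s$sae <- s$sae + p / j^2; s$lae <- s$lae + p * j^2
    s$lgl <- s$lgl + p / i^2; s$hgl <- s$hgl + p * i^2
    s$sal <- s$sal + p / (i^2 * j^2); s$sah <- s$sah + p * i^2 / j^2
    s$lal <- s$lal + p * j^2 / i^2; s$lah <- s$lah + p * i^2 * j^2
    s$gv <- s$gv + p * (i - mu_i)^2; s$zv <- s$zv + p * (j - mu_j)^2
    if (p > 0) s$ze <- s$ze - p * log2(p)
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  szn <- 0; for (j in 1:maxs) szn <- szn + sum(P[, j])^2
  out <- c(SmallAreaEmphasis = s$sae, LargeAreaEmphasis = s$lae,
           GrayLevelNonUniformity = gln / nz,
           GrayLevelNonUniformityNormalized = gln / nz^2,
           SizeZoneNonUniformity = szn / nz,
           SizeZoneNonUniformityNormalized = szn / nz^2,
           ZonePercentage = nz / np, GrayLevelVariance = s$gv,
           ZoneVariance = s$zv, ZoneEntropy = s$ze,
           LowGrayLevelZoneEmphasis = s$lgl,
           HighGrayLevelZoneEmphasis = s$hgl,
           SmallAreaLowGrayLevelEmphasis = s$sal,
           SmallAreaHighGrayLevelEmphasis = s$sah,
           LargeAreaLowGrayLevelEmphasis = s$lal,
           LargeAreaHighGrayLevelEmphasis = s$lah)
  names(out) <- paste0("glszm_", names(out))
  out
}

oracle_gldm_features <- function(disc, alpha = 0) {
  lv <- disc$levels; ng <- disc$ng
  h <- nrow(lv); w <- ncol(lv)
  lev <- integer(0); dep <- integer(0)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (is.na(lv[r, cc])) next
    cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (in_bounds(r2, c2, h, w) && !is.na(lv[r2, c2]) &&
          abs(lv[r2, c2] - lv[r, cc]) <= alpha) cnt <- cnt + 1L
    }
    lev <- c(lev, lv[r, cc]); dep <- c(dep, cnt + 1L)
  }
  nz <- length(lev)
  maxd <- max(dep)
  P <- matrix(0, ng, maxd)
  for (q in seq_len(nz)) P[lev[q], dep[q]] <- P[lev[q], dep[q]] + 1
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:maxd) {
    p <- P[i, j] / nz; mu_i <- mu_i + i * p; mu_j <- mu_j + j * p
  }
  s <- list(sde = 0, lde = 0, lgl = 0, hgl = 0, sdl = 0, sdh = 0, ldl = 0,
            ldh = 0, gv = 0, dv = 0, de = 0)
  for (i in 1:ng) for (j in 1:maxd) {
    p <- P[i, j] / nz
    s$sde <- s$sde + p / j^2; s$lde <- s$lde + p * j^2
    s$lgl <- s$lgl + p / i^2; s$hgl <- s$hgl + p * i^2
    s$sdl <- s$sdl + p / (i^2 * j^2); s$sdh <- s$sdh + p * i^2 / j^2
    s$ldl <- s$ldl + p * j^2 / i^2; s$ldh <- s$ldh + p * i^2 * j^2
    s$gv <- s$gv + p * (i - mu_i)^2; s$dv <- s$dv + p * (j - mu_j)^2
    if (p > 0) s$de <- s$de - p * log2(p)
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  dn <- 0; for (j in 1:maxd) dn <- dn + sum(P[, j])^2
  out <- c(SmallDependenceEmphasis = s$sde, LargeDependenceEmphasis = s$lde,
           GrayLevelNonUniformity = gln / nz, DependenceNonUniformity = dn / nz,
           DependenceNonUniformityNormalized = dn / nz^2,
           GrayLevelVariance = s$gv, DependenceVariance = s$dv,
           DependenceEntropy = s$de, LowGrayLevelEmphasis = s$lgl,
           HighGrayLevelEmphasis = s$hgl,
           SmallDependenceLowGrayLevelEmphasis = s$sdl,
           SmallDependenceHighGrayLevelEmphasis = s$sdh,
           LargeDependenceLowGrayLevelEmphasis = s$ldl,
           LargeDependenceHighGrayLevelEmphasis = s$ldh)
  names(out) <- paste0("gldm_", names(out))
  out
}

oracle_ngtdm_features <- function(disc) {
  lv <- disc$levels; ng <- disc$ng
  h <- nrow(lv); w <- ncol(lv)
  n_i <- numeric(ng); s_i <- numeric(ng); nvp <- 0
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (is.na(lv[r, cc])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (in_bounds(r2, c2, h, w) && !is.na(lv[r2, c2])) nb <- c(nb, lv[r2, c2])
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    i <- lv[r, cc]
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nb))
  }
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    con <- 0; bden <- 0; str_num <- 0; cx <- 0
    for (a in present) for (b in present) {
      con <- con + p_i[a] * p_i[b] * (a - b)^2
      bden <- bden + abs(a * p_i[a] - b * p_i[b])
      str_num <- str_num + (p_i[a] + p_i[b]) * (a - b)^2
      cx <- cx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
    }
    contrast <- con / (ngp * (ngp - 1)) * sum(s_i) / nvp
    busyness <- if (bden > 0) coarse_den / bden else 0
    strength <- if (sum(s_i) > 0) str_num / sum(s_i) else 0
    complexity <- cx / nvp
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

# O(n^2) explicit pair-classification adjusted Rand index
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- 0; s00 <- 0; s10 <- 0; s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# compare feature vectors ignoring the bookkeeping `flagged` attribute
expect_feature_equal <- function(object, expected, tol = 1e-9) {
  attr(object, "flagged") <- NULL
  attr(expected, "flagged") <- NULL
  testthat::expect_equal(object, expected, tolerance = tol)
}
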