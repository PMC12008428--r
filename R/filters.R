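#' @title Image filter bank for radiomic feature extraction
#' @description
#' Filtered derivatives of a B-scan prior to texture analysis. Supported
#' filters: `"original"` (identity), `"wavelet"` (single-level separable
#' Coiflet-1 DWT; four subbands LL/LH/HL/HH upsampled back to the input
#' shape), `"log-sigma"` (Laplacian of Gaussian, sigma given in mm and
#' converted to pixels through the pixel spacing), `"logarithm"`,
#' `"exponential"`, `"squareroot"`, `"square"` (intensity-rescaled point
#' maps), `"gradient"` (first-difference gradient magnitude) and `"lbp-2D"`
#' (rotation-invariant uniform local binary pattern code image, radius 1,
#' 8 points).
#'
#' Point-filter definitions, with `M = max(|x|)` over the image (all preserve
#' the input range and are identity-safe on constant images):
#' \itemize{
#'   \item logarithm: `sign(x) * M * log(1 + |x|) / log(1 + M)`
#'   \item exponential: `M * (exp(|x|) - 1) / (exp(M) - 1)` computed stably as
#'         `M * expm1(|x| - M) / (1 - exp(-M))` ... implemented via a rescaled
#'         exponent so that large 8-bit ranges do not overflow:
#'         `exp(c * x)` with `c = log(M + 1) / M`, shifted to start at 0.
#'   \item squareroot: `sign(x) * sqrt(|x| * M)`
#'   \item square: `x^2 / M`
#' }
#'
#' @param image Numeric matrix.
#' @param spec Filter name (one of the above).
#' @param spacing_mm Numeric length-2 (row, col) pixel spacing in mm; used by
#'   `"log-sigma"` only.
#' @param sigma_mm Numeric vector of LoG sigmas in mm (default `c(3, 5)`).
#' @return Named list of derived images. Point filters return one image named
#'   after the filter; `"wavelet"` returns four (`wavelet-LL` .. `wavelet-HH`);
#'   `"log-sigma"` returns one per sigma, named engine-style
#'   (`log-sigma-3-mm-3D`, ...).
#' @export
apply_filter <- function(image, spec, spacing_mm = c(1, 1), sigma_mm = c(3, 5)) {
  stopifnot(is.matrix(image), is.numeric(image))
  switch(spec,
    "original"    = list(original = image),
    "logarithm"   = list(logarithm = point_filter(image, "logarithm")),
    "exponential" = list(exponential = point_filter(image, "exponential")),
    "squareroot"  = list(squareroot = point_filter(image, "squareroot")),
    "square"      = list(square = point_filter(image, "square")),
    "gradient"    = list(gradient = gradient_magnitude(image)),
    "wavelet"     = wavelet_subbands(image),
    "log-sigma"   = log_filter_set(image, spacing_mm, sigma_mm),
    "lbp-2D"      = list(`lbp-2D` = lbp_image(image)),
    stop("unknown filter spec: ", spec)
  )
}

point_filter <- function(x, kind) {
  M <- max(abs(x))
  if (M == 0) return(x)
  switch(kind,
    logarithm   = sign(x) * M * log1p(abs(x)) / log1p(M),
    squareroot  = sign(x) * sqrt(abs(x) * M),
    square      = x^2 / M,
    exponential = {
      c0 <- log1p(M) / M
      (exp(c0 * abs(x)) - 1) * sign(x)
    }
  )
}

# gradient magnitude from first differences (central in the interior,
# one-sided at the borders), in pixel units
gradient_magnitude <- function(x) {
  h <- nrow(x); w <- ncol(x)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  if (h > 1) {
    gr[2:(h - 1), ] <- (x[3:h, , drop = FALSE] - x[1:(h - 2), , drop = FALSE]) / 2
    gr[1, ] <- x[2, ] - x[1, ]
    gr[h, ] <- x[h, ] - x[h - 1, ]
  }
  if (w > 1) {
    gc[, 2:(w - 1)] <- (x[, 3:w, drop = FALSE] - x[, 1:(w - 2), drop = FALSE]) / 2
    gc[, 1] <- x[, 2] - x[, 1]
    gc[, w] <- x[, w] - x[, w - 1]
  }
  sqrt(gr^2 + gc^2)
}

# Coiflet-1 decomposition filters (standard published taps)
coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
               0.852572020212255,  0.337897662457809, -0.072732619512854)
coif1_hi <- c( 0.072732619512854,  0.337897662457809, -0.852572020212255,
               0.384864846864203,  0.072732619512854, -0.015655728135465)

# symmetric (half-sample) extension by n samples each side
sym_ext <- function(v, n) {
  L <- length(v)
  idx <- c(rev(seq_len(min(n, L))), seq_len(L), L + 1 - seq_len(min(n, L)))
  # if n > L, recycle reflection (images are >= 8 px so this is a corner case)
  while (length(idx) < L + 2 * n) idx <- c(idx[1], idx, idx[length(idx)])
  v[idx]
}

# single-level 1D analysis along a vector: convolve with filter, downsample by 2
dwt_step <- function(v, f) {
  n <- length(f)
  ve <- sym_ext(v, n - 1)
  full <- stats::filter(ve, rev(f), method = "convolution", sides = 1)
  full <- full[!is.na(full)]
  full[seq(2, length(full), by = 2)]
}

# apply dwt_step down the rows of a matrix (to each column)
dwt_cols <- function(m, f) {
  out <- apply(m, 2, dwt_step, f = f)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' @keywords internal
wavelet_subbands <- function(x) {
  h <- nrow(x); w <- ncol(x)
  # rows first (filter along columns index), then columns
  lo_r <- dwt_cols(x, coif1_lo)          # lowpass along rows
  hi_r <- dwt_cols(x, coif1_hi)
  ll <- t(dwt_cols(t(lo_r), coif1_lo))   # then along columns
  lh <- t(dwt_cols(t(lo_r), coif1_hi))   # low rows, high columns
  hl <- t(dwt_cols(t(hi_r), coif1_lo))   # high rows, low columns
  hh <- t(dwt_cols(t(hi_r), coif1_hi))
  up <- function(m) upsample_to(m, h, w)
  list(`wavelet-LL` = up(ll), `wavelet-LH` = up(lh),
       `wavelet-HL` = up(hl), `wavelet-HH` = up(hh))
}

# nearest-neighbour 2x upsampling then crop to target shape
upsample_to <- function(m, h, w) {
  r <- rep(seq_len(nrow(m)), each = 2)[seq_len(h)]
  c <- rep(seq_len(ncol(m)), each = 2)[seq_len(w)]
  r[r > nrow(m)] <- nrow(m); c[c > ncol(m)] <- ncol(m)
  m[r, c, drop = FALSE]
}

log_filter_set <- function(image, spacing_mm, sigma_mm) {
  out <- list()
  for (s in sigma_mm) {
    nm <- sprintf("log-sigma-%g-mm-3D", s)
    out[[nm]] <- log_of_gaussian(image, s, spacing_mm)
  }
  out
}

#' Laplacian-of-Gaussian filtered image
#'
#' Convolution with the analytic LoG kernel, truncated at 4 sigma, applied by
#' FFT with symmetric border padding. `sigma_mm` is converted to pixels via
#' the mean pixel spacing; values below 1 px or above `min(H, W) / 4` px are
#' clamped with a warning (a sigma wider than a quarter of the image support
#' carries no usable band-pass information at this image size).
#'
#' @param image Numeric matrix.
#' @param sigma_mm Sigma of the Gaussian in mm.
#' @param spacing_mm (row, col) pixel spacing in mm.
#' @return Filtered matrix of the same shape.
#' @export
log_of_gaussian <- function(image, sigma_mm, spacing_mm = c(1, 1)) {
  sigma_px <- sigma_mm / mean(spacing_mm)
  max_sigma <- min(dim(image)) / 4
  if (sigma_px < 1) {
    warning("LoG sigma below one pixel; clamped to 1 px")
    sigma_px <- 1
  } else if (sigma_px > max_sigma) {
    warning(sprintf("LoG sigma %.1f px exceeds min(H,W)/4; clamped to %.1f px",
                    sigma_px, max_sigma))
    sigma_px <- max_sigma
  }
  r <- ceiling(4 * sigma_px)
  g <- seq(-r, r)
  k2 <- outer(g^2, g^2, "+")
  kern <- (k2 - 2 * sigma_px^2) / sigma_px^4 * exp(-k2 / (2 * sigma_px^2))
  kern <- kern - mean(kern)  # zero DC response
  conv2_sym(image, kern)
}

# 2D convolution with symmetric padding, via FFT
conv2_sym <- function(x, k) {
  kr <- (nrow(k) - 1) / 2; kc <- (ncol(k) - 1) / 2
  xp <- pad_sym(x, kr, kc)
  H <- nrow(xp); W <- ncol(xp)
  kp <- matrix(0, H, W)
  kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  # circular shift so kernel center sits at (1,1)
  kp <- kp[c((kr + 1):H, seq_len(kr)), c((kc + 1):W, seq_len(kc))]
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / (H * W)
  out[(kr + 1):(kr + nrow(x)), (kc + 1):(kc + ncol(x))]
}

pad_sym <- function(x, pr, pc) {
  h <- nrow(x); w <- ncol(x)
  ridx <- c(pmin(rev(seq_len(pr)), h), seq_len(h), pmax(h + 1 - seq_len(pr), 1))
  cidx <- c(pmin(rev(seq_len(pc)), w), seq_len(w), pmax(w + 1 - seq_len(pc), 1))
  x[ridx, cidx, drop = FALSE]
}

#' Rotation-invariant uniform local binary pattern code image
#'
#' Radius-1, 8-point LBP. Diagonal sampling points are bilinearly
#' interpolated; the image border is replicate-padded. Uniform patterns
#' (at most two 0/1 transitions around the circle) code to the number of
#' set bits (0..8); non-uniform patterns code to 9.
#'
#' @param x Numeric matrix.
#' @return Integer-valued matrix of codes in `0..9`, same shape as `x`.
#' @export
lbp_image <- function(x) {
  h <- nrow(x); w <- ncol(x)
  xp <- pad_sym(x, 1, 1)
  # sampling offsets (dr, dc) at angles k * 45 deg, radius 1; row axis points down
  ang <- (0:7) * pi / 4
  dr <- -sin(ang); dc <- cos(ang)
  dr[abs(dr) < 1e-12] <- 0; dc[abs(dc) < 1e-12] <- 0
  dr[abs(dr - round(dr)) < 1e-12] <- round(dr[abs(dr - round(dr)) < 1e-12])
  dc[abs(dc - round(dc)) < 1e-12] <- round(dc[abs(dc - round(dc)) < 1e-12])
  ctr <- xp[2:(h + 1), 2:(w + 1)]
  bits <- vector("list", 8)
  for (k in 1:8) {
    rr <- 2:(h + 1) + dr[k]; cc <- 2:(w + 1) + dc[k]
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    r1 <- pmin(r0 + 1, h + 2); c1 <- pmin(c0 + 1, w + 2)
    # bilinear sample on padded image (outer products give full grids);
    # the clamped r1/c1 indices only ever carry zero weight
    v <- outer(1 - fr, 1 - fc) * xp[r0, c0] +
         outer(1 - fr, fc)     * xp[r0, c1] +
         outer(fr, 1 - fc)     * xp[r1, c0] +
         outer(fr, fc)         * xp[r1, c1]
    bits[[k]] <- (v >= ctr) * 1L
  }
  ones <- Reduce(`+`, bits)
  trans <- matrix(0L, h, w)
  for (k in 1:8) {
    nxt <- bits[[if (k == 8) 1 else k + 1]]
    trans <- trans + (bits[[k]] != nxt)
  }
  code <- ifelse(trans <= 2, ones, 9L)
  matrix(as.numeric(code), h, w)
}
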