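test_that("fixed-bin-width discretization follows the floor rule", {
  img <- matrix(rep(0:255, length.out = 256), 16, 16)
  msk <- matrix(TRUE, 16, 16)
  d <- discretize(img, msk, 25)
  expect_equal(d$ng, 11L)  # floor(255/25) + 1
  expect_true(all(d$levels[msk] >= 1 & d$levels[msk] <= 11))

  dc <- discretize(matrix(7, 8, 8), matrix(TRUE, 8, 8), 25)
  expect_equal(dc$ng, 1L)
  expect_true(all(dc$levels == 1L))

  expect_error(discretize(img, msk, 0), "bin_width")
  expect_error(discretize(img, msk, -3), "bin_width")
  expect_error(discretize(img, matrix(FALSE, 16, 16), 25), "empty mask")
})

test_that("point and gradient filters behave on degenerate inputs", {
  const <- matrix(5, 8, 8)
  expect_true(all(apply_filter(const, "gradient")$gradient == 0))
  expect_equal(stats::sd(apply_filter(const, "logarithm")$logarithm), 0)
  expect_equal(stats::sd(apply_filter(const, "exponential")$exponential), 0)
  expect_error(apply_filter(const, "no-such-filter"), "unknown filter")
  # rescaled point maps preserve the intensity range
  set.seed(1)
  x <- matrix(runif(64, 0, 255), 8, 8)
  for (f in c("logarithm", "squareroot", "square")) {
    y <- apply_filter(x, f)[[1]]
    expect_lte(max(abs(y)), max(x) * (1 + 1e-12))
  }
})

test_that("wavelet subbands isolate step-edge detail in the right channel", {
  x <- matrix(0, 8, 8); x[, 5:8] <- 1   # intensity varies along columns
  wb <- apply_filter(x, "wavelet")
  en <- vapply(wb, function(m) sum(m^2), numeric(1))
  expect_gt(en["wavelet-LH"], 1)
  expect_lt(en["wavelet-HL"], 1e-20)
  expect_lt(en["wavelet-HH"], 1e-20)
  # transposed edge flips the detail channel
  wb2 <- apply_filter(t(x), "wavelet")
  en2 <- vapply(wb2, function(m) sum(m^2), numeric(1))
  expect_gt(en2["wavelet-HL"], 1)
  expect_lt(en2["wavelet-LH"], 1e-20)
})

test_that("LoG filter clamps out-of-range sigma with a warning", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_warning(log_of_gaussian(img, 0.5, c(1, 1)), "clamped to 1 px")
  expect_warning(log_of_gaussian(img, 3, c(0.011, 0.011)), "exceeds")
  # a legal sigma produces a zero-mean-ish response on a constant image
  out <- log_of_gaussian(matrix(3, 32, 32), 2, c(1, 1))
  expect_lt(max(abs(out)), 1e-8)
})

test_that("LBP code image is rotation-invariant-uniform coded in 0..9", {
  set.seed(2)
  x <- matrix(runif(400), 20, 20)
  code <- lbp_image(x)
  expect_true(all(code %in% 0:9))
  # constant image: all neighbours >= center -> all bits set -> code 8
  expect_true(all(lbp_image(matrix(1, 10, 10)) == 8))
})

test_that("first-order features match closed forms and an independent oracle", {
  fo <- first_order_features(matrix(c(2, 2, 2, 2), 2, 2), matrix(TRUE, 2, 2))
  expect_equal(unname(fo["firstorder_Mean"]), 2)
  expect_equal(unname(fo["firstorder_Variance"]), 0)
  expect_equal(unname(fo["firstorder_Skewness"]), 0)
  expect_true("Skewness" %in% attr(fo, "flagged"))

  fo2 <- first_order_features(matrix(c(1, 2, 3, 4), 2, 2), matrix(TRUE, 2, 2))
  expect_equal(unname(fo2["firstorder_Mean"]), 2.5)
  expect_equal(unname(fo2["firstorder_Median"]), 2.5)
  expect_equal(unname(fo2["firstorder_Minimum"]), 1)
  expect_equal(unname(fo2["firstorder_Range"]), 3)

  # independent per-formula oracle on a random patch
  set.seed(5)
  img <- matrix(runif(256, 0, 255), 16, 16)
  msk <- matrix(TRUE, 16, 16)
  fo3 <- first_order_features(img, msk, bin_width = 25, spacing_mm = c(2, 3))
  x <- img[msk]; n <- length(x); mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  q <- stats::quantile(x, c(.1, .25, .75, .9), names = FALSE)
  rob <- x[x >= q[1] & x <= q[4]]
  lev <- floor((x - min(x)) / 25) + 1
  pr <- as.vector(table(lev)) / n
  expected <- c(mu, sort(x)[c(n / 2, n / 2 + 1)] |> mean(), min(x), max(x),
                max(x) - min(x), m2,
                sum((x - mu)^3) / n / m2^1.5, sum((x - mu)^4) / n / m2^2,
                sum(x^2), sum(x^2) * 6, -sum(pr * log2(pr)),
                q[1], q[4], q[3] - q[2], sum(abs(x - mu)) / n,
                sum(abs(rob - mean(rob))) / length(rob),
                sqrt(sum(x^2) / n), sum(pr^2))
  expect_equal(as.numeric(fo3), expected, tolerance = 1e-9)
})

test_that("2D shape descriptors match geometric references", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  sh <- shape2d_features(sq, c(1, 1))
  expect_equal(unname(sh["shape2D_PixelSurface"]), 100)
  expect_equal(unname(sh["shape2D_MeshSurface"]), 99.5)

  rr <- row(matrix(0, 50, 50)) - 25.5
  cc <- col(matrix(0, 50, 50)) - 25.5
  disk <- (rr^2 + cc^2) <= 20^2
  shd <- shape2d_features(disk, c(1, 1))
  expect_lt(abs(shd["shape2D_Sphericity"] - 1), 0.06)
  expect_lt(abs(shd["shape2D_MaximumDiameter"] - 40), 1.5)

  ln <- matrix(FALSE, 10, 10); ln[5, 2:9] <- TRUE
  expect_lt(shape2d_features(ln, c(1, 1))["shape2D_Elongation"], 1e-8)

  # physical units scale with spacing
  sh2 <- shape2d_features(sq, c(2, 2))
  expect_equal(unname(sh2["shape2D_PixelSurface"]), 400)
  expect_error(shape2d_features(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("texture families reproduce hand-enumerated toy cases", {
  # constant ROI: no contrast anywhere
  dcon <- make_disc(matrix(1L, 4, 4))
  g <- glcm_features(dcon)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_ClusterShade"]), 0)
  expect_equal(unname(g["glcm_Correlation"]), 1)  # flagged constant
  expect_true("Correlation" %in% attr(g, "flagged"))

  # 2x2 checkerboard: horizontal/vertical contrast 1, diagonal 0 -> mean 0.5
  dchk <- make_disc(matrix(c(1L, 2L, 2L, 1L), 2, 2))
  expect_equal(unname(glcm_features(dchk)["glcm_Contrast"]), 0.5)

  # single row of three equal pixels: horizontal run 9, other directions 1
  drow <- make_disc(matrix(1L, 1, 3))
  rl <- glrlm_features(drow)
  expect_equal(unname(rl["glrlm_LongRunHighGrayLevelEmphasis"]), (9 + 1 + 1 + 1) / 4)
  # constant single-row ROI: every direction collapses to one run cell
  expect_equal(unname(rl["glrlm_RunEntropy"]), 0)

  # constant 3x3 zone: one zone of size 9
  dz <- make_disc(matrix(1L, 3, 3))
  expect_equal(unname(glszm_features(dz)["glszm_LargeAreaHighGrayLevelEmphasis"]), 81)
  # all-distinct levels: every zone is a single pixel
  dd <- make_disc(matrix(1:9, 3, 3))
  expect_equal(unname(glszm_features(dd)["glszm_SmallAreaEmphasis"]), 1)

  # NGTDM of a constant region: all s_i zero, flagged constants
  ng <- ngtdm_features(dcon)
  expect_equal(unname(ng["ngtdm_Contrast"]), 0)
  expect_equal(unname(ng["ngtdm_Busyness"]), 0)
  expect_true("Busyness" %in% attr(ng, "flagged"))

  # spec GLDM toy grid against the exhaustive neighbour-count oracle
  dg <- make_disc(matrix(c(1L, 1L, 2L, 1L, 2L, 2L, 2L, 2L, 1L), 3, 3, byrow = TRUE))
  expect_equal(unname(gldm_features(dg)["gldm_DependenceVariance"]),
               unname(oracle_gldm_features(dg)["gldm_DependenceVariance"]),
               tolerance = 1e-12)
})

test_that("matrix-family features equal brute-force enumeration on random ROIs", {
  set.seed(10)
  for (s in 1:12) {
    h <- sample(4:12, 1); w <- sample(4:12, 1); ng <- sample(2:6, 1)
    d <- rand_disc(h, w, ng, seed = 400 + s)
    expect_feature_equal(glcm_features(d), oracle_glcm_features(d))
    expect_feature_equal(glrlm_features(d), oracle_glrlm_features(d))
    expect_feature_equal(glszm_features(d), oracle_glszm_features(d))
    expect_feature_equal(gldm_features(d), oracle_gldm_features(d))
    expect_feature_equal(ngtdm_features(d), oracle_ngtdm_features(d))
  }
})

test_that("texture features are translation invariant and shift-stable", {
  set.seed(3)
  img <- matrix(round(runif(144, 0, 255)), 12, 12)
  msk <- matrix(FALSE, 12, 12); msk[3:10, 2:11] <- TRUE
  cfg <- extraction_config(filters = "original",
                           families = c("firstorder", "glcm", "gldm"))
  base <- extract_features(img, msk, cfg)
  # translate image + mask together by padding two rows/cols
  img2 <- rbind(matrix(0, 2, 14), cbind(img, matrix(0, 12, 2)))
  msk2 <- rbind(matrix(FALSE, 2, 14), cbind(msk, matrix(FALSE, 12, 2)))
  expect_equal(extract_features(img2, msk2, cfg), base, tolerance = 1e-12)
  # constant intensity shift away from bin boundaries leaves levels unchanged
  shifted <- extract_features(img + 25, msk, cfg)
  tex <- grepl("_(glcm|gldm)_", names(base))
  expect_equal(shifted[tex], base[tex], tolerance = 1e-12)
})

test_that("extraction schema is deterministic and configuration-driven", {
  set.seed(4)
  img <- matrix(round(runif(1024, 0, 255)), 32, 32)
  msk <- matrix(FALSE, 32, 32); msk[8:24, ] <- TRUE
  cfg_min <- extraction_config(filters = "original",
                               families = c("firstorder", "shape2d"))
  v <- extract_features(img, msk, cfg_min)
  expect_length(v, 18 + 9)
  expect_identical(v, extract_features(img, msk, cfg_min))
  # a second eye yields the same schema
  img2 <- matrix(round(runif(1024, 0, 255)), 32, 32)
  expect_identical(names(extract_features(img2, msk, cfg_min)), names(v))
  expect_error(extract_features(img, matrix(FALSE, 32, 32), cfg_min), "mask")
})
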