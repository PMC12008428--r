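test_that("Snellen-to-logMAR conversion matches the closed form", {
  expect_equal(snellen_to_logmar(20, 20), 0)
  expect_equal(snellen_to_logmar(20, 200), 1)
  expect_equal(snellen_to_logmar(20, 63), log10(63 / 20))
  expect_error(snellen_to_logmar(0, 20), "positive")
})

test_that("residual-DME banding rule applies the four thresholds", {
  expect_true(classify_residual_dme(400, 370))    # 7.5% < 10%
  expect_false(classify_residual_dme(500, 420))   # 16% >= 15%
  expect_false(classify_residual_dme(601, 430))   # 28.5% >= 25%
  expect_true(classify_residual_dme(650, 520))    # 20% < 25% (band > 600)
  expect_true(classify_residual_dme(300, 320))    # worsening is residual
  expect_error(classify_residual_dme(0, 300), "positive")
  # monotone: for a fixed baseline, lowering post-CMT never flips
  # not-residual back to residual
  for (b in c(350, 450, 550, 700)) {
    res <- classify_residual_dme(rep(b, 200), seq(b * 1.1, b * 0.3,
                                                  length.out = 200))
    expect_true(all(diff(res) <= 0))  # once FALSE, stays FALSE as post drops
  }
})

test_that("the composite RDME label is the OR of its parts", {
  expect_false(rdme_label(FALSE, FALSE))
  expect_true(rdme_label(TRUE, FALSE))
  expect_true(rdme_label(FALSE, TRUE))
  expect_true(rdme_label(TRUE, TRUE))
})

test_that("BCVA dichotomization includes the 20/63 boundary in poor vision", {
  expect_true(dichotomize_bcva(1.0))
  expect_false(dichotomize_bcva(0.0))
  expect_true(dichotomize_bcva(log10(63 / 20)))
  expect_error(dichotomize_bcva(NaN), "finite")
})

test_that("univariate logistic regression is calibrated and flags separation", {
  set.seed(1)
  n <- 10000
  x <- rnorm(n)
  y0 <- rbinom(n, 1, 0.4)          # independent of x
  r0 <- univariate_logistic(x, y0)
  expect_gt(r0$or, 0.95); expect_lt(r0$or, 1.05)
  expect_false(r0$separation)
  expect_equal(r0$ci_lo, exp(r0$beta - 1.96 * r0$se), tolerance = 1e-12)
  expect_equal(r0$ci_hi, exp(r0$beta + 1.96 * r0$se), tolerance = 1e-12)
  # perfectly separating predictor
  ys <- as.integer(x > 0)
  rs <- univariate_logistic(x, ys)
  expect_true(rs$separation)
  expect_true(is.infinite(rs$or) || rs$or == 0)
  expect_error(univariate_logistic(x, rep(1, n)), "binary|both classes")
})

test_that("logistic estimates approach the true coefficient with n", {
  or_at <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + 0.56 * x))
    univariate_logistic(x, y)$or
  }
  expect_lt(abs(or_at(5000, 2) - exp(0.56)) / exp(0.56), 0.10)
  bias_small <- abs(mean(vapply(1:20, function(s) or_at(500, s), numeric(1))) - exp(0.56))
  bias_large <- abs(mean(vapply(1:20, function(s) or_at(5000, 100 + s), numeric(1))) - exp(0.56))
  expect_lt(bias_large, bias_small + 0.02)
})

test_that("backward stepwise keeps real predictors and obeys stay_p", {
  set.seed(3)
  n <- 1500
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  colnames(X) <- paste0("v", 1:6)
  y <- rbinom(n, 1, plogis(0.8 * X$v1))
  sw <- backward_stepwise_logistic(X, y)
  expect_true("v1" %in% sw$retained)
  expect_true(all(sw$final$p < 0.05))
  # single already-significant candidate passes through unchanged
  sw1 <- backward_stepwise_logistic(X[, "v1", drop = FALSE], y)
  expect_equal(sw1$retained, "v1")
  # all-null candidates usually end with an empty model
  empty <- vapply(1:20, function(s) {
    set.seed(100 + s)
    Xn <- as.data.frame(matrix(rnorm(400 * 4), 400, 4))
    yn <- rbinom(400, 1, 0.5)
    length(backward_stepwise_logistic(Xn, yn)$retained) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})

test_that("cluster comparison dispatches the right tests per variable type", {
  set.seed(4)
  g <- rep(1:4, times = c(40, 20, 20, 20))
  clin <- data.frame(
    const = rep(3.3, 100),
    shifted = c(rnorm(40), rnorm(20, 2), rnorm(20, 2), rnorm(20, 4)),
    cat_big = sample(c("a", "b"), 100, replace = TRUE),
    cat_small = c(rep("x", 97), rep("y", 3))
  )
  out <- compare_clusters(clin, g)
  expect_equal(unname(out$const$statistic), 0)
  expect_lt(out$shifted$p, 0.01)
  expect_false(is.null(out$shifted$dunn))
  expect_equal(out$cat_big$test, "chi-square")
  expect_equal(out$cat_small$test, "fisher")  # expected cell below 5
  expect_error(compare_clusters(clin, rep(1, 100)), "at least 2 clusters")
})

test_that("Dunn post-hoc z-tests agree with rank arithmetic", {
  set.seed(5)
  x <- c(rnorm(30), rnorm(30, 3))
  g <- rep(c("a", "b"), each = 30)
  d <- dunn_test(x, g)
  expect_equal(nrow(d), 1)
  expect_lt(d$p, 0.001)
  # z sign follows mean-rank ordering
  expect_gt(abs(d$z), 3)
  expect_equal(d$p_adj, min(1, d$p * 1))
  # no tie correction needed for continuous data: SE = sqrt(N(N+1)/12 * 2/30)
  r <- rank(x)
  z_hand <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt(60 * 61 / 12 * (1 / 30 + 1 / 30))
  expect_equal(d$z, z_hand, tolerance = 1e-12)
})

test_that("2x2 odds ratio matches the cross-product with Woolf interval", {
  tab <- rbind(c(12, 23), c(122, 77))
  o <- odds_ratio_woolf(tab)
  expect_equal(o$or, (12 * 77) / (23 * 122), tolerance = 1e-12)
  se <- sqrt(1 / 12 + 1 / 23 + 1 / 122 + 1 / 77)
  expect_equal(o$ci_lo, exp(log(o$or) - 1.96 * se), tolerance = 1e-12)
  expect_equal(o$ci_hi, exp(log(o$or) + 1.96 * se), tolerance = 1e-12)
})

test_that("intra-rater ICC behaves across agreement regimes", {
  set.seed(6)
  t1 <- rnorm(100)
  expect_equal(icc_intra_rater(t1, t1)$icc, 1, tolerance = 1e-9)
  ic0 <- icc_intra_rater(rnorm(200), rnorm(200))
  expect_lt(abs(ic0$icc), 0.12)
  # variance-component construction targeting ICC = 0.94
  set.seed(7)
  subj <- rnorm(500, 0, sqrt(0.94))
  m1 <- subj + rnorm(500, 0, sqrt(0.06))
  m2 <- subj + rnorm(500, 0, sqrt(0.06))
  ic <- icc_intra_rater(m1, m2)
  expect_lt(abs(ic$icc - 0.94), 0.02)
  expect_lt(ic$ci_lo, ic$icc); expect_gt(ic$ci_hi, ic$icc)
  expect_error(icc_intra_rater(1:2, 1:2), "at least 3")
})
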