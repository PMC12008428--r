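test_that("collinearity pruning removes duplicates and respects the threshold", {
  set.seed(1)
  a <- rnorm(60)
  tab <- data.frame(a = a, b = a, c = rnorm(60))
  kept <- prune_collinear(tab, 0.8)
  expect_true("c" %in% kept)
  expect_equal(sum(c("a", "b") %in% kept), 1)
  # no retained pair above threshold
  cm <- abs(cor(tab[, kept])); diag(cm) <- 0
  expect_true(all(cm <= 0.8))
})

test_that("independent features all survive pruning at large n", {
  set.seed(2)
  tab <- as.data.frame(matrix(rnorm(5000 * 8), 5000, 8))
  expect_length(prune_collinear(tab, 0.8), 8)
})

test_that("threshold zero keeps a single feature per correlated block", {
  set.seed(3)
  tab <- as.data.frame(matrix(rnorm(50 * 4), 50, 4))
  expect_length(prune_collinear(tab, 0), 1)
})

test_that("pruning is invariant to row order", {
  set.seed(4)
  x <- matrix(rnorm(80 * 6), 80, 6)
  x[, 2] <- x[, 1] + rnorm(80, sd = 0.1)
  x[, 5] <- -x[, 4] + rnorm(80, sd = 0.1)
  tab <- as.data.frame(x)
  expect_identical(prune_collinear(tab, 0.8),
                   prune_collinear(tab[sample(80), ], 0.8))
})

test_that("ANOVA screen keeps separated features and drops flat ones", {
  set.seed(5)
  g <- rep(1:3, each = 15)
  tab <- data.frame(flat = rep(2, 45),
                    sep = g + rnorm(45, sd = 0.01),
                    noise = rnorm(45))
  kept <- suppressWarnings(anova_filter(tab, g, alpha = 0.05))
  expect_true("sep" %in% kept)
  expect_false("flat" %in% kept)
  p <- attr(kept, "p_values")
  expect_equal(unname(p["flat"]), 1)
  expect_error(anova_filter(tab, rep(1, 45)), "at least 2 groups")
  expect_error(anova_filter(tab[1:16, ], c(rep(1, 15), 2)), "at least 2 members")
})

test_that("vectorized ANOVA equals anova(lm()) per feature", {
  set.seed(6)
  x <- matrix(rnorm(60 * 5), 60, 5); colnames(x) <- paste0("f", 1:5)
  g <- rep(1:4, each = 15)
  p <- attr(anova_filter(as.data.frame(x), g, alpha = 1), "p_values")
  for (j in 1:5) {
    expect_equal(unname(p[j]),
                 anova(lm(x[, j] ~ factor(g)))$`Pr(>F)`[1],
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment can only shrink the retained set", {
  set.seed(7)
  x <- as.data.frame(matrix(rnorm(90 * 20), 90, 20))
  g <- rep(1:3, each = 30)
  raw <- anova_filter(x, g, alpha = 0.2, fdr = FALSE)
  bh <- anova_filter(x, g, alpha = 0.2, fdr = TRUE)
  expect_true(all(bh %in% raw))
})

test_that("Boruta confirms planted predictors and is reproducible", {
  set.seed(8)
  n <- 200
  x <- matrix(rnorm(n * 20), n, 20); colnames(x) <- paste0("f", 1:20)
  y <- rbinom(n, 1, plogis(2 * (x[, 1] + x[, 2] + x[, 3]) / sqrt(3)))
  b <- boruta_select(as.data.frame(x), y, max_iter = 60, seed = 9,
                     rf_trees = 300)
  expect_true(all(paste0("f", 1:3) %in% b$confirmed))
  expect_equal(nrow(b$importance_history), b$iterations)
  b2 <- boruta_select(as.data.frame(x), y, max_iter = 60, seed = 9,
                      rf_trees = 300)
  expect_identical(b$confirmed, b2$confirmed)
  expect_identical(b$rejected, b2$rejected)
  expect_error(boruta_select(as.data.frame(x), rep(1, n)), "binary")
})

test_that("a single iteration leaves every feature tentative", {
  set.seed(10)
  x <- as.data.frame(matrix(rnorm(50 * 6), 50, 6))
  y <- rbinom(50, 1, 0.5)
  b <- boruta_select(x, y, max_iter = 1, seed = 1, rf_trees = 100,
                     rough_fix = FALSE)
  expect_length(b$tentative, 6)
  expect_length(b$confirmed, 0)
})

test_that("on pure noise the vast majority of features are rejected", {
  # a handful of chance in-sample associations may be confirmed (all-relevant
  # semantics); the bulk must be rejected
  set.seed(11)
  x <- matrix(rnorm(200 * 40), 200, 40); colnames(x) <- paste0("f", 1:40)
  y <- rbinom(200, 1, 0.5)
  b <- boruta_select(as.data.frame(x), y, max_iter = 60, seed = 12,
                     rf_trees = 300)
  expect_gte(length(b$rejected), 32)     # >= 80% rejected
  expect_lte(length(b$confirmed), 4)     # <= 10% confirmed
})

test_that("the cascade stages are nested and partition correctly", {
  pl <- make_planted_table(n = 120, p = 25, k = 4, sep = 3, seed = 13)
  tab <- pl$table
  tab$dup <- tab$f1  # guarantee stage-1 activity
  set.seed(14)
  outcome <- rbinom(120, 1, plogis(scale(tab$f1)))
  sel <- select_features(tab, pl$labels, outcome, max_iter = 40,
                         rf_trees = 200, seed = 15)
  expect_true(all(sel$stage2 %in% sel$stage1))
  s3 <- c(sel$stage3_confirmed, sel$stage3_tentative, sel$stage3_rejected)
  expect_setequal(s3, sel$stage2)
  expect_lt(length(sel$stage1), ncol(tab))
})

test_that("Boruta confirmations are monotone in the planted effect size", {
  set.seed(16)
  n <- 150
  x <- matrix(rnorm(n * 15), n, 15); colnames(x) <- paste0("f", 1:15)
  run <- function(beta) {
    set.seed(17)
    y <- rbinom(n, 1, plogis(beta * x[, 1]))
    b <- boruta_select(as.data.frame(x), y, max_iter = 40, seed = 18,
                       rf_trees = 200)
    "f1" %in% b$confirmed
  }
  weak <- run(0.3); strong <- run(3)
  expect_true(strong)
  expect_gte(strong, weak)
})
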