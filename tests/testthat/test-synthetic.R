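test_that("cohort configuration validates its inputs", {
  expect_error(cohort_config(n_eyes = 0), "positive")
  expect_error(cohort_config(n_eyes = 3), "n_eyes must be >=")
  expect_error(cohort_config(class_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(cohort_config(outcome_link = list(rdme = c(0.5, 1.2, 0.3, 0.1),
                                                 vision_poor = rep(0.5, 4))),
               "\\[0, 1\\]")
  expect_error(cohort_config(pixel_spacing_mm = 0), "positive")
})

test_that("class counts follow largest-remainder apportionment", {
  cfg <- cohort_config(n_eyes = 8, class_proportions = rep(0.25, 4),
                       image_size = c(16, 16), seed = 1)
  coh <- generate_cohort(cfg)
  expect_equal(as.vector(table(coh$clinical$true_class)), rep(2L, 4))
  expect_length(coh$eyes, 8)
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n_eyes = 6, image_size = c(32, 32), seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$eyes, `[[`, "image"), lapply(b$eyes, `[[`, "image"))
  expect_identical(a$clinical, b$clinical)
  cfg2 <- cohort_config(n_eyes = 6, image_size = c(32, 32), seed = 10)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a$eyes[[1]]$image, c2$eyes[[1]]$image))
})

test_that("rendered B-scans have valid masks and 8-bit intensities", {
  cfg <- cohort_config(n_eyes = 5, image_size = c(48, 48), seed = 2)
  coh <- generate_cohort(cfg)
  for (e in coh$eyes) {
    expect_true(all(e$image >= 0 & e$image <= 255))
    expect_true(all(e$image == round(e$image)))
    expect_gte(sum(e$mask), 0.10 * length(e$mask))
    expect_identical(dim(e$mask), dim(e$image))
  }
})

test_that("noise-free cyst-free scans are constant within layer bands", {
  tp <- default_texture_params()[1, ]
  tp$cyst_density <- 0; tp$focus_density <- 0; tp$layer_amp <- 0; tp$base_sd <- 0
  set.seed(7)
  bs <- generate_bscan(tp, c(64, 64), noise_sd = 0)
  # every row inside the band is constant across columns (layer profile only)
  rows <- which(rowSums(bs$mask) > 0)
  for (r in rows) expect_equal(stats::sd(bs$image[r, ]), 0)
  # determinism under identical RNG state
  set.seed(7)
  bs2 <- generate_bscan(tp, c(64, 64), noise_sd = 0)
  expect_identical(bs$image, bs2$image)
})

test_that("degenerate outcome links force the labels", {
  for (p in c(0, 1)) {
    cfg <- cohort_config(n_eyes = 12, image_size = c(16, 16),
                         outcome_link = list(rdme = rep(p, 4),
                                             vision_poor = rep(0.5, 4)),
                         seed = 3)
    coh <- generate_cohort(cfg)
    expect_true(all(coh$clinical$rdme == as.logical(p)))
  }
})

test_that("empirical outcome rates match the link probabilities", {
  # law-of-large-numbers check on the class-4 reference rate
  set.seed(3)
  link <- list(rdme = c(0.59, 0.69, 0.59, 0.34), vision_poor = rep(0.5, 4))
  draws <- vapply(seq_len(10000), function(i) {
    link_outcomes(4, link, cmt_baseline_um = 420)$rdme
  }, logical(1))
  expect_lt(abs(mean(draws) - 0.34), 0.01)

  # per-class empirical RDME rates inside simultaneous binomial bounds at
  # cohort scale (99% per class ~ 95% jointly over the four classes)
  cfg <- cohort_config(n_eyes = 234,
                       class_proportions = c(0.52, 0.19, 0.14, 0.15),
                       outcome_link = list(rdme = c(0.59, 0.69, 0.59, 0.34),
                                           vision_poor = rep(0.5, 4)),
                       image_size = c(16, 16), seed = 7)
  coh <- generate_cohort(cfg)
  tab <- table(coh$clinical$true_class, coh$clinical$rdme)
  n_c <- rowSums(tab)
  for (k in 1:4) {
    p0 <- cfg$outcome_link$rdme[k]
    ci <- stats::qbinom(c(0.005, 0.995), n_c[k], p0)
    expect_gte(tab[k, "TRUE"], ci[1])
    expect_lte(tab[k, "TRUE"], ci[2])
  }
})

test_that("synthesized CMT pairs round-trip through the residual rule", {
  cfg <- cohort_config(n_eyes = 120, image_size = c(16, 16), seed = 13)
  coh <- generate_cohort(cfg)
  cl <- coh$clinical
  residual_rederived <- classify_residual_dme(cl$cmt_baseline_um, cl$cmt_post_um)
  rdme_rederived <- rdme_label(residual_rederived, cl$recurrence_within_6mo)
  expect_identical(rdme_rederived, cl$rdme)
  # vision label consistent with the 6-month logMAR draw
  expect_identical(dichotomize_bcva(cl$bcva_logmar_6mo), cl$vision_poor)
})

test_that("cyst density differences are detectable in first-order statistics", {
  tp0 <- default_texture_params()[1, ]; tp0$cyst_density <- 0.5
  tp1 <- tp0; tp1$cyst_density <- 5
  set.seed(21)
  mean_of <- function(tp) {
    vapply(1:40, function(i) {
      bs <- generate_bscan(tp, c(48, 48), noise_sd = 0.02)
      mean(bs$image[bs$mask])
    }, numeric(1))
  }
  m0 <- mean_of(tp0); m1 <- mean_of(tp1)
  expect_lt(stats::t.test(m0, m1)$p.value, 0.01)
})
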