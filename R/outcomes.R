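#' Convert a Snellen fraction to logMAR
#'
#' `logMAR = log10(denominator / numerator)`; 20/20 maps to 0, 20/200 to 1.
#' @param numerator,denominator Positive numbers of the Snellen fraction.
#' @return logMAR value.
#' @export
snellen_to_logmar <- function(numerator, denominator) {
  if (any(numerator <= 0) || any(denominator <= 0)) {
    stop("Snellen components must be positive")
  }
  log10(denominator / numerator)
}

#' Classify residual DME from the CMT reduction rule
#'
#' Residual edema means the central macular thickness (CMT) reduction after
#' the loading injections fell short of the band-specific criterion:
#' below 10% for baseline CMT <= 400 um, below 15% for 401-500 um, below 20%
#' for 501-600 um and below 25% above 600 um. A negative reduction
#' (thickening) is residual in every band.
#'
#' @param cmt_baseline_um,cmt_post_um Positive thicknesses in micrometres
#'   (vectorized).
#' @return Logical vector: `TRUE` = residual DME.
#' @export
classify_residual_dme <- function(cmt_baseline_um, cmt_post_um) {
  if (any(cmt_baseline_um <= 0) || any(cmt_post_um <= 0)) {
    stop("CMT values must be positive")
  }
  reduction <- (cmt_baseline_um - cmt_post_um) / cmt_baseline_um
  reduction < residual_threshold(cmt_baseline_um)
}

# band-specific minimum fractional CMT reduction
residual_threshold <- function(cmt_baseline_um) {
  ifelse(cmt_baseline_um <= 400, 0.10,
  ifelse(cmt_baseline_um <= 500, 0.15,
  ifelse(cmt_baseline_um <= 600, 0.20, 0.25)))
}

#' Residual/recurrent DME label
#'
#' The composite endpoint: residual edema after the loading phase OR fluid
#' re-emergence within six months.
#' @param residual,recurrence_within_6mo Logical vectors.
#' @return Logical vector.
#' @export
rdme_label <- function(residual, recurrence_within_6mo) {
  residual | recurrence_within_6mo
}

#' Dichotomize visual acuity at the 20/63 boundary
#'
#' Poor vision is BCVA of 20/63 or worse at six months, i.e.
#' `logMAR >= log10(63/20)`; the boundary itself counts as poor.
#' @param logmar_6mo logMAR at six months.
#' @param threshold_logmar Dichotomization point (default `log10(63/20)`).
#' @return Logical vector: `TRUE` = poor vision.
#' @export
dichotomize_bcva <- function(logmar_6mo, threshold_logmar = log10(63 / 20)) {
  if (any(!is.finite(logmar_6mo))) stop("logMAR must be finite")
  logmar_6mo >= threshold_logmar
}

#' Univariate logistic regression of one feature on a binary outcome
#'
#' Maximum-likelihood single-predictor fit with Wald standard error and P
#' value; the odds ratio and its 95% CI are `exp(beta +/- 1.96 SE)`.
#' Quasi-complete separation is detected (glm convergence warning or an
#' absurd coefficient) and flagged, with an infinite-OR sentinel.
#'
#' @param feature Numeric predictor.
#' @param outcome Binary outcome (logical, 0/1 or 2-level factor).
#' @return One-row data frame: `beta`, `se`, `p`, `or`, `ci_lo`, `ci_hi`,
#'   `separation`.
#' @export
univariate_logistic <- function(feature, outcome) {
  y <- as_binary(outcome)
  if (length(unique(y)) < 2) stop("outcome must have both classes present")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ feature, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  beta <- co["feature", "Estimate"]; se <- co["feature", "Std. Error"]
  if (abs(beta) > 20) sep <- TRUE
  if (sep) {
    data.frame(beta = beta, se = se, p = NA_real_,
               or = ifelse(beta > 0, Inf, 0), ci_lo = NA_real_,
               ci_hi = NA_real_, separation = TRUE)
  } else {
    data.frame(beta = beta, se = se, p = co["feature", "Pr(>|z|)"],
               or = exp(beta), ci_lo = exp(beta - 1.96 * se),
               ci_hi = exp(beta + 1.96 * se), separation = FALSE)
  }
}

as_binary <- function(outcome) {
  if (is.logical(outcome)) return(as.integer(outcome))
  if (is.factor(outcome)) {
    if (nlevels(outcome) != 2) stop("outcome must be binary")
    return(as.integer(outcome) - 1L)
  }
  u <- sort(unique(outcome))
  if (length(u) != 2) stop("outcome must be binary")
  as.integer(outcome == u[2])
}

#' Backward stepwise multivariable logistic regression
#'
#' Candidates entering at univariate `P < entry_p` start in a joint model;
#' the predictor with the largest Wald P is removed while that P is at or
#' above `stay_p`, until every remaining predictor satisfies `stay_p`.
#'
#' @param table Data frame of candidate predictors.
#' @param outcome Binary outcome.
#' @param entry_p Univariate entry threshold (default 0.1).
#' @param stay_p Wald stay threshold (default 0.05).
#' @return `oct_stepwise` list: `univariate` (all candidates), `final`
#'   (coefficient table of the surviving model, possibly empty), `retained`.
#' @export
backward_stepwise_logistic <- function(table, outcome, entry_p = 0.1,
                                       stay_p = 0.05) {
  x <- as.data.frame(table)
  y <- as_binary(outcome)
  uni <- do.call(rbind, lapply(colnames(x), function(nm) {
    cbind(feature = nm, univariate_logistic(x[[nm]], y))
  }))
  entrants <- uni$feature[!is.na(uni$p) & uni$p < entry_p]
  current <- as.character(entrants)
  final <- NULL
  while (length(current) > 0) {
    dat <- x[, current, drop = FALSE]
    dat$.y <- y
    fit <- suppressWarnings(
      stats::glm(.y ~ ., family = stats::binomial(), data = dat)
    )
    co <- summary(fit)$coefficients
    co <- co[setdiff(rownames(co), "(Intercept)"), , drop = FALSE]
    pv <- co[, "Pr(>|z|)"]
    if (max(pv) < stay_p) {
      final <- data.frame(
        feature = current[match(rownames(co), make.names(current))],
        beta = co[, "Estimate"], se = co[, "Std. Error"], p = pv,
        or = exp(co[, "Estimate"]),
        ci_lo = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
        ci_hi = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
        row.names = NULL
      )
      break
    }
    worst <- rownames(co)[which.max(pv)]
    current <- current[make.names(current) != worst]
  }
  structure(list(univariate = uni, final = final,
                 retained = if (is.null(final)) character(0) else final$feature,
                 entry_p = entry_p, stay_p = stay_p),
            class = "oct_stepwise")
}

#' Compare clinical variables across clusters
#'
#' For continuous variables: Shapiro-Wilk normality, the Kruskal-Wallis H
#' test across clusters and Dunn's pairwise post-hoc z-tests
#' (Bonferroni-corrected), with per-cluster median (IQR). For categorical
#' variables: chi-square test, switching to Fisher's exact test when any
#' expected cell count is below 5, with per-cluster counts (%).
#'
#' @param clinical Data frame of per-eye variables.
#' @param labels Cluster labels (length `nrow(clinical)`).
#' @param continuous,categorical Names of columns to treat as each type
#'   (defaults: numeric columns are continuous, the rest categorical).
#' @return List with one entry per variable: test name, P value, per-cluster
#'   summaries, and for significant continuous variables the Dunn table.
#' @export
compare_clusters <- function(clinical, labels, continuous = NULL,
                             categorical = NULL) {
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 clusters")
  if (is.null(continuous)) {
    continuous <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  }
  if (is.null(categorical)) {
    categorical <- setdiff(names(clinical), continuous)
  }
  out <- list()
  for (v in continuous) {
    xv <- clinical[[v]]
    if (all(is.na(xv))) next
    sw <- tryCatch(stats::shapiro.test(xv)$p.value, error = function(e) NA)
    if (stats::var(xv, na.rm = TRUE) == 0) {
      kw <- list(statistic = 0, p.value = 1)   # constant variable
    } else {
      kw <- stats::kruskal.test(xv, g)
    }
    med <- tapply(xv, g, function(z) {
      q <- stats::quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
    })
    ent <- list(variable = v, type = "continuous", test = "kruskal-wallis",
                statistic = unname(kw$statistic), p = kw$p.value,
                shapiro_p = sw, per_cluster = med)
    if (!is.na(kw$p.value) && kw$p.value < 0.05) {
      ent$dunn <- dunn_test(xv, g)
    }
    out[[v]] <- ent
  }
  for (v in categorical) {
    xv <- factor(clinical[[v]])
    if (all(is.na(xv))) next
    tab <- table(xv, g)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      ft <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                               B = 1e4)
      ent <- list(variable = v, type = "categorical", test = "fisher",
                  p = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      ent <- list(variable = v, type = "categorical", test = "chi-square",
                  statistic = unname(ct$statistic), p = ct$p.value)
    }
    pct <- sweep(tab, 2, colSums(tab), "/") * 100
    ent$per_cluster <- matrix(sprintf("%d (%.2f)", tab, pct), nrow(tab),
                              dimnames = dimnames(tab))
    out[[v]] <- ent
  }
  out
}

#' Dunn's pairwise post-hoc test on ranks
#'
#' Pairwise z-statistics on mean ranks with the tie correction, two-sided P,
#' Bonferroni-adjusted.
#' @param x Numeric vector.
#' @param g Group factor.
#' @return Data frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- table(g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- unname(rbar[[i]] - rbar[[j]]) / se
    c(z, 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res[1, ], p = res[2, ])
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' 2x2 odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d) / (b c)` for a table
#' `rbind(c(a, b), c(c, d))`, with the Woolf (log) 95% interval.
#' @param tab 2x2 numeric matrix of counts.
#' @return List: `or`, `ci_lo`, `ci_hi`.
#' @export
odds_ratio_woolf <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_lo = exp(log(or) - 1.96 * se),
       ci_hi = exp(log(or) + 1.96 * se))
}

#' Outcome rates and cluster-vs-rest odds ratios from a count table
#'
#' Reconstructs the percentages of a cluster-by-outcome count summary and
#' the odds ratio of one cluster against the pooled remaining clusters.
#'
#' @param counts Data frame with columns `cluster`, `n_eyes`, and paired
#'   yes/no count columns (e.g. `rdme_yes`, `rdme_no`).
#' @param outcome Prefix of the count pair (e.g. `"rdme"`).
#' @param vs_cluster Cluster id contrasted against the pooled rest.
#' @return List: `rates_pct` (per-cluster percentage of `<outcome>_yes`),
#'   `overall_pct`, `or` (with Woolf CI) for `vs_cluster` vs rest.
#' @export
outcome_rate_table <- function(counts, outcome = "rdme", vs_cluster = 4) {
  yes <- counts[[paste0(outcome, "_yes")]]
  no <- counts[[paste0(outcome, "_no")]]
  stopifnot(all(yes + no == counts$n_eyes))
  rates <- 100 * yes / (yes + no)
  sel <- counts$cluster == vs_cluster
  tab <- rbind(c(sum(yes[sel]), sum(no[sel])),
               c(sum(yes[!sel]), sum(no[!sel])))
  list(rates_pct = stats::setNames(rates, counts$cluster),
       overall_pct = 100 * sum(yes) / sum(yes + no),
       or = odds_ratio_woolf(tab))
}

#' Intra-rater intraclass correlation (two-way mixed, consistency, single)
#'
#' ICC(3,1) for two repeated measurements on the same subjects:
#' `(MSR - MSE) / (MSR + (k-1) MSE)` from the two-way (subject x rater)
#' mean squares, with the F-based 95% confidence interval.
#'
#' @param t1,t2 Paired numeric vectors (or matrices, flattened cell-wise)
#'   of first and second measurements; at least 3 subjects.
#' @return List: `icc`, `ci_lo`, `ci_hi`, `n`.
#' @export
icc_intra_rater <- function(t1, t2) {
  x1 <- as.numeric(t1); x2 <- as.numeric(t2)
  if (length(x1) != length(x2)) stop("paired measurements must match")
  n <- length(x1)
  if (n < 3) stop("need at least 3 subjects")
  k <- 2
  m <- cbind(x1, x2)
  subj_means <- rowMeans(m)
  rater_means <- colMeans(m)
  grand <- mean(m)
  msr <- k * sum((subj_means - grand)^2) / (n - 1)
  msc <- n * sum((rater_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(subj_means, rep(1, k)) -
                outer(rep(1, n), rater_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f0 <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f0 / stats::qf(0.975, df1, df2)
  fu <- f0 * stats::qf(0.975, df2, df1)
  list(icc = icc,
       ci_lo = (fl - 1) / (fl + k - 1),
       ci_hi = (fu - 1) / (fu + k - 1),
       n = n)
}
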