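#' Greedy collinearity pruning
#'
#' Repeatedly finds the pair of retained features with the largest absolute
#' Pearson correlation above `r_threshold` and drops the member with the
#' larger mean absolute correlation to all other retained features (ties
#' broken by column order: the later column is dropped). Terminates when no
#' retained pair exceeds the threshold, so the output set is guaranteed
#' pairwise-decorrelated at the threshold. Correlations that are undefined
#' (constant columns) are treated as 0.
#'
#' @param table Numeric feature table.
#' @param r_threshold Absolute-correlation threshold (default 0.8).
#' @return Character vector of retained column names (original order).
#' @export
prune_collinear <- function(table, r_threshold = 0.8) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 rows")
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  keep <- rep(TRUE, ncol(x))
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    if (all(sub <= r_threshold)) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ki <- which(keep)
    a <- ki[w[1]]; b <- ki[w[2]]
    mean_a <- mean(cm[a, keep])
    mean_b <- mean(cm[b, keep])
    drop <- if (mean_a > mean_b) a else if (mean_b > mean_a) b else max(a, b)
    keep[drop] <- FALSE
  }
  colnames(x)[keep]
}

#' One-way ANOVA screening of features across groups
#'
#' Classic fixed-effects one-way F-test per feature across the group labels,
#' computed in vectorized form (identical to `anova(lm(feature ~ group))`);
#' features with `P < alpha` are retained, optionally after Benjamini-
#' Hochberg adjustment.
#'
#' @param table Numeric feature table.
#' @param groups Group labels (>= 2 groups, each with >= 2 members).
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg adjustment before thresholding.
#' @return Character vector of retained names; attribute `p_values` carries
#'   the per-feature (possibly adjusted) P values.
#' @export
anova_filter <- function(table, groups, alpha = 0.05, fdr = FALSE) {
  x <- as.matrix(table)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  n <- nrow(x); kg <- nlevels(g)
  gm <- rowsum(x, g) / as.vector(table(g))       # group means (k x p)
  grand <- colMeans(x)
  ssb <- colSums(as.vector(table(g)) * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(x, 2, grand)^2)
  ssw <- sst - ssb
  df1 <- kg - 1; df2 <- n - kg
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1   # fully constant feature: F = 0/0, keep out
  p[ssw == 0 & ssb > 0] <- 0    # perfect separation
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  retained <- colnames(x)[!is.na(p) & p < alpha]
  attr(retained, "p_values") <- stats::setNames(p, colnames(x))
  retained
}

#' Boruta all-relevant feature selection
#'
#' The canonical shadow-feature wrapper: each iteration appends a permuted
#' ("shadow") copy of every still-undecided-or-confirmed feature, fits a
#' random forest (impurity importance, via `ranger`), and scores a *hit* for
#' every real feature whose importance exceeds the maximum shadow
#' importance. Accumulated hits are tested against Binomial(iterations, 1/2)
#' two-sidedly with Bonferroni correction across the still-undecided
#' features: significantly many hits confirms a feature, significantly few
#' rejects it (rejected features leave the model). The loop stops when all
#' features are decided or `max_iter` is reached; remaining tentative
#' features are resolved by comparing their median importance against the
#' median of the per-iteration maximum shadow importance (`rough_fix`,
#' on by default, mirroring the usual tentative rough fix).
#'
#' @param table Numeric feature table.
#' @param target Binary outcome (two levels), length `nrow(table)`.
#' @param max_iter Maximum iterations (default 500).
#' @param seed Integer seed.
#' @param rf_trees Trees per forest.
#' @param p_value Test level before Bonferroni correction (default 0.05).
#' @param rough_fix Resolve leftover tentative features at termination.
#' @return `oct_boruta` list: `confirmed`, `tentative`, `rejected` (name
#'   vectors partitioning the input features), `importance_history`
#'   (iterations x features, NA once a feature leaves the model) and
#'   `shadow_max_history`.
#' @export
boruta_select <- function(table, target, max_iter = 500, seed = 1,
                          rf_trees = 500, p_value = 0.05, rough_fix = TRUE) {
  x <- as.matrix(table)
  if (nrow(x) < 20) stop("need at least 20 rows")
  y <- factor(target)
  if (nlevels(y) != 2) stop("target must be binary")
  p <- ncol(x)
  feat <- colnames(x)
  if (is.null(feat)) feat <- paste0("V", seq_len(p))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  status <- rep("tentative", p)   # tentative / confirmed / rejected
  hits <- integer(p)
  tested_rounds <- 0L
  hist <- matrix(NA_real_, 0, p, dimnames = list(NULL, feat))
  shadow_hist <- numeric(0)

  for (it in seq_len(max_iter)) {
    active <- status != "rejected"
    if (!any(status == "tentative")) break
    xa <- x[, active, drop = FALSE]
    sh <- apply(xa, 2, sample)
    # at least 5 shadows, as in the reference algorithm
    while (ncol(sh) < 5) sh <- cbind(sh, apply(xa, 2, sample))
    colnames(sh) <- paste0("shadow_", seq_len(ncol(sh)))
    dat <- data.frame(cbind(xa, sh))
    dat$.y <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = rf_trees, importance = "impurity",
      seed = sample.int(2^30, 1), num.threads = 1
    )
    imp <- fit$variable.importance
    sh_max <- max(imp[grepl("^shadow_", names(imp))])
    real_imp <- imp[make.names(colnames(xa))]
    hit <- real_imp > sh_max
    hits[active] <- hits[active] + hit
    tested_rounds <- tested_rounds + 1L
    row <- rep(NA_real_, p); row[active] <- real_imp
    hist <- rbind(hist, row)
    shadow_hist <- c(shadow_hist, sh_max)

    und <- which(status == "tentative")
    n_und <- length(und)
    p_up <- stats::pbinom(hits[und] - 1L, tested_rounds, 0.5,
                          lower.tail = FALSE)
    p_dn <- stats::pbinom(hits[und], tested_rounds, 0.5, lower.tail = TRUE)
    status[und][pmin(p_up * n_und, 1) < p_value] <- "confirmed"
    und2 <- which(status == "tentative")
    p_dn <- p_dn[match(und2, und)]
    status[und2][pmin(p_dn * length(und2), 1) < p_value] <- "rejected"
  }

  if (rough_fix && any(status == "tentative")) {
    med_sh <- stats::median(shadow_hist)
    for (iu in which(status == "tentative")) {
      mi <- stats::median(hist[, iu], na.rm = TRUE)
      status[iu] <- if (isTRUE(mi > med_sh)) "confirmed" else "rejected"
    }
    resolved <- TRUE
  } else resolved <- FALSE

  structure(list(
    confirmed = feat[status == "confirmed"],
    tentative = feat[status == "tentative"],
    rejected = feat[status == "rejected"],
    hits = stats::setNames(hits, feat),
    iterations = tested_rounds,
    importance_history = hist,
    shadow_max_history = shadow_hist,
    rough_fixed = resolved
  ), class = "oct_boruta")
}

#' Three-stage feature-selection cascade
#'
#' Stage 1 prunes collinear features (|r| > `r_threshold`); stage 2 screens
#' the survivors with one-way ANOVA across the cluster labels; stage 3 runs
#' Boruta against a binary outcome on the stage-2 set. The stage sets are
#' nested by construction.
#'
#' @param table Feature table.
#' @param cluster_labels Cluster labels for the ANOVA screen.
#' @param outcome Binary outcome for Boruta.
#' @param r_threshold,alpha,fdr,max_iter,rf_trees,seed Stage parameters.
#' @return `oct_selection` list: `stage1`, `stage2`, `stage3_confirmed`,
#'   `stage3_tentative`, `stage3_rejected`, `boruta` (full stage-3 object),
#'   `parameters`.
#' @export
select_features <- function(table, cluster_labels, outcome,
                            r_threshold = 0.8, alpha = 0.05, fdr = FALSE,
                            max_iter = 500, rf_trees = 500, seed = 1) {
  s1 <- prune_collinear(table, r_threshold)
  s2 <- anova_filter(table[, s1, drop = FALSE], cluster_labels, alpha, fdr)
  bor <- boruta_select(table[, s2, drop = FALSE], outcome,
                       max_iter = max_iter, rf_trees = rf_trees, seed = seed)
  structure(list(
    stage1 = s1, stage2 = as.character(s2),
    stage3_confirmed = bor$confirmed,
    stage3_tentative = bor$tentative,
    stage3_rejected = bor$rejected,
    boruta = bor,
    parameters = list(r_threshold = r_threshold, alpha = alpha, fdr = fdr,
                      max_iter = max_iter, rf_trees = rf_trees, seed = seed)
  ), class = "oct_selection")
}
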