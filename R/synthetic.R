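#' Synthetic OCT-like cohort configuration
#'
#' Parameters of the synthetic B-scan cohort generator. Defaults emulate the
#' reference DME cohort the pipeline targets: 234 eyes in four latent
#' texture phenotypes with class shares 122/45/32/35 of 234 and
#' cluster-linked binary outcomes (residual/recurrent edema prevalences
#' 59.0/68.9/59.4/34.3%, poor-vision prevalences 57.4/60.0/65.6/28.6%).
#' Class texture parameters control the rendered motifs: dark cystoid
#' ellipses, bright hyperreflective foci, a layered reflectivity profile
#' with smooth disruption.
#'
#' @param n_eyes Number of eyes (>= n_classes).
#' @param n_classes Number of latent phenotypes.
#' @param class_proportions Simplex vector of class shares (sums to 1).
#' @param image_size (H, W) in pixels.
#' @param pixel_spacing_mm Isotropic pixel spacing in mm.
#' @param texture_params Data frame with one row per class and columns
#'   `cyst_density` (cysts per 1000 mask px), `cyst_r_min`, `cyst_r_max`
#'   (px), `focus_density` (foci per 1000 mask px), `layer_amp` (disruption
#'   amplitude on \[0,1\]), `base_mean`, `base_sd` (\[0,1\] reflectivity).
#' @param outcome_link List with per-class Bernoulli probabilities `rdme`
#'   and `vision_poor`.
#' @param noise_sd Additive Gaussian noise SD on \[0,1\] intensities.
#' @param seed Integer seed.
#' @return `oct_cohort_config` list.
#' @export
cohort_config <- function(n_eyes = 234, n_classes = 4,
                          class_proportions = c(122, 45, 32, 35) / 234,
                          image_size = c(128, 128),
                          pixel_spacing_mm = 0.011,
                          texture_params = default_texture_params(n_classes),
                          outcome_link = list(
                            rdme = c(72, 31, 19, 12) / c(122, 45, 32, 35),
                            vision_poor = c(70, 27, 21, 10) / c(122, 45, 32, 35)
                          ),
                          noise_sd = 0.02, seed = 1) {
  if (n_eyes < 1) stop("n_eyes must be positive")
  if (n_eyes < n_classes) stop("n_eyes must be >= n_classes")
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    stop("class_proportions must sum to 1")
  }
  if (length(class_proportions) != n_classes) {
    stop("class_proportions length must equal n_classes")
  }
  for (p in unlist(outcome_link)) {
    if (p < 0 || p > 1) stop("outcome probabilities must lie in [0, 1]")
  }
  if (any(lengths(outcome_link) != n_classes)) {
    stop("outcome_link probabilities must have one entry per class")
  }
  if (nrow(texture_params) != n_classes) {
    stop("texture_params must have one row per class")
  }
  if (any(image_size < 8)) stop("image_size must be at least 8x8")
  if (pixel_spacing_mm <= 0) stop("pixel spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(
    n_eyes = as.integer(n_eyes), n_classes = as.integer(n_classes),
    class_proportions = class_proportions,
    image_size = as.integer(image_size),
    pixel_spacing_mm = pixel_spacing_mm,
    texture_params = texture_params,
    outcome_link = outcome_link,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "oct_cohort_config")
}

#' @rdname cohort_config
#' @export
default_texture_params <- function(n_classes = 4) {
  tp <- data.frame(
    cyst_density = c(2.0, 5.0, 1.0, 0.5),
    cyst_r_min = c(2, 3, 2, 2),
    cyst_r_max = c(5, 7, 4, 4),
    focus_density = c(1.0, 2.0, 4.0, 0.5),
    layer_amp = c(0.05, 0.08, 0.12, 0.03),
    base_mean = c(0.55, 0.50, 0.60, 0.65),
    base_sd = c(0.03, 0.03, 0.03, 0.03)
  )
  tp[rep_len(seq_len(4), n_classes), , drop = FALSE]
}

#' Preset cohort configurations
#'
#' `"default"` uses moderately separated class textures emulating the
#' reference cohort; `"high_separation"` spreads the class reflectivity
#' means and motif densities far apart so that downstream clustering should
#' recover the planted classes essentially perfectly; `"null"` gives every
#' class identical texture parameters, so any clustering structure found is
#' spurious.
#'
#' @param preset One of `"default"`, `"high_separation"`, `"null"`.
#' @param ... Overrides passed to [cohort_config()].
#' @return `oct_cohort_config`.
#' @export
cohort_preset <- function(preset = c("default", "high_separation", "null"),
                          ...) {
  preset <- match.arg(preset)
  tp <- default_texture_params()
  args <- list(...)
  if (preset != "default" && is.null(args$class_proportions)) {
    # planted-partition benchmarks use mildly unbalanced classes: large enough
    # minority groups for stable recovery, no single dominating cluster
    args$class_proportions <- c(0.35, 0.25, 0.20, 0.20)
  }
  if (preset == "high_separation") {
    tp$base_mean <- c(0.30, 0.30, 0.80, 0.80)
    tp$base_sd <- rep(0.01, 4)
    tp$cyst_density <- c(15, 0, 12, 0)
    tp$cyst_r_min <- rep(2, 4); tp$cyst_r_max <- rep(4, 4)
    tp$focus_density <- c(0, 10, 0, 0)
    tp$layer_amp <- c(0.005, 0.12, 0.005, 0.005)
  } else if (preset == "null") {
    tp <- tp[rep(1, 4), ]
  }
  do.call(cohort_config, c(list(texture_params = tp), args))
}

#' Generate one synthetic B-scan and its ROI mask
#'
#' Renders a horizontal retina-like band (the mask, always covering at least
#' 10% of pixels) holding a layered reflectivity profile with smooth
#' column-wise disruption, dark elliptical cystoid spaces, small bright
#' hyperreflective foci, and additive Gaussian noise; intensities are
#' clipped to \[0,1\] and quantized to the 8-bit scale (0..255), mirroring
#' what would be read back from an 8-bit image file. Uses the current RNG
#' state (callers control the seed).
#'
#' @param params One row of the texture-parameter table.
#' @param size (H, W) pixels.
#' @param noise_sd Gaussian noise SD on the \[0,1\] scale.
#' @return List: `image` (matrix, values 0..255), `mask` (logical matrix).
#' @export
generate_bscan <- function(params, size = c(128, 128), noise_sd = 0.02) {
  h <- size[1]; w <- size[2]
  if (h < 8 || w < 8) stop("image size must be at least 8x8")
  band_top <- max(1L, round(0.25 * h) + sample(-2:2, 1))
  band_bot <- min(h, round(0.75 * h) + sample(-2:2, 1))
  mask <- matrix(FALSE, h, w)
  mask[band_top:band_bot, ] <- TRUE

  img <- matrix(0.05, h, w)
  band_h <- band_bot - band_top + 1
  rows <- band_top:band_bot
  # layered profile: base reflectivity + sinusoidal sub-layer modulation
  prof <- params$base_mean +
    0.08 * sin(2 * pi * 1.5 * (rows - band_top) / band_h)
  img[rows, ] <- matrix(prof, band_h, w)
  # smooth column-wise disruption of the layers
  if (params$layer_amp > 0) {
    raw <- stats::rnorm(w)
    sm <- stats::filter(c(raw, raw, raw), rep(1 / 15, 15), circular = TRUE)
    sm <- as.numeric(sm)[(w + 1):(2 * w)]
    disp <- params$layer_amp * sm / max(stats::sd(sm), 1e-8)
    img[rows, ] <- img[rows, ] + matrix(disp, band_h, w, byrow = TRUE)
  }
  # per-eye reflectivity offset
  img[rows, ] <- img[rows, ] + stats::rnorm(1, 0, params$base_sd)

  area_k <- band_h * w / 1000
  n_cyst <- stats::rpois(1, params$cyst_density * area_k)
  if (n_cyst > 0) {
    cc <- col(img); rr <- row(img)
    for (i in seq_len(n_cyst)) {
      cy <- stats::runif(1, band_top + 2, band_bot - 2)
      cx <- stats::runif(1, 1, w)
      ra <- stats::runif(1, params$cyst_r_min, params$cyst_r_max)
      rb <- stats::runif(1, params$cyst_r_min, params$cyst_r_max)
      inside <- ((rr - cy) / ra)^2 + ((cc - cx) / rb)^2 <= 1
      img[inside & mask] <- img[inside & mask] * 0.25
    }
  }
  n_foci <- stats::rpois(1, params$focus_density * area_k)
  if (n_foci > 0) {
    fr <- round(stats::runif(n_foci, band_top, band_bot))
    fc <- round(stats::runif(n_foci, 1, w))
    for (i in seq_len(n_foci)) {
      r0 <- max(1, fr[i] - 1):min(h, fr[i])
      c0 <- max(1, fc[i] - 1):min(w, fc[i])
      img[r0, c0] <- 0.95
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = round(img * 255), mask = mask)
}

#' Draw outcome labels and consistent clinical thickness/acuity values
#'
#' RDME and poor-vision labels are independent Bernoulli draws at the
#' class-specific probabilities. The clinical fields are synthesized to be
#' consistent with the drawn labels under the endpoint rules: an RDME eye is
#' either residual (post-treatment CMT reduction drawn below its baseline
#' band threshold, occasionally negative, i.e. worsening) or recurrent
#' (adequate reduction but fluid re-emergence within six months); six-month
#' logMAR lands on the poor side of the 20/63 boundary exactly when the
#' poor-vision label was drawn. Uses the current RNG state.
#'
#' @param true_class Integer class (1..n_classes).
#' @param outcome_link Per-class probability list (see [cohort_config()]).
#' @param cmt_baseline_um Baseline central macular thickness in um.
#' @return List: `rdme`, `vision_poor`, `residual`, `recurrence_within_6mo`,
#'   `cmt_post_um`, `bcva_logmar_6mo`.
#' @export
link_outcomes <- function(true_class, outcome_link, cmt_baseline_um) {
  p_rdme <- outcome_link$rdme[true_class]
  p_poor <- outcome_link$vision_poor[true_class]
  if (is.na(p_rdme) || is.na(p_poor)) stop("class outside outcome_link range")
  rdme <- stats::runif(1) < p_rdme
  thr <- residual_threshold(cmt_baseline_um)
  if (rdme) {
    residual <- stats::runif(1) < 0.8
    if (residual) {
      reduction <- stats::runif(1, -0.10, thr - 1e-6)
      recurrence <- stats::runif(1) < 0.2
    } else {
      reduction <- stats::runif(1, thr + 1e-6, 0.6)
      recurrence <- TRUE
    }
  } else {
    residual <- FALSE
    recurrence <- FALSE
    reduction <- stats::runif(1, thr + 1e-6, 0.6)
  }
  vision_poor <- stats::runif(1) < p_poor
  bound <- log10(63 / 20)
  logmar6 <- if (vision_poor) stats::runif(1, bound, 1.3) else
    stats::runif(1, 0.0, bound - 1e-6)
  list(rdme = rdme, vision_poor = vision_poor, residual = residual,
       recurrence_within_6mo = recurrence,
       cmt_post_um = cmt_baseline_um * (1 - reduction),
       bcva_logmar_6mo = logmar6)
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the config seed. Class counts follow the configured
#' proportions by largest-remainder apportionment (equal proportions with a
#' divisible `n_eyes` give exactly equal counts). Each eye carries an image,
#' mask, latent class, a clinical record (age, diabetes duration, HbA1c,
#' baseline/post CMT, baseline/6-month logMAR BCVA, retinopathy stage,
#' medication) and the derived endpoint labels.
#'
#' @param config An [cohort_config()].
#' @return `oct_cohort`: list with `eyes` (list of per-eye lists), `config`,
#'   and `clinical` (per-eye data frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "oct_cohort_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  counts <- apportion_counts(config$n_eyes, config$class_proportions)
  classes <- rep(seq_len(config$n_classes), counts)
  cmt_medians <- rep_len(c(390, 510, 540, 290), config$n_classes)
  eyes <- vector("list", config$n_eyes)
  for (i in seq_len(config$n_eyes)) {
    cl <- classes[i]
    bs <- generate_bscan(config$texture_params[cl, ],
                         config$image_size, config$noise_sd)
    cmt0 <- stats::rlnorm(1, log(cmt_medians[cl]), 0.25)
    cmt0 <- min(max(cmt0, 150), 900)
    oc <- link_outcomes(cl, config$outcome_link, cmt0)
    clin <- list(
      eye_id = sprintf("eye_%03d", i),
      age = round(stats::rnorm(1, 59, 10)),
      sex = sample(c("M", "F"), 1),
      dm_duration = round(stats::rlnorm(1, log(10), 0.5), 1),
      hba1c = round(stats::rnorm(1, 7.3, 0.8), 2),
      cmt_baseline_um = cmt0,
      cmt_post_um = oc$cmt_post_um,
      bcva_logmar_baseline = round(max(0, stats::rnorm(1, 0.5, 0.2)), 2),
      bcva_logmar_6mo = round(oc$bcva_logmar_6mo, 3),
      dr_stage = sample(c("NPDR", "PDR"), 1, prob = c(0.76, 0.24)),
      medication = sample(c("ranibizumab", "conbercept", "aflibercept"), 1,
                          prob = c(0.41, 0.27, 0.32)),
      recurrence_within_6mo = oc$recurrence_within_6mo
    )
    eyes[[i]] <- list(
      eye_id = clin$eye_id, true_class = cl,
      image = bs$image, mask = bs$mask,
      clinical = clin,
      endpoints = list(rdme = oc$rdme, vision_poor = oc$vision_poor,
                       residual = oc$residual)
    )
  }
  clinical <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(e$clinical, true_class = e$true_class,
               rdme = e$endpoints$rdme, vision_poor = e$endpoints$vision_poor)
  }))
  structure(list(eyes = eyes, config = config, clinical = clinical),
            class = "oct_cohort")
}

# largest-remainder apportionment of n into shares p
apportion_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
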