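# Synthetic cohort generator.
#
# Cohorts are generated directly on the folding-law geometry: draw size
# (log10 exposed SA) and thickness, place log10(total SA) on the group's
# folding line with Gaussian noise on the log10 scale, apply group shifts
# along the orthogonal offset/isometric/shape directions, and derive
# supratentorial volume by inverting the total-SA scaling relation so that
# all three scaling models are estimable. Outcome scores are linked to each
# subject's true shape deviance.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: three groups (control n = 345,
#' preterm n = 73, CHD n = 107), group folding exponents 1.26 / 1.41 / 1.18,
#' group shifts of the offset/isometric/shape terms matching the reported
#' group contrasts, scans at 37 to 44+6 weeks PMA (CHD restricted to
#' 37.14 to 42.29), and Bayley-scaled outcomes (mean 100, SD 15) in which
#' cognitive scores decline with shape deviance in the preterm group only.
#'
#' Morphometric location/spread values (`exposed_sa_log10_*`, `ct_*`,
#' `folding_offset_*`) are calibration choices for a plausible neonatal
#' cortex (exposed SA about 300 cm^2, CT about 1.2 mm, gyrification index
#' about 1.8); the source tables report group contrasts, not variance
#' components.
#'
#' @param n_per_group named integer vector of group sizes.
#' @param seed RNG seed; the generated cohort is a deterministic function of
#'   the full configuration.
#' @param folding_alpha named vector of group folding exponents.
#' @param folding_offset_mean mean level of `log10(total_sa * ct^0.5)` at the
#'   cohort-average exposed SA (log10 units). The folding lines of all
#'   groups pivot about `exposed_sa_log10_mean`, so gyrification stays
#'   physiological for every exponent.
#' @param folding_offset_sd SD of the log10-scale folding noise (the
#'   residual SD of the folding regression).
#' @param exposed_sa_log10_mean,exposed_sa_log10_sd distribution of
#'   log10(exposed SA / mm^2).
#' @param ct_mean_mm,ct_sd_mm cortical thickness distribution, mm.
#' @param ct_size_slope increase of log10(CT) per unit log10(exposed SA)
#'   above its mean: couples thickness to cortical size so the CT-volume
#'   scaling model has signal.
#' @param sa_volume_alpha,sa_volume_intercept,volume_noise_sd parameters of
#'   the inverted total-SA/volume relation,
#'   `log10(volume) = (log10(total_sa) - intercept - noise) / alpha`.
#' @param term_shifts named list of per-group `c(offset, isometric, shape)`
#'   shifts (log10 units), applied along the orthogonal term directions.
#' @param covariate_effects effects of demographics on log10(exposed SA):
#'   `pma` (per week above 40), `sex_male`, `birthweight_z`,
#'   `multiple_birth`.
#' @param pma_ranges,ga_ranges named lists of per-group uniform ranges
#'   (weeks).
#' @param outcome_model list: `intercept`, `residual_sd`, `shape_z_slope`
#'   (named per group; points of cognitive score per unit of true shape
#'   deviance z), `imd_effect` (points per SD of IMD rank),
#'   `parent_english_effect` (language-score deficit when no parent speaks
#'   English first), `n_followup` (named; `NA` = all).
#' @param chd_subtype_probs,chd_subtype_isometric,do2_mean,do2_sd,do2_isometric_effect
#'   CHD-only structure: lesion subtype mix, subtype and cerebral oxygen
#'   delivery (mL O2/min) effects on the isometric term.
#' @return a `sim_config` list.
#' @export
sim_config <- function(
  n_per_group = c(control = 345, preterm = 73, chd = 107),
  seed = 1,
  folding_alpha = c(control = 1.26, preterm = 1.41, chd = 1.18),
  folding_offset_mean = 4.77,
  folding_offset_sd = 0.01,
  exposed_sa_log10_mean = 4.48,
  exposed_sa_log10_sd = 0.06,
  ct_mean_mm = 1.2,
  ct_sd_mm = 0.05,
  ct_size_slope = 0.125,
  sa_volume_alpha = 0.873,
  sa_volume_intercept = -0.108,
  volume_noise_sd = 0.001,
  term_shifts = list(
    control = c(offset = 0,      isometric = 0,      shape = 0),
    preterm = c(offset = -0.012, isometric = 0.035,  shape = -0.141),
    chd     = c(offset = -0.004, isometric = -0.047, shape = -0.051)
  ),
  covariate_effects = c(pma = 0.012, sex_male = 0.010,
                        birthweight_z = 0.005, multiple_birth = -0.005),
  pma_ranges = list(control = c(37, 44.857), preterm = c(37, 44.857),
                    chd = c(37.14, 42.29)),
  ga_ranges = list(control = c(37, 42), preterm = c(23, 32.857),
                   chd = c(37, 42)),
  outcome_model = list(
    intercept = 100, residual_sd = 15,
    shape_z_slope = c(control = 0, preterm = -4.78, chd = 0),
    imd_effect = 1.5, parent_english_effect = -3,
    n_followup = c(control = NA, preterm = 57, chd = 65)
  ),
  chd_subtype_probs = c(abnormal_streaming = 0.40, left_sided = 0.35,
                        right_sided = 0.25),
  chd_subtype_isometric = c(abnormal_streaming = 0, left_sided = 0.081,
                            right_sided = -0.28),
  do2_mean = 40, do2_sd = 10, do2_isometric_effect = 0.001
) {
  cfg <- as.list(environment())
  sds <- c(folding_offset_sd = folding_offset_sd,
           exposed_sa_log10_sd = exposed_sa_log10_sd, ct_sd_mm = ct_sd_mm)
  if (any(sds < 0)) abort("SDs must be non-negative")
  if (any(n_per_group < 0)) abort("group counts must be >= 0")
  for (g in names(pma_ranges)) {
    r <- pma_ranges[[g]]
    if (r[1] < .pma_eligible[1] - 1e-9 || r[2] > .pma_eligible[2] + 1e-9) {
      abort("pma range for '%s' outside the 37 to 44+6 week eligibility window", g)
    }
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic cohort
#'
#' See [sim_config()] for the generative model. Deterministic given the
#' configuration (including its seed); the result passes all cohort
#' invariants.
#'
#' @param config a [sim_config()].
#' @return a `cohort_table`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_per_group = c(control = 50), seed = 7))
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  basis <- morph_basis()
  groups <- names(cfg$n_per_group)[cfg$n_per_group > 0]
  rows <- lapply(groups, function(g) {
    n <- cfg$n_per_group[[g]]
    pma <- stats::runif(n, cfg$pma_ranges[[g]][1], cfg$pma_ranges[[g]][2])
    ga <- stats::runif(n, cfg$ga_ranges[[g]][1], cfg$ga_ranges[[g]][2])
    sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
    mb <- stats::runif(n) < 0.05
    bwz <- stats::rnorm(n)

    eff <- cfg$covariate_effects
    e <- stats::rnorm(n, cfg$exposed_sa_log10_mean, cfg$exposed_sa_log10_sd) +
      eff[["pma"]] * (pma - 40) + eff[["sex_male"]] * (sex == "male") +
      eff[["birthweight_z"]] * bwz + eff[["multiple_birth"]] * mb
    lct <- log10(cfg$ct_mean_mm) +
      cfg$ct_size_slope * (e - cfg$exposed_sa_log10_mean) +
      stats::rnorm(n, 0, cfg$ct_sd_mm / (cfg$ct_mean_mm * log(10)))
    cc <- 2 * lct

    # folding line pivoted at the mean exposed SA + log10-scale noise
    alpha <- cfg$folding_alpha[[g]]
    folding <- cfg$folding_offset_mean +
      alpha * (e - cfg$exposed_sa_log10_mean) +
      stats::rnorm(n, 0, cfg$folding_offset_sd)
    a <- folding - cc / 4  # log10(total SA) = folding response - 0.5*log10(ct)

    x <- cbind(a = a, e = e, c = cc)
    shift <- cfg$term_shifts[[g]] %||% c(offset = 0, isometric = 0, shape = 0)
    if (g == "chd") {
      subtype <- sample(names(cfg$chd_subtype_probs), n, replace = TRUE,
                        prob = cfg$chd_subtype_probs)
      do2 <- stats::rnorm(n, cfg$do2_mean, cfg$do2_sd)
      iso_extra <- cfg$chd_subtype_isometric[subtype] +
        cfg$do2_isometric_effect * (do2 - cfg$do2_mean)
    } else {
      subtype <- NA_character_
      do2 <- NA_real_
      iso_extra <- 0
    }
    for (term in rownames(basis)) {
      v <- basis[term, ]
      delta <- rep_len(shift[[term]], n) +
        if (term == "isometric") iso_extra else 0
      x <- x + outer(delta, v / sum(v^2))
    }

    vol <- 10^((x[, "a"] - cfg$sa_volume_intercept -
                  stats::rnorm(n, 0, cfg$volume_noise_sd)) / cfg$sa_volume_alpha)

    data.frame(
      subject_id = sprintf("%s_%04d", g, seq_len(n)),
      group = g,
      total_sa = 10^x[, "a"],
      exposed_sa = 10^x[, "e"],
      ct = 10^(x[, "c"] / 2),
      supratentorial_volume = vol,
      pma_weeks = pma, ga_weeks = ga, sex = sex,
      birthweight_z = bwz, multiple_birth = mb,
      imd_rank = sample.int(32844L, n, replace = TRUE),
      chd_subtype = subtype, cerebral_do2 = do2,
      parenteral_nutrition_days =
        if (g == "preterm") stats::rpois(n, 18) else NA_integer_,
      respiratory_support_days =
        if (g == "preterm") stats::rpois(n, 12) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)

  # outcomes linked to the subject's true shape deviance from the control
  # covariate model (the quantity the normative module estimates)
  terms <- compute_terms(df$total_sa, df$exposed_sa, df$ct)
  ctrl <- df$group == "control"
  om <- cfg$outcome_model
  if (any(ctrl)) {
    X <- cbind(1, df$pma_weeks, (df$pma_weeks - mean(df$pma_weeks[ctrl]))^2,
               df$sex == "male", df$birthweight_z, df$multiple_birth)
    fit <- stats::lm.fit(X[ctrl, , drop = FALSE], terms$shape_s[ctrl])
    resid_all <- terms$shape_s - X %*% fit$coefficients
    z_true <- (resid_all - mean(resid_all[ctrl])) / stats::sd(resid_all[ctrl])
  } else {
    z_true <- rep(0, nrow(df))
  }
  imd_std <- (df$imd_rank - 32845 / 2) / (32844 / sqrt(12))
  slope <- vapply(df$group, function(g) {
    if (g %in% names(om$shape_z_slope)) om$shape_z_slope[[g]] else 0
  }, numeric(1), USE.NAMES = FALSE)
  parent_en <- stats::runif(nrow(df)) < 0.9
  base <- om$intercept + slope * as.vector(z_true) + om$imd_effect * imd_std
  df$cognitive_score <- base + stats::rnorm(nrow(df), 0, om$residual_sd)
  df$language_score <- om$intercept + om$imd_effect * imd_std +
    om$parent_english_effect * (!parent_en) +
    stats::rnorm(nrow(df), 0, om$residual_sd)
  df$motor_score <- om$intercept + om$imd_effect * imd_std +
    stats::rnorm(nrow(df), 0, om$residual_sd)
  df$corrected_age_months <- stats::runif(nrow(df), 17.26, 40.29)
  df$parent_first_language_english <- parent_en

  # follow-up attendance: outcomes observed for a subsample per group
  for (g in groups) {
    n_fu <- if (g %in% names(om$n_followup)) om$n_followup[[g]] else NA
    idx <- which(df$group == g)
    if (!is.na(n_fu) && n_fu < length(idx)) {
      miss <- sample(idx, length(idx) - n_fu)
      df[miss, c("cognitive_score", "language_score", "motor_score",
                 "corrected_age_months")] <- NA_real_
    }
  }
  new_cohort_table(df, provenance = sprintf("synthetic (seed %d)", cfg$seed))
}

#' Generate a noiseless self-similar family of cortices
#'
#' Every member is the base cortex scaled by a factor lambda: areas scale as
#' lambda^2, thickness as lambda, volume as lambda^3. On such a family the
#' surface-area and thickness scaling exponents are exactly 2/3 and 1/3, the
#' folding exponent is exactly 1.25, the offset and shape terms are constant,
#' and the isometric term increases by 6*log10(lambda).
#'
#' @param n number of members (>= 3).
#' @param base named vector `c(total_sa, exposed_sa, ct)` in mm^2/mm.
#' @param scale_range range of lambda, drawn uniformly.
#' @param seed RNG seed for the lambda draws.
#' @return a `cohort_table` (neutral demographics: term-born, PMA 40).
#' @export
generate_self_similar_family <- function(n = 10,
                                         base = c(total_sa = 54000,
                                                  exposed_sa = 30000,
                                                  ct = 1.2),
                                         scale_range = c(0.8, 1.25),
                                         seed = 1) {
  if (n < 3) abort("n must be >= 3")
  if (scale_range[1] <= 0) abort("scale_range must be positive")
  lambda <- with_seed(seed, stats::runif(n, scale_range[1], scale_range[2]))
  r0 <- sqrt(base[["exposed_sa"]] / (4 * pi))
  vol0 <- 4 / 3 * pi * r0^3
  df <- data.frame(
    subject_id = sprintf("fam_%03d", seq_len(n)),
    group = "control",
    total_sa = base[["total_sa"]] * lambda^2,
    exposed_sa = base[["exposed_sa"]] * lambda^2,
    ct = base[["ct"]] * lambda,
    supratentorial_volume = vol0 * lambda^3,
    pma_weeks = 40, ga_weeks = 40,
    sex = rep_len(c("female", "male"), n),
    birthweight_z = 0, multiple_birth = FALSE,
    stringsAsFactors = FALSE
  )
  new_cohort_table(df, provenance = sprintf("self-similar family (seed %d)", seed))
}
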