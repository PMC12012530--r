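# Normative deviance scoring: fit a robust control-population model for each
# metric, apply it to every subject, and z-score the residuals to the
# control residual distribution. Deviance z-scores then enter outcome models
# (group x deviance interactions, bootstrapped variance explained).

.normative_metrics <- c("total_sa_scaling", "ct_scaling", "folding_scaling",
                        "offset_k", "isometric_i", "shape_s")

# metric -> response column + optional log regressor entering the design
normative_metric_spec <- function(metric) {
  metric <- match.arg(metric, .normative_metrics)
  if (metric %in% c("offset_k", "isometric_i", "shape_s")) {
    return(list(metric = metric,
                response = function(d) add_morph_terms(d)[[metric]],
                regressor = NULL, regressor_name = NULL))
  }
  kind <- sub("_scaling$", "", metric)
  kind <- c(total_sa = "total_sa_vs_volume", ct = "ct_vs_volume",
            folding = "folding")[[kind]]
  spec <- scaling_model_spec(kind)
  list(metric = metric, response = spec$response, regressor = spec$regressor,
       regressor_name = spec$regressor_name)
}

#' Fit a normative control-population model for one metric
#'
#' Fits a robust (fast-S) regression of the metric on the covariates -- and,
#' for the scaling metrics, on the corresponding log regressor -- using
#' control subjects only, and stores the control residual mean and SD. The
#' model is later applied unchanged to clinical subjects by [deviance_z()],
#' so a subject's z-score measures deviation from the typical population
#' given their demographics (and volume/exposed SA for scaling metrics).
#'
#' @param controls a `cohort_table` of control subjects only.
#' @param metric one of `total_sa_scaling`, `ct_scaling`, `folding_scaling`,
#'   `offset_k`, `isometric_i`, `shape_s`.
#' @param covariates covariate names (default: PMA, PMA^2, sex, multiple
#'   birth, birth-weight z).
#' @param method `"fast_s"` (default) or `"ols"`.
#' @param seed fast-S resampling seed.
#' @return object of class `normative_model`.
#' @export
fit_normative <- function(controls, metric,
                          covariates = c("pma", "pma2", "sex",
                                         "multiple_birth", "bwz"),
                          method = c("fast_s", "ols"), seed = 1) {
  method <- match.arg(method)
  if (any(controls$group != "control")) {
    abort("fit_normative expects control records only")
  }
  spec <- normative_metric_spec(metric)
  y <- spec$response(controls)
  cov <- build_covariates(controls, covariates)
  X <- cbind(`(Intercept)` = 1, cov$mat)
  if (!is.null(spec$regressor)) {
    X <- cbind(X[, 1, drop = FALSE],
               structure(spec$regressor(controls), names = NULL),
               X[, -1, drop = FALSE])
    colnames(X)[2] <- spec$regressor_name
  }
  assert_full_rank(X)
  fit <- if (method == "fast_s") fit_fast_s(X, y, seed = seed) else ols_fit(X, y)
  r <- as.vector(y - X %*% fit$coefficients)
  structure(list(
    metric = metric,
    coefficients = fit$coefficients,
    method = method,
    covariates = covariates,
    pma_center = cov$pma_center,
    regressor_name = spec$regressor_name,
    control_residual_mean = mean(r),
    control_residual_sd = stats::sd(r),
    n_controls = nrow(X),
    seed = seed
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %s (%s, n = %d controls)\n", x$metric,
              x$method, x$n_controls))
  cat(sprintf("  control residual mean %.4g, SD %.4g\n",
              x$control_residual_mean, x$control_residual_sd))
  invisible(x)
}

#' Deviance z-scores under a normative model
#'
#' Applies the control-fitted coefficients to each subject and standardises
#' the residual by the control residual mean and SD:
#' `z = (observed - predicted - control_mean) / control_sd`. Controls
#' themselves score mean 0 / SD 1 by construction (up to the robust fit's
#' non-zero residual mean, which the stored constants absorb).
#'
#' @param model a `normative_model`.
#' @param subjects a `cohort_table` (any groups).
#' @return data.frame `subject_id`, `group`, `metric`, `z`.
#' @export
deviance_z <- function(model, subjects) {
  stopifnot(inherits(model, "normative_model"))
  spec <- normative_metric_spec(model$metric)
  y <- spec$response(subjects)
  cov <- build_covariates(subjects, model$covariates,
                          pma_center = model$pma_center)
  X <- cbind(`(Intercept)` = 1, cov$mat)
  if (!is.null(spec$regressor)) {
    X <- cbind(X[, 1, drop = FALSE],
               structure(spec$regressor(subjects), names = NULL),
               X[, -1, drop = FALSE])
    colnames(X)[2] <- spec$regressor_name
  }
  pred <- as.vector(X %*% model$coefficients[colnames(X)])
  z <- (y - pred - model$control_residual_mean) / model$control_residual_sd
  data.frame(subject_id = subjects$subject_id, group = subjects$group,
             metric = model$metric, z = z, stringsAsFactors = FALSE)
}

#' Deviance z-scores for all six metrics
#'
#' Fits one normative model per metric on the controls in `cohort` and
#' scores every subject, returning a wide table of z-scores.
#'
#' @param cohort a `cohort_table` containing a control group.
#' @inheritParams fit_normative
#' @param metrics metrics to score.
#' @return data.frame with `subject_id`, `group`, and one `z_<metric>`
#'   column per metric; attribute `models` holds the fitted
#'   `normative_model`s.
#' @export
deviance_table <- function(cohort, metrics = .normative_metrics,
                           covariates = c("pma", "pma2", "sex",
                                          "multiple_birth", "bwz"),
                           method = "fast_s", seed = 1) {
  controls <- cohort[cohort$group == "control", , drop = FALSE]
  if (!nrow(controls)) abort("cohort has no control group")
  models <- lapply(metrics, function(m) {
    fit_normative(controls, m, covariates = covariates, method = method,
                  seed = seed)
  })
  names(models) <- metrics
  out <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                    stringsAsFactors = FALSE)
  for (m in metrics) out[[paste0("z_", m)]] <- deviance_z(models[[m]], cohort)$z
  attr(out, "models") <- models
  out
}

#' Test a group-by-deviance interaction on an outcome score
#'
#' Fits `outcome ~ z * group + covariates` on the follow-up subsample of the
#' two groups and tests the interaction with a Freedman-Lane permutation
#' p-value; reports parametric per-group simple slopes post hoc.
#'
#' @param cohort a `cohort_table` with outcome columns.
#' @param z numeric deviance z-scores aligned with `cohort` rows (e.g. a
#'   column of [deviance_table()]).
#' @param outcome `"cognitive"`, `"language"`, or `"motor"`.
#' @param groups `c(reference, target)`.
#' @param covariates adjustment covariates; defaults to IMD rank, plus the
#'   parent-English-language flag for language outcomes.
#' @param n_perm,seed permutation settings.
#' @return object of class `outcome_association` (extends
#'   `permutation_result`) with a `simple_slopes` data.frame.
#' @export
test_outcome_interaction <- function(cohort, z, outcome,
                                     groups = c("control", "preterm"),
                                     covariates = NULL,
                                     n_perm = 5000, seed = 1) {
  outcome <- match.arg(outcome, c("cognitive", "language", "motor"))
  covariates <- covariates %||%
    if (outcome == "language") c("imd", "parent_english") else "imd"
  ycol <- paste0(outcome, "_score")
  cohort$.__z <- as.numeric(z)
  d <- two_group_subset(cohort, groups)
  keep <- !is.na(d[[ycol]]) & !is.na(d$.__z)
  d <- d[keep, , drop = FALSE]
  if (!all(table(factor(d$group, levels = groups)) > 0)) {
    abort("a group has no follow-up subjects with '%s' scores", outcome)
  }
  cov <- build_covariates(d, covariates)
  X <- cbind(`(Intercept)` = 1, z = d$.__z, group = d$group_ind, cov$mat,
             interaction = d$.__z * d$group_ind)
  assert_full_rank(X)
  res <- permutation_lm(d[[ycol]], X, "interaction", n_perm = n_perm,
                        seed = seed,
                        term_name = sprintf("%s: z x (%s vs %s)", outcome,
                                            groups[2], groups[1]))
  slopes <- do.call(rbind, lapply(groups, function(g) {
    dg <- d[d$group == g, , drop = FALSE]
    covg <- build_covariates(dg, covariates)
    Xg <- cbind(`(Intercept)` = 1, z = dg$.__z, covg$mat)
    fit <- ols_fit(Xg, dg[[ycol]])
    tt <- fit$coefficients[["z"]] / fit$se[["z"]]
    data.frame(group = g, slope = fit$coefficients[["z"]],
               se = fit$se[["z"]], t = tt,
               p = 2 * stats::pt(-abs(tt), fit$df_residual),
               n = nrow(Xg), stringsAsFactors = FALSE)
  }))
  res$simple_slopes <- slopes
  res$outcome <- outcome
  class(res) <- c("outcome_association", class(res))
  res
}

#' Outcome-association family for all six deviance metrics
#'
#' Runs [test_outcome_interaction()] for every `z_` column of a
#' [deviance_table()] and Holm-corrects the six interaction p-values as one
#' family (one outcome, one group pair).
#'
#' @param cohort a `cohort_table` with outcome scores.
#' @param ztab a [deviance_table()] aligned with `cohort`.
#' @inheritParams test_outcome_interaction
#' @return a `hypothesis_family`.
#' @export
outcome_family <- function(cohort, ztab, outcome,
                           groups = c("control", "preterm"),
                           covariates = NULL, n_perm = 5000, seed = 1) {
  zcols <- grep("^z_", names(ztab), value = TRUE)
  results <- lapply(zcols, function(zc) {
    r <- test_outcome_interaction(cohort, ztab[[zc]], outcome, groups,
                                  covariates, n_perm, seed)
    r$term_name <- sprintf("%s: %s x group", outcome, sub("^z_", "", zc))
    class(r) <- "permutation_result"
    r["simple_slopes"] <- NULL
    r
  })
  hypothesis_family(results, label = sprintf("%s, %s vs %s", outcome,
                                             groups[2], groups[1]))
}

#' Bootstrapped incremental variance explained by a deviance z-score
#'
#' Within one group, the gain in R^2 when the z-score is added to the
#' covariate-only model of the outcome:
#' `delta R^2 = R^2(outcome ~ z + covariates) - R^2(outcome ~ covariates)`.
#' The point estimate is the original-sample delta R^2; the CI is the
#' percentile interval of a case-resampling bootstrap.
#'
#' @param cohort a `cohort_table` with outcome scores.
#' @param z deviance z-scores aligned with `cohort` rows.
#' @param outcome `"cognitive"`, `"language"`, or `"motor"`.
#' @param group group to analyse (`NULL` = all rows with data).
#' @param covariates adjustment covariates (default IMD rank).
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed bootstrap seed.
#' @param conf confidence level of the percentile interval.
#' @return list: `delta_r2`, `ci`, `boot` (replicate values), `n`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_delta_r2 <- function(cohort, z, outcome, group = NULL,
                               covariates = "imd", n_boot = 2000, seed = 1,
                               conf = 0.95) {
  if (n_boot < 100) abort("n_boot must be at least 100")
  outcome <- match.arg(outcome, c("cognitive", "language", "motor"))
  ycol <- paste0(outcome, "_score")
  cohort$.__z <- as.numeric(z)
  d <- cohort
  if (!is.null(group)) d <- d[d$group %in% group, , drop = FALSE]
  d <- d[!is.na(d[[ycol]]) & !is.na(d$.__z), , drop = FALSE]
  cov <- build_covariates(d, covariates)
  y <- as.numeric(d[[ycol]])
  zv <- d$.__z
  C <- cov$mat

  delta <- function(idx) {
    yy <- y[idx]
    Xr <- cbind(1, C[idx, , drop = FALSE])
    Xf <- cbind(Xr, zv[idx])
    r2 <- function(X) {
      f <- stats::lm.fit(X, yy)
      1 - sum(f$residuals^2) / sum((yy - mean(yy))^2)
    }
    r2(Xf) - r2(Xr)
  }
  est <- delta(seq_along(y))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      delta(sample.int(length(y), replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  list(delta_r2 = est,
       ci = unname(stats::quantile(boot, c(a, 1 - a), na.rm = TRUE)),
       boot = boot, n = length(y), n_boot = n_boot, seed = seed)
}
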