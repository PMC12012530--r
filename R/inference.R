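# Permutation-tested linear models and Holm family-wise error correction.
#
# All group and demographic contrasts share one engine: the focal
# coefficient's t-statistic is referenced to a Freedman-Lane null in which
# the residuals of the reduced model (without the focal column) are permuted
# about its fitted values. Estimates and CIs are parametric; only the
# p-value is permutation-based.

#' Freedman-Lane permutation test of one regression coefficient
#'
#' Fits `response ~ design`, then permutes the residuals of the reduced
#' model (the design without the focal column) about its fitted values,
#' recomputing the focal t-statistic for each permuted response. The
#' two-sided p-value is `(1 + #{|t*| >= |t_obs|}) / (1 + n_perm)` (ties
#' count, so p is never 0 and never below `1/(n_perm + 1)`). With no
#' reduced-model covariates beyond the intercept this is exactly simple
#' permutation of the response.
#'
#' @param response numeric response.
#' @param design design matrix including intercept.
#' @param focal name or index of the tested column.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draws.
#' @param term_name label carried into the result.
#' @return object of class `permutation_result`: `term_name`, `b_estimate`,
#'   `b_ci`, `b_se`, `t_stat`, `p_perm`, `p_parametric`, `n_perm`, `seed`,
#'   `n`.
#' @export
permutation_lm <- function(response, design, focal, n_perm = 5000, seed = 1,
                           term_name = NULL) {
  x <- as.matrix(design)
  y <- as.numeric(response)
  n <- length(y)
  if (is.character(focal)) focal <- match(focal, colnames(x))
  if (is.na(focal) || focal < 1 || focal > ncol(x)) abort("focal column not found")
  full <- ols_fit(x, y)
  b <- unname(full$coefficients[focal])
  se <- unname(full$se[focal])
  t_obs <- b / se
  df <- full$df_residual
  d_ff <- full$vcov[focal, focal] / full$sigma^2  # (X'X)^-1 focal diagonal

  xr <- x[, -focal, drop = FALSE]
  red <- ols_fit(xr, y)
  g <- red$fitted_values
  e <- red$residuals

  qrx <- full$qr
  t_star <- with_seed(seed, {
    E <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm)) E[, j] <- e[sample.int(n)]
    Ystar <- g + E
    coefs <- qr.coef(qrx, Ystar)            # p x n_perm
    R <- Ystar - x %*% coefs
    sigma2 <- colSums(R^2) / df
    coefs[focal, ] / sqrt(sigma2 * d_ff)
  })
  exceed <- sum(abs(t_star) >= abs(t_obs) - 1e-12)
  tq <- stats::qt(0.975, df)
  structure(list(
    term_name = term_name %||% colnames(x)[focal],
    b_estimate = b,
    b_se = se,
    b_ci = c(b - tq * se, b + tq * se),
    t_stat = t_obs,
    p_perm = (1 + exceed) / (1 + n_perm),
    p_parametric = 2 * stats::pt(-abs(t_obs), df),
    p_fwe = NA_real_,
    n_perm = n_perm,
    seed = seed,
    n = n,
    df = df
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: B = %.4g (%.4g to %.4g), t = %.3f, p_perm = %.4g",
              x$term_name, x$b_estimate, x$b_ci[1], x$b_ci[2], x$t_stat,
              x$p_perm))
  if (!is.na(x$p_fwe)) cat(sprintf(" (pFWE = %.4g)", x$p_fwe))
  cat(sprintf(" [n_perm = %d]\n", x$n_perm))
  invisible(x)
}

two_group_subset <- function(cohort, groups) {
  if (length(groups) != 2) abort("exactly two groups required (reference first)")
  present <- groups %in% cohort$group
  if (!all(present)) abort("group '%s' not present", groups[!present][1])
  d <- cohort[cohort$group %in% groups, , drop = FALSE]
  d$group_ind <- as.numeric(d$group == groups[2])
  d
}

#' Test a group difference in a scaling coefficient
#'
#' Fits `response ~ group * log10(x) + covariates` on the two groups and
#' tests the group-by-regressor interaction, i.e. the difference in scaling
#' exponent between the target and reference group, with a Freedman-Lane
#' permutation p-value.
#'
#' @param cohort a `cohort_table` containing both groups.
#' @param model_kind scaling model, as in [fit_scaling()].
#' @param groups `c(reference, target)`; the estimate is target minus
#'   reference.
#' @param covariates covariate names (see [fit_scaling()]).
#' @param n_perm,seed permutation settings.
#' @return a `permutation_result` for the interaction coefficient.
#' @export
test_scaling_difference <- function(cohort, model_kind,
                                    groups = c("control", "preterm"),
                                    covariates = c("sex", "pma", "pma2",
                                                   "bwz", "multiple_birth"),
                                    n_perm = 5000, seed = 1) {
  spec <- scaling_model_spec(model_kind)
  d <- two_group_subset(cohort, groups)
  check_group_sizes(d, length(covariates) + 4)
  y <- spec$response(d)
  xreg <- spec$regressor(d)
  cov <- build_covariates(d, covariates)
  X <- cbind(`(Intercept)` = 1, xreg = xreg, group = d$group_ind, cov$mat,
             interaction = d$group_ind * xreg)
  assert_full_rank(X)
  permutation_lm(y, X, "interaction", n_perm = n_perm, seed = seed,
                 term_name = sprintf("%s scaling: %s vs %s", model_kind,
                                     groups[2], groups[1]))
}

#' Test a group difference in a morphological term or individual metric
#'
#' Fits `term ~ group + covariates` on the two groups and tests the group
#' main effect with a Freedman-Lane permutation p-value. `term` may be one
#' of the multivariate terms (`offset_k`, `isometric_i`, `shape_s`,
#' computed on the fly if absent) or an individual metric (`total_sa`,
#' `ct`, `gi`, `supratentorial_volume`).
#'
#' @inheritParams test_scaling_difference
#' @param term outcome column name.
#' @return a `permutation_result` for the group effect.
#' @export
test_term_difference <- function(cohort, term,
                                 groups = c("control", "preterm"),
                                 covariates = c("sex", "pma", "pma2",
                                                "bwz", "multiple_birth"),
                                 n_perm = 5000, seed = 1) {
  if (is.null(cohort[[term]]) &&
      term %in% c("offset_k", "isometric_i", "shape_s", "gi")) {
    cohort <- add_morph_terms(cohort)
  }
  if (is.null(cohort[[term]])) abort("unknown term/metric '%s'", term)
  d <- two_group_subset(cohort, groups)
  check_group_sizes(d, length(covariates) + 3)
  cov <- build_covariates(d, covariates)
  X <- cbind(`(Intercept)` = 1, group = d$group_ind, cov$mat)
  assert_full_rank(X)
  permutation_lm(as.numeric(d[[term]]), X, "group", n_perm = n_perm,
                 seed = seed,
                 term_name = sprintf("%s: %s vs %s", term, groups[2], groups[1]))
}

check_group_sizes <- function(d, need) {
  tab <- table(d$group_ind)
  if (length(tab) < 2 || any(tab < need)) {
    abort("each group needs at least %d records", need)
  }
  invisible(TRUE)
}

#' Test a demographic or clinical effect within a cohort
#'
#' For a morphological-term outcome the predictor enters as a main effect;
#' for a scaling outcome (`model_kind`) the predictor-by-log-regressor
#' interaction is tested, with the log regressor and covariates adjusted
#' for. A categorical predictor with more than two levels (e.g.
#' `chd_subtype`) yields a Holm-corrected family of pairwise contrasts.
#'
#' @param cohort a `cohort_table` (typically one group).
#' @param predictor covariate name (continuous, binary, or categorical).
#' @param outcome a term/metric column name, or a scaling `model_kind`.
#' @param covariates adjustment covariates.
#' @param n_perm,seed permutation settings.
#' @return a `permutation_result`, or a `hypothesis_family` of pairwise
#'   contrasts for a categorical predictor.
#' @export
test_covariate_effect <- function(cohort, predictor, outcome,
                                  covariates = c("sex", "pma", "pma2",
                                                 "bwz", "multiple_birth"),
                                  n_perm = 5000, seed = 1) {
  pred_col <- cohort[[predictor]]
  if (is.null(pred_col)) {
    # vocabulary names that are derived, e.g. ga/bwz
    pred_col <- build_covariates(cohort, predictor)$mat[, 1]
  }
  if (is.character(pred_col) || is.factor(pred_col)) {
    levels <- unique(stats::na.omit(as.character(pred_col)))
    if (length(levels) < 2) abort("predictor '%s' is constant", predictor)
    if (length(levels) > 2) {
      pairs <- utils::combn(levels, 2, simplify = FALSE)
      results <- lapply(pairs, function(pr) {
        sub <- cohort[pred_col %in% pr, , drop = FALSE]
        sub$.__pred <- as.numeric(as.character(sub[[predictor]]) == pr[2])
        res <- covariate_effect_numeric(sub, ".__pred", outcome, covariates,
                                        n_perm, seed)
        res$term_name <- sprintf("%s: %s vs %s (%s)", predictor, pr[2], pr[1],
                                 outcome)
        res
      })
      return(hypothesis_family(results,
                               label = sprintf("%s on %s", predictor, outcome)))
    }
    cohort$.__pred <- as.numeric(as.character(pred_col) == levels[2])
    res <- covariate_effect_numeric(cohort, ".__pred", outcome, covariates,
                                    n_perm, seed)
    res$term_name <- sprintf("%s (%s vs %s) on %s", predictor, levels[2],
                             levels[1], outcome)
    return(res)
  }
  if (stats::var(pred_col, na.rm = TRUE) == 0) {
    abort("predictor '%s' is constant", predictor)
  }
  cohort$.__pred <- as.numeric(pred_col)
  res <- covariate_effect_numeric(cohort, ".__pred", outcome, covariates,
                                  n_perm, seed)
  res$term_name <- sprintf("%s on %s", predictor, outcome)
  res
}

covariate_effect_numeric <- function(cohort, pred_name, outcome, covariates,
                                     n_perm, seed) {
  covariates <- setdiff(covariates, pred_name)
  if (outcome %in% .model_kinds) {
    spec <- scaling_model_spec(outcome)
    y <- spec$response(cohort)
    xreg <- spec$regressor(cohort)
    cov <- build_covariates(cohort, covariates)
    p <- as.numeric(cohort[[pred_name]])
    X <- cbind(`(Intercept)` = 1, xreg = xreg, pred = p, cov$mat,
               interaction = p * xreg)
    assert_full_rank(X)
    return(permutation_lm(y, X, "interaction", n_perm = n_perm, seed = seed))
  }
  if (is.null(cohort[[outcome]]) &&
      outcome %in% c("offset_k", "isometric_i", "shape_s", "gi")) {
    cohort <- add_morph_terms(cohort)
  }
  if (is.null(cohort[[outcome]])) abort("unknown outcome '%s'", outcome)
  cov <- build_covariates(cohort, covariates)
  X <- cbind(`(Intercept)` = 1, pred = as.numeric(cohort[[pred_name]]),
             cov$mat)
  assert_full_rank(X)
  permutation_lm(as.numeric(cohort[[outcome]]), X, "pred", n_perm = n_perm,
                 seed = seed)
}

#' Holm step-down family-wise error correction
#'
#' Adjusts a family of p-values by the Holm step-down rule: sort ascending,
#' multiply the i-th smallest by (m - i + 1), enforce monotonicity, cap at
#' 1, and return in the input order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param labels optional names for the result.
#' @return adjusted p-values in input order.
#' @examples
#' holm_correct(c(0.441, 0.802, 0.005, 0.0005, 0.014, 0.0005))
#' @export
holm_correct <- function(p_values, labels = NULL) {
  p <- stats::setNames(as.numeric(p_values), names(p_values))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- stats::p.adjust(p, method = "holm")
  if (!is.null(labels)) names(out) <- labels
  out
}

#' Bundle permutation results into a Holm-corrected hypothesis family
#'
#' @param results list of `permutation_result` objects tested jointly.
#' @param label family label.
#' @return object of class `hypothesis_family`; each member's `p_fwe` is the
#'   Holm-adjusted permutation p over exactly this family.
#' @export
hypothesis_family <- function(results, label = "family") {
  stopifnot(all(vapply(results, inherits, logical(1), "permutation_result")))
  p <- vapply(results, `[[`, numeric(1), "p_perm")
  adj <- holm_correct(p)
  for (i in seq_along(results)) results[[i]]$p_fwe <- adj[i]
  structure(list(label = label, results = results), class = "hypothesis_family")
}

#' @export
print.hypothesis_family <- function(x, ...) {
  cat(sprintf("<hypothesis_family> %s (m = %d)\n", x$label, length(x$results)))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.hypothesis_family <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(term = r$term_name, b = r$b_estimate, ci_low = r$b_ci[1],
               ci_high = r$b_ci[2], t = r$t_stat, p_perm = r$p_perm,
               p_fwe = r$p_fwe, stringsAsFactors = FALSE)
  }))
}

#' Run the six-test group-contrast family of one group pair
#'
#' The three scaling-coefficient interactions (total SA, CT, folding) and
#' the three term main effects (offset, isometric, shape), Holm-corrected
#' as one family of six.
#'
#' @inheritParams test_scaling_difference
#' @return a `hypothesis_family` of six `permutation_result`s.
#' @export
group_contrast_family <- function(cohort, groups = c("control", "preterm"),
                                  covariates = c("sex", "pma", "pma2",
                                                 "bwz", "multiple_birth"),
                                  n_perm = 5000, seed = 1) {
  scal <- lapply(.model_kinds, function(mk) {
    test_scaling_difference(cohort, mk, groups, covariates, n_perm, seed)
  })
  terms <- lapply(c("offset_k", "isometric_i", "shape_s"), function(tm) {
    test_term_difference(cohort, tm, groups, covariates, n_perm, seed)
  })
  hypothesis_family(c(scal, terms),
                    label = sprintf("%s vs %s", groups[2], groups[1]))
}
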