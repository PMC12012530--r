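# Full-pipeline orchestration: from a cohort (file or simulation config) to
# machine-readable (JSON) and human-readable (markdown) reports mirroring
# the study's table layout.

#' Analysis configuration
#'
#' @param input path to a cohort CSV, a `cohort_table`, or a [sim_config()]
#'   (a synthetic cohort is generated).
#' @param contrasts list of `c(reference, target)` group pairs.
#' @param scaling_covariates,term_covariates,outcome_covariates covariate
#'   sets per analysis stage (see [fit_scaling()] for the vocabulary);
#'   `outcome_covariates = NULL` uses the stage default (IMD, plus the
#'   parent-language flag for language models).
#' @param reference_values named list of constants the control scaling
#'   coefficients are tested against.
#' @param outcomes outcome scores to model when present in the data.
#' @param n_perm,n_boot,seed inference settings; the seed is recorded in
#'   every output artifact.
#' @param output_dir directory for `report.json`/`report.md` (`NULL` =
#'   don't write).
#' @return a `analysis_config` list.
#' @export
analysis_config <- function(input = sim_config(),
                            contrasts = list(c("control", "preterm"),
                                             c("control", "chd"),
                                             c("preterm", "chd")),
                            scaling_covariates = c("sex", "pma", "pma2",
                                                   "bwz", "multiple_birth"),
                            term_covariates = scaling_covariates,
                            outcome_covariates = NULL,
                            reference_values = list(
                              total_sa_vs_volume = c(theoretical_2_3 = 2 / 3,
                                                     adult_0_89 = 0.89),
                              ct_vs_volume = c(theoretical_1_3 = 1 / 3,
                                               adult_0_03 = 0.03),
                              folding = c(universal_1_25 = 1.25)
                            ),
                            outcomes = c("cognitive", "language", "motor"),
                            n_perm = 5000, n_boot = 2000, seed = 1,
                            output_dir = NULL) {
  structure(as.list(environment()), class = "analysis_config")
}

# covariates that actually vary within an analysis subset (e.g. multiple
# birth can be constant inside a small group, which would alias the design)
usable_covariates <- function(d, covariates) {
  keep <- vapply(covariates, function(nm) {
    col <- tryCatch(build_covariates(d, nm)$mat[, 1], error = function(e) NULL)
    !is.null(col) && stats::var(col) > 0
  }, logical(1))
  covariates[keep]
}

resolve_input <- function(input) {
  if (inherits(input, "cohort_table")) return(input)
  if (inherits(input, "sim_config")) return(generate_cohort(input))
  if (is.character(input)) return(read_cohort(input))
  if (is.data.frame(input)) return(as_cohort(input))
  abort("input must be a path, cohort_table, data.frame, or sim_config")
}

#' Run the full scaling/morphometry/outcome analysis
#'
#' Executes, in order: validation, morphological terms, per-group scaling
#' fits with reference-value comparisons, group-contrast families (three
#' scaling interactions + three term effects per pair, Holm-corrected;
#' control-vs-CHD contrasts restrict controls to the CHD PMA range and add
#' GA as covariate), individual-metric group effects, normative deviance
#' z-scores, and (when outcome scores are present) group-by-deviance
#' outcome families with bootstrapped incremental R^2 for the strongest
#' association. Every result records the seed and method used.
#'
#' @param config an [analysis_config()].
#' @return a `report_bundle` list; when `config$output_dir` is set,
#'   `report.json` and `report.md` are written there.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- "validate"
  bundle <- tryCatch({
    cohort <- resolve_input(config$input)
    cohort <- add_morph_terms(cohort)
    groups_present <- unique(cohort$group)

    stage <- "scaling_fits"
    fits <- list()
    comparisons <- list()
    for (g in groups_present) {
      sub <- cohort[cohort$group == g, , drop = FALSE]
      covars_g <- usable_covariates(sub, config$scaling_covariates)
      fits[[g]] <- lapply(stats::setNames(.model_kinds, .model_kinds),
                          function(mk) {
        fit_scaling(sub, mk, covariates = covars_g, seed = config$seed)
      })
      if (g == "control") {
        comparisons <- lapply(stats::setNames(.model_kinds, .model_kinds),
                              function(mk) {
          refs <- config$reference_values[[mk]]
          lapply(stats::setNames(names(refs), names(refs)), function(lbl) {
            compare_alpha(fits[[g]][[mk]], refs[[lbl]], lbl)
          })
        })
      }
    }

    stage <- "group_contrasts"
    contrast_families <- list()
    metric_families <- list()
    for (pair in config$contrasts) {
      if (!all(pair %in% groups_present)) next
      key <- paste(pair[2], "vs", pair[1])
      d <- cohort
      covars <- config$term_covariates
      if (setequal(pair, c("control", "chd"))) {
        d <- filter_pma_overlap(d, reference_group = "control",
                                target_group = "chd")
        covars <- union(covars, "ga")
      }
      covars <- usable_covariates(d[d$group %in% pair, , drop = FALSE], covars)
      contrast_families[[key]] <- group_contrast_family(
        d, groups = pair, covariates = covars,
        n_perm = config$n_perm, seed = config$seed
      )
      metric_families[[key]] <- hypothesis_family(
        lapply(c("supratentorial_volume", "total_sa", "gi", "ct"),
               function(m) {
          test_term_difference(d, m, groups = pair, covariates = covars,
                               n_perm = config$n_perm, seed = config$seed)
        }),
        label = paste("individual metrics:", key)
      )
    }

    stage <- "deviance"
    ztab <- NULL
    outcome_families <- list()
    delta_r2 <- list()
    if ("control" %in% groups_present) {
      norm_covars <- usable_covariates(
        cohort[cohort$group == "control", , drop = FALSE],
        c("pma", "pma2", "sex", "multiple_birth", "bwz")
      )
      ztab <- deviance_table(cohort, covariates = norm_covars,
                             seed = config$seed)
      has_outcomes <- any(!is.na(cohort$cognitive_score %||% NA))
      if (has_outcomes) {
        stage <- "outcomes"
        for (pair in config$contrasts) {
          if (!all(pair %in% groups_present) || pair[1] != "control") next
          for (oc in config$outcomes) {
            key <- sprintf("%s (%s vs %s)", oc, pair[2], pair[1])
            fam <- outcome_family(cohort, ztab, oc, groups = pair,
                                  covariates = config$outcome_covariates,
                                  n_perm = config$n_perm, seed = config$seed)
            outcome_families[[key]] <- fam
            fdf <- as.data.frame(fam)
            best <- which.min(fdf$p_fwe)
            if (fdf$p_fwe[best] < 0.05) {
              zc <- paste0("z_", sub(sprintf("^%s: ", oc), "",
                                     sub(" x group$", "", fdf$term[best])))
              delta_r2[[key]] <- c(
                list(metric = zc),
                bootstrap_delta_r2(cohort, ztab[[zc]], oc, group = pair[2],
                                   covariates = config$outcome_covariates %||% "imd",
                                   n_boot = config$n_boot, seed = config$seed)[
                                     c("delta_r2", "ci", "n", "n_boot")]
              )
            }
          }
        }
      }
    }

    list(
      seed = config$seed,
      n_perm = config$n_perm,
      cohort_summary = as.list(table(cohort$group)),
      validation = validation_report(cohort),
      scaling_fits = fits,
      reference_comparisons = comparisons,
      group_contrasts = contrast_families,
      individual_metrics = metric_families,
      deviance = ztab,
      outcome_models = outcome_families,
      bootstrap_delta_r2 = delta_r2
    )
  }, error = function(e) {
    abort("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  class(bundle) <- "report_bundle"
  if (!is.null(config$output_dir)) write_report(bundle, config$output_dir)
  bundle
}

report_json <- function(bundle) {
  strip <- function(x) {
    if (inherits(x, "scaling_fit")) {
      return(list(model_kind = x$model_kind, alpha = x$alpha,
                  alpha_se = x$alpha_se, alpha_ci = x$alpha_ci,
                  intercept = x$intercept, method = x$method,
                  assumption_global_p = x$assumption_report$global_p,
                  n = x$n, seed = x$seed))
    }
    if (inherits(x, "hypothesis_comparison")) return(unclass(x))
    if (inherits(x, "hypothesis_family")) return(as.data.frame(x))
    if (inherits(x, "permutation_result")) {
      return(x[c("term_name", "b_estimate", "b_ci", "t_stat", "p_perm",
                 "p_fwe", "n_perm", "seed")])
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  jsonlite::toJSON(strip(unclass(bundle)), auto_unbox = TRUE, digits = 10,
                   dataframe = "rows", null = "null", na = "null")
}

write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(bundle), file.path(dir, "report.json"))
  md <- c("# Cortical scaling analysis report",
          sprintf("seed: %d; permutations: %d", bundle$seed, bundle$n_perm), "")
  for (g in names(bundle$scaling_fits)) {
    md <- c(md, sprintf("## Scaling coefficients: %s", g))
    for (f in bundle$scaling_fits[[g]]) {
      md <- c(md, sprintf("- %s: alpha = %.3f (%.3f to %.3f) [%s]",
                          f$model_kind, f$alpha, f$alpha_ci[1],
                          f$alpha_ci[2], f$method))
    }
    md <- c(md, "")
  }
  for (key in names(bundle$group_contrasts)) {
    fam <- as.data.frame(bundle$group_contrasts[[key]])
    md <- c(md, sprintf("## Group contrast: %s", key),
            "", "| term | B (95% CI) | t | p (pFWE) |", "|---|---|---|---|",
            sprintf("| %s | %.3f (%.3f to %.3f) | %.2f | %.3f (%.3f) |",
                    fam$term, fam$b, fam$ci_low, fam$ci_high, fam$t,
                    fam$p_perm, fam$p_fwe), "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(x$cohort_summary),
                                 unlist(x$cohort_summary)), collapse = ", "),
      "\n")
  cat("  contrasts:", paste(names(x$group_contrasts), collapse = "; "), "\n")
  cat("  outcome families:", length(x$outcome_models), "\n")
  invisible(x)
}
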