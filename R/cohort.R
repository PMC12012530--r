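# Cohort tables: reading, validation, writing, and inclusion filters.
#
# The canonical column dictionary is defined here (snake_case); arbitrary CSV
# headers are bridged onto it with a user-supplied schema_map, and units other
# than mm/mm^2/mm^3 are converted at read time.

.group_levels <- c("control", "preterm", "chd")
.chd_subtypes <- c("abnormal_streaming", "left_sided", "right_sided")

.required_columns <- c(
  "group", "total_sa", "exposed_sa", "ct", "supratentorial_volume",
  "pma_weeks", "ga_weeks", "sex", "multiple_birth"
)

.optional_columns <- c(
  "subject_id", "birthweight_z", "imd_rank", "chd_subtype", "cerebral_do2",
  "parenteral_nutrition_days", "respiratory_support_days",
  "cognitive_score", "language_score", "motor_score",
  "corrected_age_months", "parent_first_language_english"
)

#' Canonical cohort column names
#'
#' @return character vector of all canonical column names, required first.
#' @export
cohort_columns <- function() c("subject_id", .required_columns,
                               setdiff(.optional_columns, "subject_id"))

# eligibility window for the analysis: scans at 37+0 to 44+6 weeks PMA
.pma_eligible <- c(37, 44 + 6 / 7)

.unit_factors <- c(
  mm2 = 1, cm2 = 100, m2 = 1e6,
  mm = 1, cm = 10,
  mm3 = 1, cm3 = 1000
)

new_cohort_table <- function(df, validation = NULL, provenance = "") {
  rownames(df) <- NULL
  structure(df,
    class = c("cohort_table", "data.frame"),
    validation = validation %||% empty_validation(),
    provenance = provenance
  )
}

empty_validation <- function() {
  data.frame(subject_id = character(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects", nrow(x)))
  if (nrow(x)) {
    tab <- table(factor(x$group, levels = .group_levels))
    cat(" (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  rep <- validation_report(x)
  if (nrow(rep)) cat(sprintf("  %d record(s) excluded at validation\n", length(unique(rep$subject_id))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Validation report of a cohort table
#'
#' @param cohort a `cohort_table`.
#' @return data.frame with one row per violated invariant (`subject_id`,
#'   `field`, `message`) for records excluded at read/validation time.
#' @export
validation_report <- function(cohort) {
  attr(cohort, "validation") %||% empty_validation()
}

#' Read and validate a per-subject cohort CSV
#'
#' Reads a CSV of per-subject cortical morphometrics and demographics,
#' renames columns onto the canonical dictionary via `schema_map`, converts
#' declared units to mm/mm^2/mm^3, parses "weeks+days" age strings, and
#' applies the record invariants. Rows violating an invariant are excluded
#' (not an error) and enumerated in the attached validation report.
#'
#' Record invariants: `total_sa > exposed_sa > 0`; `ct > 0`;
#' `supratentorial_volume > 0`; controls born at `ga_weeks >= 37`; preterm
#' at `ga_weeks < 33`; analysis-eligible scans at 37+0 to 44+6 weeks PMA.
#'
#' @param path CSV file path (header row, UTF-8, period decimal separator).
#' @param schema_map optional named character vector mapping file column
#'   names to canonical names, e.g. `c(TotalSurfArea = "total_sa")`.
#' @param units optional named character vector declaring the unit of
#'   morphometric columns (canonical names), one of mm2/cm2/m2 for areas,
#'   mm/cm for thickness, mm3/cm3 for volume. Default mm2/mm/mm3.
#' @param drop_ineligible exclude scans outside the 37 to 44+6 week PMA
#'   window (default TRUE, matching the study inclusion rule).
#' @return a `cohort_table`; see [validation_report()] for excluded rows.
#' @export
read_cohort <- function(path, schema_map = NULL, units = NULL,
                        drop_ineligible = TRUE) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(df, schema_map = schema_map, units = units,
            drop_ineligible = drop_ineligible, provenance = path)
}

#' Coerce a data.frame to a validated cohort table
#'
#' @param df data.frame of subject records.
#' @inheritParams read_cohort
#' @param provenance free-text provenance recorded on the result.
#' @return a `cohort_table`.
#' @export
as_cohort <- function(df, schema_map = NULL, units = NULL,
                      drop_ineligible = TRUE, provenance = "in-memory") {
  if (!is.null(schema_map)) {
    hit <- names(schema_map)[names(schema_map) %in% names(df)]
    names(df)[match(hit, names(df))] <- unname(schema_map[hit])
  }
  missing <- setdiff(.required_columns, names(df))
  if (length(missing)) {
    abort("required column(s) missing after schema mapping: %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(df$subject_id)) {
    df$subject_id <- sprintf("S%04d", seq_len(nrow(df)))
  }
  df$subject_id <- as.character(df$subject_id)

  # unit conversion (declared per canonical column)
  if (!is.null(units)) {
    for (nm in names(units)) {
      u <- tolower(units[[nm]])
      if (!u %in% names(.unit_factors)) abort("unknown unit '%s' for %s", u, nm)
      df[[nm]] <- suppressWarnings(as.numeric(df[[nm]])) * .unit_factors[[u]]
    }
  }

  df$pma_weeks <- parse_weeks(df$pma_weeks)
  df$ga_weeks <- parse_weeks(df$ga_weeks)
  df$group <- tolower(trimws(as.character(df$group)))
  df$sex <- tolower(trimws(as.character(df$sex)))
  df$sex[df$sex %in% c("f", "0")] <- "female"
  df$sex[df$sex %in% c("m", "1")] <- "male"
  mb <- as.logical(df$multiple_birth)
  mb_num <- suppressWarnings(as.numeric(as.character(df$multiple_birth)))
  fixable <- is.na(mb) & !is.na(mb_num)
  mb[fixable] <- mb_num[fixable] == 1
  df$multiple_birth <- mb

  for (nm in c("total_sa", "exposed_sa", "ct", "supratentorial_volume")) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  for (nm in intersect(.optional_columns, names(df))) {
    if (nm %in% c("chd_subtype", "subject_id")) next
    if (nm == "parent_first_language_english") {
      df[[nm]] <- as.logical(df[[nm]])
      next
    }
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }

  issues <- validate_records(df, drop_ineligible = drop_ineligible)
  bad <- unique(issues$subject_id)
  kept <- df[!df$subject_id %in% bad, , drop = FALSE]

  dup <- kept$subject_id[duplicated(kept$subject_id)]
  if (length(dup)) {
    abort("subject_id not unique: %s", paste(unique(dup), collapse = ", "))
  }
  new_cohort_table(kept, validation = issues, provenance = provenance)
}

validate_records <- function(df, drop_ineligible = TRUE) {
  issues <- empty_validation()
  flag <- function(mask, field, message) {
    mask[is.na(mask)] <- TRUE
    if (any(mask)) {
      issues <<- rbind(issues, data.frame(
        subject_id = df$subject_id[mask], field = field, message = message,
        stringsAsFactors = FALSE
      ))
    }
  }
  flag(!is.finite(df$total_sa) | df$total_sa <= 0, "total_sa",
       "total_sa must be a positive number")
  flag(!is.finite(df$exposed_sa) | df$exposed_sa <= 0, "exposed_sa",
       "exposed_sa must be a positive number")
  flag(is.finite(df$total_sa) & is.finite(df$exposed_sa) &
         df$total_sa <= df$exposed_sa, "exposed_sa",
       "total_sa must exceed exposed_sa (pial surface exceeds exposed hull)")
  flag(!is.finite(df$ct) | df$ct <= 0, "ct", "ct must be a positive number")
  flag(!is.finite(df$supratentorial_volume) | df$supratentorial_volume <= 0,
       "supratentorial_volume", "supratentorial_volume must be positive")
  flag(!df$group %in% .group_levels, "group",
       sprintf("group must be one of %s", paste(.group_levels, collapse = "/")))
  flag(!df$sex %in% c("female", "male"), "sex", "sex must be female/male")
  flag(is.na(df$multiple_birth), "multiple_birth",
       "multiple_birth must be TRUE/FALSE (or 0/1)")
  flag(df$group == "control" & (is.na(df$ga_weeks) | df$ga_weeks < 37),
       "ga_weeks", "controls must be born at term (ga_weeks >= 37)")
  flag(df$group == "preterm" & (is.na(df$ga_weeks) | df$ga_weeks >= 33),
       "ga_weeks", "preterm group requires ga_weeks < 33")
  if (drop_ineligible) {
    flag(is.na(df$pma_weeks) | df$pma_weeks < .pma_eligible[1] |
           df$pma_weeks > .pma_eligible[2] + 1e-9, "pma_weeks",
         "scan outside the 37+0 to 44+6 week PMA eligibility window")
  }
  issues
}

#' Write a cohort table to CSV
#'
#' Canonical columns only, in dictionary order; round-trips through
#' [read_cohort()] bit-for-bit for valid rows.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(cohort_columns(), names(cohort))
  utils::write.csv(as.data.frame(cohort)[, cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Restrict a reference group to the scan-age range of a target group
#'
#' Group comparisons against a clinical group are made on a common
#' postmenstrual-age support: reference-group records scanned outside the
#' `[min, max]` PMA range of the target group are removed (in the study this
#' drops controls scanned outside the CHD range of 37.14 to 42.29 weeks).
#' Records of any other group pass through unchanged. Idempotent.
#'
#' @param cohort a `cohort_table`.
#' @param reference_group group to be trimmed (e.g. `"control"`).
#' @param target_group group whose PMA range defines the window.
#' @return the filtered `cohort_table` with attribute `n_removed`.
#' @export
filter_pma_overlap <- function(cohort, reference_group, target_group) {
  if (!any(cohort$group == target_group)) {
    abort("target group '%s' is empty", target_group)
  }
  if (!any(cohort$group == reference_group)) {
    abort("reference group '%s' is empty", reference_group)
  }
  rng <- range(cohort$pma_weeks[cohort$group == target_group])
  drop <- cohort$group == reference_group &
    (cohort$pma_weeks < rng[1] | cohort$pma_weeks > rng[2])
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "validation") <- attr(cohort, "validation")
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "n_removed") <- sum(drop)
  class(out) <- class(cohort)
  out
}
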