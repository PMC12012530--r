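#' Orthogonal multivariate morphological terms
#'
#' Every cortex can be represented as a point in the three-dimensional log
#' space with axes \eqn{[\log_{10}(\mathrm{total\ SA}),
#' \log_{10}(\mathrm{exposed\ SA}), \log_{10}(\mathrm{CT}^2)]}. The universal
#' folding law, total SA \eqn{\times} CT\eqn{^{0.5}} \eqn{\propto} (exposed
#' SA)\eqn{^{1.25}}, defines a plane in this space, and cortical morphology
#' decomposes along three mutually orthogonal directions:
#'
#' * **offset** `K = a - 1.25 e + 0.25 c` — orthogonal deviation from the
#'   folding plane; indexes the propensity of the surface to fold (higher
#'   with more total SA and thicker cortex, lower with more exposed SA);
#' * **isometric** `I = a + e + c` — pure size along `[1, 1, 1]`;
#' * **shape** `S = 1.5 a + 0.75 e - 2.25 c` — the orthogonal complement
#'   (cross product of the other two directions), a size- and
#'   offset-independent shape descriptor.
#'
#' Here `a = log10(total_sa)`, `e = log10(exposed_sa)`,
#' `c = log10(ct^2)`. Base-10 logarithms are used throughout the package;
#' changing the base rescales all three terms by one positive constant and
#' leaves every downstream t-statistic and z-score unchanged.
#'
#' @param total_sa total pial surface area, mm^2 (vectorised).
#' @param exposed_sa exposed pial surface area, mm^2.
#' @param ct mean (curvature-corrected) cortical thickness, mm.
#' @return `compute_terms()`: a data.frame with columns `offset_k`,
#'   `isometric_i`, `shape_s` (log10 units) and `gi` (gyrification index,
#'   total/exposed SA, dimensionless). `embed_log_coordinates()`: a matrix
#'   with columns `a`, `e`, `c`.
#' @examples
#' compute_terms(1e5, 10^4.5, 10^0.3)
#' @export
compute_terms <- function(total_sa, exposed_sa, ct) {
  xyz <- embed_log_coordinates(total_sa, exposed_sa, ct)
  basis <- morph_basis()
  proj <- xyz %*% t(basis)
  data.frame(
    offset_k    = proj[, "offset"],
    isometric_i = proj[, "isometric"],
    shape_s     = proj[, "shape"],
    gi          = total_sa / exposed_sa
  )
}

#' @rdname compute_terms
#' @export
embed_log_coordinates <- function(total_sa, exposed_sa, ct) {
  if (any(!is.finite(total_sa)) || any(!is.finite(exposed_sa)) ||
      any(!is.finite(ct))) {
    abort("morphometrics must be finite")
  }
  if (any(total_sa <= 0) || any(exposed_sa <= 0) || any(ct <= 0)) {
    abort("morphometrics must be strictly positive")
  }
  cbind(a = log10(total_sa), e = log10(exposed_sa), c = 2 * log10(ct))
}

#' Coefficient vectors of the offset/isometric/shape decomposition
#'
#' The three rows are mutually orthogonal in the `[a, e, c]` log space.
#'
#' @return a 3x3 numeric matrix with rows `offset`, `isometric`, `shape`.
#' @export
morph_basis <- function() {
  rbind(
    offset    = c(1,   -1.25,  0.25),
    isometric = c(1,    1,     1),
    shape     = c(1.5,  0.75, -2.25)
  )
}

#' Append morphological term columns to a cohort table
#'
#' @param cohort a `cohort_table` (or data.frame with the canonical
#'   morphometric columns).
#' @return the input with columns `offset_k`, `isometric_i`, `shape_s`, `gi`
#'   added (recomputed if already present).
#' @export
add_morph_terms <- function(cohort) {
  terms <- compute_terms(cohort$total_sa, cohort$exposed_sa, cohort$ct)
  for (nm in names(terms)) cohort[[nm]] <- terms[[nm]]
  cohort
}

#' Z-score term columns to the control group
#'
#' Convenience for visualisation: the raw terms are unitless only up to the
#' unit of measurement, so group overlays are usually drawn on a scale
#' standardised to the control distribution. All statistics in the package
#' operate on the raw terms.
#'
#' @param cohort a cohort table with term columns present.
#' @param columns columns to standardise.
#' @param control_group label of the reference group.
#' @return the cohort with `<column>_zctrl` columns appended.
#' @export
zscore_to_controls <- function(cohort,
                               columns = c("offset_k", "isometric_i", "shape_s"),
                               control_group = "control") {
  ctrl <- cohort$group == control_group
  if (!any(ctrl)) abort("no records in control group '%s'", control_group)
  for (nm in columns) {
    if (is.null(cohort[[nm]])) abort("column '%s' not present", nm)
    mu <- mean(cohort[[nm]][ctrl])
    sd_ <- stats::sd(cohort[[nm]][ctrl])
    cohort[[paste0(nm, "_zctrl")]] <- (cohort[[nm]] - mu) / sd_
  }
  cohort
}
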