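# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Parse gestational/postmenstrual ages given either as decimal weeks or as
#' a clinical "weeks+days" string ("44+6" = 44 weeks 6 days).
#'
#' @param x numeric or character vector.
#' @return numeric vector of decimal weeks; unparseable entries become `NA`.
#' @examples
#' parse_weeks(c("40", "44+6", "38.5"))
#' @export
parse_weeks <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  plus <- grepl("^\\d+\\s*\\+\\s*\\d+$", x)
  if (any(plus)) {
    parts <- strsplit(x[plus], "\\+")
    out[plus] <- vapply(parts, function(p) {
      as.numeric(p[1]) + as.numeric(p[2]) / 7
    }, numeric(1))
  }
  out
}

# stop() with call. = FALSE everywhere, sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
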