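# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize an identifier for cross-source matching
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds to lower case. Association matching across
#' EMR-mined, knowledge-base and literature sources uses exact equality of
#' normalized identifiers; no synonym expansion is performed.
#'
#' @param x character vector of identifiers.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_id(c("  Hodgkin  Lymphoma ", "HP:0001"))
normalize_id <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

# round() uses round-half-to-even; reports follow the conventional half-up
# rule so printed tables match manual rounding.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_probability <- function(x, field, allow_zero = TRUE, allow_one = TRUE) {
  if (length(x) == 0) return(invisible(x))
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric and non-missing")
  lo <- if (allow_zero) x >= 0 else x > 0
  hi <- if (allow_one) x <= 1 else x < 1
  if (!all(lo & hi)) {
    stop_field(field, sprintf(
      "must lie in %s0, 1%s", if (allow_zero) "[" else "(", if (allow_one) "]" else ")"
    ))
  }
  invisible(x)
}

check_count <- function(x, field, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) || x < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

# Deterministic sampling that leaves the caller's RNG state untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
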