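`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) stop_input(sprintf("`%s` must be finite", name))
  if (positive && x <= 0) stop_input(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# value carried when an estimate cannot be produced; keeps the reason with the NA
missing_with_reason <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Reason an estimate is missing
#'
#' Estimators in this package return `NA` with a `reason` attribute when an
#' eligibility rule is not met (for example too few validated measurements).
#' `missing_reason()` retrieves that reason, or `NULL` for ordinary values.
#'
#' @param x A value returned by one of the estimators.
#' @return A character string, or `NULL` when `x` carries no reason.
#' @export
missing_reason <- function(x) attr(x, "reason", exact = TRUE)
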