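#' Validate a 2-D image matrix
#'
#' Images are plain numeric matrices of intensities (arbitrary units).
#' Every operation in the package accepts and returns such matrices.
#'
#' @param x object to validate.
#' @param arg name used in error messages.
#' @return the validated matrix, invisibly.
#' @keywords internal
assert_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("invalid input: `%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("invalid input: `%s` must have at least one row and column", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("invalid input: `%s` contains non-finite entries (NaN/Inf/NA)", arg), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
assert_scalar <- function(x, arg, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("invalid parameter: `%s` must be a finite numeric scalar", arg), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("invalid parameter: `%s` must be %s %g", arg,
                 if (strict) ">" else ">=", lower), call. = FALSE)
  }
  invisible(x)
}

# Frobenius norm, used throughout for residuals.
fnorm <- function(x) sqrt(sum(x^2))
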