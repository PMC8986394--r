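#' Mean squared error between two images
#'
#' `MSE(a, b) = (1/(A*B)) * sum_ij (a_ij - b_ij)^2` for images of size
#' `A x B`. Symmetric in its arguments; zero iff the images are identical.
#'
#' @param a,b numeric matrices of identical dimensions (by convention `a` is
#'   the clean/ideal reference, `b` the image under assessment).
#' @return nonnegative scalar in squared intensity units.
#' @export
mse <- function(a, b) {
  assert_image(a, "a")
  assert_image(b, "b")
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("invalid input: image dimensions differ (%d x %d vs %d x %d)",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR(a, b) = 10 * log10(L^2 / MSE(a, b))` in decibels, where `L` is the
#' peak signal (e.g. 255 for 8-bit images). Larger values indicate closer
#' agreement with the reference. Identical images give `MSE = 0`; the
#' documented sentinel `+Inf` is returned rather than an error.
#'
#' @inheritParams mse
#' @param peak_L positive peak signal value.
#' @return PSNR in dB, or `Inf` when the images are identical.
#' @export
psnr <- function(a, b, peak_L) {
  assert_scalar(peak_L, "peak_L", lower = 0, strict = TRUE)
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(peak_L^2 / m)
}

#' Full quality report for a (reference, test) image pair
#'
#' @param reference clean/ideal image.
#' @param test image under assessment.
#' @param peak_L peak signal; `NULL` defaults to the `bit_depth` attribute of
#'   `reference` when present (255 for 8-bit, 65535 for 16-bit), otherwise to
#'   `max(reference)`. The value actually used is recorded in the report.
#' @return list of class `metric_report` with `mse`, `psnr` and `peak_L`.
#' @export
metric_report <- function(reference, test, peak_L = NULL) {
  if (is.null(peak_L)) {
    bd <- attr(reference, "bit_depth")
    peak_L <- if (!is.null(bd)) 2^bd - 1 else max(reference)
  }
  assert_scalar(peak_L, "peak_L", lower = 0, strict = TRUE)
  structure(list(mse = mse(reference, test),
                 psnr = psnr(reference, test, peak_L),
                 peak_L = peak_L),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MSE = %.4f, PSNR = %.4f dB (peak L = %g)\n", x$mse, x$psnr, x$peak_L))
  invisible(x)
}
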