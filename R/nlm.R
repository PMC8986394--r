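#' Non-local-means configuration
#'
#' @param patch_radius nonnegative integer; patches are
#'   `(2*patch_radius+1)^2` pixels. Default 3 (7x7 patches).
#' @param search_radius positive integer, at least `patch_radius`; candidate
#'   pixels come from the `(2*search_radius+1)^2` window. Default 10.
#' @param h positive filtering bandwidth in intensity units. `NULL` (the
#'   default) resolves at denoise time to 10% of the image's intensity range.
#' @return a list of class `nlm_config`.
#' @export
nlm_config <- function(patch_radius = 3L, search_radius = 10L, h = NULL) {
  assert_scalar(patch_radius, "patch_radius", lower = 0)
  assert_scalar(search_radius, "search_radius", lower = 1)
  if (search_radius < patch_radius) {
    stop("invalid parameter: `search_radius` must be >= `patch_radius`", call. = FALSE)
  }
  if (!is.null(h)) assert_scalar(h, "h", lower = 0, strict = TRUE)
  structure(list(patch_radius = as.integer(patch_radius),
                 search_radius = as.integer(search_radius), h = h),
            class = "nlm_config")
}

#' Non-local-means denoising
#'
#' Baseline comparator: each output pixel is the weight-normalized average of
#' the pixels in its search window, with weights `exp(-d2/h^2)` where `d2` is
#' the mean squared difference between the two pixels' patches. Patches are
#' taken from the symmetrically (mirror) padded image; the search window is
#' clipped at the image boundary. Weights at each pixel sum to one before
#' averaging, so the output is a convex combination of input intensities.
#'
#' @param S numeric matrix (noisy image), at least `2*patch_radius + 1`
#'   pixels in each dimension.
#' @param config an [nlm_config()].
#' @return the denoised image, same shape as `S`.
#' @export
nlm_denoise <- function(S, config = nlm_config()) {
  assert_image(S, "S")
  stopifnot(inherits(config, "nlm_config"))
  win <- 2L * config$patch_radius + 1L
  if (nrow(S) < win || ncol(S) < win) {
    stop(sprintf("invalid input: image (%d x %d) is smaller than the %d x %d patch window",
                 nrow(S), ncol(S), win, win), call. = FALSE)
  }
  h <- config$h
  if (is.null(h)) {
    h <- 0.1 * (max(S) - min(S))
    if (h <= 0) return(S)  # constant image: nothing to filter
  }
  .nlm_cpp(S, config$patch_radius, config$search_radius, h)
}
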