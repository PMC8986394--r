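#' Nuclear norm of a matrix
#'
#' Sum of all singular values; the convex surrogate for rank used in the
#' low-rank denoising objective.
#'
#' @param M numeric matrix.
#' @return nonnegative scalar, zero iff `M` is the zero matrix.
#' @examples
#' nuclear_norm(diag(3))      # 3
#' nuclear_norm(diag(c(3, 4)))  # 7
#' @export
nuclear_norm <- function(M) {
  assert_image(M, "M")
  sum(svd(M, nu = 0, nv = 0)$d)
}

#' Elementwise soft thresholding
#'
#' Shrink-toward-zero operator `sign(x) * max(|x| - tau, 0)`: the proximal
#' operator of the (scaled) l1 norm, used to update the sparse component.
#'
#' @param M numeric matrix.
#' @param tau nonnegative threshold.
#' @return matrix of the same shape as `M`.
#' @export
soft_threshold <- function(M, tau) {
  assert_image(M, "M")
  assert_scalar(tau, "tau", lower = 0)
  sign(M) * pmax(abs(M) - tau, 0)
}

#' Singular value thresholding
#'
#' Applies soft thresholding to the singular values of `M`: with
#' `M = U diag(b) V'`, returns `U diag(max(b - tau, 0)) V'`. This is the
#' proximal operator of the nuclear norm and the workhorse of the low-rank
#' update.
#'
#' @param M numeric matrix.
#' @param tau nonnegative threshold.
#' @return matrix of the same shape as `M` whose singular values are
#'   `max(b_i - tau, 0)`.
#' @export
singular_value_threshold <- function(M, tau) {
  assert_image(M, "M")
  assert_scalar(tau, "tau", lower = 0)
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) {
    return(matrix(0, nrow(M), ncol(M)))
  }
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Truncated-PCA denoising (best rank-r approximation)
#'
#' For low levels of dense noise the clean image is recovered as the best
#' rank-`rank_r` approximation of `S` in Frobenius norm, i.e. the
#' reconstruction from the `rank_r` largest singular values and their
#' singular vectors (Eckart--Young).
#'
#' @param S numeric matrix (noisy image).
#' @param rank_r target rank, `1 <= rank_r <= min(dim(S))`.
#' @return matrix of the same shape with rank at most `rank_r`.
#' @export
truncated_pca_denoise <- function(S, rank_r) {
  assert_image(S, "S")
  if (!is.numeric(rank_r) || length(rank_r) != 1L || !is.finite(rank_r) ||
      rank_r != round(rank_r) || rank_r < 1 || rank_r > min(dim(S))) {
    stop("invalid parameter: `rank_r` must be an integer in [1, min(dim(S))]",
         call. = FALSE)
  }
  r <- as.integer(rank_r)
  s <- svd(S, nu = r, nv = r)
  s$u %*% (s$d[seq_len(r)] * t(s$v))
}

#' Solver configuration for the robust decomposition
#'
#' @param alpha positive sparsity/low-rank trade-off. The default
#'   `1/sqrt(max(dim(S)))` (resolved at solve time when `NULL`) is the
#'   standard choice with exact-recovery guarantees for robust PCA.
#' @param tol positive stopping threshold on the relative constraint
#'   residual `||S - R - H||_F / ||S||_F`.
#' @param max_iter maximum number of iterations.
#' @param rank_r optional target rank for the truncated-PCA path.
#' @return a list of class `rpca_config`.
#' @export
rpca_config <- function(alpha = NULL, tol = 1e-7, max_iter = 1000L, rank_r = NULL) {
  if (!is.null(alpha)) assert_scalar(alpha, "alpha", lower = 0, strict = TRUE)
  assert_scalar(tol, "tol", lower = 0, strict = TRUE)
  assert_scalar(max_iter, "max_iter", lower = 1)
  if (!is.null(rank_r)) assert_scalar(rank_r, "rank_r", lower = 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 rank_r = if (is.null(rank_r)) NULL else as.integer(rank_r)),
            class = "rpca_config")
}

#' Robust low-rank + sparse decomposition
#'
#' Splits an observed image `S` into a low-rank component `R` and a sparse
#' component `H` by solving
#' `min alpha*||H||_1 + ||R||_*  s.t.  S = R + H`
#' with the inexact augmented Lagrange multiplier (ALM) method: alternating
#' singular value thresholding on `R`, elementwise soft thresholding on `H`,
#' and a dual (Lagrange multiplier) update, with the penalty `mu` increased
#' geometrically.
#'
#' @param S numeric matrix (noisy image).
#' @param config an [rpca_config()]; `config$alpha = NULL` resolves to
#'   `1/sqrt(max(dim(S)))`.
#' @return an object of class `rpca_decomposition`: list with `low_rank`,
#'   `sparse`, `iterations`, `converged`, `relative_residual`, `objective`
#'   (`alpha*||H||_1 + ||R||_*`) and `alpha`.
#' @details Non-convergence within `max_iter` raises a warning and returns
#'   the last iterate with `converged = FALSE`; no error is thrown.
#' @export
rpca_decompose <- function(S, config = rpca_config()) {
  assert_image(S, "S")
  stopifnot(inherits(config, "rpca_config"))
  alpha <- if (is.null(config$alpha)) 1 / sqrt(max(dim(S))) else config$alpha
  eps <- 1e-12
  s_fnorm <- max(fnorm(S), eps)

  if (all(S == 0)) {
    Z <- matrix(0, nrow(S), ncol(S))
    return(new_rpca_result(Z, Z, 0L, TRUE, 0, alpha))
  }

  spec <- svd(S, nu = 0, nv = 0)$d[1L]
  mu <- 1.25 / spec
  rho <- 1.5
  # dual ascent starting point: S scaled into the dual-feasible ball
  Y <- S / max(spec, max(abs(S)) / alpha)
  H <- matrix(0, nrow(S), ncol(S))
  R <- H
  converged <- FALSE
  rel <- Inf
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    R <- singular_value_threshold(S - H + Y / mu, 1 / mu)
    H <- soft_threshold(S - R + Y / mu, alpha / mu)
    Z <- S - R - H
    rel <- fnorm(Z) / s_fnorm
    if (rel <= config$tol) {
      converged <- TRUE
      break
    }
    Y <- Y + mu * Z
    mu <- mu * rho
  }
  if (!converged) {
    warning(sprintf(
      "rpca_decompose did not converge in %d iterations (relative residual %.3g > tol %.3g)",
      config$max_iter, rel, config$tol))
  }
  new_rpca_result(R, H, iter, converged, rel, alpha)
}

new_rpca_result <- function(R, H, iterations, converged, rel, alpha) {
  structure(list(
    low_rank = R,
    sparse = H,
    iterations = iterations,
    converged = converged,
    relative_residual = rel,
    objective = alpha * sum(abs(H)) + nuclear_norm_or_zero(R),
    alpha = alpha
  ), class = "rpca_decomposition")
}

nuclear_norm_or_zero <- function(M) {
  if (all(M == 0)) 0 else nuclear_norm(M)
}

#' @export
print.rpca_decomposition <- function(x, ...) {
  cat(sprintf("Low-rank + sparse decomposition (%d x %d)\n",
              nrow(x$low_rank), ncol(x$low_rank)))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  relative residual ||S-R-H||_F/||S||_F: %.3g\n", x$relative_residual))
  cat(sprintf("  objective alpha*||H||_1 + ||R||_*: %.6g (alpha = %.4g)\n",
              x$objective, x$alpha))
  cat(sprintf("  nonzero entries in sparse part: %d\n", sum(x$sparse != 0)))
  invisible(x)
}

#' Denoise an image by the low-rank model
#'
#' Dispatches to [rpca_decompose()] (returning the low-rank component) for
#' sparse, strong noise, or to [truncated_pca_denoise()] for low dense
#' noise. The path is user-selected via `method`; no automatic noise-level
#' detection is attempted.
#'
#' @param S numeric matrix (noisy image).
#' @param method `"rpca"` or `"pca"`.
#' @param config an [rpca_config()]; the `pca` method requires `rank_r`.
#' @return the denoised image, same shape as `S`. Values are left on the raw
#'   intensity scale; clipping to a bit depth happens only in [write_image()].
#' @export
denoise_image <- function(S, method = c("rpca", "pca"), config = rpca_config()) {
  method <- match.arg(method)
  assert_image(S, "S")
  stopifnot(inherits(config, "rpca_config"))
  if (method == "pca") {
    if (is.null(config$rank_r)) {
      stop("invalid parameter: method = \"pca\" requires `rank_r` in the config",
           call. = FALSE)
    }
    truncated_pca_denoise(S, config$rank_r)
  } else {
    rpca_decompose(S, config)$low_rank
  }
}
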