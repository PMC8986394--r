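# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Recipe for a synthetic clean image
#'
#' Phantoms stand in for clean MRI slices, with known ground truth so any
#' denoiser's recovery error is computable exactly. Two kinds are provided:
#' `"lowrank"` images are exactly low-rank (the assumption under which the
#' robust decomposition has recovery guarantees), `"ellipses"` images are
#' piecewise-constant overlapping ellipses on a dark background, a
#' brain-slice-like setting where low rank holds only approximately.
#'
#' @param height,width positive integers.
#' @param kind `"lowrank"` or `"ellipses"`.
#' @param rank_r exact rank of a `"lowrank"` phantom (default 5).
#' @param n_ellipses number of tissue ellipses for `"ellipses"` (default 6).
#' @param intensity_range length-2 numeric `c(lo, hi)`, `lo < hi`; all
#'   generated intensities fall inside it. Default `c(0, 255)`.
#' @param seed integer RNG seed; identical specs give bit-identical images.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width, kind = c("lowrank", "ellipses"),
                         rank_r = 5L, n_ellipses = 6L,
                         intensity_range = c(0, 255), seed = 1L) {
  kind <- match.arg(kind)
  assert_scalar(height, "height", lower = 1)
  assert_scalar(width, "width", lower = 1)
  if (length(intensity_range) != 2L || !all(is.finite(intensity_range)) ||
      intensity_range[1] >= intensity_range[2]) {
    stop("invalid parameter: `intensity_range` must be c(lo, hi) with lo < hi",
         call. = FALSE)
  }
  if (kind == "lowrank") {
    assert_scalar(rank_r, "rank_r", lower = 1)
    if (rank_r > min(height, width)) {
      stop("invalid parameter: `rank_r` must not exceed min(height, width)",
           call. = FALSE)
    }
  } else {
    assert_scalar(n_ellipses, "n_ellipses", lower = 1)
  }
  assert_scalar(seed, "seed")
  structure(list(height = as.integer(height), width = as.integer(width),
                 kind = kind, rank_r = as.integer(rank_r),
                 n_ellipses = as.integer(n_ellipses),
                 intensity_range = as.numeric(intensity_range),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic clean image
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix `height x width`, deterministic given the seed.
#'   For `kind = "lowrank"` the numerical rank is exactly `rank_r` and the
#'   intensities span `intensity_range` (for `rank_r >= 2`; a rank-1 phantom
#'   is scaled to peak at the range top). For `kind = "ellipses"` the
#'   background sits at the range floor and tissue levels lie within range.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lo <- spec$intensity_range[1]
  hi <- spec$intensity_range[2]
  with_seed(spec$seed, {
    if (spec$kind == "lowrank") {
      lowrank_phantom(spec$height, spec$width, spec$rank_r, lo, hi)
    } else {
      ellipses_phantom(spec$height, spec$width, spec$n_ellipses, lo, hi)
    }
  })
}

# Exact-rank-r image in [lo, hi]. The constant (all-ones) rank-1 term is part
# of the rank budget, so the affine rescale into [lo, hi] -- which only adds
# multiples of that term -- cannot raise the rank above r.
lowrank_phantom <- function(A, B, r, lo, hi) {
  if (r == 1L) {
    u <- abs(rnorm(A)) + 0.1
    v <- abs(rnorm(B)) + 0.1
    X <- outer(u, v)
    return(X * (hi / max(X)))  # positive entries peaking at hi
  }
  G <- matrix(0, A, B)
  for (k in seq_len(r - 1L)) {
    G <- G + outer(rnorm(A), rnorm(B))
  }
  X <- G + 2 * max(abs(G))  # + constant: strictly positive, rank exactly r a.s.
  lo + (X - min(X)) * (hi - lo) / (max(X) - min(X))
}

# Piecewise-constant brain-slice-like image: a large head ellipse plus
# n randomly placed tissue ellipses painted over it (later ellipses win).
ellipses_phantom <- function(A, B, n, lo, hi) {
  img <- matrix(lo, A, B)
  ii <- matrix(seq_len(A), A, B)
  jj <- matrix(rep(seq_len(B), each = A), A, B)
  span <- hi - lo
  paint <- function(cy, cx, ay, ax, theta, level) {
    dy <- (ii - cy) / ay
    dx <- (jj - cx) / ax
    y2 <- dy * cos(theta) + dx * sin(theta)
    x2 <- -dy * sin(theta) + dx * cos(theta)
    inside <- (y2^2 + x2^2) <= 1
    img[inside] <<- level
  }
  paint(A / 2, B / 2, 0.45 * A, 0.42 * B, 0, lo + 0.25 * span)
  for (k in seq_len(n)) {
    paint(cy = runif(1, 0.25 * A, 0.75 * A),
          cx = runif(1, 0.25 * B, 0.75 * B),
          ay = runif(1, 0.05, 0.22) * A,
          ax = runif(1, 0.05, 0.22) * B,
          theta = runif(1, 0, pi),
          level = lo + runif(1, 0.35, 1) * span)
  }
  img
}

#' Noise model for corrupting a clean image
#'
#' Describes the observation model `S = clean + G + E`: `G` is i.i.d.
#' Gaussian with standard deviation `gaussian_sigma` and `E` places
#' `+/- impulse_amplitude` spikes at a uniformly chosen fraction of pixels
#' (salt-and-pepper about the clean value, so the sparse component has
#' entries of either sign).
#'
#' @param gaussian_sigma nonnegative Gaussian standard deviation
#'   (intensity units).
#' @param impulse_fraction fraction of pixels corrupted by impulses, in
#'   `[0, 1)`; the corrupted count is exactly `floor(fraction * npixels)`.
#' @param impulse_amplitude positive impulse magnitude (intensity units).
#' @param seed integer seed. Gaussian draws use the stream seeded with
#'   `seed`, impulse draws the stream seeded with `seed + 1`, so changing
#'   one noise source does not perturb the other's realization.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0, impulse_fraction = 0,
                        impulse_amplitude = 1, seed = 1L) {
  assert_scalar(gaussian_sigma, "gaussian_sigma", lower = 0)
  assert_scalar(impulse_fraction, "impulse_fraction", lower = 0)
  if (impulse_fraction >= 1) {
    stop("invalid parameter: `impulse_fraction` must be < 1", call. = FALSE)
  }
  assert_scalar(impulse_amplitude, "impulse_amplitude", lower = 0, strict = TRUE)
  assert_scalar(seed, "seed")
  structure(list(gaussian_sigma = gaussian_sigma,
                 impulse_fraction = impulse_fraction,
                 impulse_amplitude = impulse_amplitude,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Corrupt a clean image with Gaussian and/or impulse noise
#'
#' @param clean numeric matrix.
#' @param model a [noise_model()].
#' @return the noisy image `S = clean + G + E`, with the realizations kept
#'   as attributes for ground-truth testing: `gaussian` (matrix `G`),
#'   `impulse` (matrix `E`) and `impulse_mask` (logical matrix of corrupted
#'   pixels). Deterministic given the model's seed.
#' @export
add_noise <- function(clean, model) {
  assert_image(clean, "clean")
  stopifnot(inherits(model, "noise_model"))
  A <- nrow(clean); B <- ncol(clean)
  G <- with_seed(model$seed, {
    if (model$gaussian_sigma > 0) {
      matrix(rnorm(A * B, sd = model$gaussian_sigma), A, B)
    } else matrix(0, A, B)
  })
  E <- matrix(0, A, B)
  m <- floor(model$impulse_fraction * A * B)
  if (m > 0) {
    with_seed(model$seed + 1L, {
      idx <- sample.int(A * B, m)
      E[idx] <- model$impulse_amplitude * sample(c(-1, 1), m, replace = TRUE)
    })
  }
  S <- clean + G + E
  attr(S, "gaussian") <- G
  attr(S, "impulse") <- E
  attr(S, "impulse_mask") <- E != 0
  S
}
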