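# Independent brute-force oracles used across the suite.

# 1-based symmetric (mirror) index, edge pixel duplicated.
reflect1 <- function(x, n) {
  while (x < 1 || x > n) {
    if (x < 1) x <- 1 - x
    if (x > n) x <- 2 * n + 1 - x
  }
  x
}

# Quadruple-loop non-local means, written directly from the definition:
# weights exp(-mean patch squared difference / h^2), search window clipped
# to the image, patches mirror-padded.
nlm_brute <- function(img, pr, sr, h) {
  A <- nrow(img); B <- ncol(img)
  px <- function(i, j) img[reflect1(i, A), reflect1(j, B)]
  out <- matrix(0, A, B)
  for (i in seq_len(A)) for (j in seq_len(B)) {
    wsum <- 0; vsum <- 0
    for (k in max(1, i - sr):min(A, i + sr)) {
      for (l in max(1, j - sr):min(B, j + sr)) {
        d2 <- 0
        for (p in -pr:pr) for (q in -pr:pr) {
          d2 <- d2 + (px(i + p, j + q) - px(k + p, l + q))^2
        }
        d2 <- d2 / (2 * pr + 1)^2
        w <- exp(-d2 / h^2)
        wsum <- wsum + w
        vsum <- vsum + w * img[k, l]
      }
    }
    out[i, j] <- vsum / wsum
  }
  out
}

# Unweighted mean over the clipped search window (the large-h limit of NLM).
windowed_mean <- function(img, sr) {
  A <- nrow(img); B <- ncol(img)
  out <- matrix(0, A, B)
  for (i in seq_len(A)) for (j in seq_len(B)) {
    out[i, j] <- mean(img[max(1, i - sr):min(A, i + sr),
                          max(1, j - sr):min(B, j + sr)])
  }
  out
}

# Best rank-r approximation assembled from a full SVD with all but the
# top-r singular values zeroed.
svd_truncate_oracle <- function(S, r) {
  s <- svd(S)
  d <- s$d
  d[-seq_len(r)] <- 0
  s$u %*% diag(d, length(d)) %*% t(s$v)
}

# Seeded robust-PCA test instance: exact rank-r low-rank part plus sparse
# +/- spikes at a known support.
make_rpca_instance <- function(seed, n = 100L, r = 5L, frac = 0.05,
                               amp_sd = 5) {
  set.seed(seed)
  L0 <- matrix(rnorm(n * r), n, r) %*% t(matrix(rnorm(n * r), n, r))
  m <- floor(frac * n * n)
  idx <- sample.int(n * n, m)
  E0 <- matrix(0, n, n)
  E0[idx] <- amp_sd * sd(L0) * sample(c(-1, 1), m, replace = TRUE)
  list(L0 = L0, E0 = E0, S = L0 + E0, support = E0 != 0)
}

rel_fro <- function(x, y) norm(x - y, "F") / norm(y, "F")

jaccard <- function(a, b) sum(a & b) / sum(a | b)
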