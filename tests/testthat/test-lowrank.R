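test_that("nuclear norm sums singular values", {
  expect_equal(nuclear_norm(diag(3)), 3)
  expect_equal(nuclear_norm(diag(c(3, 4))), 7)
  expect_equal(nuclear_norm(matrix(c(0, 1, 1, 0), 2, 2)), 2)
  expect_equal(nuclear_norm(matrix(0, 4, 7)), 0)
  set.seed(1)
  M <- matrix(rnorm(12), 3, 4)
  expect_gt(nuclear_norm(M), 0)
  expect_error(nuclear_norm(matrix(c(1, NaN), 1, 2)), "non-finite")
})

test_that("soft thresholding shrinks toward zero elementwise", {
  M <- matrix(rnorm(20), 4, 5)
  expect_identical(soft_threshold(M, 0), M)
  expect_equal(soft_threshold(matrix(c(3, -0.5, 1), 1, 3), 1),
               matrix(c(2, 0, 0), 1, 3))
  set.seed(7)
  X <- matrix(rnorm(16), 4, 4)
  oracle <- X
  for (i in seq_along(X)) {
    oracle[i] <- sign(X[i]) * max(abs(X[i]) - 0.7, 0)
  }
  expect_equal(soft_threshold(X, 0.7), oracle, tolerance = 1e-15)
  expect_error(soft_threshold(M, -0.1), "invalid parameter")
})

test_that("singular value thresholding shrinks the spectrum", {
  set.seed(2)
  M <- matrix(rnorm(30), 5, 6)
  expect_equal(singular_value_threshold(M, 0), M, tolerance = 1e-12)
  big <- svd(M, nu = 0, nv = 0)$d[1] + 1
  expect_equal(singular_value_threshold(M, big), matrix(0, 5, 6))
  expect_equal(singular_value_threshold(diag(c(3, 1)), 2), diag(c(1, 0)),
               tolerance = 1e-12)
  # singular values of the result are max(b_i - tau, 0)
  tau <- 0.8
  got <- svd(singular_value_threshold(M, tau), nu = 0, nv = 0)$d
  want <- pmax(svd(M, nu = 0, nv = 0)$d - tau, 0)
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(singular_value_threshold(M, -1), "invalid parameter")
})

test_that("proximal operators are non-expansive", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(48), 6, 8)
    Y <- matrix(rnorm(48), 6, 8)
    tau <- runif(1, 0, 2)
    expect_lte(norm(soft_threshold(X, tau) - soft_threshold(Y, tau), "F"),
               norm(X - Y, "F") + 1e-12)
    expect_lte(norm(singular_value_threshold(X, tau) -
                    singular_value_threshold(Y, tau), "F"),
               norm(X - Y, "F") + 1e-12)
  }
})

test_that("truncated PCA gives the best rank-r approximation", {
  set.seed(3)
  S <- matrix(rnorm(35), 5, 7)
  expect_equal(truncated_pca_denoise(S, 5), S, tolerance = 1e-12)
  S1 <- outer(rnorm(6), rnorm(9))
  expect_equal(truncated_pca_denoise(S1, 1), S1, tolerance = 1e-12)
  expect_equal(truncated_pca_denoise(diag(c(3, 1)), 1), diag(c(3, 0)),
               tolerance = 1e-12)
  # Eckart-Young against the full-SVD oracle
  for (i in 1:50) {
    A <- sample(2:20, 1); B <- sample(2:30, 1)
    S <- matrix(rnorm(A * B), A, B)
    r <- sample(seq_len(min(A, B)), 1)
    expect_lt(norm(truncated_pca_denoise(S, r) - svd_truncate_oracle(S, r), "F") /
                norm(S, "F"), 1e-10)
  }
  expect_error(truncated_pca_denoise(S, 0), "invalid parameter")
  expect_error(truncated_pca_denoise(diag(3), 4), "invalid parameter")
})

test_that("rpca_decompose recovers known low-rank + sparse splits", {
  # zero input
  z <- rpca_decompose(matrix(0, 4, 4))
  expect_true(z$converged)
  expect_equal(z$low_rank, matrix(0, 4, 4))
  expect_equal(z$sparse, matrix(0, 4, 4))
  expect_equal(z$objective, 0)

  # clean rank-1, no corruption: low-rank part absorbs everything
  set.seed(5)
  S1 <- outer(rnorm(100), rnorm(100))
  d1 <- rpca_decompose(S1)
  expect_true(d1$converged)
  expect_lt(rel_fro(d1$low_rank, S1), 1e-5)
  expect_lt(norm(d1$sparse, "F") / norm(S1, "F"), 1e-5)

  # rank-5 plus 5% impulse corruption: exact-recovery regime
  inst <- make_rpca_instance(17)
  d <- rpca_decompose(inst$S)
  expect_true(d$converged)
  expect_lt(rel_fro(d$low_rank, inst$L0), 1e-4)
  expect_gte(jaccard(abs(d$sparse) > 1e-6, inst$support), 0.99)
})

test_that("decomposition diagnostics are self-consistent", {
  inst <- make_rpca_instance(23, n = 60L, r = 3L)
  cfg <- rpca_config(tol = 1e-7)
  d <- rpca_decompose(inst$S, cfg)
  # additivity at convergence
  expect_lte(norm(inst$S - d$low_rank - d$sparse, "F") / norm(inst$S, "F"),
             cfg$tol)
  expect_lte(d$relative_residual, cfg$tol)
  # objective recomputed independently
  obj <- d$alpha * sum(abs(d$sparse)) + sum(svd(d$low_rank, nu = 0, nv = 0)$d)
  expect_equal(d$objective, obj, tolerance = 1e-10)
  # objective no worse than the trivial feasible points (S,0) and (0,S)
  triv <- min(sum(svd(inst$S, nu = 0, nv = 0)$d), d$alpha * sum(abs(inst$S)))
  expect_lte(d$objective, triv + cfg$tol * norm(inst$S, "F"))
})

test_that("decomposition is scale covariant", {
  inst <- make_rpca_instance(31, n = 50L, r = 3L)
  d1 <- rpca_decompose(inst$S)
  d2 <- rpca_decompose(3.7 * inst$S)
  expect_lt(norm(d2$low_rank - 3.7 * d1$low_rank, "F") / norm(3.7 * d1$low_rank, "F"),
            1e-5)
  expect_lt(norm(d2$sparse - 3.7 * d1$sparse, "F") / norm(inst$S, "F"), 1e-5)
})

test_that("non-convergence warns and reports converged = FALSE", {
  inst <- make_rpca_instance(7, n = 40L, r = 3L)
  expect_warning(
    d <- rpca_decompose(inst$S, rpca_config(tol = 1e-12, max_iter = 2L)),
    "did not converge")
  expect_false(d$converged)
  expect_equal(d$iterations, 2L)
  expect_gt(d$relative_residual, 1e-12)
})

test_that("denoise_image dispatches consistently", {
  inst <- make_rpca_instance(41, n = 60L, r = 4L)
  expect_equal(denoise_image(inst$S, "rpca"),
               rpca_decompose(inst$S)$low_rank)
  expect_equal(denoise_image(inst$S, "pca", rpca_config(rank_r = 60L)), inst$S,
               tolerance = 1e-10)
  expect_error(denoise_image(inst$S, "pca"), "rank_r")
  # both paths recover the same clean low-rank image
  clean <- inst$L0
  r_rpca <- denoise_image(clean, "rpca")
  r_pca <- denoise_image(clean, "pca", rpca_config(rank_r = 4L))
  expect_lt(rel_fro(r_rpca, r_pca), 1e-4)
})
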