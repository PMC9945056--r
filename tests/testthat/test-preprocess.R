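test_that("normalize_log follows the library-size formula and preserves zeros", {
  counts <- Matrix::Matrix(matrix(c(1, 0, 2, 0, 3, 5), 3, 2), sparse = TRUE)
  rownames(counts) <- paste0("g", 1:3); colnames(counts) <- c("s1", "s2")
  out <- normalize_log(counts, scale = 1)
  expect_equal(out[1, 1], log(1 + 1 / 3))          # counts 1, libsize 3
  expect_equal(out[2, 1], 0)                        # zeros stay zero
  expect_s4_class(out, "sparseMatrix")

  # per-spot scale invariance: doubling one spot's counts changes nothing
  doubled <- counts
  doubled[, 1] <- doubled[, 1] * 2
  expect_equal(as.matrix(normalize_log(doubled, 1e4)[, 1]),
               as.matrix(normalize_log(counts, 1e4)[, 1]))

  empty <- counts; empty[, 2] <- 0
  expect_error(normalize_log(empty), "s2")
})

test_that("select_hvgs ranks by variance with deterministic ties", {
  # hand-computed column variances: 2.0, 0.5, 1.0
  m <- rbind(g1 = c(0, 2, 0, 2), g2 = c(1, 2, 1, 2), g3 = c(0, 2, 1, 1))
  expect_equal(apply(m, 1, var), c(g1 = 4 / 3, g2 = 1 / 3, g3 = 2 / 3))
  expect_equal(select_hvgs(m, 2), c(1L, 3L))
  expect_equal(select_hvgs(m, 10), c(1L, 3L, 2L))   # no truncation, ordered

  const <- rbind(m, g4 = c(5, 5, 5, 5))
  expect_equal(select_hvgs(const, 4)[4], 4L)        # constant gene last

  # invariant to spot order
  expect_equal(select_hvgs(m[, c(3, 1, 4, 2)], 2), select_hvgs(m, 2))
  expect_error(select_hvgs(matrix(0, 0, 0), 1), "empty")
})

test_that("classical PCA matches a dense eigendecomposition oracle", {
  set.seed(11)
  X <- matrix(rnorm(20), 5, 4)
  p <- classical_pca(X, 3)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(cov(Xc), symmetric = TRUE)$values
  expect_equal(p$explained_variance, ev[1:3], tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # orthonormal loadings, scores with diagonal covariance
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-8)
  sc <- crossprod(p$scores) / (nrow(X) - 1)
  expect_lt(max(abs(sc[upper.tri(sc)])), 1e-8)
  # exact rank-2 input reconstructs exactly with q = 2
  X2 <- matrix(rnorm(30), 10, 3) %*% matrix(rnorm(6), 3, 2) %*%
    matrix(rnorm(8), 2, 4)
  p2 <- classical_pca(X2, 2)
  X2c <- sweep(X2, 2, colMeans(X2))
  expect_lt(norm(X2c - p2$scores %*% t(p2$loadings), "F"), 1e-10)
  expect_error(classical_pca(X, 5), "exceeds")
})

test_that("approximate PCA is seeded, reproducible, and accurate", {
  set.seed(3)
  # exactly rank-3: approximate equals classical up to the fixed signs
  X <- matrix(rnorm(60), 20, 3) %*% matrix(rnorm(24), 3, 8)
  pa <- approximate_pca(X, 3, seed = 7)
  pc <- classical_pca(X, 3)
  expect_equal(abs(pa$scores), abs(pc$scores), tolerance = 1e-8)
  expect_identical(pa, approximate_pca(X, 3, seed = 7))   # bit-identical
  # well-separated spectrum: principal angles between subspaces ~ 0
  D <- diag(c(20, 10, 5, 0.1, 0.05))
  set.seed(4)
  U <- qr.Q(qr(matrix(rnorm(200 * 5), 200, 5)))
  V <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  Xs <- U %*% D %*% t(V)
  pa2 <- approximate_pca(Xs, 3, seed = 1)
  pc2 <- classical_pca(Xs, 3)
  sv <- svd(crossprod(pa2$loadings, pc2$loadings))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("weighted PCA honours weights and reduces to classical", {
  set.seed(5)
  X <- matrix(rnorm(200), 25, 8)
  pw <- weighted_pca(X, 3, weights = rep(2, 8))
  pc <- classical_pca(X, 3)
  # equal weights: same subspace, scores scaled by sqrt(2)
  expect_equal(abs(pw$scores), sqrt(2) * abs(pc$scores), tolerance = 1e-8)
  # a ~zero-weight gene drops out of the loadings
  w <- rep(1, 8); w[4] <- 1e-12
  expect_lt(max(abs(weighted_pca(X, 3, w)$loadings[4, ])), 1e-6)
  # homoskedastic data: rank-2 signal with equal per-gene amplitude plus
  # iid unit noise, so every gene has the same residual variance and the
  # auto weights agree within sampling error (~10%)
  set.seed(6)
  G <- 6; n <- 5000
  theta <- 2 * pi * (1:G) / G
  Xh <- matrix(rnorm(n * 2), n, 2) %*% (rbind(cos(theta), sin(theta)) * 5) +
    matrix(rnorm(n * G), n, G)
  wa <- weighted_pca(Xh, 2, "auto")$weights
  expect_lt(max(wa) / min(wa), 1.1)
  expect_error(weighted_pca(X, 3, rep(-1, 8)), "positive")
})

test_that("the three PCA methods agree on exact rank-q input", {
  set.seed(8)
  X <- matrix(rnorm(45), 15, 3) %*% matrix(rnorm(18), 3, 6)
  sc <- list(classical_pca(X, 3)$scores,
             approximate_pca(X, 3, seed = 2)$scores,
             weighted_pca(X, 3, rep(1, 6))$scores)
  expect_equal(abs(sc[[1]]), abs(sc[[2]]), tolerance = 1e-6)
  expect_equal(abs(sc[[1]]), abs(sc[[3]]), tolerance = 1e-6)
})

test_that("preprocess_dataset produces shared embeddings from counts", {
  sim <- simulate_multisample(sim_config(lattice = c(8, 8), seed = 21,
                                         n_genes = 60))
  ds <- sim$dataset
  for (t in seq_along(ds$slides)) ds$slides[[t]]$embeddings <- NULL
  ds$q <- NULL
  out <- preprocess_dataset(ds, q = 4, n_hvg = 50, method = "classical",
                            min_libsize = 1, min_spot_frac = 0)
  expect_equal(out$q, 4)
  expect_length(validate_dataset(out), 0L)
  expect_equal(nrow(out$slides[[1]]$embeddings), nrow(out$slides[[1]]$spots))
})
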