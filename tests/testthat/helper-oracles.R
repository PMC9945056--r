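# Shared fixtures and independent oracles used across test files.

# one-hot responsibility matrix from hard labels
onehot <- function(y, K) {
  R <- matrix(0, length(y), K)
  R[cbind(seq_along(y), y)] <- 1
  R
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# best-permutation RMSE between estimated and true cluster means
matched_mu_rmse <- function(mu_hat, mu_true) {
  K <- nrow(mu_true)
  best <- Inf
  for (p in all_perms(K)) {
    r <- sqrt(mean((mu_hat[unlist(p), , drop = FALSE] - mu_true)^2))
    best <- min(best, r)
  }
  best
}

# a tiny single-slide dataset around given embeddings, neighbour-free spots
toy_dataset <- function(X, radius = 0.8, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  spots <- data.frame(spot_id = sprintf("sp%03d", seq_len(n)),
                      x = stats::runif(n) * 10, y = stats::runif(n) * 10)
  ds <- multi_sample_dataset(list(slide_data("s1", spots, embeddings = X)))
  add_neighbors(ds, "radius", radius = radius)
}

# dense multivariate normal density (independent of the package's helper)
dmv_oracle <- function(X, m, S) {
  q <- ncol(X)
  Sinv <- solve(S)
  dets <- det(S)
  apply(X, 1L, function(x) {
    d <- x - m
    exp(-0.5 * sum(d * (Sinv %*% d))) / sqrt((2 * pi)^q * dets)
  })
}

# equal-mixing-weight Gaussian mixture EM, plain R, mirroring nothing of the
# package internals; runs to near machine convergence from the given init
em_gmm_oracle <- function(X, mu, sigma, ridge = 1e-6, tol = 1e-14,
                          max_iter = 1000L) {
  K <- nrow(mu)
  llp <- NA_real_
  R <- NULL
  for (it in seq_len(max_iter)) {
    dens <- sapply(seq_len(K), function(k) dmv_oracle(X, mu[k, ], sigma[, , k]))
    R <- dens / rowSums(dens)
    ll <- sum(log(rowSums(dens / K)))
    for (k in seq_len(K)) {
      w <- sum(R[, k])
      mu[k, ] <- colSums(R[, k] * X) / w
      xc <- sweep(X, 2L, mu[k, ]) * sqrt(R[, k])
      sigma[, , k] <- crossprod(xc) / w + diag(ridge, ncol(X))
    }
    if (!is.na(llp) && abs(ll - llp) / abs(llp) < tol) break
    llp <- ll
  }
  list(mu = mu, sigma = sigma, resp = R, loglik = ll)
}

# fraction of edges whose endpoints share a label
edge_concordance <- function(labels, graph) {
  mean(labels[graph$edges[, 1L]] == labels[graph$edges[, 2L]])
}

per_slide_labels <- function(fit) {
  split(fit$state$labels, rep(seq_along(fit$n_per_slide), fit$n_per_slide))
}
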