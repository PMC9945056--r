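#' Library-size normalization with log transform
#'
#' Scales each spot (column) to a common library size and applies
#' `log(1 + x)`. Entry (g, i) becomes
#' `log(1 + scale * counts[g, i] / libsize(i))` with `libsize(i)` the column
#' sum. Zeros are preserved exactly, so sparse inputs stay sparse.
#'
#' @param counts Non-negative gene x spot matrix (dense or `Matrix` sparse).
#' @param scale Positive target library size (default `1e4`).
#' @return Normalized matrix of the same shape and sparsity class.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  stopifnot(scale > 0)
  libsize <- Matrix::colSums(counts)
  if (any(libsize <= 0)) {
    bad <- which(libsize <= 0)
    nm <- colnames(counts)
    lab <- if (!is.null(nm)) nm[bad[1L]] else as.character(bad[1L])
    stop("spot '", lab, "' has zero library size; filter empty spots first")
  }
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale / libsize)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2L, scale / libsize, `*`))
  }
}

#' Select highly variable genes
#'
#' Ranks genes by across-spot variance of the normalized values and returns
#' the indices of the top `n_hvg`, ties broken by lower gene index.
#' Deterministic and invariant to spot order.
#'
#' @param normmat Normalized gene x spot matrix.
#' @param n_hvg Number of genes to keep (clamped to the number of genes).
#' @return Integer vector of gene indices, variance-descending.
#' @export
select_hvgs <- function(normmat, n_hvg = 2000) {
  stopifnot(n_hvg >= 1)
  if (length(normmat) == 0L || nrow(normmat) == 0L || ncol(normmat) == 0L)
    stop("empty matrix")
  n <- ncol(normmat)
  mu <- Matrix::rowMeans(normmat)
  v <- (Matrix::rowMeans(normmat^2) - mu^2) * n / max(n - 1, 1)
  ord <- order(-v, seq_along(v))
  ord[seq_len(min(n_hvg, length(v)))]
}

# Fix component signs: largest-|loading| entry of each column made positive.
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

pca_result <- function(scores, loadings, explained_variance, method,
                       seed = NULL) {
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = explained_variance,
                 method = method, seed = seed),
            class = "pca_result")
}

#' Classical principal component analysis
#'
#' Exact top-q singular subspace of the column-centered matrix, computed by
#' dense SVD. The sign of each component is fixed so that the
#' largest-magnitude loading entry is positive, making results fully
#' deterministic.
#'
#' @param X Numeric spots x genes matrix (centered internally, globally
#'   across all rows).
#' @param q Number of components, at most `min(dim(X))`.
#' @return A `pca_result` with `scores` (spots x q), orthonormal `loadings`
#'   (genes x q) and non-increasing `explained_variance`.
#' @export
classical_pca <- function(X, q) {
  X <- as.matrix(X)
  if (q > min(dim(X))) stop("q = ", q, " exceeds min(dim(X)) = ", min(dim(X)))
  Xc <- sweep(X, 2L, colMeans(X), `-`)
  sv <- svd(Xc, nu = q, nv = q)
  scores <- sv$u %*% diag(sv$d[seq_len(q)], q, q)
  fs <- fix_signs(sv$v, scores)
  pca_result(fs$scores, fs$loadings, sv$d[seq_len(q)]^2 / (nrow(X) - 1),
             "classical")
}

#' Approximate (randomized) principal component analysis
#'
#' Randomized range-finder SVD (Gaussian sketch, oversampling, power
#' iterations with QR re-orthonormalization). Much faster than the dense
#' SVD for wide matrices and reproducible for a fixed seed; intended for
#' initial-value computation.
#'
#' @inheritParams classical_pca
#' @param seed Integer RNG seed.
#' @param n_oversample Extra sketch columns beyond `q` (default 10).
#' @param n_power_iter Power iterations sharpening the spectrum (default 2).
#' @return A `pca_result`; identical call with identical seed is
#'   bit-reproducible.
#' @export
approximate_pca <- function(X, q, seed = 1L, n_oversample = 10L,
                            n_power_iter = 2L) {
  X <- as.matrix(X)
  if (q > min(dim(X))) stop("q = ", q, " exceeds min(dim(X)) = ", min(dim(X)))
  Xc <- sweep(X, 2L, colMeans(X), `-`)
  l <- min(q + n_oversample, ncol(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  omega <- matrix(stats::rnorm(ncol(Xc) * l), ncol(Xc), l)
  Y <- Xc %*% omega
  Q <- qr.Q(qr(Y))
  for (it in seq_len(n_power_iter)) {
    Z <- qr.Q(qr(crossprod(Xc, Q)))
    Q <- qr.Q(qr(Xc %*% Z))
  }
  B <- crossprod(Q, Xc)                # l x genes
  sv <- svd(B, nu = q, nv = q)
  scores <- Q %*% sv$u %*% diag(sv$d[seq_len(q)], q, q)
  fs <- fix_signs(sv$v, scores)
  pca_result(fs$scores, fs$loadings, sv$d[seq_len(q)]^2 / (nrow(X) - 1),
             "approximate", seed = seed)
}

#' Weighted principal component analysis
#'
#' PCA of the column-centered matrix with gene g scaled by `sqrt(w_g)`,
#' down-weighting noisy genes. With `weights = "auto"` the weight of gene g
#' is the inverse residual variance after a first-pass rank-q classical PCA
#' fit, floored at `1e-8`.
#'
#' @inheritParams classical_pca
#' @param weights Positive per-gene weights, or `"auto"`.
#' @return A `pca_result`; loadings are orthonormal in the weighted space.
#' @export
weighted_pca <- function(X, q, weights = "auto") {
  X <- as.matrix(X)
  if (q > min(dim(X))) stop("q = ", q, " exceeds min(dim(X)) = ", min(dim(X)))
  Xc <- sweep(X, 2L, colMeans(X), `-`)
  if (identical(weights, "auto")) {
    p0 <- classical_pca(X, q)
    res <- Xc - p0$scores %*% t(p0$loadings)
    rv <- pmax(colSums(res^2) / max(nrow(X) - 1, 1), 1e-8)
    weights <- 1 / rv
  }
  weights <- as.numeric(weights)
  if (length(weights) != ncol(X)) stop("need one weight per gene")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  Xw <- sweep(Xc, 2L, sqrt(weights), `*`)
  sv <- svd(Xw, nu = q, nv = q)
  scores <- sv$u %*% diag(sv$d[seq_len(q)], q, q)
  fs <- fix_signs(sv$v, scores)
  out <- pca_result(fs$scores, fs$loadings, sv$d[seq_len(q)]^2 / (nrow(X) - 1),
                    "weighted")
  out$weights <- weights
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Preprocess a multi-slide dataset into shared embeddings
#'
#' The standard pipeline from raw counts to the low-dimensional spot
#' embeddings the spatial model consumes: filter low-quality spots (library
#' size below `min_libsize`) and rarely expressed genes (below
#' `min_spot_frac` of spots), library-size log-normalize, select highly
#' variable genes on the spot-concatenated matrix, then run PCA on the
#' combined (all slides pooled) normalized matrix so every slide shares one
#' embedding basis. Batch differences are deliberately left in the
#' embeddings; the spatial model absorbs them in its batch component.
#'
#' @param ds A [multi_sample_dataset] whose slides carry counts.
#' @param q Embedding dimension (default 15).
#' @param n_hvg Number of highly variable genes (default 2000).
#' @param method One of `"approximate"`, `"classical"`, `"weighted"`.
#' @param scale Library-size normalization target (default `1e4`).
#' @param min_libsize Drop spots with total counts below this (default 15).
#' @param min_spot_frac Drop genes expressed in fewer than this fraction of
#'   spots (default 0.01).
#' @param seed Seed for the approximate method.
#' @return The dataset with `embeddings` filled in on every slide (filtered
#'   spots removed) and a `pca` attribute holding the [classical_pca]-style
#'   result.
#' @export
preprocess_dataset <- function(ds, q = 15, n_hvg = 2000,
                               method = c("approximate", "classical", "weighted"),
                               scale = 1e4, min_libsize = 15,
                               min_spot_frac = 0.01, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "msd"))
  if (any(vapply(ds$slides, function(s) is.null(s$counts), logical(1))))
    stop("all slides need counts for preprocessing")
  # spot filter per slide
  for (t in seq_along(ds$slides)) {
    sl <- ds$slides[[t]]
    keep <- Matrix::colSums(sl$counts) >= min_libsize
    sl$counts <- sl$counts[, keep, drop = FALSE]
    sl$spots <- sl$spots[keep, , drop = FALSE]
    ds$slides[[t]] <- sl
  }
  pooled <- do.call(cbind, lapply(ds$slides, `[[`, "counts"))
  expr_frac <- Matrix::rowMeans(pooled > 0)
  gkeep <- which(expr_frac >= min_spot_frac)
  if (length(gkeep) < q) stop("fewer than q genes survive filtering")
  pooled <- pooled[gkeep, , drop = FALSE]
  norm <- normalize_log(pooled, scale = scale)
  hvg <- select_hvgs(norm, n_hvg)
  Xt <- t(as.matrix(norm[hvg, , drop = FALSE]))     # spots x genes
  pca <- switch(method,
    classical = classical_pca(Xt, q),
    approximate = approximate_pca(Xt, q, seed = seed),
    weighted = weighted_pca(Xt, q))
  ns <- n_spots_per_slide(ds)
  off <- c(0L, cumsum(ns))
  for (t in seq_along(ds$slides)) {
    ds$slides[[t]]$embeddings <- pca$scores[(off[t] + 1L):off[t + 1L], ,
                                            drop = FALSE]
    rownames(ds$slides[[t]]$embeddings) <- ds$slides[[t]]$spots$spot_id
  }
  ds$q <- q
  attr(ds, "pca") <- pca
  ds
}
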