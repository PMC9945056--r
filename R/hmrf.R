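#' Fitting controls for the spatial mixture model
#'
#' @param beta_grid Increasing non-negative grid searched for each slide's
#'   Potts smoothness (default `seq(0, 4, by = 0.2)`).
#' @param max_iter Maximum ICM-EM iterations (default 25).
#' @param icm_sweeps Maximum label sweeps per ICM step (default 10; sweeps
#'   stop early at a fixed point).
#' @param u_sweeps Maximum batch-embedding sweeps per ICM step (default 50;
#'   sweeps stop early once the largest per-entry change falls below
#'   `u_tol`). Iterating the Gauss-Seidel sweep to its fixed point before
#'   the CAR variances are re-estimated matters: a single sweep leaves u
#'   artificially smooth, which would collapse the roughness-based lambda
#'   estimate and freeze u before it can absorb slide-level shifts.
#' @param u_tol Early-stop threshold for the u sweeps (default 1e-3).
#' @param tol Relative change of the pseudo-log-likelihood declaring
#'   convergence (default 1e-6).
#' @param seed Top-level seed; the fit for cluster count K uses `seed + K`
#'   so parallel and serial multi-K runs agree exactly.
#' @param mbic_c Penalty constant of the modified BIC (default 1).
#' @param ridge Ridge added to covariance diagonals and floor for variance
#'   parameters (default 1e-6).
#' @param n_threads Worker processes for multi-K fitting (default 1).
#' @param fix_u If `TRUE`, clamp the batch embeddings at zero (the model
#'   then reduces to a spatially smoothed Gaussian mixture; with
#'   `beta_grid = 0` it is exactly an equal-weight Gaussian mixture EM).
#' @param verbose If `TRUE`, log one line per ICM-EM iteration (objective,
#'   change, per-slide beta).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(beta_grid = seq(0, 4, by = 0.2), max_iter = 25L,
                       icm_sweeps = 10L, u_sweeps = 50L, u_tol = 1e-3,
                       tol = 1e-6, seed = 1L,
                       mbic_c = 1, ridge = 1e-6, n_threads = 1L,
                       fix_u = FALSE, verbose = FALSE) {
  stopifnot(length(beta_grid) >= 1L, all(beta_grid >= 0),
            !is.unsorted(beta_grid), tol > 0, max_iter >= 1L,
            icm_sweeps >= 1L, u_sweeps >= 1L, u_tol > 0, mbic_c >= 0,
            ridge > 0)
  structure(list(beta_grid = as.numeric(beta_grid),
                 max_iter = as.integer(max_iter),
                 icm_sweeps = as.integer(icm_sweeps),
                 u_sweeps = as.integer(u_sweeps), u_tol = u_tol, tol = tol,
                 seed = as.integer(seed), mbic_c = mbic_c, ridge = ridge,
                 n_threads = as.integer(n_threads), fix_u = isTRUE(fix_u),
                 verbose = isTRUE(verbose)),
            class = "fit_config")
}

# ---- small numerics -------------------------------------------------------

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# n x K matrix of log N(r_i; mu_k, Sigma_k)
gauss_logdens <- function(r, mu, sigma) {
  n <- nrow(r); K <- nrow(mu); q <- ncol(r)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ch <- chol(sigma[, , k])
    z <- backsolve(ch, t(r) - mu[k, ], transpose = TRUE)
    out[, k] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) -
      0.5 * q * log(2 * pi)
  }
  out
}

slide_spans <- function(graphs) {
  ns <- vapply(graphs, `[[`, integer(1), "n_spots")
  off <- c(0L, cumsum(ns))
  lapply(seq_along(ns), function(t) (off[t] + 1L):(off[t + 1L]))
}

nbr_list <- function(graph) {
  nb <- lapply(seq_len(graph$n_spots), function(i) integer(0))
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  lapply(nb, as.integer)
}

ds_graphs <- function(ds) {
  lapply(ds$slides, function(s) {
    if (is.null(s$graph)) stop("slide '", s$slide_id,
                               "' has no neighbour graph; run add_neighbors()")
    s$graph
  })
}

# cached per-fit geometry: pooled v, graphs, neighbour lists, slide spans
fit_geometry <- function(ds) {
  graphs <- ds_graphs(ds)
  list(v = pooled_embeddings(ds), graphs = graphs,
       nbrs = lapply(graphs, nbr_list), spans = slide_spans(graphs),
       T = length(graphs))
}

# ---- sufficient statistics ------------------------------------------------

#' Per-spot neighbour label counts
#'
#' The Potts sufficient statistic: `m[i, k]` is the number of neighbours of
#' spot i currently labelled k. Rows of isolated spots are zero and row sums
#' equal the spot degree.
#'
#' @param labels Integer labels in `1..K` for one slide.
#' @param graph The slide's [neighbor_graph].
#' @param K Number of clusters.
#' @return Integer n x K matrix.
#' @export
neighbor_label_counts <- function(labels, graph, K) {
  stopifnot(length(labels) == graph$n_spots, all(labels >= 1L), all(labels <= K))
  onehot <- Matrix::sparseMatrix(i = seq_along(labels), j = labels, x = 1,
                                 dims = c(length(labels), K))
  m <- as.matrix(graph$adj %*% onehot)
  storage.mode(m) <- "integer"
  m
}

pooled_label_counts <- function(labels, geom, K) {
  m <- matrix(0L, length(labels), K)
  for (t in seq_len(geom$T)) {
    sp <- geom$spans[[t]]
    m[sp, ] <- neighbor_label_counts(labels[sp], geom$graphs[[t]], K)
  }
  m
}

# ---- ICM updates ----------------------------------------------------------

#' ICM label update
#'
#' Sequential sweeps setting each spot's label to the posterior mode
#' `argmax_k { log N(v - u; mu_k, Sigma_k) + beta_t * m[i, k] }` with the
#' neighbour counts m recomputed within the sweep; ties go to the smaller
#' cluster index. Sweeps stop early at a fixed point.
#'
#' @param ds Dataset with embeddings and graphs.
#' @param state Latent state (list with `labels`, `u`).
#' @param params Model parameters (list with `mu`, `sigma`, `beta`).
#' @param sweeps Maximum sweeps (default 1).
#' @return Pooled integer label vector.
#' @export
icm_update_labels <- function(ds, state, params, sweeps = 1L) {
  geom <- fit_geometry(ds)
  icm_update_labels_geom(geom, state, params, sweeps)
}

icm_update_labels_geom <- function(geom, state, params, sweeps) {
  labels <- state$labels
  r <- geom$v - state$u
  for (t in seq_len(geom$T)) {
    sp <- geom$spans[[t]]
    ld <- gauss_logdens(r[sp, , drop = FALSE], params$mu, params$sigma)
    labels[sp] <- icm_labels_cpp(ld, params$beta[t], geom$nbrs[[t]],
                                 as.integer(labels[sp]), as.integer(sweeps))
  }
  labels
}

#' ICM batch-embedding update
#'
#' One sweep of posterior-mode updates for the batch embeddings u given the
#' current labels: with degree d and neighbour mean ubar,
#' `u_i <- (Sigma_k^-1 + d Lambda_t^-1)^-1 (Sigma_k^-1 (v_i - mu_k) + d Lambda_t^-1 ubar)`;
#' isolated spots shrink towards zero under the marginal prior
#' `N(0, Lambda_t)`. After the sweep u is grand-mean-centered over all spots
#' of all slides, which pins down the translation otherwise shared between
#' the cluster means and u (per-slide u means are the batch shifts and are
#' deliberately retained).
#'
#' @inheritParams icm_update_labels
#' @return Pooled n x q matrix of batch embeddings, grand-mean zero.
#' @export
icm_update_batch <- function(ds, state, params) {
  geom <- fit_geometry(ds)
  icm_update_batch_geom(geom, state, params)
}

icm_update_batch_geom <- function(geom, state, params) {
  K <- nrow(params$mu); q <- ncol(params$mu)
  siginv <- array(0, c(q, q, K))
  for (k in seq_len(K)) siginv[, , k] <- chol2inv(chol(params$sigma[, , k]))
  u <- state$u
  for (t in seq_len(geom$T)) {
    sp <- geom$spans[[t]]
    u[sp, ] <- icm_u_cpp(geom$v[sp, , drop = FALSE], params$mu, siginv,
                         1 / params$lambda[t, ],
                         as.integer(state$labels[sp]), geom$nbrs[[t]],
                         u[sp, , drop = FALSE])
  }
  sweep(u, 2L, colMeans(u), `-`)
}

# Diagonal Laplace-approximation posterior variances of u: per spot,
# diag((Sigma_k^-1 + d_i Lambda_t^-1)^-1). Depends on the spot only through
# (slide, label, degree), so distinct combinations are cached.
u_var_diag <- function(geom, state, params) {
  K <- nrow(params$mu); q <- ncol(params$mu)
  siginv <- array(0, c(q, q, K))
  for (k in seq_len(K)) siginv[, , k] <- chol2inv(chol(params$sigma[, , k]))
  out <- matrix(0, nrow(geom$v), q)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(geom$T)) {
    sp <- geom$spans[[t]]
    laminv <- 1 / params$lambda[t, ]
    deg <- geom$graphs[[t]]$degree
    for (ii in seq_along(sp)) {
      k <- state$labels[sp[ii]]
      d <- max(deg[ii], 1L)            # isolated spots: marginal prior
      key <- paste(t, k, d)
      v <- cache[[key]]
      if (is.null(v)) {
        v <- diag(chol2inv(chol(siginv[, , k] + d * diag(laminv, q))))
        cache[[key]] <- v
      }
      out[sp[ii], ] <- v
    }
  }
  out
}

# ---- E step ---------------------------------------------------------------

#' Soft cluster responsibilities
#'
#' Pseudo-likelihood E step: `R[i, k]` proportional to
#' `exp(beta_t * m[i, k]) * N(v_i - u_i; mu_k, Sigma_k)` with the neighbour
#' counts taken at the current hard labels, normalized over k with
#' log-sum-exp stabilization.
#'
#' @inheritParams icm_update_labels
#' @return Pooled n x K matrix; rows sum to 1.
#' @export
compute_responsibilities <- function(ds, state, params) {
  geom <- fit_geometry(ds)
  compute_responsibilities_geom(geom, state, params)
}

compute_responsibilities_geom <- function(geom, state, params) {
  K <- nrow(params$mu)
  m <- pooled_label_counts(state$labels, geom, K)
  r <- geom$v - state$u
  lr <- gauss_logdens(r, params$mu, params$sigma)
  for (t in seq_len(geom$T)) {
    sp <- geom$spans[[t]]
    lr[sp, ] <- lr[sp, ] + params$beta[t] * m[sp, ]
  }
  resp <- exp(lr - logsumexp_rows(lr))
  resp / rowSums(resp)
}

#' Pseudo-log-likelihood of the fitted model
#'
#' The objective tracked by the ICM-EM loop:
#' `sum_i log sum_k p[i, k] N(v_i - u_i; mu_k, Sigma_k)` where
#' `p[i, k] = softmax_k(beta_t * m[i, k])` is the pseudo-likelihood Potts
#' prior given the current hard neighbour labels. Additive across slides.
#' The intractable Potts partition function never appears; this surrogate
#' is what the modified BIC consumes.
#'
#' @inheritParams icm_update_labels
#' @return A scalar.
#' @export
pseudo_loglik <- function(ds, state, params) {
  geom <- fit_geometry(ds)
  pseudo_loglik_geom(geom, state, params)
}

pseudo_loglik_geom <- function(geom, state, params) {
  K <- nrow(params$mu)
  m <- pooled_label_counts(state$labels, geom, K)
  lr <- gauss_logdens(geom$v - state$u, params$mu, params$sigma)
  lp <- matrix(0, nrow(m), K)
  for (t in seq_len(geom$T)) {
    sp <- geom$spans[[t]]
    bm <- params$beta[t] * m[sp, , drop = FALSE]
    lp[sp, ] <- bm - logsumexp_rows(bm)
  }
  sum(logsumexp_rows(lp + lr))
}

# ---- M steps --------------------------------------------------------------

#' Gaussian M step
#'
#' Responsibility-weighted means and covariances of the batch-corrected
#' embeddings `r = v - u`; each covariance gets `ridge * I` added. Clusters
#' whose total responsibility falls below 1e-8 keep their previous
#' parameters (with a warning) instead of producing degenerate estimates.
#'
#' @param v Pooled n x q embeddings.
#' @param resp Pooled n x K responsibilities.
#' @param u Pooled n x q batch embeddings.
#' @param ridge Diagonal regularizer.
#' @param prev Optional previous parameters (list with `mu`, `sigma`) used
#'   for dead clusters.
#' @param uvar Optional pooled n x q matrix of per-spot posterior variances
#'   of the batch embeddings; when supplied, their responsibility-weighted
#'   mean is added to each covariance diagonal (the expected rather than
#'   plug-in second moment of `r = v - u`). The fitting loop passes this;
#'   without it the covariances can collapse towards the ridge floor when
#'   the batch field starts interpolating noise.
#' @return List with `mu` (K x q) and `sigma` (q x q x K).
#' @export
m_step_gaussian <- function(v, resp, u, ridge = 1e-6, prev = NULL,
                            uvar = NULL) {
  r <- v - u
  K <- ncol(resp); q <- ncol(r)
  w <- colSums(resp)
  mu <- matrix(0, K, q)
  sigma <- array(0, c(q, q, K))
  for (k in seq_len(K)) {
    if (w[k] < 1e-8) {
      if (is.null(prev)) stop("cluster ", k, " empty and no previous parameters")
      warning("cluster ", k, " has vanishing weight; keeping previous parameters")
      mu[k, ] <- prev$mu[k, ]
      sigma[, , k] <- prev$sigma[, , k]
      next
    }
    mu[k, ] <- colSums(resp[, k] * r) / w[k]
    rc <- sweep(r, 2L, mu[k, ], `-`) * sqrt(resp[, k])
    sigma[, , k] <- crossprod(rc) / w[k] + diag(ridge, q)
    if (!is.null(uvar))
      sigma[, , k] <- sigma[, , k] +
        diag(colSums(resp[, k] * uvar) / w[k], q)
  }
  list(mu = mu, sigma = sigma)
}

#' CAR variance M step
#'
#' Per slide and embedding dimension, the intrinsic-CAR variance estimate
#' `lambda_td = mean over non-isolated spots of d_i (u_i - ubar_i)^2` where
#' `ubar_i` is the neighbour mean; floored at `ridge`. Slides without edges
#' fall back to the per-slide variance of u.
#'
#' @param u Pooled n x q batch embeddings.
#' @param graphs List of per-slide [neighbor_graph]s (defines the slide
#'   partition of the rows of `u`).
#' @param ridge Floor for the variance.
#' @param uvar Optional pooled n x q matrix of per-spot posterior variances
#'   of u. When supplied, `d_i * uvar` is added to the squared deviations,
#'   the expected (rather than plug-in) sufficient statistic. The fitting
#'   loop passes the Laplace-approximation variances; without this term the
#'   roughness of the posterior mode systematically underestimates lambda
#'   and the batch field degenerates towards a constant.
#' @return T x q matrix of positive variances.
#' @export
m_step_car <- function(u, graphs, ridge = 1e-6, uvar = NULL) {
  spans <- slide_spans(graphs)
  q <- ncol(u)
  lambda <- matrix(ridge, length(graphs), q)
  for (t in seq_along(graphs)) {
    g <- graphs[[t]]
    ut <- u[spans[[t]], , drop = FALSE]
    act <- g$degree > 0L
    if (!any(act)) {
      lambda[t, ] <- pmax(apply(ut, 2L, function(x)
        if (length(x) > 1L) stats::var(x) else 0), ridge)
      next
    }
    ubar <- as.matrix(g$adj %*% ut) / pmax(g$degree, 1L)
    dev2 <- (ut - ubar)^2 * g$degree
    if (!is.null(uvar))
      dev2 <- dev2 + uvar[spans[[t]], , drop = FALSE] * g$degree
    lambda[t, ] <- pmax(colSums(dev2[act, , drop = FALSE]) / sum(act), ridge)
  }
  lambda
}

#' Grid search for the Potts smoothness
#'
#' For each slide picks the grid value maximizing the pseudo-likelihood
#' objective
#' `g_t(beta) = sum_i sum_k R[i,k] (beta m[i,k] - log sum_k' exp(beta m[i,k']))`;
#' ties (e.g. a slide of isolated spots, where g is constant) resolve to the
#' smallest grid value. There is no closed form for beta, hence the grid.
#'
#' @param resp Pooled n x K responsibilities.
#' @param labels Pooled hard labels (define the neighbour counts).
#' @param graphs Per-slide [neighbor_graph] list.
#' @param beta_grid Non-negative increasing grid.
#' @return Numeric vector, one beta per slide.
#' @export
grid_search_beta <- function(resp, labels, graphs, beta_grid) {
  stopifnot(length(beta_grid) >= 1L)
  K <- ncol(resp)
  spans <- slide_spans(graphs)
  beta <- numeric(length(graphs))
  for (t in seq_along(graphs)) {
    sp <- spans[[t]]
    m <- neighbor_label_counts(labels[sp], graphs[[t]], K)
    Rt <- resp[sp, , drop = FALSE]
    rm_sum <- sum(Rt * m)
    g <- vapply(beta_grid, function(b)
      b * rm_sum - sum(logsumexp_rows(b * m)), numeric(1))
    beta[t] <- beta_grid[which.max(g)]   # which.max: first max -> smallest beta
  }
  beta
}

# ---- initialization -------------------------------------------------------

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers with
# probability proportional to squared distance from the chosen set.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(X) - X[idx[1L], ])^2)
  for (k in seq_len(K - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    idx[k] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, colSums((t(X) - X[idx[k], ])^2))
  }
  X[idx, , drop = FALSE]
}

#' Initialize parameters and latents
#'
#' Pooled k-means (k-means++ seeding, 10 restarts, best within-cluster sum
#' of squares) provides initial hard labels; cluster means/covariances are
#' the per-cluster moments (plus ridge), u starts at zero,
#' responsibilities are the one-hot labels, each slide's beta is the
#' smallest positive grid value, and each slide's lambda is half the
#' per-slide residual variance of the embeddings around the assigned
#' cluster means (floored). Re-seeds up to 5 times if k-means returns an
#' empty cluster.
#'
#' @param ds Dataset with embeddings and graphs.
#' @param K Number of clusters.
#' @param seed Integer seed (fixed seed gives identical initialization).
#' @param cfg A [fit_config] (supplies `beta_grid` and `ridge`).
#' @return List with `params` and `state`.
#' @export
initialize_hmrf <- function(ds, K, seed = 1L, cfg = fit_config()) {
  v <- pooled_embeddings(ds)
  n <- nrow(v); q <- ncol(v)
  stopifnot(K >= 1L, n >= K)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  labels <- NULL
  for (attempt in 0:4) {
    set.seed(seed + 1000L * attempt)
    best <- NULL
    for (r in 1:10) {
      centers <- kmeanspp_centers(v, K)
      km <- tryCatch(
        stats::kmeans(v, centers = centers, iter.max = 100L),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (!is.null(best) && length(unique(best$cluster)) == K) {
      labels <- as.integer(best$cluster)
      break
    }
  }
  if (is.null(labels))
    stop("k-means produced an empty cluster in 5 attempts (K = ", K, ")")
  ridge <- cfg$ridge
  mu <- matrix(0, K, q)
  sigma <- array(0, c(q, q, K))
  for (k in seq_len(K)) {
    vk <- v[labels == k, , drop = FALSE]
    mu[k, ] <- colMeans(vk)
    sg <- if (nrow(vk) > 1L) stats::cov(vk) else diag(1, q)
    sigma[, , k] <- sg + diag(ridge, q)
  }
  graphs <- ds_graphs(ds)
  spans <- slide_spans(graphs)
  lambda <- matrix(0, length(graphs), q)
  for (t in seq_along(graphs)) {
    sp <- spans[[t]]
    resid <- v[sp, , drop = FALSE] - mu[labels[sp], , drop = FALSE]
    lambda[t, ] <- pmax(0.5 * apply(resid, 2L, stats::var), ridge)
  }
  pos <- cfg$beta_grid[cfg$beta_grid > 0]
  beta0 <- if (length(pos)) min(pos) else min(cfg$beta_grid)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), labels)] <- 1
  list(params = list(mu = mu, sigma = sigma, lambda = lambda,
                     beta = rep(beta0, length(graphs))),
       state = list(labels = labels, u = matrix(0, n, q), resp = resp))
}

# ---- model selection ------------------------------------------------------

#' Modified BIC
#'
#' `MBIC = -2 loglik + c * d_K * log(n) * log(log(n))` with
#' `d_K = K q + K q (q + 1) / 2 + T q + T` free parameters (cluster means,
#' covariances, diagonal CAR variances, per-slide smoothness). The extra
#' `log(log n)` factor strengthens the penalty relative to BIC, guarding
#' against over-selection of K at large n.
#'
#' @param loglik Fitted pseudo-log-likelihood.
#' @param K Clusters.
#' @param q Embedding dimension.
#' @param T Number of slides.
#' @param n_total Total spots (must be >= 3 so `log(log(n)) > 0`).
#' @param c Penalty constant (default 1).
#' @return The criterion value (smaller is better).
#' @export
mbic <- function(loglik, K, q, T, n_total, c = 1) {
  if (n_total < 3) stop("n_total must be >= 3")
  d_K <- K * q + K * q * (q + 1) / 2 + T * q + T
  -2 * loglik + c * d_K * log(n_total) * log(log(n_total))
}

# ---- main fitting loop ----------------------------------------------------

#' Fit the spatial mixture for one cluster count
#'
#' The ICM-EM loop: (ICM) label sweeps to the posterior mode, then one
#' batch-embedding sweep with grand-mean centering; (E) pseudo-likelihood
#' responsibilities; (M) Gaussian moments, CAR variances and grid-searched
#' Potts smoothness. Iterates until the relative change of the
#' pseudo-log-likelihood drops below `tol` or `max_iter` is hit.
#' Deterministic for a fixed config (the k-means initialization is seeded
#' with `cfg$seed + K`).
#'
#' @param ds Dataset with embeddings and graphs on every slide.
#' @param K Number of clusters.
#' @param cfg A [fit_config].
#' @return An object of class `hmrf_fit`: `params`, `state`,
#'   `objective_trace` (value at initialization then per iteration),
#'   `loglik`, `mbic`, `K`, `converged`, `n_iter`.
#' @export
fit_single_k <- function(ds, K, cfg = fit_config()) {
  geom <- fit_geometry(ds)
  init <- initialize_hmrf(ds, K, seed = cfg$seed + K, cfg = cfg)
  params <- init$params
  state <- init$state
  if (cfg$fix_u) params$lambda[] <- cfg$ridge
  ll <- pseudo_loglik_geom(geom, state, params)
  trace <- ll
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    n_iter <- iter
    params_prev <- params
    state_prev <- state
    state$labels <- icm_update_labels_geom(geom, state, params,
                                           cfg$icm_sweeps)
    if (!cfg$fix_u) {
      for (s in seq_len(cfg$u_sweeps)) {
        u_new <- icm_update_batch_geom(geom, state, params)
        delta <- max(abs(u_new - state$u))
        state$u <- u_new
        if (delta < cfg$u_tol) break
      }
    }
    state$resp <- compute_responsibilities_geom(geom, state, params)
    uvar <- if (cfg$fix_u) NULL else u_var_diag(geom, state, params)
    gm <- m_step_gaussian(geom$v, state$resp, state$u, ridge = cfg$ridge,
                          prev = params, uvar = uvar)
    params$mu <- gm$mu
    params$sigma <- gm$sigma
    if (!cfg$fix_u)
      params$lambda <- m_step_car(state$u, geom$graphs, ridge = cfg$ridge,
                                  uvar = uvar)
    params$beta <- grid_search_beta(state$resp, state$labels, geom$graphs,
                                    cfg$beta_grid)
    ll_new <- pseudo_loglik_geom(geom, state, params)
    # ICM-EM is not a strict ascent method: once the parameters are
    # stationary the interplay of the mode updates can nudge the objective
    # down by a whisker each iteration. A small decrease therefore signals
    # convergence: keep the previous (better) state and stop. Large drops
    # (genuine reorganization, e.g. a label avalanche early on) continue.
    if (ll_new < ll && (ll - ll_new) / (abs(ll) + 1e-10) < 1e-3) {
      params <- params_prev
      state <- state_prev
      n_iter <- iter - 1L
      converged <- TRUE
      break
    }
    trace <- c(trace, ll_new)
    if (cfg$verbose)
      message(sprintf("[%s] K=%d iter %d: loglik %.4f (delta %.2e), beta %s",
                      format(Sys.time(), "%H:%M:%S"), K, iter, ll_new,
                      ll_new - ll,
                      paste(sprintf("%.1f", params$beta), collapse = "/")))
    if (abs(ll_new - ll) / (abs(ll) + 1e-10) < cfg$tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  structure(list(params = params, state = state, objective_trace = trace,
                 loglik = ll,
                 mbic = mbic(ll, K, ncol(geom$v), geom$T, nrow(geom$v),
                             cfg$mbic_c),
                 K = as.integer(K), converged = converged,
                 n_iter = n_iter, config = cfg,
                 slide_ids = vapply(ds$slides, `[[`, character(1), "slide_id"),
                 n_per_slide = n_spots_per_slide(ds)),
            class = "hmrf_fit")
}

#' @export
print.hmrf_fit <- function(x, ...) {
  cat(sprintf(
    "Spatial mixture fit: K = %d, %d spots, %d slide(s)\n  pseudo-loglik %.3f, MBIC %.3f, %d iteration(s)%s\n  beta: %s\n",
    x$K, sum(x$n_per_slide), length(x$slide_ids), x$loglik, x$mbic, x$n_iter,
    if (x$converged) " (converged)" else "",
    paste(sprintf("%.2f", x$params$beta), collapse = ", ")))
  invisible(x)
}

#' Fit over a sequence of cluster counts and select K by MBIC
#'
#' Fits [fit_single_k] independently for each K (optionally in parallel via
#' forked workers; each fit derives its seed as `seed + K`, so serial and
#' parallel runs are identical) and selects the K minimizing the modified
#' BIC, ties resolving to the smaller K. Cluster counts exceeding the
#' pooled spot count are skipped with a warning.
#'
#' @param ds Dataset with embeddings and graphs.
#' @param K_list Integer vector of candidate cluster counts.
#' @param cfg A [fit_config]; `cfg$n_threads` controls parallelism.
#' @return An object of class `hmrf_fit_list`: `fits` (named by K),
#'   `mbic_table` (data frame with K, loglik, mbic, n_iter, converged),
#'   `selected_k` and `best` (the selected fit).
#' @export
fit_hmrf <- function(ds, K_list, cfg = fit_config()) {
  stopifnot(length(K_list) >= 1L)
  n_total <- sum(n_spots_per_slide(ds))
  keep <- K_list <= n_total
  if (!all(keep)) {
    warning("skipping K > total spot count: ",
            paste(K_list[!keep], collapse = ", "))
    K_list <- K_list[keep]
  }
  if (!length(K_list)) stop("no feasible K in K_list")
  runner <- function(K) fit_single_k(ds, K, cfg)
  fits <- if (cfg$n_threads > 1L) {
    parallel::mclapply(K_list, runner, mc.cores = cfg$n_threads,
                       mc.preschedule = FALSE)
  } else {
    lapply(K_list, runner)
  }
  bad <- !vapply(fits, inherits, logical(1), "hmrf_fit")
  if (any(bad))
    stop("fit failed for K = ", paste(K_list[bad], collapse = ", "))
  names(fits) <- as.character(K_list)
  tab <- data.frame(
    K = as.integer(K_list),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    mbic = vapply(fits, `[[`, numeric(1), "mbic"),
    n_iter = vapply(fits, `[[`, integer(1), "n_iter"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  sel <- tab$K[which.min(tab$mbic)]   # first min -> smaller K on ties
  structure(list(fits = fits, mbic_table = tab, selected_k = sel,
                 best = fits[[as.character(sel)]]),
            class = "hmrf_fit_list")
}

#' @export
print.hmrf_fit_list <- function(x, ...) {
  cat("Multi-K spatial mixture fits\n")
  print(x$mbic_table)
  cat("Selected K =", x$selected_k, "(minimum MBIC)\n")
  invisible(x)
}

#' Batch-corrected (aligned) embeddings
#'
#' Subtracts the fitted batch embeddings from the raw ones:
#' `z = v - u`, the component explained by the shared clusters. The slide
#' partition of the rows is preserved; `z + u` reconstructs `v` exactly.
#'
#' @param ds The dataset the model was fitted on.
#' @param fit An `hmrf_fit`.
#' @return List of per-slide n_t x q matrices.
#' @export
corrected_embeddings <- function(ds, fit) {
  v <- pooled_embeddings(ds)
  split_by_slide(ds, v - fit$state$u)
}
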