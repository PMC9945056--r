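#' Regular lattice coordinates
#'
#' Spot positions for a `rows x cols` lattice with unit spacing. The square
#' geometry places spots on the integer grid (4 nearest neighbours); the
#' hexagonal geometry offsets odd rows by half a spacing with row pitch
#' `sqrt(3)/2`, so each interior spot has 6 neighbours at distance 1.
#'
#' @param rows,cols Lattice extent.
#' @param geometry `"square"` or `"hex"`.
#' @param prefix Spot-id prefix.
#' @return Spot table (data frame with `spot_id`, `x`, `y`).
#' @export
lattice_coords <- function(rows, cols, geometry = c("square", "hex"),
                           prefix = "s") {
  geometry <- match.arg(geometry)
  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  if (geometry == "square") {
    x <- c_ - 1; y <- r - 1
  } else {
    x <- c_ - 1 + 0.5 * ((r - 1) %% 2)
    y <- (r - 1) * sqrt(3) / 2
  }
  data.frame(spot_id = sprintf("%s%05d", prefix, seq_along(x)),
             x = x, y = y, stringsAsFactors = FALSE)
}

#' Synthetic-data configuration
#'
#' Defines the generative study conditions for the multi-slide simulator:
#' Potts-distributed labels per slide, shared Gaussian cluster emissions,
#' and per-slide spatially correlated batch fields (proper CAR) with
#' slide-level mean shifts. Defaults describe two 30 x 30 square-lattice
#' slides with 4 clusters in 2 embedding dimensions, smoothness 1, cluster
#' separation 6 noise SDs, and a (+2, -2) batch shift on the second slide.
#'
#' @param T Number of slides.
#' @param lattice Data frame with columns `rows`, `cols`, `geometry`
#'   (one row per slide), or a single `c(rows, cols)` recycled.
#' @param K Clusters.
#' @param q Embedding dimension (>= 2).
#' @param beta_true Per-slide Potts smoothness (recycled).
#' @param mu_separation Minimum pairwise distance between cluster means.
#' @param sigma_scale Emission noise SD (emissions are
#'   `N(mu_k, sigma_scale^2 I)`).
#' @param lambda_true Per-slide CAR conditional variances (length q,
#'   recycled across slides).
#' @param rho CAR autocorrelation in `[0, 1)` (default 0.9, close to the
#'   intrinsic limit the fitting model assumes).
#' @param batch_shift T x q matrix of slide-level mean shifts; default zero
#'   on slide 1 and `(2, -2, 0, ...)` on later slides.
#' @param seed Integer seed; the whole draw is bit-reproducible.
#' @param n_genes Optional: also generate a Poisson count layer with this
#'   many genes.
#' @param noise_sd Log-rate noise SD of the count layer.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(T = 2L, lattice = c(30L, 30L), K = 4L, q = 2L,
                       beta_true = 1, mu_separation = 6, sigma_scale = 1,
                       lambda_true = 1, rho = 0.9, batch_shift = NULL,
                       seed = 1L, n_genes = NULL, noise_sd = 0.2) {
  stopifnot(T >= 1L, K >= 1L, q >= 2L, rho >= 0, rho < 1,
            mu_separation >= 0, sigma_scale > 0)
  if (!is.data.frame(lattice))
    lattice <- data.frame(rows = lattice[1L], cols = lattice[2L],
                          geometry = "square")
  lattice <- lattice[rep_len(seq_len(nrow(lattice)), T), , drop = FALSE]
  if (is.null(batch_shift)) {
    batch_shift <- matrix(0, T, q)
    if (T > 1L)
      for (t in 2:T) batch_shift[t, ] <- rep_len(c(2, -2), q)
  }
  batch_shift <- matrix(batch_shift, T, q)
  lam <- matrix(rep_len(as.numeric(lambda_true), q), T, q, byrow = TRUE)
  stopifnot(all(lam > 0))
  structure(list(T = as.integer(T), lattice = lattice, K = as.integer(K),
                 q = as.integer(q),
                 beta_true = rep_len(as.numeric(beta_true), T),
                 mu_separation = mu_separation, sigma_scale = sigma_scale,
                 lambda_true = lam, rho = rho, batch_shift = batch_shift,
                 seed = as.integer(seed), n_genes = n_genes,
                 noise_sd = noise_sd),
            class = "sim_config")
}

# K cluster means in R^q with minimum pairwise distance `sep`: a regular
# simplex when q >= K - 1, otherwise a regular K-gon in the first two dims.
cluster_means <- function(K, q, sep) {
  if (K == 1L) return(matrix(0, 1L, q))
  mu <- matrix(0, K, q)
  if (q >= K - 1L) {
    C <- diag(K) - 1 / K               # centered simplex, edge sqrt(2)
    sv <- svd(C)
    coords <- (sv$u %*% diag(sv$d))[, seq_len(K - 1L), drop = FALSE]
    mu[, seq_len(K - 1L)] <- coords * sep / sqrt(2)
  } else {
    ang <- 2 * pi * (seq_len(K) - 1) / K
    rad <- sep / (2 * sin(pi / K))
    mu[, 1L] <- rad * cos(ang)
    mu[, 2L] <- rad * sin(ang)
  }
  mu
}

# draws using the current RNG stream (callers seed)
potts_draw <- function(graph, K, beta, n_sweeps) {
  init <- sample.int(K, graph$n_spots, replace = TRUE)
  potts_gibbs_cpp(nbr_list(graph), as.integer(K), beta, as.integer(init),
                  as.integer(n_sweeps))
}

car_draw <- function(graph, lambda, rho) {
  n <- graph$n_spots; q <- length(lambda)
  Q0 <- diag(pmax(graph$degree, 0)) - rho * as.matrix(graph$adj)
  iso <- graph$degree == 0L
  if (any(iso)) diag(Q0)[iso] <- 1
  R <- chol(Q0)
  z <- matrix(stats::rnorm(n * q), n, q)
  x <- backsolve(R, z)                  # cov(x) = Q0^{-1}
  sweep(x, 2L, sqrt(lambda), `*`)
}

#' Sample a Potts label field
#'
#' Gibbs sampler on the neighbour graph: uniform random initialization,
#' then `n_sweeps` sequential full sweeps of the conditional
#' `P(y_i = k | neighbours) proportional to exp(beta * m_ik)`.
#' Reproducible for a fixed seed.
#'
#' @param graph A [neighbor_graph].
#' @param K Number of states.
#' @param beta Smoothness (>= 0).
#' @param seed Integer seed.
#' @param n_sweeps Full Gibbs sweeps (default 100).
#' @return Integer label vector in `1..K`.
#' @export
sample_potts <- function(graph, K, beta, seed = 1L, n_sweeps = 100L) {
  stopifnot(n_sweeps >= 1L, beta >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  potts_draw(graph, K, beta, n_sweeps)
}

#' Sample a proper-CAR Gaussian field
#'
#' Exact draw from the joint distribution with per-dimension precision
#' `lambda_d^{-1} (D - rho A)` (degree matrix D, adjacency A) via Cholesky
#' factorization of the precision; isolated spots get unit precision times
#' `lambda_d^{-1}`. `rho = 0` gives i.i.d. spots; `rho` close to 1
#' approaches the intrinsic CAR the fitting model assumes (the intrinsic
#' limit itself is improper and cannot be sampled).
#'
#' @param graph A [neighbor_graph].
#' @param lambda Length-q positive conditional variances.
#' @param rho Autocorrelation in `[0, 1)`.
#' @param seed Integer seed.
#' @return n x q matrix.
#' @export
sample_car <- function(graph, lambda, rho, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  stopifnot(all(lambda > 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  car_draw(graph, lambda, rho)
}

#' Generate a synthetic multi-slide dataset
#'
#' The generative twin of the fitted model. Per slide: lattice coordinates,
#' neighbour graph (radius rule, factor 1.2), Potts labels at
#' `beta_true[t]`, batch field `u` = proper-CAR draw plus the slide's mean
#' shift, and embeddings `v = mu[y] + N(0, sigma_scale^2 I) + u` with
#' cluster means spread to `mu_separation`. Optionally adds a Poisson count
#' layer `counts ~ Poisson(exp(W v + eps))` with seeded random loadings.
#'
#' @param cfg A [sim_config].
#' @return List with `dataset` (a [multi_sample_dataset] carrying
#'   embeddings, coordinates and graphs) and `truth` (per-slide `labels`
#'   and `u` lists plus the generative `params`).
#' @export
simulate_multisample <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  mu <- cluster_means(cfg$K, cfg$q, cfg$mu_separation)
  slides <- vector("list", cfg$T)
  labels <- vector("list", cfg$T)
  ufields <- vector("list", cfg$T)
  for (t in seq_len(cfg$T)) {
    lat <- cfg$lattice[t, ]
    spots <- lattice_coords(lat$rows, lat$cols, as.character(lat$geometry),
                            prefix = sprintf("t%d_", t))
    n <- nrow(spots)
    if (cfg$K > n) stop("K = ", cfg$K, " exceeds slide spot count ", n)
    graph <- build_neighbors_radius(spots, auto_radius(spots, 1.2))
    y <- potts_draw(graph, cfg$K, cfg$beta_true[t], 100L)
    u <- car_draw(graph, cfg$lambda_true[t, ], cfg$rho)
    u <- sweep(u, 2L, cfg$batch_shift[t, ], `+`)
    noise <- matrix(stats::rnorm(n * cfg$q, sd = cfg$sigma_scale), n, cfg$q)
    v <- mu[y, , drop = FALSE] + noise + u
    rownames(v) <- spots$spot_id
    slides[[t]] <- slide_data(sprintf("slide%d", t), spots, embeddings = v,
                              graph = graph)
    labels[[t]] <- y
    ufields[[t]] <- u
  }
  if (!is.null(cfg$n_genes)) {
    W <- matrix(stats::rnorm(cfg$n_genes * cfg$q), cfg$n_genes, cfg$q)
    W <- W / sqrt(rowSums(W^2)) * 0.25
    for (t in seq_len(cfg$T)) {
      v <- slides[[t]]$embeddings
      eta <- W %*% t(v) +
        matrix(stats::rnorm(cfg$n_genes * nrow(v), sd = cfg$noise_sd),
               cfg$n_genes, nrow(v))
      cts <- matrix(stats::rpois(length(eta), exp(eta)),
                    cfg$n_genes, nrow(v))
      rownames(cts) <- sprintf("gene%04d", seq_len(cfg$n_genes))
      colnames(cts) <- slides[[t]]$spots$spot_id
      slides[[t]]$counts <- Matrix::Matrix(cts, sparse = TRUE)
    }
  }
  ds <- multi_sample_dataset(slides,
                             gene_ids = if (!is.null(cfg$n_genes))
                               sprintf("gene%04d", seq_len(cfg$n_genes)))
  sigma <- array(0, c(cfg$q, cfg$q, cfg$K))
  for (k in seq_len(cfg$K)) sigma[, , k] <- diag(cfg$sigma_scale^2, cfg$q)
  list(dataset = ds,
       truth = list(labels = labels, u = ufields,
                    params = list(mu = mu, sigma = sigma,
                                  lambda = cfg$lambda_true,
                                  beta = cfg$beta_true,
                                  batch_shift = cfg$batch_shift)),
       config = cfg)
}
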