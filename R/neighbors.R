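#' Neighbour graph over the spots of one slide
#'
#' Undirected, self-loop-free adjacency used by both the Potts label prior
#' and the CAR batch field. Stored as an edge list plus a sparse symmetric
#' 0/1 adjacency matrix and the per-spot degree.
#'
#' @param n_spots Number of spots.
#' @param edges Two-column integer matrix of unordered spot-index pairs
#'   (1-based, i < j).
#' @return An object of class `neighbor_graph`.
#' @export
neighbor_graph <- function(n_spots, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops not allowed")
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  adj <- Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                              j = c(edges[, 2L], edges[, 1L]),
                              x = 1, dims = c(n_spots, n_spots))
  structure(list(n_spots = as.integer(n_spots), edges = edges, adj = adj,
                 degree = as.integer(Matrix::rowSums(adj))),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("Neighbour graph: %d spots, %d edges, mean degree %.2f\n",
              x$n_spots, nrow(x$edges), mean(x$degree)))
  invisible(x)
}

#' Fixed-radius neighbour graph
#'
#' Connects every pair of spots at Euclidean distance in `(0, radius]`.
#' Platform-free: no array row/column convention is assumed, only the
#' provided coordinates. Isolated spots (degree 0) are permitted.
#'
#' @param spots Spot table (data frame with `x`, `y`).
#' @param radius Positive cutoff in coordinate units.
#' @return A [neighbor_graph].
#' @export
build_neighbors_radius <- function(spots, radius) {
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(spots)
  stopifnot(n >= 1L)
  # grid-bucket the plane so only nearby pairs are examined
  cx <- floor(spots$x / radius); cy <- floor(spots$y / radius)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  r2 <- radius^2
  ei <- integer(0); ej <- integer(0)
  for (k in names(buckets)) {
    ids <- buckets[[k]]
    c0 <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
    cand <- ids
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      nk <- paste(c0[1L] + dx, c0[2L] + dy)
      if (!is.null(v <- lookup[[nk]])) cand <- c(cand, v)
    }
    for (i in ids) {
      js <- cand[cand > i]
      if (!length(js)) next
      d2 <- (spots$x[js] - spots$x[i])^2 + (spots$y[js] - spots$y[i])^2
      hit <- js[d2 > 0 & d2 <= r2]
      ei <- c(ei, rep.int(i, length(hit))); ej <- c(ej, hit)
    }
  }
  neighbor_graph(n, cbind(ei, ej))
}

#' k-nearest-neighbour graph
#'
#' Directed k-nearest-neighbour relation symmetrized by union; distance ties
#' broken by lower spot index. Useful on irregular platforms where a single
#' radius is awkward.
#'
#' @param spots Spot table.
#' @param k Neighbours per spot; values `>= n_spots` are clamped to
#'   `n_spots - 1` with a warning.
#' @return A [neighbor_graph].
#' @export
build_neighbors_knn <- function(spots, k) {
  n <- nrow(spots)
  stopifnot(k >= 1L, n >= 2L)
  if (k >= n) {
    warning("k = ", k, " clamped to n_spots - 1 = ", n - 1L)
    k <- n - 1L
  }
  d <- as.matrix(stats::dist(cbind(spots$x, spots$y)))
  diag(d) <- Inf
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(k)]   # ties -> lower index
    ei <- c(ei, rep.int(i, k)); ej <- c(ej, nb)
  }
  keep <- ei != ej
  neighbor_graph(n, cbind(ei[keep], ej[keep]))
}

#' Default neighbourhood radius from spot spacing
#'
#' `factor` times the median over spots of the distance to the nearest
#' other spot. With the default factor 1.2 this reproduces the canonical
#' lattice neighbourhoods without platform flags: degree 4 in the interior
#' of a square lattice and degree 6 on a hexagonal one.
#'
#' @param spots Spot table with at least 2 spots.
#' @param factor Positive multiplier (default 1.2).
#' @return A positive radius in coordinate units.
#' @export
auto_radius <- function(spots, factor = 1.2) {
  n <- nrow(spots)
  if (n < 2L) stop("need at least 2 spots to infer a radius")
  stopifnot(factor > 0)
  if (n <= 2048L) {
    d <- as.matrix(stats::dist(cbind(spots$x, spots$y)))
    diag(d) <- Inf
    nn <- apply(d, 1L, min)
  } else {
    # nearest neighbour via bucket grid at a growing radius
    nn <- rep(Inf, n)
    r <- sqrt(diff(range(spots$x)) * diff(range(spots$y)) / n) + 1e-9
    remaining <- seq_len(n)
    while (length(remaining)) {
      g <- build_neighbors_radius(spots, r)
      for (i in remaining) {
        nb <- which(g$adj[i, ] > 0)
        if (length(nb))
          nn[i] <- sqrt(min((spots$x[nb] - spots$x[i])^2 +
                            (spots$y[nb] - spots$y[i])^2))
      }
      remaining <- remaining[!is.finite(nn[remaining])]
      r <- r * 2
    }
  }
  factor * stats::median(nn)
}

#' Attach neighbour graphs to every slide
#'
#' @param ds A [multi_sample_dataset].
#' @param method `"radius"` (default; cutoff from [auto_radius] unless
#'   `radius` given) or `"knn"`.
#' @param radius Optional explicit radius.
#' @param k Neighbours for the knn method (default 6).
#' @param factor Multiplier for [auto_radius] (default 1.2).
#' @return The dataset with `graph` populated per slide.
#' @export
add_neighbors <- function(ds, method = c("radius", "knn"), radius = NULL,
                          k = 6L, factor = 1.2) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "msd"))
  for (t in seq_along(ds$slides)) {
    sp <- ds$slides[[t]]$spots
    ds$slides[[t]]$graph <- switch(method,
      radius = build_neighbors_radius(
        sp, if (is.null(radius)) auto_radius(sp, factor) else radius),
      knn = build_neighbors_knn(sp, k))
  }
  ds
}
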