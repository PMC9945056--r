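#' Per-slide container for spatial transcriptomics data
#'
#' Bundles the measurements of one tissue section: optionally a gene-by-spot
#' count matrix, optionally a spot-by-dimension embedding matrix, always a
#' spot table with 2-D positions, and optionally a neighbour graph.
#' At least one of `counts` / `embeddings` must be supplied.
#'
#' @param slide_id Single string identifying the slide.
#' @param spots Data frame with columns `spot_id` (unique strings), `x`, `y`
#'   (finite reals, platform units).
#' @param counts Optional non-negative integer matrix (genes x spots), dense
#'   or `Matrix` sparse; column count must equal `nrow(spots)`.
#' @param embeddings Optional numeric matrix (spots x q).
#' @param graph Optional [neighbor_graph] over the spots.
#' @return An object of class `slide_data`.
#' @export
slide_data <- function(slide_id, spots, counts = NULL, embeddings = NULL,
                       graph = NULL) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  if (!is.data.frame(spots) || !all(c("spot_id", "x", "y") %in% names(spots)))
    stop("`spots` must be a data frame with columns spot_id, x, y")
  spots$spot_id <- as.character(spots$spot_id)
  if (is.null(counts) && is.null(embeddings))
    stop("slide '", slide_id, "': at least one of counts/embeddings required")
  if (!is.null(embeddings)) embeddings <- as.matrix(embeddings)
  structure(list(slide_id = slide_id, counts = counts,
                 embeddings = embeddings, spots = spots, graph = graph),
            class = "slide_data")
}

#' Multi-slide dataset
#'
#' An ordered collection of [slide_data] objects sharing a gene universe
#' (when counts are present) and an embedding dimension (when embeddings are
#' present). All per-spot quantities downstream (labels, batch embeddings,
#' responsibilities) index spots by slide order then within-slide file order.
#'
#' @param slides List of [slide_data] objects with unique `slide_id`s.
#' @param gene_ids Optional character vector naming the shared gene order;
#'   defaults to the rownames of the first slide's counts.
#' @return An object of class `msd` (multi-sample dataset).
#' @export
multi_sample_dataset <- function(slides, gene_ids = NULL) {
  stopifnot(is.list(slides), length(slides) >= 1L)
  if (!all(vapply(slides, inherits, logical(1), "slide_data")))
    stop("all elements of `slides` must be slide_data objects")
  if (is.null(gene_ids)) {
    cm <- slides[[1L]]$counts
    if (!is.null(cm)) gene_ids <- rownames(cm)
  }
  q <- NULL
  for (sl in slides)
    if (!is.null(sl$embeddings)) { q <- ncol(sl$embeddings); break }
  structure(list(slides = slides, gene_ids = gene_ids, q = q), class = "msd")
}

#' @export
print.msd <- function(x, ...) {
  ns <- vapply(x$slides, function(s) nrow(s$spots), integer(1))
  cat(sprintf("Multi-sample spatial dataset: %d slide(s), %d spots total\n",
              length(x$slides), sum(ns)))
  for (s in x$slides)
    cat(sprintf("  %s: %d spots%s%s%s\n", s$slide_id, nrow(s$spots),
                if (!is.null(s$counts)) sprintf(", %d genes", nrow(s$counts)) else "",
                if (!is.null(s$embeddings)) sprintf(", q=%d", ncol(s$embeddings)) else "",
                if (!is.null(s$graph)) sprintf(", %d edges", nrow(s$graph$edges)) else ""))
  invisible(x)
}

n_spots_per_slide <- function(ds) {
  vapply(ds$slides, function(s) nrow(s$spots), integer(1))
}

#' Validate a multi-sample dataset
#'
#' Checks every container invariant and returns the findings instead of
#' raising: spot_id uniqueness per slide, finite coordinates, dimension
#' agreement between spot tables and counts/embeddings, shared gene order
#' across slides, shared embedding dimension, and slide_id uniqueness.
#' Side-effect free and idempotent.
#'
#' @param ds A [multi_sample_dataset].
#' @return A character vector of human-readable violations; `character(0)`
#'   when the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "msd"))
  rep <- character(0)
  ids <- vapply(ds$slides, `[[`, character(1), "slide_id")
  if (anyDuplicated(ids))
    rep <- c(rep, sprintf("dataset: duplicate slide_id '%s'",
                          ids[duplicated(ids)][1L]))
  qs <- integer(0)
  for (sl in ds$slides) {
    id <- sl$slide_id
    n <- nrow(sl$spots)
    if (anyDuplicated(sl$spots$spot_id))
      rep <- c(rep, sprintf("slide '%s': spot_id not unique ('%s')", id,
                            sl$spots$spot_id[duplicated(sl$spots$spot_id)][1L]))
    if (!all(is.finite(sl$spots$x)) || !all(is.finite(sl$spots$y)))
      rep <- c(rep, sprintf("slide '%s': non-finite coordinates", id))
    if (is.null(sl$counts) && is.null(sl$embeddings))
      rep <- c(rep, sprintf("slide '%s': neither counts nor embeddings present", id))
    if (!is.null(sl$counts)) {
      if (ncol(sl$counts) != n)
        rep <- c(rep, sprintf("slide '%s': counts has %d columns for %d spots",
                              id, ncol(sl$counts), n))
      if (!is.null(ds$gene_ids) && !is.null(rownames(sl$counts)) &&
          !identical(rownames(sl$counts), ds$gene_ids))
        rep <- c(rep, sprintf("slide '%s': gene order differs from dataset gene_ids", id))
      if (any(sl$counts < 0))
        rep <- c(rep, sprintf("slide '%s': negative counts", id))
    }
    if (!is.null(sl$embeddings)) {
      if (nrow(sl$embeddings) != n)
        rep <- c(rep, sprintf("slide '%s': embeddings has %d rows for %d spots",
                              id, nrow(sl$embeddings), n))
      qs <- c(qs, ncol(sl$embeddings))
      if (!all(is.finite(sl$embeddings)))
        rep <- c(rep, sprintf("slide '%s': non-finite embeddings", id))
    }
    if (!is.null(sl$graph) && sl$graph$n_spots != n)
      rep <- c(rep, sprintf("slide '%s': graph built for %d spots, slide has %d",
                            id, sl$graph$n_spots, n))
  }
  if (length(unique(qs)) > 1L)
    rep <- c(rep, sprintf("dataset: embedding dimensions differ across slides (%s)",
                          paste(unique(qs), collapse = ", ")))
  rep
}

# Pooled spots x q embedding matrix, rows in slide order then file order.
pooled_embeddings <- function(ds) {
  do.call(rbind, lapply(ds$slides, function(s) {
    if (is.null(s$embeddings))
      stop("slide '", s$slide_id, "' has no embeddings; run PCA first")
    s$embeddings
  }))
}

# Split a pooled per-spot matrix/vector back into per-slide pieces.
split_by_slide <- function(ds, x) {
  ns <- n_spots_per_slide(ds)
  idx <- rep(seq_along(ns), ns)
  if (is.matrix(x)) lapply(seq_along(ns), function(t) x[idx == t, , drop = FALSE])
  else split(x, idx)
}
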