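as_membership <- function(x) as.integer(factor(as.character(x)))

apply_mask <- function(values, mask) {
  if (is.null(mask)) return(values)
  stopifnot(length(mask) == length(values))
  values[mask]
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions with the expected-index
#' correction: 1 for identical partitions, ~0 for independent ones, and
#' possibly negative for systematic disagreement. Invariant to relabeling
#' of either side and to spot order. Optional masks restrict both vectors
#' to annotated spots.
#'
#' @param a,b Label vectors (any type coercible to categories) of equal
#'   length after masking; at least 2 spots.
#' @param mask_a,mask_b Optional logical vectors marking annotated spots.
#' @return A number in `[-1, 1]`.
#' @export
ari <- function(a, b, mask_a = NULL, mask_b = NULL) {
  a <- apply_mask(a, mask_a); b <- apply_mask(b, mask_b)
  if (length(a) != length(b))
    stop("label vectors differ in length after masking (", length(a),
         " vs ", length(b), ")")
  if (length(a) < 2L) stop("need at least 2 spots")
  mclust::adjustedRandIndex(as_membership(a), as_membership(b))
}

#' Normalized mutual information
#'
#' Mutual information of the empirical joint label distribution divided by
#' the arithmetic mean of the two entropies (the 2I/(H1 + H2)
#' normalization). Defined as 1 when both partitions consist of a single
#' cluster. Symmetric and invariant to relabeling.
#'
#' @inheritParams ari
#' @param normalization Normalization convention; only `"arithmetic"`.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(a, b, mask_a = NULL, mask_b = NULL,
                normalization = "arithmetic") {
  normalization <- match.arg(normalization)
  a <- apply_mask(a, mask_a); b <- apply_mask(b, mask_b)
  if (length(a) != length(b))
    stop("label vectors differ in length after masking (", length(a),
         " vs ", length(b), ")")
  if (length(a) < 2L) stop("need at least 2 spots")
  a <- as_membership(a); b <- as_membership(b)
  if (max(a) == 1L && max(b) == 1L) return(1)
  val <- igraph::compare(a, b, method = "nmi")
  min(max(val, 0), 1)
}

#' Integrated (pooled) clustering metric across slides
#'
#' Concatenates predicted and true labels over all slides (dropping masked
#' spots) and scores the pooled vectors once. Unlike averaging per-slide
#' scores, this is sensitive to cluster identities being swapped between
#' slides, i.e. it measures integration quality as well as per-slide
#' accuracy.
#'
#' @param per_slide_pred,per_slide_truth Lists (one element per slide) of
#'   label vectors, matched in slide order and length.
#' @param metric `"ari"` or `"nmi"`.
#' @param per_slide_mask Optional list of logical masks.
#' @return The pooled metric value.
#' @export
integrated_metric <- function(per_slide_pred, per_slide_truth,
                              metric = c("ari", "nmi"),
                              per_slide_mask = NULL) {
  metric <- match.arg(metric)
  if (length(per_slide_pred) != length(per_slide_truth))
    stop("slide counts differ (", length(per_slide_pred), " vs ",
         length(per_slide_truth), ")")
  pred <- unlist(lapply(per_slide_pred, as.character), use.names = FALSE)
  truth <- unlist(lapply(per_slide_truth, as.character), use.names = FALSE)
  mask <- if (is.null(per_slide_mask)) NULL
          else unlist(per_slide_mask, use.names = FALSE)
  if (metric == "ari") ari(pred, truth, mask, mask)
  else nmi(pred, truth, mask, mask)
}

#' Between-slide spread of per-cluster centroids
#'
#' For each cluster, computes the centroid of its spots separately per
#' slide and measures the mean Euclidean distance of those per-slide
#' centroids from their across-slide mean; the result averages over
#' clusters present in at least two slides. Near zero when slides are well
#' aligned; comparing the value on raw vs batch-corrected embeddings
#' quantifies batch-effect removal.
#'
#' @param emb_list List of per-slide n_t x q embedding matrices.
#' @param labels_list List of per-slide label vectors.
#' @return Non-negative scalar (0 when no cluster spans two slides).
#' @export
centroid_spread <- function(emb_list, labels_list) {
  stopifnot(length(emb_list) == length(labels_list))
  labs <- sort(unique(unlist(lapply(labels_list, unique))))
  total <- 0; used <- 0L
  for (k in labs) {
    cent <- list()
    for (t in seq_along(emb_list)) {
      sel <- labels_list[[t]] == k
      if (any(sel))
        cent[[length(cent) + 1L]] <-
          colMeans(emb_list[[t]][sel, , drop = FALSE])
    }
    if (length(cent) < 2L) next
    cm <- do.call(rbind, cent)
    center <- colMeans(cm)
    total <- total + mean(sqrt(rowSums((cm - matrix(center, nrow(cm),
                                                    ncol(cm), byrow = TRUE))^2)))
    used <- used + 1L
  }
  if (used == 0L) 0 else total / used
}
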