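#' Embed network nodes in two dimensions by adjacency-matrix PCA
#'
#' Network dimensionality reduction: principal component analysis of the
#' symmetric cross-sectional adjacency matrix. Each node's coordinates are
#' its loadings on the first `n_dims` components, scaled so the largest
#' absolute value per axis is 1 (making in-plane distances commensurate with
#' the unit inter-layer gap of the 3D assembly). Nodes with similar
#' connectivity profiles land close together, so Euclidean distance in the
#' embedding is expected to anti-correlate with edge weight.
#'
#' The adjacency diagonal (a free convention) is set per
#' `config$ndr_diagonal`: each node's mean off-diagonal weight (default,
#' preventing the diagonal from dominating component 1) or zero. PCA signs
#' are arbitrary, so axes are oriented deterministically: axis 1 so the
#' designated `anchor_x` item has negative x (placing cognitive items on the
#' left), axis 2 so the `anchor_y_items` (distress items) have positive mean
#' y. Anchors absent from the network fall back to the first node (negative
#' x) and second node (positive y).
#'
#' @param net A symmetric cross-sectional `network_matrix` (or bare symmetric
#'   matrix).
#' @param n_dims Number of embedding dimensions (default 2).
#' @param config An [analysis_config()] (diagonal convention).
#' @param anchor_x Item anchoring the negative x direction (default
#'   `"Hallucinations"`).
#' @param anchor_y_items Items anchoring positive y (default the affective
#'   distress items).
#' @return An object of class `network_embedding`: `coordinates` (nodes x
#'   n_dims), `explained_variance`, `accuracy_r`, `accuracy_p`.
#' @export
embed_network <- function(net, n_dims = 2L, config = analysis_config(),
                          anchor_x = "Hallucinations",
                          anchor_y_items = c("Sadness", "Anxiety", "Irritation",
                                             "Feeling-Rejected")) {
  W <- if (inherits(net, "network_matrix")) net$weights else as.matrix(net)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    stop("embedding requires a symmetric cross-sectional matrix")
  }
  if (all(W == 0)) stop("cannot embed an all-zero network")
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(W)))
  A <- W
  diag(A) <- if (config$ndr_diagonal == "mean_offdiag") {
    (rowSums(W) - diag(W)) / (ncol(W) - 1L)
  } else 0
  pc <- stats::prcomp(A, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  n_dims <- min(n_dims, ncol(pc$rotation))
  coords <- pc$rotation[, seq_len(n_dims), drop = FALSE]
  rownames(coords) <- labels

  sorted <- sort(labels)   # permutation-invariant fallback anchors
  ax <- if (anchor_x %in% labels) anchor_x else sorted[1L]
  if (coords[ax, 1L] > 0) coords[, 1L] <- -coords[, 1L]
  if (n_dims >= 2L) {
    ay <- intersect(anchor_y_items, labels)
    if (!length(ay)) ay <- sorted[min(2L, length(sorted))]
    if (mean(coords[ay, 2L]) < 0) coords[, 2L] <- -coords[, 2L]
  }
  for (j in seq_len(n_dims)) {
    m <- max(abs(coords[, j]))
    if (m > 0) coords[, j] <- coords[, j] / m
  }
  colnames(coords) <- c("x", "y", "z")[seq_len(min(n_dims, 3L))]
  emb <- structure(
    list(coordinates = coords, explained_variance = frac,
         accuracy_r = NA_real_, accuracy_p = NA_real_),
    class = "network_embedding"
  )
  acc <- embedding_accuracy(emb, W)
  emb$accuracy_r <- acc[["r"]]
  emb$accuracy_p <- acc[["p"]]
  emb
}

#' @export
print.network_embedding <- function(x, ...) {
  cat(sprintf(
    "<network_embedding> %d nodes in %d dims (variance %s); accuracy r = %.3f (p = %.3g)\n",
    nrow(x$coordinates), ncol(x$coordinates),
    paste(sprintf("%.0f%%", 100 * utils::head(x$explained_variance,
                                              ncol(x$coordinates))),
          collapse = "/"),
    x$accuracy_r, x$accuracy_p))
  invisible(x)
}

#' Fidelity of a network embedding
#'
#' Pearson correlation, over all unordered node pairs, between the Euclidean
#' distance separating two nodes in the embedding and the edge weight
#' connecting them. A faithful layout puts strongly connected nodes close
#' together, so the expected correlation on structured networks is negative.
#'
#' @param emb A `network_embedding`.
#' @param net The `network_matrix` (or symmetric matrix) it was computed from.
#' @return Named numeric vector `c(r = , p = )`.
#' @export
embedding_accuracy <- function(emb, net) {
  W <- if (inherits(net, "network_matrix")) net$weights else as.matrix(net)
  coords <- emb$coordinates
  if (nrow(coords) != nrow(W)) stop("embedding and network sizes differ")
  dmat <- as.matrix(stats::dist(coords))
  up <- upper.tri(W)
  if (sum(up) < 3L) stop("need at least 3 node pairs")
  d <- dmat[up]; w <- W[up]
  if (stats::sd(d) == 0 || stats::sd(w) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(d, w)
  c(r = unname(ct$estimate), p = ct$p.value)
}
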