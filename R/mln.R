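#' Assemble the 3D two-layer temporal network
#'
#' Duplicates the embedded nodes at z = 0 (temporal layer TL1) and z = 1
#' (TL2), instantiates retained within-layer edges from the cross-sectional
#' blocks of the multilayer matrix and directed TL1-to-TL2 edges from the
#' lagged block, and assigns each edge a traversal length `1/|weight|`
#' (strong coupling of either sign = short edge; the weight's sign is kept
#' as metadata). Pruned (zero-weight) pairs have no edge.
#'
#' @param embedding A `network_embedding` covering all items.
#' @param multilayer The `"multilayer"` `network_matrix` from
#'   [build_networks()].
#' @param transform Length transform; only `"inverse_abs"`.
#' @return An object of class `mln3d`: `nodes` (data.frame: name, item,
#'   layer, x, y, z) and `edges` (data.frame: from, to, weight, length,
#'   type in within_TL1/within_TL2/between).
#' @export
assemble_3d <- function(embedding, multilayer, transform = "inverse_abs") {
  stopifnot(inherits(embedding, "network_embedding"),
            inherits(multilayer, "network_matrix"),
            multilayer$kind == "multilayer",
            identical(transform, "inverse_abs"))
  k <- nrow(multilayer$weights) / 2L
  items <- sub("@TL1$", "", multilayer$labels[seq_len(k)])
  missing_items <- setdiff(items, rownames(embedding$coordinates))
  if (length(missing_items)) {
    stop("embedding lacks coordinates for: ",
         paste(missing_items, collapse = ", "))
  }
  xy <- embedding$coordinates[items, 1:2, drop = FALSE]
  nodes <- data.frame(
    name = c(paste0(items, "@TL1"), paste0(items, "@TL2")),
    item = rep(items, 2L),
    layer = rep(c("TL1", "TL2"), each = k),
    x = rep(xy[, 1L], 2L), y = rep(xy[, 2L], 2L),
    z = rep(c(0, 1), each = k),
    stringsAsFactors = FALSE
  )
  W <- multilayer$weights
  i1 <- seq_len(k); i2 <- k + i1
  edge_rows <- list()
  add_edges <- function(from_idx, to_idx, type, undirected) {
    B <- W[from_idx, to_idx, drop = FALSE]
    sel <- which(B != 0, arr.ind = TRUE)
    if (undirected) sel <- sel[sel[, 1L] < sel[, 2L], , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    w <- B[sel]
    if (any(multilayer$mask[from_idx, to_idx][sel] & w == 0)) {
      stop("retained edge with weight 0: internal inconsistency")
    }
    data.frame(
      from = nodes$name[from_idx[sel[, 1L]]],
      to = nodes$name[to_idx[sel[, 2L]]],
      weight = w, length = 1 / abs(w), type = type,
      stringsAsFactors = FALSE
    )
  }
  edges <- rbind(
    add_edges(i1, i1, "within_TL1", undirected = TRUE),
    add_edges(i2, i2, "within_TL2", undirected = TRUE),
    add_edges(i1, i2, "between", undirected = FALSE)
  )
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), length = numeric(0),
                        type = character(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, provenance = multilayer),
            class = "mln3d")
}

#' @export
print.mln3d <- function(x, ...) {
  tw <- table(factor(x$edges$type,
                     levels = c("within_TL1", "within_TL2", "between")))
  cat(sprintf("<mln3d> %d nodes; edges: %d within TL1, %d within TL2, %d between\n",
              nrow(x$nodes), tw[[1L]], tw[[2L]], tw[[3L]]))
  invisible(x)
}

#' Export a 3D multilayer network and its paths as viewer JSON
#'
#' Writes a single JSON document with `nodes` (name, item, layer, x, y, z,
#' size = summed absolute connectivity, centrality = number of shortest
#' paths through the node), `edges` (endpoints, weight, length, type,
#' n_shortest_paths traversing), and `paths` (ordered node sequences with
#' total length). The document round-trips losslessly through
#' [read_network_export()].
#'
#' @param mln An `mln3d`.
#' @param paths A `behavioral_paths` collection (or NULL for none).
#' @param out Output file path.
#' @return Invisibly, `out`.
#' @export
write_network_export <- function(mln, paths = NULL, out) {
  stopifnot(inherits(mln, "mln3d"))
  nodes <- mln$nodes
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z))) {
    stop("node without finite coordinates")
  }
  edges <- mln$edges
  size <- stats::setNames(numeric(nrow(nodes)), nodes$name)
  for (i in seq_len(nrow(edges))) {
    w <- abs(edges$weight[i])
    size[edges$from[i]] <- size[edges$from[i]] + w
    size[edges$to[i]] <- size[edges$to[i]] + w
  }
  node_counts <- stats::setNames(integer(nrow(nodes)), nodes$name)
  edge_counts <- integer(nrow(edges))
  path_list <- list()
  if (!is.null(paths) && length(paths$paths)) {
    bt <- longitudinal_betweenness(mln, paths)
    node_counts[names(bt$node_counts)] <- bt$node_counts
    edge_counts <- bt$edge_counts
    path_list <- lapply(paths$paths, function(p) {
      list(start_item = p$start_item, end_item = p$end_item,
           nodes = p$nodes, total_length = p$total_length)
    })
  }
  doc <- list(
    nodes = data.frame(nodes, size = unname(size),
                       centrality = unname(node_counts),
                       stringsAsFactors = FALSE),
    edges = if (nrow(edges)) {
      data.frame(edges, n_shortest_paths = edge_counts,
                 stringsAsFactors = FALSE)
    } else list(),
    paths = path_list
  )
  jsonlite::write_json(doc, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out)
}

#' Read a viewer JSON export back into R
#'
#' Paired reader for [write_network_export()].
#'
#' @param path JSON file path.
#' @return List with `mln` (an `mln3d`, without provenance) and `paths`
#'   (a `behavioral_paths` collection rebuilt from the stored sequences).
#' @export
read_network_export <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  edges <- if (length(doc$edges)) {
    as.data.frame(doc$edges, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               length = numeric(0), type = character(0),
               stringsAsFactors = FALSE)
  }
  keep_e <- intersect(c("from", "to", "weight", "length", "type"), names(edges))
  mln <- structure(
    list(nodes = nodes[, c("name", "item", "layer", "x", "y", "z")],
         edges = edges[, keep_e, drop = FALSE], provenance = NULL),
    class = "mln3d"
  )
  paths <- NULL
  if (length(doc$paths)) {
    coord <- as.matrix(nodes[, c("x", "y", "z")])
    rownames(coord) <- nodes$name
    # jsonlite may simplify the path records into a data.frame
    precs <- if (is.data.frame(doc$paths)) {
      lapply(seq_len(nrow(doc$paths)), function(i) {
        list(nodes = unlist(doc$paths$nodes[[i]]),
             total_length = doc$paths$total_length[i])
      })
    } else {
      lapply(doc$paths, function(p) {
        list(nodes = unlist(p$nodes), total_length = p$total_length)
      })
    }
    plist <- lapply(precs, function(p) {
      make_behavioral_path(p$nodes, coord[p$nodes, , drop = FALSE],
                           p$total_length)
    })
    paths <- structure(list(paths = plist, unreachable = 0L),
                       class = "behavioral_paths")
  }
  list(mln = mln, paths = paths)
}
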