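# Behavioral paths: interlayer shortest paths on the 3D multilayer network.
#
# Within-layer edges are traversable in both directions; between-layer edges
# only go TL1 -> TL2, so every path from a TL1 node to a TL2 node makes
# exactly one forward-in-time layer transition and can never return.

make_behavioral_path <- function(nodes, coords, total_length) {
  layers <- ifelse(grepl("@TL2$", nodes), "TL2", "TL1")
  p <- list(
    start_item = sub("@TL[12]$", "", nodes[1L]),
    end_item = sub("@TL[12]$", "", nodes[length(nodes)]),
    nodes = nodes,
    layers = layers,
    coords = coords,
    total_length = total_length
  )
  p$anchors <- extract_anchors(p)
  class(p) <- "behavioral_path"
  p
}

#' @export
print.behavioral_path <- function(x, ...) {
  cat(sprintf("<behavioral_path> %s -> %s (%d nodes, length %.3f)\n",
              x$nodes[1L], x$nodes[length(x$nodes)], length(x$nodes),
              x$total_length))
  invisible(x)
}

#' @export
print.behavioral_paths <- function(x, ...) {
  cat(sprintf("<behavioral_paths> %d paths (%d item pairs unreachable)\n",
              length(x$paths), x$unreachable))
  invisible(x)
}

# -1 / 0 / 1 comparison of (dist, hops, lexicographic path) labels
compare_labels <- function(d1, h1, p1, d2, h2, p2, rank) {
  tol <- 1e-9 * (1 + max(abs(d1), abs(d2)))
  if (d1 < d2 - tol) return(-1L)
  if (d1 > d2 + tol) return(1L)
  if (h1 != h2) return(if (h1 < h2) -1L else 1L)
  r1 <- rank[p1]; r2 <- rank[p2]
  m <- min(length(r1), length(r2))
  for (i in seq_len(m)) {
    if (r1[i] != r2[i]) return(if (r1[i] < r2[i]) -1L else 1L)
  }
  if (length(r1) == length(r2)) 0L else if (length(r1) < length(r2)) -1L else 1L
}

# Dijkstra from one source with deterministic tie-breaking:
# shorter total length, then fewer hops, then lexicographically smaller
# node-name sequence. Label-setting is valid for the hop/lex refinements
# because appending a common continuation preserves their order.
dijkstra_paths <- function(adj, n_nodes, source, rank) {
  dist <- rep(Inf, n_nodes); hops <- rep(Inf, n_nodes)
  paths <- vector("list", n_nodes)
  visited <- rep(FALSE, n_nodes)
  dist[source] <- 0; hops[source] <- 0L; paths[[source]] <- source
  repeat {
    u <- 0L; best <- NULL
    for (v in which(!visited & is.finite(dist))) {
      if (u == 0L ||
          compare_labels(dist[v], hops[v], paths[[v]],
                         dist[u], hops[u], paths[[u]], rank) < 0L) {
        u <- v
      }
    }
    if (u == 0L) break
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (i in seq_along(nb$to)) {
      v <- nb$to[i]
      if (visited[v]) next
      nd <- dist[u] + nb$len[i]
      nh <- hops[u] + 1L
      np <- c(paths[[u]], v)
      if (!is.finite(dist[v]) ||
          compare_labels(nd, nh, np, dist[v], hops[v], paths[[v]], rank) < 0L) {
        dist[v] <- nd; hops[v] <- nh; paths[[v]] <- np
      }
    }
  }
  list(dist = dist, paths = paths)
}

mln_adjacency <- function(mln) {
  nodes <- mln$nodes$name
  idx <- stats::setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  add <- function(a, b, len) {
    adj[[a]] <<- list(to = c(adj[[a]]$to, b), len = c(adj[[a]]$len, len))
  }
  e <- mln$edges
  for (i in seq_len(nrow(e))) {
    a <- idx[[e$from[i]]]; b <- idx[[e$to[i]]]
    if (e$type[i] == "between") add(a, b, e$length[i])
    else { add(a, b, e$length[i]); add(b, a, e$length[i]) }
  }
  list(adj = adj, idx = idx, nodes = nodes)
}

#' Interlayer shortest paths of a 3D multilayer network
#'
#' For every ordered (TL1 item, TL2 item) pair, the minimum-total-length path
#' by Dijkstra's algorithm, with deterministic tie-breaking (fewer hops, then
#' lexicographically smaller node-name sequence). Because between-layer edges
#' only run TL1 to TL2, every returned path contains exactly one layer
#' transition. Unreachable pairs are omitted and counted.
#'
#' @param mln An `mln3d`.
#' @param pairs Optional 2-column character matrix / data.frame of
#'   (start item, end item) pairs to restrict to.
#' @return An object of class `behavioral_paths`: `paths` (list of
#'   `behavioral_path`), `unreachable` (count of omitted pairs).
#' @export
shortest_interlayer_paths <- function(mln, pairs = NULL) {
  stopifnot(inherits(mln, "mln3d"))
  if (!any(mln$edges$type == "between")) {
    return(structure(list(paths = list(),
                          unreachable = sum(mln$nodes$layer == "TL1")^2),
                     class = "behavioral_paths"))
  }
  g <- mln_adjacency(mln)
  rank <- rank(g$nodes, ties.method = "first")
  coords <- as.matrix(mln$nodes[, c("x", "y", "z")])
  rownames(coords) <- g$nodes
  items1 <- mln$nodes$item[mln$nodes$layer == "TL1"]
  items2 <- mln$nodes$item[mln$nodes$layer == "TL2"]
  if (is.null(pairs)) {
    pairs <- expand.grid(start = items1, end = items2,
                         stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs) <- c("start", "end")
  }
  out <- list(); unreachable <- 0L
  for (s_item in unique(pairs$start)) {
    s <- g$idx[[paste0(s_item, "@TL1")]]
    if (is.null(s)) stop("unknown start item: ", s_item)
    res <- dijkstra_paths(g$adj, length(g$nodes), s, rank)
    for (e_item in pairs$end[pairs$start == s_item]) {
      t <- g$idx[[paste0(e_item, "@TL2")]]
      if (is.null(t)) stop("unknown end item: ", e_item)
      if (!is.finite(res$dist[t])) { unreachable <- unreachable + 1L; next }
      nd <- g$nodes[res$paths[[t]]]
      out[[length(out) + 1L]] <-
        make_behavioral_path(nd, coords[nd, , drop = FALSE], res$dist[t])
    }
  }
  structure(list(paths = out, unreachable = unreachable),
            class = "behavioral_paths")
}

#' Four-anchor coordinates of a behavioral path
#'
#' Summarizes a path's 3D trajectory by the XYZ coordinates of four anchor
#' nodes: the TL1 starting node, the TL1 exit node (last node at z = 0), the
#' TL2 entry node (first node at z = 1), and the TL2 ending node. A direct
#' lagged hop gives Start = Exit and Entry = End.
#'
#' @param path A `behavioral_path`.
#' @return Named numeric vector of 12 values
#'   (`start_x`, ..., `end_z`), with z in {0, 0, 1, 1}.
#' @export
extract_anchors <- function(path) {
  z <- path$coords[, "z"]
  in_tl1 <- z == 0
  if (!any(in_tl1) || all(in_tl1)) stop("path has no layer transition")
  exit_i <- max(which(in_tl1))
  entry_i <- min(which(!in_tl1))
  a <- c(path$coords[1L, ], path$coords[exit_i, ],
         path$coords[entry_i, ], path$coords[nrow(path$coords), ])
  names(a) <- as.vector(outer(c("x", "y", "z"),
                              c("start", "exit", "entry", "end"),
                              function(c2, c1) paste(c1, c2, sep = "_")))
  a
}

#' Mean 3D diffusion direction of paths through a node
#'
#' For every path traversing the node, the displacement to the node's
#' successor (for a terminal TL2 node: the displacement from its predecessor
#' into the node); the diffusion direction is the arithmetic mean of these
#' displacements. dz is never negative because paths only move forward in
#' time.
#'
#' @param node Node name (`"Item@TL1"` / `"Item@TL2"`).
#' @param paths A `behavioral_paths` collection.
#' @return An object of class `diffusion_vector`: `node`, `direction`
#'   (named dx, dy, dz), `n_paths`.
#' @export
behavioral_diffusion <- function(node, paths) {
  stopifnot(inherits(paths, "behavioral_paths"))
  disp <- matrix(numeric(0), 0L, 3L)
  for (p in paths$paths) {
    pos <- match(node, p$nodes)
    if (is.na(pos)) next
    d <- if (pos < length(p$nodes)) {
      p$coords[pos + 1L, ] - p$coords[pos, ]
    } else if (pos > 1L) {
      p$coords[pos, ] - p$coords[pos - 1L, ]
    } else next   # single-node path cannot occur (>= 2 nodes)
    disp <- rbind(disp, d)
  }
  n <- nrow(disp)
  dir <- if (n) colMeans(disp) else c(0, 0, 0)
  structure(list(node = node,
                 direction = stats::setNames(as.numeric(dir),
                                             c("dx", "dy", "dz")),
                 n_paths = n, flagged = n == 0L),
            class = "diffusion_vector")
}

#' @export
print.diffusion_vector <- function(x, ...) {
  cat(sprintf("<diffusion_vector> %s: (%.3f, %.3f, %.3f), n = %d%s\n",
              x$node, x$direction[1L], x$direction[2L], x$direction[3L],
              x$n_paths, if (x$flagged) " [no traversing path]" else ""))
  invisible(x)
}

#' Diffusion directions for every node of a network
#'
#' @param mln An `mln3d`.
#' @param paths A `behavioral_paths` collection.
#' @return data.frame with one row per node: `node`, `dx`, `dy`, `dz`,
#'   `n_paths`.
#' @export
diffusion_field <- function(mln, paths) {
  rows <- lapply(mln$nodes$name, function(nm) {
    dv <- behavioral_diffusion(nm, paths)
    data.frame(node = nm, dx = dv$direction[["dx"]], dy = dv$direction[["dy"]],
               dz = dv$direction[["dz"]], n_paths = dv$n_paths,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Longitudinal betweenness: shortest-path traversal counts
#'
#' Per node, the number of interlayer shortest paths passing through it
#' (endpoints count for their own paths); per edge, the number of shortest
#' paths traversing it (either direction for within-layer edges).
#'
#' @param mln An `mln3d`.
#' @param paths A `behavioral_paths` collection.
#' @return List with `node_counts` (named integer, all network nodes) and
#'   `edge_counts` (integer, aligned with `mln$edges` rows).
#' @export
longitudinal_betweenness <- function(mln, paths) {
  stopifnot(inherits(mln, "mln3d"), inherits(paths, "behavioral_paths"))
  node_counts <- stats::setNames(integer(nrow(mln$nodes)), mln$nodes$name)
  e <- mln$edges
  ekey <- stats::setNames(seq_len(nrow(e)), paste(e$from, e$to, sep = "\r"))
  ekey_rev <- stats::setNames(
    ifelse(e$type == "between", NA_integer_, seq_len(nrow(e))),
    paste(e$to, e$from, sep = "\r"))
  edge_counts <- integer(nrow(e))
  for (p in paths$paths) {
    nd <- p$nodes
    node_counts[nd] <- node_counts[nd] + 1L
    if (length(nd) < 2L) next
    for (i in seq_len(length(nd) - 1L)) {
      key <- paste(nd[i], nd[i + 1L], sep = "\r")
      j <- ekey[key]
      if (is.na(j)) j <- ekey_rev[key]
      if (!is.na(j)) edge_counts[j] <- edge_counts[j] + 1L
    }
  }
  list(node_counts = node_counts, edge_counts = edge_counts)
}
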