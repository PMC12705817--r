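# Bundles: k-means families of behavioral paths with similar 3D trajectories.

anchor_matrix <- function(paths) {
  A <- t(vapply(paths$paths, function(p) p$anchors, numeric(12L)))
  rownames(A) <- vapply(paths$paths, function(p) {
    paste(p$start_item, p$end_item, sep = "->")
  }, character(1))
  A
}

quadrant_name <- function(x, y) {
  paste0(if (y >= 0) "upper" else "lower", "-", if (x < 0) "left" else "right")
}

seeded_kmeans <- function(X, k, seed, nstart = 50L) {
  withr::with_seed(seed, stats::kmeans(X, centers = k, nstart = nstart))
}

# mean silhouette width of a k-means clustering (requires >= 2 clusters)
mean_silhouette <- function(cl, X) {
  sil <- cluster::silhouette(cl, stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Cluster behavioral paths into trajectory bundles
#'
#' K-means (50 restarts, best within-cluster sum of squares) on the
#' 12-dimensional anchor vectors. With `k = "auto"`, k in 4..12 is chosen to
#' maximize the mean silhouette width; a fixed k (such as 9, the granularity
#' reported for real cohorts) makes runs comparable across populations.
#'
#' @param paths A `behavioral_paths` collection.
#' @param k Number of bundles, or `"auto"`.
#' @param seed Integer seed for the k-means restarts.
#' @return An object of class `bundle_set`: list of bundles (each with `id`,
#'   `member_idx`, `member_paths`, `centroid`, `label`
#'   start-quadrant -> end-quadrant), plus `assignment` and `k`.
#' @export
cluster_bundles <- function(paths, k = "auto", seed = 1L) {
  A <- anchor_matrix(paths)
  n <- nrow(A)
  if (identical(k, "auto")) {
    ks <- 4:12
    ks <- ks[ks < n]
    if (!length(ks)) stop("too few paths (", n, ") for automatic bundle count")
    sil <- vapply(ks, function(kk) {
      km <- seeded_kmeans(A, kk, seed)
      mean_silhouette(km$cluster, A)
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k > n) stop("k = ", k, " exceeds the number of paths (", n, ")")
  if (k == 1L) {
    assignment <- rep(1L, n)
    centers <- matrix(colMeans(A), 1L, dimnames = list(NULL, colnames(A)))
  } else {
    km <- seeded_kmeans(A, k, seed)
    assignment <- km$cluster
    centers <- km$centers
  }
  bundles <- lapply(seq_len(k), function(b) {
    idx <- which(assignment == b)
    ctr <- centers[b, ]
    list(id = b, member_idx = idx, member_paths = paths$paths[idx],
         centroid = ctr,
         label = paste0(quadrant_name(ctr[["start_x"]], ctr[["start_y"]]),
                        " -> ",
                        quadrant_name(ctr[["end_x"]], ctr[["end_y"]])))
  })
  structure(list(bundles = bundles, assignment = assignment, k = k),
            class = "bundle_set")
}

#' @export
print.bundle_set <- function(x, ...) {
  cat(sprintf("<bundle_set> %d bundles:\n", x$k))
  for (b in x$bundles) {
    cat(sprintf("  %d: %d paths, %s\n", b$id, length(b$member_idx), b$label))
  }
  invisible(x)
}

# match two path collections by (start_item, end_item); returns the pair key
# index into each collection for pairs reachable in both populations
match_paths <- function(paths_a, paths_b) {
  key <- function(paths) vapply(paths$paths, function(p) {
    paste(p$start_item, p$end_item, sep = "\r")
  }, character(1))
  ka <- key(paths_a); kb <- key(paths_b)
  common <- intersect(ka, kb)
  data.frame(key = common,
             ia = match(common, ka), ib = match(common, kb),
             stringsAsFactors = FALSE)
}

#' Joint bundle clustering of two populations' paths
#'
#' Matches the two populations' shortest paths by (start item, end item) —
#' only pairs reachable in both populations enter — and k-means-clusters the
#' 18-dimensional concatenated anchor vectors (Start, Exit-A, Exit-B,
#' Entry-A, Entry-B, End; Start/End coordinates are shared because both
#' populations use the common embedding). Each resulting bundle connects a
#' shared set of TL1 to TL2 variables while allowing population-specific
#' trajectories between them.
#'
#' @param paths_a,paths_b `behavioral_paths` computed on each population's
#'   own network (same embedding).
#' @param k Number of bundles, or `"auto"` (silhouette over 4..12).
#' @param seed Integer seed.
#' @return An object of class `two_population_bundles`: `bundles` (each with
#'   `id`, `pairs`, `member_idx` into the matched set, `centroid`),
#'   `matched` (the pair table), `vectors` (the 18-D matrix), `assignment`.
#' @export
two_population_cluster <- function(paths_a, paths_b, k = "auto", seed = 1L) {
  m <- match_paths(paths_a, paths_b)
  if (!nrow(m)) stop("no (start, end) pair is reachable in both populations")
  V <- t(vapply(seq_len(nrow(m)), function(i) {
    aa <- paths_a$paths[[m$ia[i]]]$anchors
    ab <- paths_b$paths[[m$ib[i]]]$anchors
    c(start = unname(aa[1:3]),
      exit_a = unname(aa[4:6]), exit_b = unname(ab[4:6]),
      entry_a = unname(aa[7:9]), entry_b = unname(ab[7:9]),
      end = unname(aa[10:12]))
  }, numeric(18L)))
  rownames(V) <- sub("\r", "->", m$key, fixed = TRUE)
  n <- nrow(V)
  if (identical(k, "auto")) {
    ks <- 4:12; ks <- ks[ks < n]
    if (!length(ks)) stop("too few matched pairs (", n, ") for automatic k")
    sil <- vapply(ks, function(kk) {
      mean_silhouette(seeded_kmeans(V, kk, seed)$cluster, V)
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k > n) stop("k = ", k, " exceeds the number of matched pairs (", n, ")")
  assignment <- if (k == 1L) rep(1L, n) else seeded_kmeans(V, k, seed)$cluster
  pairs_se <- do.call(rbind, strsplit(m$key, "\r", fixed = TRUE))
  bundles <- lapply(seq_len(k), function(b) {
    idx <- which(assignment == b)
    list(id = b,
         pairs = data.frame(start = pairs_se[idx, 1L], end = pairs_se[idx, 2L],
                            stringsAsFactors = FALSE),
         member_idx = idx,
         centroid = colMeans(V[idx, , drop = FALSE]))
  })
  structure(list(bundles = bundles, matched = m, vectors = V,
                 assignment = assignment, k = k),
            class = "two_population_bundles")
}

#' @export
print.two_population_bundles <- function(x, ...) {
  cat(sprintf("<two_population_bundles> %d bundles over %d matched pairs\n",
              x$k, nrow(x$matched)))
  invisible(x)
}

# between/within distance ratio for one bundle's matched pairs, given the
# two populations' path collections (restricted or full)
divergence_statistic <- function(paths_a, paths_b, bundle_pairs) {
  m <- match_paths(paths_a, paths_b)
  key <- paste(bundle_pairs$start, bundle_pairs$end, sep = "\r")
  m <- m[m$key %in% key, , drop = FALSE]
  if (nrow(m) < 1L) return(NA_real_)
  Aa <- t(vapply(m$ia, function(i) paths_a$paths[[i]]$anchors, numeric(12L)))
  Ab <- t(vapply(m$ib, function(i) paths_b$paths[[i]]$anchors, numeric(12L)))
  # between: population-specific trajectory parts (exit, entry) per pair
  between <- mean(sqrt(rowSums((Aa[, 4:9, drop = FALSE] -
                                  Ab[, 4:9, drop = FALSE])^2)))
  within_d <- c(as.numeric(stats::dist(Aa)), as.numeric(stats::dist(Ab)))
  within <- if (length(within_d)) mean(within_d) else 0
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else {
    between / within
  }
}

#' Two-population tractography
#'
#' End-to-end two-population analysis: estimates each population's networks
#' on a shared pooled embedding, computes population-specific interlayer
#' shortest paths, and clusters the matched paths into joint bundles. The
#' returned object retains the panel and group assignment so
#' [bundle_divergence_test()] can rebuild everything under subject
#' permutations.
#'
#' @param panel An `ema_panel`.
#' @param groups Named character vector of "A"/"B" labels by subject id.
#' @param config An [analysis_config()].
#' @param embedding Optional `network_embedding`; default: embedding of the
#'   pooled (all-subject) cross-sectional network.
#' @param k Bundle count passed to [two_population_cluster()]; default
#'   `config$n_bundles`.
#' @return An object of class `bt_two_pop` with `networks_a`, `networks_b`,
#'   `paths_a`, `paths_b`, `bundles`, `embedding` and the inputs.
#' @export
two_population_tractography <- function(panel, groups,
                                        config = analysis_config(),
                                        embedding = NULL,
                                        k = config$n_bundles) {
  stopifnot(inherits(panel, "ema_panel"))
  subj <- unique(panel$data$subject_id)
  groups <- groups[subj]
  if (anyNA(groups) || !all(groups %in% c("A", "B"))) {
    stop("groups must label every panel subject 'A' or 'B'")
  }
  prep <- prepare_panel(panel, config$lag_rule)
  if (is.null(embedding)) {
    pooled <- assemble_network_matrices(
      estimate_edge_matrices(prep, config), config)
    embedding <- embed_network(pooled$cross_sectional, config = config)
  }
  build_side <- function(ids) {
    nets <- assemble_network_matrices(
      estimate_edge_matrices(prep, config, subjects = ids), config)
    mln <- assemble_3d(embedding, nets$multilayer, config$length_transform)
    list(nets = nets, mln = mln, paths = shortest_interlayer_paths(mln))
  }
  a <- build_side(names(groups)[groups == "A"])
  b <- build_side(names(groups)[groups == "B"])
  bundles <- two_population_cluster(a$paths, b$paths, k = k,
                                    seed = config$rng_seed)
  structure(
    list(panel = panel, groups = groups, config = config,
         embedding = embedding, prep = prep,
         networks_a = a$nets, networks_b = b$nets,
         mln_a = a$mln, mln_b = b$mln,
         paths_a = a$paths, paths_b = b$paths, bundles = bundles),
    class = "bt_two_pop"
  )
}

#' @export
print.bt_two_pop <- function(x, ...) {
  cat(sprintf(
    "<bt_two_pop> %d A + %d B subjects; %d/%d paths; %d bundles\n",
    sum(x$groups == "A"), sum(x$groups == "B"),
    length(x$paths_a$paths), length(x$paths_b$paths), x$bundles$k))
  invisible(x)
}

#' Permutation test of a bundle's between-population divergence
#'
#' Observed statistic: the mean Euclidean distance between the two
#' populations' trajectory anchors (exit and entry coordinates) across the
#' bundle's matched (start, end) pairs, divided by the mean within-population
#' pairwise distance among the bundle's path anchor vectors. Each permutation
#' reassigns subjects to populations (preserving group sizes), re-estimates
#' both populations' networks and shortest paths — holding the embedding and
#' the bundle's pair set fixed — and recomputes the statistic; the p-value is
#' the proportion of permuted statistics at least as large as the observed
#' one. Permutations in which no bundle pair is reachable in both permuted
#' populations are excluded (and counted).
#'
#' @param tp A `bt_two_pop` from [two_population_tractography()].
#' @param bundle_id Bundle id to test.
#' @param n_permutations Number of permutations (default
#'   `tp$config$n_permutations`).
#' @param seed Integer seed (default `tp$config$rng_seed`).
#' @return An object of class `divergence_result`: `bundle_id`, `ratio`,
#'   `p`, `n_permutations`, `n_valid`, `perm_stats`, `seed`.
#' @export
bundle_divergence_test <- function(tp, bundle_id,
                                   n_permutations = tp$config$n_permutations,
                                   seed = tp$config$rng_seed) {
  stopifnot(inherits(tp, "bt_two_pop"))
  bundle <- NULL
  for (b in tp$bundles$bundles) if (b$id == bundle_id) bundle <- b
  if (is.null(bundle)) stop("no bundle with id ", bundle_id)
  if (nrow(bundle$pairs) < 2L) stop("bundle has fewer than 2 matched pairs")
  observed <- divergence_statistic(tp$paths_a, tp$paths_b, bundle$pairs)
  subj <- names(tp$groups)
  n_a <- sum(tp$groups == "A")
  config <- tp$config
  pair_tab <- bundle$pairs
  side_paths <- function(ids) {
    nets <- assemble_network_matrices(
      estimate_edge_matrices(tp$prep, config, subjects = ids), config)
    mln <- assemble_3d(tp$embedding, nets$multilayer, config$length_transform)
    shortest_interlayer_paths(mln, pairs = pair_tab)
  }
  perm_stats <- withr::with_seed(seed, vapply(seq_len(n_permutations),
    function(i) {
      perm <- sample(subj)
      pa <- side_paths(perm[seq_len(n_a)])
      pb <- side_paths(perm[-seq_len(n_a)])
      divergence_statistic(pa, pb, pair_tab)
    }, numeric(1)))
  valid <- perm_stats[!is.na(perm_stats)]
  # a permutation p-value needs a usable null sample: when fewer than half
  # the permutations yield a statistic (no bundle pair reachable in both
  # permuted populations), the test is not interpretable for this bundle
  p <- if (length(valid) >= n_permutations / 2) {
    mean(valid >= observed)
  } else {
    warning("only ", length(valid), "/", n_permutations,
            " permutations valid; p-value not interpretable")
    NA_real_
  }
  structure(
    list(bundle_id = bundle_id, ratio = observed, p = p,
         n_permutations = as.integer(n_permutations),
         n_valid = length(valid), perm_stats = perm_stats,
         seed = as.integer(seed)),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(
    "<divergence_result> bundle %d: ratio = %.3f, p = %.3g (%d/%d valid permutations)\n",
    x$bundle_id, x$ratio, x$p, x$n_valid, x$n_permutations))
  invisible(x)
}
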