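# Shared fixtures and independent oracles, all built in code.

# minimal wide panel: one row per completed prompt, given item values
make_test_panel <- function(values, items = names(values[[1]]$scores),
                            prompts_per_day = 8L, days = 6L) {
  rows <- do.call(rbind, lapply(seq_along(values), function(i) {
    v <- values[[i]]
    data.frame(subject_id = v$subject_id, day = v$day, prompt = v$prompt,
               as.list(v$scores), check.names = FALSE)
  }))
  ema_panel(rows, items = items, prompts_per_day = prompts_per_day, days = days)
}

# panel from an obs x item score matrix plus design columns
panel_from_matrix <- function(scores, subject_id, day, prompt,
                              prompts_per_day = 8L, days = 6L) {
  df <- data.frame(subject_id = subject_id, day = day, prompt = prompt,
                   scores, check.names = FALSE)
  ema_panel(df, items = colnames(scores),
            prompts_per_day = prompts_per_day, days = days)
}

# build an mln3d directly from cross/lag weight matrices and coordinates
make_mln <- function(cross, lag, coords = NULL) {
  items <- rownames(cross)
  if (is.null(items)) {
    items <- paste0("I", seq_len(nrow(cross)))
    dimnames(cross) <- dimnames(lag) <- list(items, items)
  }
  k <- length(items)
  lab <- c(paste0(items, "@TL1"), paste0(items, "@TL2"))
  W <- matrix(0, 2 * k, 2 * k, dimnames = list(lab, lab))
  i1 <- seq_len(k); i2 <- k + i1
  W[i1, i1] <- cross; W[i2, i2] <- cross
  W[i1, i2] <- t(lag)
  ml <- network_matrix(W, W != 0, kind = "multilayer", labels = lab)
  if (is.null(coords)) {
    coords <- cbind(x = seq_len(k) / k, y = rev(seq_len(k)) / k)
    rownames(coords) <- items
  }
  emb <- structure(list(coordinates = coords,
                        explained_variance = rep(1 / ncol(coords), ncol(coords)),
                        accuracy_r = NA_real_, accuracy_p = NA_real_),
                   class = "network_embedding")
  assemble_3d(emb, ml)
}

# random sparse multilayer graph on <= 8 items, guaranteed >= 1 lagged edge
random_mln <- function(k, density = 0.5) {
  items <- paste0("I", seq_len(k))
  cross <- matrix(0, k, k, dimnames = list(items, items))
  up <- upper.tri(cross)
  w <- ifelse(stats::runif(sum(up)) < density,
              stats::runif(sum(up), 0.1, 1) *
                sign(stats::runif(sum(up)) - 0.3), 0)
  cross[up] <- w
  cross <- cross + t(cross)
  lag <- matrix(ifelse(stats::runif(k * k) < density,
                       stats::runif(k * k, 0.1, 1), 0),
                k, k, dimnames = list(items, items))
  if (all(lag == 0)) lag[1, 1] <- 0.5
  coords <- cbind(x = stats::runif(k, -1, 1), y = stats::runif(k, -1, 1))
  rownames(coords) <- items
  make_mln(cross, lag, coords)
}

# exhaustive shortest-path oracle: DFS over all simple paths from
# start@TL1 to end@TL2, same tie-breaking (length, hops, lexicographic)
enumerate_shortest <- function(mln, start_item, end_item) {
  e <- mln$edges
  adj <- list()
  adde <- function(a, b, len) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(to = b, len = len))
  }
  for (i in seq_len(nrow(e))) {
    if (e$type[i] == "between") adde(e$from[i], e$to[i], e$length[i])
    else { adde(e$from[i], e$to[i], e$length[i]); adde(e$to[i], e$from[i], e$length[i]) }
  }
  target <- paste0(end_item, "@TL2")
  best <- NULL
  better <- function(cand_len, cand_path) {
    if (is.null(best)) return(TRUE)
    tol <- 1e-9 * (1 + max(abs(cand_len), abs(best$len)))
    if (cand_len < best$len - tol) return(TRUE)
    if (cand_len > best$len + tol) return(FALSE)
    if (length(cand_path) != length(best$path)) {
      return(length(cand_path) < length(best$path))
    }
    for (i in seq_along(cand_path)) {
      if (cand_path[i] != best$path[i]) return(cand_path[i] < best$path[i])
    }
    FALSE
  }
  dfs <- function(node, len, path) {
    if (node == target) {
      if (better(len, path)) best <<- list(len = len, path = path)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$to[i]
      if (nxt %in% path) next
      dfs(nxt, len + nb$len[i], c(path, nxt))
    }
  }
  s <- paste0(start_item, "@TL1")
  dfs(s, 0, s)
  best
}

# synthetic behavioral-path families with controllable anchor centroids
make_path_family <- function(n, center, spread = 0.05, start_items = NULL,
                             prefix = "P") {
  lapply(seq_len(n), function(i) {
    a <- center + stats::rnorm(12, sd = spread)
    a[c(3, 6)] <- 0; a[c(9, 12)] <- 1     # z structure
    nodes <- c(paste0(prefix, i, "a@TL1"), paste0(prefix, i, "b@TL1"),
               paste0(prefix, i, "c@TL2"), paste0(prefix, i, "d@TL2"))
    coords <- matrix(a, 4, 3, byrow = TRUE,
                     dimnames = list(nodes, c("x", "y", "z")))
    ematract:::make_behavioral_path(nodes, coords, total_length = 1)
  })
}

as_paths <- function(plist) {
  structure(list(paths = plist, unreachable = 0L), class = "behavioral_paths")
}

# brute-force optimal single-threshold split for 1-D 2-means
best_threshold_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf; assign <- NULL
  for (m in seq_len(n - 1L)) {
    lo <- xs[seq_len(m)]; hi <- xs[-seq_len(m)]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best - 1e-12) {
      best <- ss
      assign <- x > xs[m] + .Machine$double.eps^0.5 * max(1, abs(xs[m]))
      thr <- (xs[m] + xs[m + 1L]) / 2
      assign <- x > thr
    }
  }
  list(withinss = best, high = assign)
}
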