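test_that("3D assembly instantiates exactly the retained edges", {
  items <- paste0("I", 1:3)
  cross <- matrix(0, 3, 3, dimnames = list(items, items))
  cross[1, 2] <- cross[2, 1] <- 0.5
  lag <- matrix(0, 3, 3, dimnames = list(items, items))
  lag[3, 1] <- 0.25   # I1(t) -> I3(t+1)
  mln <- make_mln(cross, lag)
  expect_equal(nrow(mln$nodes), 6L)
  expect_equal(sum(mln$edges$type == "within_TL1"), 1L)
  expect_equal(sum(mln$edges$type == "within_TL2"), 1L)
  expect_equal(sum(mln$edges$type == "between"), 1L)
  expect_equal(mln$edges$length[mln$edges$weight == 0.5], c(2, 2))
  be <- mln$edges[mln$edges$type == "between", ]
  expect_equal(be$from, "I1@TL1")
  expect_equal(be$to, "I3@TL2")
  expect_equal(be$length, 4)
  # all-zero network: 2k isolated nodes
  empty <- make_mln(cross * 0, lag * 0)
  expect_equal(nrow(empty$nodes), 6L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("a single direct lagged edge gives the degenerate anchor layout", {
  items <- c("A", "B")
  cross <- matrix(0, 2, 2, dimnames = list(items, items))
  lag <- matrix(0, 2, 2, dimnames = list(items, items))
  lag[1, 1] <- 1
  mln <- make_mln(cross, lag)
  paths <- shortest_interlayer_paths(mln)
  expect_length(paths$paths, 1L)
  p <- paths$paths[[1]]
  expect_equal(p$nodes, c("A@TL1", "A@TL2"))
  a <- p$anchors
  expect_equal(a[["start_x"]], a[["exit_x"]])
  expect_equal(a[["entry_x"]], a[["end_x"]])
  expect_equal(unname(a[c("start_z", "exit_z", "entry_z", "end_z")]),
               c(0, 0, 1, 1))
})

test_that("a cheaper detour beats a costly direct lagged edge", {
  items <- c("A", "B")
  cross <- matrix(0, 2, 2, dimnames = list(items, items))
  cross[1, 2] <- cross[2, 1] <- 1          # length 1 within layers
  lag <- matrix(0, 2, 2, dimnames = list(items, items))
  lag[1, 1] <- 1 / 5                       # direct A->A length 5
  lag[2, 2] <- 1                           # B->B length 1
  mln <- make_mln(cross, lag)
  paths <- shortest_interlayer_paths(mln)
  pa <- Filter(function(p) p$start_item == "A" && p$end_item == "A",
               paths$paths)[[1]]
  expect_equal(pa$nodes, c("A@TL1", "B@TL1", "B@TL2", "A@TL2"))
  expect_equal(pa$total_length, 3)
  expect_equal(pa$anchors[["exit_x"]],
               mln$nodes$x[mln$nodes$name == "B@TL1"])
})

test_that("shortest paths agree with exhaustive enumeration on random graphs", {
  set.seed(58)
  for (g in 1:40) {
    k <- sample(3:6, 1)
    mln <- random_mln(k, density = runif(1, 0.3, 0.7))
    paths <- shortest_interlayer_paths(mln)
    got <- stats::setNames(
      lapply(paths$paths, function(p) p),
      vapply(paths$paths, function(p) paste(p$start_item, p$end_item), ""))
    for (i in paste0("I", seq_len(k))) {
      for (j in paste0("I", seq_len(k))) {
        oracle <- enumerate_shortest(mln, i, j)
        mine <- got[[paste(i, j)]]
        if (is.null(oracle)) {
          expect_null(mine)
        } else {
          expect_equal(mine$total_length, oracle$len, tolerance = 1e-9)
          expect_equal(mine$nodes, oracle$path)
        }
      }
    }
  }
})

test_that("scaling all weights rescales lengths but not routes", {
  set.seed(61)
  items <- paste0("I", 1:5)
  cross <- matrix(0, 5, 5, dimnames = list(items, items))
  up <- upper.tri(cross)
  cross[up] <- ifelse(runif(sum(up)) < 0.6, runif(sum(up), 0.2, 1), 0)
  cross <- cross + t(cross)
  lag <- matrix(ifelse(runif(25) < 0.4, runif(25, 0.2, 1), 0), 5, 5,
                dimnames = list(items, items))
  lag[1, 1] <- 0.7
  p1 <- shortest_interlayer_paths(make_mln(cross, lag))
  p2 <- shortest_interlayer_paths(make_mln(3 * cross, 3 * lag))
  expect_equal(length(p1$paths), length(p2$paths))
  for (i in seq_along(p1$paths)) {
    expect_equal(p2$paths[[i]]$nodes, p1$paths[[i]]$nodes)
    expect_equal(p2$paths[[i]]$total_length, p1$paths[[i]]$total_length / 3,
                 tolerance = 1e-9)
  }
})

test_that("anchors read off a constructed multi-hop path", {
  items <- c("A", "B", "C", "D")
  coords <- cbind(x = c(0, 1, 2, 3), y = c(0, -1, 1, 0))
  rownames(coords) <- items
  cross <- matrix(0, 4, 4, dimnames = list(items, items))
  cross[1, 2] <- cross[2, 1] <- 10           # A-B cheap
  cross[3, 4] <- cross[4, 3] <- 10           # C-D cheap
  lag <- matrix(0, 4, 4, dimnames = list(items, items))
  lag[3, 2] <- 10                            # B(t) -> C(t+1) cheap
  mln <- make_mln(cross, lag, coords)
  paths <- shortest_interlayer_paths(mln)
  pd <- Filter(function(p) p$start_item == "A" && p$end_item == "D",
               paths$paths)[[1]]
  expect_equal(pd$nodes, c("A@TL1", "B@TL1", "C@TL2", "D@TL2"))
  a <- pd$anchors
  expect_equal(unname(a[c("start_x", "exit_x", "entry_x", "end_x")]),
               c(0, 1, 2, 3))
  expect_equal(unname(a[c("start_y", "exit_y", "entry_y", "end_y")]),
               c(0, -1, 1, 0))
})

test_that("diffusion directions average successor displacements", {
  p1 <- make_path_family(1, c(0, 0, 0, 1, 0, 0, 1, 0, 1, 2, 0, 1), spread = 0)
  # overwrite nodes so the two paths share the start node
  nodes1 <- c("S@TL1", "M1@TL1", "E1@TL2", "F1@TL2")
  coords1 <- matrix(c(0, 0, 0,  1, 0, 0,  1, 0, 1,  2, 0, 1), 4, 3, byrow = TRUE,
                    dimnames = list(nodes1, c("x", "y", "z")))
  nodes2 <- c("S@TL1", "M2@TL1", "E2@TL2", "F2@TL2")
  coords2 <- matrix(c(0, 0, 0,  0, 1, 0,  0, 1, 1,  0, 2, 1), 4, 3, byrow = TRUE,
                    dimnames = list(nodes2, c("x", "y", "z")))
  paths <- as_paths(list(
    ematract:::make_behavioral_path(nodes1, coords1, 3),
    ematract:::make_behavioral_path(nodes2, coords2, 3)
  ))
  dv <- behavioral_diffusion("S@TL1", paths)
  expect_equal(unname(dv$direction), c(0.5, 0.5, 0))
  expect_equal(dv$n_paths, 2L)
  # terminal node uses predecessor-to-node displacement
  dvt <- behavioral_diffusion("F1@TL2", paths)
  expect_equal(unname(dvt$direction), c(1, 0, 0))
  # untraversed node: zero vector, flagged
  dv0 <- behavioral_diffusion("Nowhere@TL1", paths)
  expect_equal(unname(dv0$direction), c(0, 0, 0))
  expect_true(dv0$flagged)
})

test_that("dz never goes negative over a full pipeline run", {
  cpl <- community_couplings(ema_item_names()[1:6], cross_within = 0.3,
                             lag_self = 0.3, lag_within = 0.1)
  coh <- generate_cohort(generative_spec(
    n_subjects = 30, items = ema_item_names()[1:6],
    cross_coupling = cpl$cross, lag_coupling = cpl$lag, compliance = 1,
    seed = 8))
  res <- behavioral_tractography(coh$panel,
                                 analysis_config(n_bundles = 3, rng_seed = 8))
  expect_true(all(res$diffusion$dz >= 0))
})

test_that("a lagged bottleneck dominates longitudinal betweenness", {
  items <- c("H", "X", "Y", "Z")
  cross <- matrix(0.5, 4, 4, dimnames = list(items, items))
  diag(cross) <- 0
  lag <- matrix(0, 4, 4, dimnames = list(items, items))
  lag[1, 1] <- 0.9               # only H(t) -> H(t+1) crosses layers
  mln <- make_mln(cross, lag)
  paths <- shortest_interlayer_paths(mln)
  expect_length(paths$paths, 16L)
  bt <- longitudinal_betweenness(mln, paths)
  counts <- bt$node_counts
  expect_equal(unname(counts["H@TL1"]), 16L)
  expect_equal(unname(counts["H@TL2"]), 16L)
  expect_true(all(counts["H@TL1"] >= counts))
  # every path touches >= 2 nodes
  expect_gte(sum(counts), 2L * length(paths$paths))
  # the bottleneck edge is traversed by every path
  be <- which(mln$edges$type == "between")
  expect_equal(bt$edge_counts[be], 16L)
  # empty path set: all zeros
  bt0 <- longitudinal_betweenness(mln, as_paths(list()))
  expect_true(all(bt0$node_counts == 0L))
})
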