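test_that("well-separated path families are recovered exactly", {
  skip_if_not_installed("mclust")
  set.seed(64)
  fam1 <- make_path_family(20, c(-1, -1, 0, -1, -1, 0, -1, -1, 1, -1, -1, 1),
                           spread = 0.05, prefix = "A")
  fam2 <- make_path_family(15, c(1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 1),
                           spread = 0.05, prefix = "B")
  paths <- as_paths(c(fam1, fam2))
  bundles <- cluster_bundles(paths, k = 2, seed = 3)
  truth <- rep(1:2, c(20, 15))
  ari <- mclust::adjustedRandIndex(bundles$assignment, truth)
  expect_equal(ari, 1.0)
  # centroid equals the member mean
  b1 <- bundles$bundles[[1]]
  A <- t(vapply(b1$member_paths, function(p) p$anchors, numeric(12)))
  expect_equal(unname(b1$centroid), unname(colMeans(A)), tolerance = 1e-10)
})

test_that("k = 1 collapses to the global mean bundle", {
  set.seed(65)
  paths <- as_paths(make_path_family(8, rep(0.2, 12)))
  bundles <- cluster_bundles(paths, k = 1, seed = 1)
  expect_equal(bundles$k, 1L)
  A <- t(vapply(paths$paths, function(p) p$anchors, numeric(12)))
  expect_equal(unname(bundles$bundles[[1]]$centroid), unname(colMeans(A)))
})

test_that("duplicating every path leaves centroids unchanged", {
  set.seed(66)
  fam1 <- make_path_family(10, rep(-0.8, 12), prefix = "A")
  fam2 <- make_path_family(10, rep(0.8, 12), prefix = "B")
  b1 <- cluster_bundles(as_paths(c(fam1, fam2)), k = 2, seed = 2)
  b2 <- cluster_bundles(as_paths(c(fam1, fam2, fam1, fam2)), k = 2, seed = 2)
  c1 <- do.call(rbind, lapply(b1$bundles, `[[`, "centroid"))
  c2 <- do.call(rbind, lapply(b2$bundles, `[[`, "centroid"))
  expect_equal(c1[order(c1[, 1]), ], c2[order(c2[, 1]), ], tolerance = 1e-8)
})

test_that("bundle labels name start and end quadrants", {
  set.seed(67)
  paths <- as_paths(make_path_family(
    6, c(-1, 1, 0, -1, 1, 0, 1, -1, 1, 1, -1, 1), spread = 0.01))
  b <- cluster_bundles(paths, k = 1, seed = 1)
  expect_equal(b$bundles[[1]]$label, "upper-left -> lower-right")
})

test_that("clustering is deterministic under a fixed seed and k too large fails", {
  set.seed(68)
  paths <- as_paths(make_path_family(9, rep(0, 12), spread = 1))
  b1 <- cluster_bundles(paths, k = 3, seed = 10)
  b2 <- cluster_bundles(paths, k = 3, seed = 10)
  expect_identical(b1$assignment, b2$assignment)
  expect_error(cluster_bundles(paths, k = 20, seed = 1), "exceeds")
})

make_tp_fixture <- function(seed, delta = 0, n_per_group = 14L) {
  items <- ema_item_names()[1:6]
  cpl <- community_couplings(items, cross_within = 0.3, lag_self = 0.3,
                             lag_within = 0.1)
  gd <- matrix(0, 6, 6, dimnames = list(items, items))
  gd[4, 5] <- delta
  spec <- generative_spec(
    n_subjects = 2L * n_per_group, items = items,
    cross_coupling = cpl$cross, lag_coupling = cpl$lag,
    group_coupling_delta = gd, compliance = 1, days = 4, prompts_per_day = 6,
    group_labels = rep(c("A", "B"), each = n_per_group), seed = seed)
  generate_cohort(spec)
}

test_that("identical populations give coincident anchors and small ratios", {
  coh <- make_tp_fixture(201)
  # feed the same subjects' panel as both populations via duplicated ids
  cfg <- analysis_config(n_bundles = 3, n_permutations = 5, rng_seed = 1)
  nets <- build_networks(coh$panel, cfg)
  emb <- embed_network(nets$cross_sectional, config = cfg)
  mln <- assemble_3d(emb, nets$multilayer)
  paths <- shortest_interlayer_paths(mln)
  tpb <- two_population_cluster(paths, paths, k = 3, seed = 1)
  for (b in tpb$bundles) {
    expect_equal(b$centroid[grep("^exit_a", names(b$centroid))],
                 b$centroid[grep("^exit_b", names(b$centroid))],
                 ignore_attr = TRUE)
  }
  # divergence numerator is zero on identical path sets -> p = 1
  stat <- ematract:::divergence_statistic(paths, paths,
                                          tpb$bundles[[1]]$pairs)
  expect_equal(stat, 0)
})

test_that("matched pairs never exceed either population's path count", {
  coh <- make_tp_fixture(202)
  cfg <- analysis_config(n_bundles = 3, rng_seed = 2)
  tp <- two_population_tractography(coh$panel, coh$groups, cfg)
  m <- tp$bundles$matched
  expect_lte(nrow(m), length(tp$paths_a$paths))
  expect_lte(nrow(m), length(tp$paths_b$paths))
  expect_true(all(table(tp$bundles$assignment) >= 1L))
})

test_that("a strong group-specific lagged coupling separates exit/entry anchors", {
  hits <- 0L
  for (s in 1:3) {
    coh <- make_tp_fixture(300 + s, delta = 0.45)
    cfg <- analysis_config(n_bundles = 3, rng_seed = s)
    tp <- two_population_tractography(coh$panel, coh$groups, cfg)
    V <- tp$bundles$vectors
    d_exit <- sqrt(rowSums((V[, 4:6] - V[, 7:9])^2))
    d_entry <- sqrt(rowSums((V[, 10:12] - V[, 13:15])^2))
    if (max(c(d_exit, d_entry)) > 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("divergence permutation test is reproducible and well-formed", {
  coh <- make_tp_fixture(203)
  cfg <- analysis_config(n_bundles = 3, n_permutations = 19, rng_seed = 7)
  tp <- two_population_tractography(coh$panel, coh$groups, cfg)
  dv1 <- bundle_divergence_test(tp, 1)
  dv2 <- bundle_divergence_test(tp, 1)
  expect_identical(dv1$perm_stats, dv2$perm_stats)
  expect_gte(dv1$ratio, 0)
  expect_gte(dv1$p, 0)
  expect_lte(dv1$p, 1)
  # p granularity is 1/n_permutations
  expect_equal(dv1$p * dv1$n_valid, round(dv1$p * dv1$n_valid))
  expect_error(bundle_divergence_test(tp, 99), "no bundle")
})
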