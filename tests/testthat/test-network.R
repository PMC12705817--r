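two_item_panel <- function(records) {
  make_test_panel(records, items = c("Anxiety", "Sadness"))
}

rec <- function(s, d, p, a = 3, sa = 4) {
  list(subject_id = s, day = d, prompt = p, scores = c(Anxiety = a, Sadness = sa))
}

test_that("same-day consecutive pairing: gaps and overnight breaks", {
  # prompts 1,2,3 on one day: two pairs
  p1 <- two_item_panel(list(rec("s", 1, 1), rec("s", 1, 2), rec("s", 1, 3)))
  expect_length(pair_lagged(p1, "Anxiety", "Sadness")$y, 2L)
  # prompts 1 and 3 only: the missed prompt breaks the chain
  p2 <- two_item_panel(list(rec("s", 1, 1), rec("s", 1, 3)))
  expect_error(pair_lagged(p2, "Anxiety", "Sadness"), "no valid lagged pairs")
  # last prompt of day 1 + first of day 2: only any_consecutive pairs them
  p3 <- two_item_panel(list(rec("s", 1, 8), rec("s", 2, 1)))
  expect_error(pair_lagged(p3, "Anxiety", "Sadness", "same_day_consecutive"),
               "no valid lagged pairs")
  expect_length(pair_lagged(p3, "Anxiety", "Sadness", "any_consecutive")$y, 1L)
})

test_that("missing item values drop pairs pairwise", {
  p <- two_item_panel(list(rec("s", 1, 1, a = 3), rec("s", 1, 2, a = 5),
                           rec("s", 1, 3, a = 4)))
  p$data$Sadness[2] <- NA
  got <- pair_lagged(p, "Sadness", "Anxiety")
  expect_length(got$y, 1L)        # only prompt2 -> prompt3 has y non-missing
  expect_equal(got$x, 5)
  expect_equal(got$y, 4)
})

test_that("BH step-up retention follows the standard rule", {
  expect_equal(bh_fdr_mask(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_equal(bh_fdr_mask(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_true(bh_fdr_mask(0.049, 0.05))
  expect_equal(bh_fdr_mask(numeric(0), 0.05), logical(0))
  # monotone in q: lowering q never retains more
  set.seed(12)
  p <- runif(50)^2
  m1 <- bh_fdr_mask(p, 0.05)
  m2 <- bh_fdr_mask(p, 0.01)
  expect_true(all(m1[m2]))
})

test_that("networks have the expected block structure and symmetry", {
  cpl <- community_couplings(ema_item_names()[1:6], cross_within = 0.3,
                             lag_self = 0.3)
  coh <- generate_cohort(generative_spec(
    n_subjects = 30, items = ema_item_names()[1:6],
    cross_coupling = cpl$cross, lag_coupling = cpl$lag, compliance = 1,
    seed = 5))
  nets <- build_networks(coh$panel, analysis_config())
  W <- nets$cross_sectional$weights
  expect_equal(W, t(W))
  expect_true(all(W[!nets$cross_sectional$mask] == 0))
  k <- 6L
  ML <- nets$multilayer$weights
  expect_equal(dim(ML), c(2 * k, 2 * k))
  i1 <- seq_len(k); i2 <- k + i1
  expect_equal(ML[i1, i1], ML[i2, i2], ignore_attr = TRUE)
  expect_equal(unname(ML[i1, i1]), unname(W))
  expect_true(all(ML[i2, i1] == 0))          # TL2 -> TL1 structurally zero
  expect_equal(unname(ML[i1, i2]), unname(t(nets$lagged$weights)))
})

test_that("a single strong contemporaneous coupling is recovered selectively", {
  items <- ema_item_names()[1:5]
  hits <- other <- 0L
  for (s in 1:5) {
    cross <- matrix(0, 5, 5, dimnames = list(items, items))
    cross[1, 2] <- cross[2, 1] <- 0.6
    coh <- generate_cohort(generative_spec(
      n_subjects = 60, items = items, cross_coupling = cross,
      compliance = 1, seed = 100 + s))
    nets <- build_networks(coh$panel, analysis_config())
    M <- nets$cross_sectional$mask
    hits <- hits + M[1, 2]
    other <- other + (sum(M) - 2 * M[1, 2]) / 2
  }
  expect_equal(hits, 5L)          # the true edge is found in every seed
  expect_lte(other / 5, 0.5)      # on average at most half a false edge
})

test_that("lagged slope scaling: weights double when couplings strengthen", {
  # structural sanity on the directed lagged matrix orientation: the
  # generative effect item1(t-1) -> item2(t) must land in row item2, col item1
  items <- ema_item_names()[1:4]
  lag <- matrix(0, 4, 4, dimnames = list(items, items))
  lag[2, 1] <- 0.5
  coh <- generate_cohort(generative_spec(
    n_subjects = 60, items = items, lag_coupling = lag, compliance = 1,
    seed = 42))
  nets <- build_networks(coh$panel, analysis_config())
  L <- nets$lagged$weights
  expect_gt(L[2, 1], 0.25)
  expect_equal(sum(abs(L) > 0.25), 1L)
  # and the multilayer between block carries it as TL1 item1 -> TL2 item2
  ML <- nets$multilayer$weights
  expect_equal(ML["Lacking-Relaxation@TL1", "Loneliness@TL2"], L[2, 1])
})

test_that("moderation matrices mask non-significant interactions to zero", {
  items <- ema_item_names()[1:4]
  lag <- matrix(0, 4, 4, dimnames = list(items, items))
  coh <- generate_cohort(generative_spec(
    n_subjects = 24, items = items, compliance = 1,
    group_labels = rep(c("A", "B"), 12), seed = 77))
  subj <- unique(coh$panel$data$subject_id)
  sc <- stats::setNames(rnorm(length(subj)), subj)
  mm <- moderation_matrices(coh$panel, sc, analysis_config())
  expect_true(all(mm$cross_sectional$weights[!mm$cross_sectional$mask] == 0))
  expect_true(all(mm$lagged$weights[!mm$lagged$mask] == 0))
  expect_equal(nrow(mm$node_effects), 4L)
})

test_that("network_matrix rejects inconsistent weight/mask pairs", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_error(network_matrix(W, matrix(FALSE, 2, 2), "cross_sectional"),
               "nonzero weight")
  asym <- matrix(c(0, 1, 0, 0), 2)
  expect_error(network_matrix(asym, asym != 0, "cross_sectional"), "symmetric")
})
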