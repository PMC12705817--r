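sips_from_matrix <- function(m) {
  sips_table(data.frame(subject_id = sprintf("s%03d", seq_len(nrow(m))), m,
                        check.names = FALSE))
}

test_that("rare-item filter drops items endorsed in <= 10% of subjects", {
  n <- 68L
  m <- matrix(0L, n, 3,
              dimnames = list(NULL, c("common", "boundary", "rare")))
  m[1:40, "common"] <- 2L
  m[1:7, "boundary"] <- 1L   # 7/68 = 10.3% > 10%: retained (strict >)
  m[1:6, "rare"] <- 1L       # 6/68 = 8.8%: dropped
  out <- filter_rare_items(sips_from_matrix(m), 0.10)
  expect_setequal(out$items, c("common", "boundary"))
  expect_equal(out$dropped_items, "rare")
  all_zero <- matrix(0L, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(filter_rare_items(sips_from_matrix(all_zero)), "all items dropped")
})

test_that("PCA explained variances equal covariance eigenvalue fractions", {
  set.seed(11)
  m <- matrix(sample(0:6, 20 * 6, TRUE), 20, 6,
              dimnames = list(NULL, paste0("it", 1:6)))
  dm <- fit_sips_pca(sips_from_matrix(m), threshold = 0.10)
  ev <- eigen(cov(m), symmetric = TRUE)$values
  expect_equal(dm$explained_variance, ev / sum(ev), tolerance = 1e-10)
  expect_equal(dm$retained, sum(ev / sum(ev) > 0.10))
  # reconstruction with all components reproduces the centered data
  recon <- dm$scores %*% t(dm$loadings)
  centered <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("rank-1 data put all variance on component 1, oriented positive", {
  m <- cbind(a = c(0, 1, 2, 3, 4, 5), b = c(0, 2, 4, 6, 6, 6) * 0L)
  m[, "b"] <- m[, "a"]  # perfectly correlated pair
  dm <- fit_sips_pca(sips_from_matrix(m), threshold = 0.10)
  expect_equal(dm$explained_variance[1], 1, tolerance = 1e-12)
  expect_gt(mean(dm$loadings[, 1]), 0)
})

test_that("retention threshold is strict and counts all qualifying components", {
  # construct data with known variance fractions straddling the threshold
  set.seed(4)
  base <- matrix(rnorm(300 * 4), 300, 4) %*% diag(c(6, 1.55, 0.9, 0.4))
  m <- round(base + 3)
  m[m < 0] <- 0; m[m > 6] <- 6
  colnames(m) <- paste0("it", 1:4)
  dm <- fit_sips_pca(sips_from_matrix(m), threshold = 0.10)
  frac <- dm$explained_variance
  expect_equal(dm$retained, sum(frac > 0.10))
  expect_gte(dm$retained, 2L)
})

test_that("1-D k-means equals the best single-threshold split", {
  set.seed(23)
  for (rep in 1:5) {
    x <- c(rnorm(120, -1), rnorm(80, 1.5, 0.8))
    names(x) <- paste0("s", seq_along(x))
    sg <- assign_subgroups(x, k = 2, seed = rep)
    oracle <- best_threshold_split(x)
    expect_equal(unname(sg$labels == "high"), unname(oracle$high))
  }
})

test_that("subgroup labels follow centroid order and sizes are sane", {
  x <- c(a = -1, b = -1, c = -1, d = 5, e = 5)
  sg <- assign_subgroups(x, k = 2, seed = 1)
  expect_equal(unname(sg$sizes), c(3L, 2L))
  expect_equal(unname(sg$labels[c("d", "e")]), c("high", "high"))
  expect_error(assign_subgroups(rep(1, 10), k = 2, seed = 1), "distinct")
  # sign flip exchanges labels but not the partition
  sg2 <- assign_subgroups(-x, k = 2, seed = 1)
  expect_equal(unname(sg2$labels == "low"), unname(sg$labels == "high"))
})

test_that("uncorrected 2x2 chi-square reproduces tabulated group contrasts", {
  # psychotic disorders: 0/52 vs 4/12
  expect_equal(round(chi_square_2x2(rbind(c(0, 52), c(4, 12)))$statistic, 2), 13.81)
  # ADHD: 30/22 vs 11/5
  expect_equal(round(chi_square_2x2(rbind(c(30, 22), c(11, 5)))$statistic, 2), 0.62)
  # gender M/F splits: 27/25 vs 10/6 and 21/12 vs 16/19
  expect_equal(round(chi_square_2x2(rbind(c(27, 25), c(10, 6)))$statistic, 2), 0.55)
  expect_equal(round(chi_square_2x2(rbind(c(21, 12), c(16, 19)))$statistic, 2), 2.20)
  # identical rows give zero
  expect_equal(chi_square_2x2(rbind(c(9, 4), c(9, 4)))$statistic, 0)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("chi-square is invariant to row/column swaps and transposition", {
  tab <- rbind(c(21, 31), c(10, 6))
  s <- chi_square_2x2(tab)$statistic
  expect_equal(chi_square_2x2(tab[2:1, ])$statistic, s)
  expect_equal(chi_square_2x2(tab[, 2:1])$statistic, s)
  expect_equal(chi_square_2x2(t(tab))$statistic, s)
})

test_that("pooled t from summaries matches tabulated values and raw-vector calls", {
  t_age <- two_sample_t(c(mean = 19.48, sd = 5.17, n = 52),
                        c(mean = 18.88, sd = 5.36, n = 16))
  expect_equal(round(t_age$statistic, 2), 0.40)
  t_ema <- two_sample_t(c(mean = 25.62, sd = 11.23, n = 52),
                        c(mean = 25.06, sd = 9.92, n = 16))
  expect_equal(round(t_ema$statistic, 2), 0.18)
  expect_equal(two_sample_t(c(mean = 1, sd = 1, n = 5),
                            c(mean = 1, sd = 1, n = 5))$statistic, 0)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # raw-vector call agrees with t.test's pooled variant
  set.seed(2)
  a <- rnorm(20); b <- rnorm(15, 0.5)
  mine <- two_sample_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("item intensity correlations hit r = 1 on perfectly aligned means", {
  subj <- sprintf("s%02d", 1:10)
  rows <- lapply(seq_along(subj), function(i) {
    list(subject_id = subj[i], day = 1, prompt = 1,
         scores = c(Anxiety = i %% 7 + 1, Sadness = 4))
  })
  panel <- make_test_panel(rows)
  scores <- sapply(seq_along(subj), function(i) i %% 7 + 1)
  names(scores) <- subj
  res <- correlate_item_intensity(panel, scores)
  expect_equal(res$r[res$item == "Anxiety"], 1, tolerance = 1e-12)
  # constant item has undefined correlation and is flagged NA
  expect_true(is.na(res$r[res$item == "Sadness"]))
})

test_that("permuted scores give near-zero mean correlation", {
  set.seed(71)
  coh <- generate_cohort(generative_spec(n_subjects = 30, seed = 17))
  subj <- unique(coh$panel$data$subject_id)
  base <- rnorm(length(subj)); names(base) <- subj
  rs <- replicate(100, {
    perm <- sample(base); names(perm) <- subj
    correlate_item_intensity(coh$panel, perm)$r[1]
  })
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("observation-level subgroup t-tests are reported per item", {
  coh <- generate_cohort(generative_spec(n_subjects = 20, seed = 29))
  subj <- unique(coh$panel$data$subject_id)
  sc <- stats::setNames(rnorm(length(subj)), subj)
  sg <- assign_subgroups(sc, k = 2, seed = 5)
  res <- correlate_item_intensity(coh$panel, sc, subgroups = sg)
  expect_true(all(c("t", "t_p", "mean_1", "mean_2") %in% names(res)))
  expect_true(all(is.finite(res$t[!is.na(res$t)])))
  expect_equal(nrow(res), length(coh$panel$items))
})
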