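#' Drop rarely endorsed clinical items
#'
#' Retains items endorsed (non-zero) in strictly more than
#' `min_nonzero_fraction` of subjects; this is the screen under which the
#' rarely reported Grandiosity item is excluded from the 0--6 interview table.
#'
#' @param sips A `sips_table`.
#' @param min_nonzero_fraction Threshold in (0, 1); default 0.10.
#' @return A `sips_table` with the surviving items; dropped names recorded in
#'   `$dropped_items`.
#' @export
filter_rare_items <- function(sips, min_nonzero_fraction = 0.10) {
  stopifnot(inherits(sips, "sips_table"),
            min_nonzero_fraction > 0, min_nonzero_fraction < 1)
  rate <- vapply(sips$items, function(it) {
    v <- sips$data[[it]]
    mean(v != 0, na.rm = TRUE)
  }, numeric(1))
  keep <- rate > min_nonzero_fraction
  if (!any(keep)) stop("all items dropped by the rare-item filter")
  out <- sips_table(sips$data[, c("subject_id", sips$items[keep]), drop = FALSE],
                    items = sips$items[keep])
  out$dropped_items <- sips$items[!keep]
  out
}

#' Principal component analysis of clinical item scores
#'
#' Mean-centered (by default unscaled, i.e. covariance-matrix) PCA of the
#' subjects x items score matrix. Components are ordered by explained
#' variance; a component is retained when its variance fraction strictly
#' exceeds `threshold`. Sign convention: component 1 is oriented so its mean
#' loading is positive (a severity dimension loads positively on every item);
#' each later component is oriented so its largest-magnitude loading is
#' positive.
#'
#' @param sips A `sips_table`.
#' @param threshold Variance-fraction retention threshold (default 0.10).
#' @param scale. Standardize items first (correlation-matrix PCA);
#'   default FALSE.
#' @return An object of class `dimension_model`: `loadings` (items x
#'   components), `explained_variance`, `scores` (subjects x components,
#'   rownames = subject ids), `retained`, `center`.
#' @export
fit_sips_pca <- function(sips, threshold = 0.10, scale. = FALSE) {
  stopifnot(inherits(sips, "sips_table"))
  X <- as.matrix(sips$data[, sips$items, drop = FALSE])
  rownames(X) <- sips$data$subject_id
  if (nrow(X) < 3L) stop("need at least 3 subjects")
  vars <- apply(X, 2L, stats::var)
  if (sum(vars > 0) < 2L) stop("need at least 2 items with nonzero variance")
  if (scale.) {
    keep <- vars > 0
    if (!all(keep)) X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  # orient components deterministically
  flip <- rep(1, ncol(pc$rotation))
  if (mean(pc$rotation[, 1L]) < 0) flip[1L] <- -1
  for (j in seq_len(ncol(pc$rotation))[-1L]) {
    top <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[top, j] < 0) flip[j] <- -1
  }
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  structure(
    list(loadings = loadings, explained_variance = frac, scores = scores,
         retained = sum(frac > threshold), center = pc$center,
         scaled = scale., scale = if (scale.) pc$scale else NULL),
    class = "dimension_model"
  )
}

#' @export
print.dimension_model <- function(x, ...) {
  cat(sprintf("<dimension_model> %d components retained (variance fractions: %s)\n",
              x$retained,
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Split subjects into subgroups by 1-D k-means on a component score
#'
#' K-means (50 restarts, best within-cluster sum of squares) on one dimension
#' of the clinical component scores. Groups are relabeled by ascending
#' centroid, so the higher-centroid group always gets the second label.
#'
#' @param scores Named numeric vector of per-subject component scores.
#' @param k Number of subgroups (default 2).
#' @param seed Integer seed making the restarts deterministic.
#' @param labels Group labels by ascending centroid; default
#'   `c("low", "high")` (use e.g. `c("neg", "pos")` for a signed contrast
#'   dimension).
#' @return An object of class `subgroup_assignment`: `labels` (named by
#'   subject), `centroids` (ascending), `sizes`.
#' @export
assign_subgroups <- function(scores, k = 2L, seed = 1L,
                             labels = c("low", "high")) {
  stopifnot(is.numeric(scores), k >= 2L, length(scores) > k)
  if (length(unique(scores)) < k) {
    stop("fewer distinct score values (", length(unique(scores)),
         ") than k = ", k)
  }
  if (length(labels) != k) labels <- paste0("g", seq_len(k))
  km <- withr::with_seed(seed,
    stats::kmeans(matrix(scores, ncol = 1L), centers = k, nstart = 50L))
  ord <- order(km$centers[, 1L])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  grp <- labels[relabel[km$cluster]]
  names(grp) <- names(scores)
  structure(
    list(labels = grp, centroids = sort(km$centers[, 1L]),
         sizes = stats::setNames(as.integer(table(factor(grp, levels = labels))),
                                 labels),
         tot_withinss = km$tot.withinss),
    class = "subgroup_assignment"
  )
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("<subgroup_assignment> sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      sprintf("; centroids: %s\n", paste(round(x$centroids, 3), collapse = ", ")))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Computes the uncorrected Pearson chi-square statistic (no Yates continuity
#' correction) with a 1-df p-value. The uncorrected statistic is what
#' reproduces standard categorical group comparisons on comorbidity counts.
#'
#' @param tab A 2x2 matrix of nonnegative integer counts.
#' @return An object of class `group_comparison`: `kind = "chi2_2x2"`,
#'   `statistic`, `p`, `table`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(0, 4, 52, 12), 2))$statistic  # 13.81
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  stat <- num / den
  structure(
    list(kind = "chi2_2x2", statistic = stat,
         p = stats::pchisq(stat, df = 1L, lower.tail = FALSE), table = tab),
    class = "group_comparison"
  )
}

#' Pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance, computable either from raw vectors
#' or from printed summary statistics `c(mean = , sd = , n = )` — the form in
#' which demographic comparisons are tabulated.
#'
#' @param a,b Either numeric data vectors, or named numeric vectors
#'   `c(mean = , sd = , n = )`.
#' @return An object of class `group_comparison`: `kind = "two_sample_t"`,
#'   `statistic` (t, group a minus group b), `p` (two-sided), `df`,
#'   `group_summaries`.
#' @export
#' @examples
#' two_sample_t(c(mean = 19.48, sd = 5.17, n = 52),
#'              c(mean = 18.88, sd = 5.36, n = 16))$statistic  # 0.40
two_sample_t <- function(a, b) {
  summ <- function(v) {
    if (!is.null(names(v)) && all(c("mean", "sd", "n") %in% names(v))) {
      list(mean = unname(v[["mean"]]), sd = unname(v[["sd"]]), n = unname(v[["n"]]))
    } else {
      v <- v[!is.na(v)]
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  sa <- summ(a); sb <- summ(b)
  stopifnot(sa$n >= 2, sb$n >= 2, sa$sd >= 0, sb$sd >= 0)
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  tstat <- if (se == 0) {
    if (sa$mean == sb$mean) 0 else sign(sa$mean - sb$mean) * Inf
  } else {
    (sa$mean - sb$mean) / se
  }
  structure(
    list(kind = "two_sample_t", statistic = tstat, df = df,
         p = 2 * stats::pt(-abs(tstat), df = df),
         group_summaries = list(a = sa, b = sb)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.3f, p = %.3g\n",
              x$kind, x$statistic, x$p))
  invisible(x)
}

#' Associate average momentary item intensity with a clinical dimension
#'
#' For each EMA item: the Pearson correlation (with two-sided p) between each
#' subject's mean item intensity and the subject's clinical component score;
#' and, if a subgroup assignment is supplied, an observation-level pooled
#' two-sample t-test of item intensity across the two subgroups (all prompts
#' pooled; this mirrors how tabulated intensity contrasts are computed, and
#' knowingly treats repeated observations per subject as independent — see
#' the methods vignette).
#'
#' @param panel An `ema_panel`.
#' @param scores Named numeric vector of per-subject component scores.
#' @param subgroups Optional `subgroup_assignment` (2 groups).
#' @return A data.frame with one row per item: `item`, `r`, `p`,
#'   `n_subjects`, per-group mean/sd, `t`, `t_p` (NA without subgroups).
#'   Items with zero variance across subject means are flagged with `NA`.
#' @export
correlate_item_intensity <- function(panel, scores, subgroups = NULL) {
  stopifnot(inherits(panel, "ema_panel"))
  common <- intersect(names(scores), unique(panel$data$subject_id))
  if (length(common) < 3L) stop("need >= 3 subjects with both panel data and scores")
  dat <- panel$data[panel$data$subject_id %in% common, , drop = FALSE]
  grp <- NULL
  if (!is.null(subgroups)) {
    stopifnot(inherits(subgroups, "subgroup_assignment"))
    grp <- subgroups$labels[dat$subject_id]
    glev <- names(subgroups$sizes)
    if (length(glev) != 2L) stop("observation-level t-test needs exactly 2 subgroups")
  }
  rows <- lapply(panel$items, function(it) {
    v <- dat[[it]]
    sm <- tapply(v, dat$subject_id, mean, na.rm = TRUE)
    sm <- sm[!is.nan(sm)]
    sc <- scores[names(sm)]
    row <- data.frame(item = it, r = NA_real_, p = NA_real_,
                      n_subjects = length(sm),
                      mean_1 = NA_real_, sd_1 = NA_real_,
                      mean_2 = NA_real_, sd_2 = NA_real_,
                      t = NA_real_, t_p = NA_real_)
    if (stats::sd(sm) > 0 && stats::sd(sc) > 0) {
      ct <- stats::cor.test(sm, sc)
      row$r <- unname(ct$estimate); row$p <- ct$p.value
    }
    if (!is.null(grp)) {
      glev <- names(subgroups$sizes)
      v1 <- v[grp == glev[1L] & !is.na(v)]
      v2 <- v[grp == glev[2L] & !is.na(v)]
      row$mean_1 <- mean(v1); row$sd_1 <- stats::sd(v1)
      row$mean_2 <- mean(v2); row$sd_2 <- stats::sd(v2)
      if (length(v1) >= 2L && length(v2) >= 2L) {
        tt <- two_sample_t(v1, v2)
        row$t <- tt$statistic; row$t_p <- tt$p
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
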