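#' Benjamini-Hochberg retention mask
#'
#' Standard step-up false-discovery-rate procedure at level `q` over one
#' family of p-values; `TRUE` marks retained (significant) entries.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` treated as 1).
#' @param q FDR level.
#' @return Logical vector, same length as `p_values`.
#' @export
#' @examples
#' bh_fdr_mask(c(0.01, 0.02, 0.03, 0.04), 0.05)  # all TRUE
bh_fdr_mask <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p <- ifelse(is.na(p_values), 1, p_values)
  stats::p.adjust(p, method = "BH") <= q
}

#' Construct a network matrix
#'
#' @param weights Square numeric matrix of edge weights (0 = absent).
#' @param mask Logical significance matrix, same shape; weights must be 0
#'   wherever `mask` is `FALSE`.
#' @param kind One of `"cross_sectional"`, `"lagged"`, `"multilayer"`.
#' @param p Optional matrix of p-values.
#' @param labels Node labels; default from `rownames(weights)`.
#' @return An object of class `network_matrix`.
#' @export
network_matrix <- function(weights, mask,
                           kind = c("cross_sectional", "lagged", "multilayer"),
                           p = NULL, labels = rownames(weights)) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == ncol(weights), is.logical(mask),
            all(dim(mask) == dim(weights)))
  if (any(weights[!mask] != 0)) stop("nonzero weight where mask is FALSE")
  if (kind == "cross_sectional" &&
      !isTRUE(all.equal(weights, t(weights), tolerance = 1e-10))) {
    stop("cross-sectional weights must be symmetric")
  }
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(weights)))
  dimnames(weights) <- dimnames(mask) <- list(labels, labels)
  if (!is.null(p)) dimnames(p) <- list(labels, labels)
  structure(list(kind = kind, weights = weights, mask = mask, p = p,
                 labels = labels),
            class = "network_matrix")
}

#' @export
print.network_matrix <- function(x, ...) {
  cat(sprintf("<network_matrix> %s, %d nodes, %d retained edges\n",
              x$kind, nrow(x$weights), sum(x$mask)))
  invisible(x)
}

#' Write a network matrix to labeled CSV files
#'
#' Writes `<prefix>_weights.csv`, `<prefix>_mask.csv` and (if present)
#' `<prefix>_p.csv`, each with row/column item labels.
#'
#' @param net A `network_matrix`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths written.
#' @export
write_network_matrix <- function(net, prefix) {
  paths <- c(weights = paste0(prefix, "_weights.csv"),
             mask = paste0(prefix, "_mask.csv"))
  utils::write.csv(net$weights, paths[["weights"]])
  utils::write.csv(net$mask * 1L, paths[["mask"]])
  if (!is.null(net$p)) {
    paths <- c(paths, p = paste0(prefix, "_p.csv"))
    utils::write.csv(net$p, paths[["p"]])
  }
  invisible(paths)
}

# ---- internal: panel preparation shared by all edge loops -------------------

# Returns the item matrix, subject vector, and lagged row-index pairs under
# the configured rule. Pairing uses (day, prompt) indices: under
# same_day_consecutive, prompt t is paired with prompt t+1 of the same day
# only when both were completed (a skipped prompt breaks the chain); under
# any_consecutive, adjacent completed prompts are paired across gaps and
# day boundaries.
prepare_panel <- function(panel, lag_rule = "same_day_consecutive") {
  d <- panel$data
  M <- as.matrix(d[, panel$items, drop = FALSE])
  subject <- d$subject_id
  n <- nrow(d)
  same_subj <- subject[-1L] == subject[-n]
  if (lag_rule == "same_day_consecutive") {
    ok <- same_subj & d$day[-1L] == d$day[-n] & d$prompt[-1L] == d$prompt[-n] + 1L
  } else {
    ok <- same_subj
  }
  t0 <- which(ok)
  list(M = M, subject = subject, items = panel$items,
       lag_from = t0, lag_to = t0 + 1L)
}

#' Paired observations for a time-lagged edge
#'
#' Extracts (x at prompt t, y at prompt t+1) pairs for two items under the
#' consecutive-prompt rule: `"same_day_consecutive"` (default) pairs prompts
#' `t` and `t+1` of the same day only when both were completed — a missed
#' intermediate prompt breaks the pair and overnight transitions are
#' excluded; `"any_consecutive"` pairs adjacent completed prompts regardless
#' of gaps or day boundaries.
#'
#' @param panel An `ema_panel`.
#' @param item_y Outcome item (measured at t+1).
#' @param item_x Predictor item (measured at t).
#' @param rule Lag rule.
#' @return List with numeric `y`, `x` and character `subject_ids`, aligned.
#' @export
pair_lagged <- function(panel, item_y, item_x,
                        rule = c("same_day_consecutive", "any_consecutive")) {
  rule <- match.arg(rule)
  stopifnot(item_y %in% panel$items, item_x %in% panel$items)
  prep <- prepare_panel(panel, rule)
  x <- prep$M[prep$lag_from, item_x]
  y <- prep$M[prep$lag_to, item_y]
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) stop("no valid lagged pairs for (", item_y, ", ", item_x, ")")
  list(y = unname(y[keep]), x = unname(x[keep]),
       subject_ids = prep$subject[prep$lag_from][keep])
}

# z-score each item column over its pooled non-missing observations
zscore_items <- function(M) {
  mu <- colMeans(M, na.rm = TRUE)
  sdv <- apply(M, 2L, stats::sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  sweep(sweep(M, 2L, mu, `-`), 2L, sdv, `/`)
}

# items usable in the edge loops: >= 3 distinct pooled values, except binary
# {0,1} context items which are kept with both levels present
usable_items <- function(M, items) {
  ok <- vapply(items, function(it) {
    v <- M[, it]; v <- v[!is.na(v)]
    u <- unique(v)
    length(u) >= 3L ||
      (it %in% binary_ema_items() && length(u) == 2L && all(u %in% c(0, 1)))
  }, logical(1))
  if (!all(ok)) {
    warning("dropping item(s) with too few distinct values: ",
            paste(items[!ok], collapse = ", "))
  }
  items[ok]
}

# core edge loops over a (possibly subject-subset) prepared panel.
# moderator: optional named per-subject score (z-scored at subject level here).
estimate_edge_matrices <- function(prep, config, subjects = NULL,
                                   moderator = NULL) {
  keep_row <- if (is.null(subjects)) rep(TRUE, nrow(prep$M)) else
    prep$subject %in% subjects
  M <- prep$M[keep_row, , drop = FALSE]
  subject <- prep$subject[keep_row]
  items <- usable_items(M, prep$items)
  k <- length(items)
  if (k < 2L) stop("fewer than 2 usable items")
  Z <- zscore_items(M[, items, drop = FALSE])

  mod_obs <- NULL
  if (!is.null(moderator)) {
    ms <- moderator[unique(subject)]
    if (anyNA(ms)) stop("moderator score missing for some subject(s)")
    if (stats::sd(ms) == 0) stop("moderator is constant across subjects")
    zs <- (moderator - mean(ms)) / stats::sd(ms)
    mod_obs <- unname(zs[subject])
  }

  fit_one <- function(y, x, subj, s = NULL) {
    ok <- !is.na(y) & !is.na(x)
    y <- y[ok]; x <- x[ok]; subj <- subj[ok]
    if (length(y) < 8L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(NA_real_, NA_real_))
    }
    X <- if (is.null(s)) cbind(1, x) else {
      s <- s[ok]; cbind(1, x, s, x * s)
    }
    fit <- tryCatch(fit_lmm_ranint(y, X, subj), error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    j <- ncol(X)  # reported coefficient: slope, or interaction when moderated
    if (is.null(s)) j <- 2L
    c(fit$beta[j], fit$p[j])
  }

  beta_cs <- p_cs <- matrix(NA_real_, k, k, dimnames = list(items, items))
  for (yi in seq_len(k)) {
    for (xi in seq_len(k)) {
      if (xi == yi) next
      est <- fit_one(Z[, yi], Z[, xi], subject, mod_obs)
      beta_cs[yi, xi] <- est[1L]; p_cs[yi, xi] <- est[2L]
    }
  }

  lf <- prep$lag_from[keep_row[prep$lag_from] & keep_row[prep$lag_to]]
  lt <- lf + 1L
  # map absolute row indices into the subset
  row_map <- cumsum(keep_row)
  Zl_from <- Z[row_map[lf], , drop = FALSE]
  Zl_to <- Z[row_map[lt], , drop = FALSE]
  subj_l <- prep$subject[lf]
  mod_l <- if (is.null(mod_obs)) NULL else mod_obs[row_map[lf]]
  beta_lag <- p_lag <- matrix(NA_real_, k, k, dimnames = list(items, items))
  for (yi in seq_len(k)) {
    for (xi in seq_len(k)) {
      est <- fit_one(Zl_to[, yi], Zl_from[, xi], subj_l, mod_l)
      beta_lag[yi, xi] <- est[1L]; p_lag[yi, xi] <- est[2L]
    }
  }
  list(items = items, beta_cs = beta_cs, p_cs = p_cs,
       beta_lag = beta_lag, p_lag = p_lag)
}

# FDR-prune and assemble network_matrix objects from raw edge matrices
assemble_network_matrices <- function(est, config) {
  items <- est$items
  k <- length(items)
  off <- !diag(k)
  mask_cs_dir <- matrix(FALSE, k, k)
  mask_cs_dir[off] <- bh_fdr_mask(est$p_cs[off], config$fdr_q)
  D <- est$beta_cs
  D[!mask_cs_dir | is.na(D)] <- 0
  W_cs <- (D + t(D)) / 2              # zero counts as zero in the average
  mask_cs <- mask_cs_dir | t(mask_cs_dir)
  W_cs[!mask_cs] <- 0

  mask_lag <- matrix(bh_fdr_mask(as.vector(est$p_lag), config$fdr_q), k, k)
  W_lag <- est$beta_lag
  W_lag[!mask_lag | is.na(W_lag)] <- 0

  cross <- network_matrix(W_cs, mask_cs, kind = "cross_sectional",
                          p = est$p_cs, labels = items)
  lagged <- network_matrix(W_lag, mask_lag, kind = "lagged",
                           p = est$p_lag, labels = items)

  lab_ml <- c(paste0(items, "@TL1"), paste0(items, "@TL2"))
  W_ml <- matrix(0, 2 * k, 2 * k, dimnames = list(lab_ml, lab_ml))
  M_ml <- matrix(FALSE, 2 * k, 2 * k, dimnames = list(lab_ml, lab_ml))
  i1 <- seq_len(k); i2 <- k + i1
  W_ml[i1, i1] <- W_cs;  M_ml[i1, i1] <- mask_cs
  W_ml[i2, i2] <- W_cs;  M_ml[i2, i2] <- mask_cs
  W_ml[i2, i1] <- 0                    # structurally zero TL2 -> TL1 block
  # TL1 -> TL2 block: rows TL1 sources, columns TL2 targets; lagged weight
  # for predictor item i (at t) on outcome item j (at t+1) sits at [i, j]
  W_ml[i1, i2] <- t(W_lag); M_ml[i1, i2] <- t(mask_lag)
  multilayer <- network_matrix(W_ml, M_ml, kind = "multilayer", labels = lab_ml)

  list(cross_sectional = cross, lagged = lagged, multilayer = multilayer)
}

#' Estimate the cross-sectional, lagged and multilayer networks
#'
#' For every ordered item pair, fits the random-intercept mixed model on
#' pooled-z-scored observations — contemporaneously for the cross-sectional
#' network and across consecutive same-day prompts for the lagged network —
#' then prunes each matrix kind as one FDR family (k(k-1) ordered
#' cross-sectional pairs; k^2 lagged pairs including self-lags) at
#' `config$fdr_q`. The cross-sectional matrix is symmetrized as the mean of
#' the two retained directional slopes (zero counting as zero). The
#' multilayer matrix places the symmetrized cross-sectional weights in both
#' temporal-layer diagonal blocks and the lagged weights in the TL1-to-TL2
#' block; the TL2-to-TL1 block is structurally zero.
#'
#' Items with fewer than 3 distinct pooled values are dropped with a warning
#' (binary 0/1 context items with both levels present are kept).
#'
#' @param panel An `ema_panel`.
#' @param config An [analysis_config()].
#' @param subjects Optional subject-id subset to estimate on.
#' @return List with `network_matrix` elements `cross_sectional`, `lagged`,
#'   `multilayer`.
#' @export
build_networks <- function(panel, config = analysis_config(), subjects = NULL) {
  stopifnot(inherits(panel, "ema_panel"))
  prep <- prepare_panel(panel, config$lag_rule)
  est <- estimate_edge_matrices(prep, config, subjects = subjects)
  assemble_network_matrices(est, config)
}

#' Estimate clinical-score moderation of network edges
#'
#' Refits every edge model with a subject-level clinical component score and
#' its interaction with the predictor; the interaction coefficient per
#' ordered pair quantifies how the within-subject coupling changes with the
#' score. Interaction matrices (cross-sectional and lagged) are FDR-masked
#' per kind; per-item associations of mean intensity with the score are
#' reported as node effects.
#'
#' @param panel An `ema_panel`.
#' @param scores Named per-subject component score.
#' @param config An [analysis_config()].
#' @return List of class `moderation_matrices`: `cross_sectional` and
#'   `lagged` `network_matrix` objects of masked interaction coefficients,
#'   and `node_effects` (data.frame from [correlate_item_intensity()]).
#' @export
moderation_matrices <- function(panel, scores, config = analysis_config()) {
  stopifnot(inherits(panel, "ema_panel"))
  prep <- prepare_panel(panel, config$lag_rule)
  est <- estimate_edge_matrices(prep, config, moderator = scores)
  items <- est$items
  k <- length(items)
  off <- !diag(k)
  m_cs <- matrix(FALSE, k, k, dimnames = list(items, items))
  m_cs[off] <- bh_fdr_mask(est$p_cs[off], config$fdr_q)
  B_cs <- est$beta_cs; B_cs[!m_cs | is.na(B_cs)] <- 0
  m_lag <- matrix(bh_fdr_mask(as.vector(est$p_lag), config$fdr_q), k, k,
                  dimnames = list(items, items))
  B_lag <- est$beta_lag; B_lag[!m_lag | is.na(B_lag)] <- 0
  structure(
    list(
      cross_sectional = structure(
        list(kind = "cross_sectional", weights = B_cs, mask = m_cs,
             p = est$p_cs, labels = items, directed = TRUE),
        class = "network_matrix"),
      lagged = network_matrix(B_lag, m_lag, kind = "lagged",
                              p = est$p_lag, labels = items),
      node_effects = correlate_item_intensity(
        structure(list(data = panel$data, items = items,
                       design = panel$design), class = "ema_panel"),
        scores)
    ),
    class = "moderation_matrices"
  )
}
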