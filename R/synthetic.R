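#' Generative specification for a synthetic EMA cohort
#'
#' Defines the ground truth of a simulated experience-sampling study. Latent
#' item intensities follow a first-order vector autoregression with a
#' per-subject random intercept: within each day,
#' `L_t = u_j + B (L_{t-1} - u_j) + e_t`, with `B` the lag-1 coupling matrix
#' and innovations `e_t ~ N(0, Sigma)` whose correlation encodes the
#' contemporaneous (partial) couplings. The latent state re-initializes each
#' day at the subject mean plus an innovation, so consecutive same-day prompts
#' carry the lagged structure and overnight pairs do not. Latent values are
#' discretized to 1..7 by fixed thresholds; the binary social-context item is
#' an independent Bernoulli flag. Each scheduled prompt is completed
#' independently with probability `compliance`.
#'
#' Defaults emulate the reference study conditions: 68 subjects, 20 items,
#' 8 prompts/day over 6 days, and compliance 0.52 (about 25 of 48 prompts).
#'
#' @param n_subjects Number of subjects (default 68).
#' @param items Item names (default [ema_item_names()]); the binary
#'   `Being-Alone` item, if present, is generated as Bernoulli and excluded
#'   from the latent dynamics.
#' @param days,prompts_per_day Sampling design (default 6 x 8).
#' @param cross_coupling Item x item symmetric matrix of contemporaneous
#'   partial associations (zero diagonal). Default: none.
#' @param lag_coupling Item x item matrix of lag-1 coefficients `B[j, k]` =
#'   effect of item k at t-1 on item j at t. Must have spectral radius < 1.
#'   Default: none.
#' @param intercept_sd Standard deviation of subject random intercepts
#'   (default 0.8).
#' @param noise_sd Innovation standard deviation (default 1).
#' @param compliance Per-prompt completion probability in (0, 1]
#'   (default 0.52).
#' @param group_labels Optional character vector (or named vector by subject
#'   id) of "A"/"B" population labels; default all "A".
#' @param group_coupling_delta Item x item matrix added to `lag_coupling` for
#'   group-B subjects (default zero).
#' @param group_cross_delta Item x item matrix added to `cross_coupling` for
#'   group-B subjects (default zero).
#' @param likert_cuts Six strictly increasing thresholds mapping latent values
#'   to the 1..7 scale (default `(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)`).
#' @param p_alone Bernoulli probability for the binary context item
#'   (default 0.36).
#' @param seed Integer RNG seed.
#' @return An object of class `generative_spec`.
#' @export
generative_spec <- function(n_subjects = 68L,
                            items = ema_item_names(),
                            days = 6L,
                            prompts_per_day = 8L,
                            cross_coupling = NULL,
                            lag_coupling = NULL,
                            intercept_sd = 0.8,
                            noise_sd = 1,
                            compliance = 0.52,
                            group_labels = NULL,
                            group_coupling_delta = NULL,
                            group_cross_delta = NULL,
                            likert_cuts = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
                            p_alone = 0.36,
                            seed = 1L) {
  k <- length(items)
  zero <- matrix(0, k, k, dimnames = list(items, items))
  if (is.null(cross_coupling)) cross_coupling <- zero
  if (is.null(lag_coupling)) lag_coupling <- zero
  if (is.null(group_coupling_delta)) group_coupling_delta <- zero
  if (is.null(group_cross_delta)) group_cross_delta <- zero
  for (m in list(cross_coupling, lag_coupling, group_coupling_delta, group_cross_delta)) {
    stopifnot(is.matrix(m), nrow(m) == k, ncol(m) == k)
  }
  if (!isTRUE(all.equal(cross_coupling, t(cross_coupling)))) {
    stop("cross_coupling must be symmetric")
  }
  stopifnot(compliance > 0, compliance <= 1)
  if (length(likert_cuts) != 6L || any(diff(likert_cuts) <= 0)) {
    stop("likert_cuts must be 6 strictly increasing thresholds")
  }
  if (is.null(group_labels)) group_labels <- rep("A", n_subjects)
  stopifnot(length(group_labels) == n_subjects, all(group_labels %in% c("A", "B")))
  for (B in list(lag_coupling, lag_coupling + group_coupling_delta)) {
    rho <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (rho >= 1) stop("lag_coupling spectral radius ", round(rho, 3), " >= 1: non-stationary")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), items = items,
         days = as.integer(days), prompts_per_day = as.integer(prompts_per_day),
         cross_coupling = cross_coupling, lag_coupling = lag_coupling,
         intercept_sd = intercept_sd, noise_sd = noise_sd,
         compliance = compliance, group_labels = group_labels,
         group_coupling_delta = group_coupling_delta,
         group_cross_delta = group_cross_delta,
         likert_cuts = likert_cuts, p_alone = p_alone,
         seed = as.integer(seed)),
    class = "generative_spec"
  )
}

#' @export
print.generative_spec <- function(x, ...) {
  cat(sprintf(
    "<generative_spec> %d subjects, %d items, %d x %d design, compliance %.2f, seed %d\n",
    x$n_subjects, length(x$items), x$prompts_per_day, x$days, x$compliance, x$seed))
  invisible(x)
}

#' Discretize a latent value to a 1..7 Likert score
#'
#' Returns `1 + ` the number of thresholds strictly below the value.
#'
#' @param latent Numeric vector of latent values.
#' @param cuts Six strictly increasing thresholds.
#' @return Integer vector in 1..7.
#' @export
#' @examples
#' latent_to_likert(0, c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5))  # 4
latent_to_likert <- function(latent, cuts) {
  if (length(cuts) != 6L || any(diff(cuts) <= 0)) {
    stop("cuts must be 6 strictly increasing thresholds")
  }
  ans <- findInterval(latent, cuts, left.open = TRUE) + 1L
  ans[is.na(latent)] <- NA_integer_
  ans
}

# innovation covariance from a partial-association matrix: the precision is
# (I - C) rescaled to unit diagonal covariance, so C holds partial correlations
cross_covariance <- function(cross, noise_sd) {
  k <- nrow(cross)
  Omega <- diag(k) - cross
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop("cross_coupling is too strong: precision not positive definite")
  Sigma <- solve(Omega)
  d <- sqrt(diag(Sigma))
  Sigma <- Sigma / tcrossprod(d)   # unit diagonal
  Sigma * noise_sd^2
}

#' Generate a synthetic cohort
#'
#' Simulates an EMA panel, a clinical interview table, and cohort metadata
#' from a [generative_spec()], deterministically for a given spec (the spec
#' carries the seed). The ground-truth spec is retained in the result so
#' recovery of generative couplings can be tested downstream.
#'
#' The clinical table is generated from two latent traits per subject: trait 1
#' (severity, correlated with the subject's random-intercept mean) loads
#' positively on all items; trait 2 contrasts the first versus second half of
#' the item list.
#'
#' @param spec A `generative_spec`.
#' @return An object of class `synthetic_cohort`: list with `panel`
#'   (`ema_panel`), `sips` (`sips_table`), `meta` (`cohort_metadata`),
#'   `groups` (named "A"/"B" vector), and `truth` (the spec).
#' @export
#' @examples
#' coh <- generate_cohort(generative_spec(n_subjects = 4, compliance = 1, seed = 7))
#' nrow(coh$panel$data)  # 4 * 48
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  items <- spec$items
  bin <- intersect(binary_ema_items(), items)
  lat_items <- setdiff(items, bin)
  k <- length(lat_items)
  idx <- match(lat_items, items)
  subj_ids <- sprintf("S%03d", seq_len(spec$n_subjects))
  groups <- spec$group_labels
  names(groups) <- subj_ids

  chol_by_group <- list()
  B_by_group <- list()
  for (g in unique(groups)) {
    cross <- spec$cross_coupling[idx, idx, drop = FALSE]
    B <- spec$lag_coupling[idx, idx, drop = FALSE]
    if (g == "B") {
      cross <- cross + spec$group_cross_delta[idx, idx, drop = FALSE]
      B <- B + spec$group_coupling_delta[idx, idx, drop = FALSE]
    }
    Sigma <- cross_covariance(cross, spec$noise_sd)
    chol_by_group[[g]] <- chol(Sigma)
    B_by_group[[g]] <- B
  }

  u <- matrix(stats::rnorm(spec$n_subjects * k, sd = spec$intercept_sd),
              spec$n_subjects, k)
  n_prompt <- spec$prompts_per_day
  rows <- vector("list", spec$n_subjects)
  for (j in seq_len(spec$n_subjects)) {
    g <- groups[j]
    B <- B_by_group[[g]]; U <- chol_by_group[[g]]
    lat <- matrix(NA_real_, spec$days * n_prompt, k)
    done <- stats::runif(spec$days * n_prompt) <= spec$compliance
    r <- 0L
    for (d in seq_len(spec$days)) {
      state <- u[j, ] + drop(stats::rnorm(k) %*% U)
      for (t in seq_len(n_prompt)) {
        if (t > 1L) {
          state <- u[j, ] + drop(B %*% (state - u[j, ])) + drop(stats::rnorm(k) %*% U)
        }
        r <- r + 1L
        lat[r, ] <- state
      }
    }
    keep <- which(done)
    if (!length(keep)) next
    obs <- matrix(NA_integer_, length(keep), length(items),
                  dimnames = list(NULL, items))
    for (m in seq_len(k)) {
      obs[, lat_items[m]] <- latent_to_likert(lat[keep, m], spec$likert_cuts)
    }
    for (bitem in bin) {
      obs[, bitem] <- as.integer(stats::runif(length(keep)) < spec$p_alone)
    }
    rows[[j]] <- data.frame(
      subject_id = subj_ids[j],
      day = ((keep - 1L) %/% n_prompt) + 1L,
      prompt = ((keep - 1L) %% n_prompt) + 1L,
      obs, check.names = FALSE
    )
  }
  data <- do.call(rbind, rows)
  panel <- ema_panel(data, items = items,
                     prompts_per_day = n_prompt, days = spec$days)

  # clinical table from two latent traits; trait 1 tracks overall intensity
  severity <- as.numeric(base::scale(rowMeans(u))) + stats::rnorm(spec$n_subjects, sd = 0.5)
  contrast <- stats::rnorm(spec$n_subjects)
  traits <- cbind(severity, contrast)
  rownames(traits) <- subj_ids
  n_sips <- length(sips_item_names())
  loadings <- cbind(
    stats::runif(n_sips, 0.4, 1.0),
    rep(c(0.5, -0.5), length.out = n_sips)
  )
  sips <- generate_sips_from_traits(traits, loadings, noise_sd = 0.6,
                                    seed = NULL, baseline = 1.5)

  meta <- cohort_metadata(data.frame(
    subject_id = subj_ids,
    age = round(pmax(10, stats::rnorm(spec$n_subjects, 19.3, 5.2)), 1),
    sex = ifelse(stats::runif(spec$n_subjects) < 0.31, "F", "M"),
    fsiq = round(stats::rnorm(spec$n_subjects, 73, 13)),
    ADHD = as.integer(stats::runif(spec$n_subjects) < 0.60),
    Anxiety = as.integer(stats::runif(spec$n_subjects) < 0.45),
    Psychosis = as.integer(stats::runif(spec$n_subjects) < 0.06),
    stringsAsFactors = FALSE
  ), panel = panel)

  structure(list(panel = panel, sips = sips, meta = meta,
                 groups = groups, truth = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n  ")
  print(x$panel)
  cat("  ")
  print(x$sips)
  invisible(x)
}

#' Generate a clinical interview table from latent traits
#'
#' Item score = round-and-clip to `[0, 6]` of
#' `baseline + loadings %*% traits + noise`. With an all-positive first
#' loading column, subjects high on trait 1 score higher on every item
#' (a severity dimension); a signed second column yields a contrast
#' dimension.
#'
#' @param trait_scores Subjects x 2 matrix of latent trait scores (rownames
#'   used as subject ids, else `S001...`).
#' @param loading_matrix Items x 2 loading matrix (default rows named by
#'   [sips_item_names()]).
#' @param noise_sd Residual standard deviation.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param baseline Scalar added to every item before rounding (default 1).
#' @return A `sips_table`.
#' @export
generate_sips_from_traits <- function(trait_scores, loading_matrix,
                                      noise_sd = 0.5, seed = 1L, baseline = 1) {
  trait_scores <- as.matrix(trait_scores)
  loading_matrix <- as.matrix(loading_matrix)
  if (ncol(trait_scores) != 2L) stop("trait_scores must have 2 columns")
  if (ncol(loading_matrix) != 2L) stop("loading_matrix must have 2 columns")
  gen <- function() {
    raw <- baseline + tcrossprod(trait_scores, loading_matrix) +
      matrix(stats::rnorm(length(trait_scores[, 1]) * nrow(loading_matrix),
                          sd = noise_sd),
             nrow(trait_scores), nrow(loading_matrix))
    scores <- round(raw)
    scores[scores < 0] <- 0
    scores[scores > 6] <- 6
    item_names <- rownames(loading_matrix)
    if (is.null(item_names)) {
      item_names <- sips_item_names()[seq_len(nrow(loading_matrix))]
    }
    ids <- rownames(trait_scores)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(trait_scores)))
    df <- data.frame(subject_id = ids, scores, check.names = FALSE)
    names(df) <- c("subject_id", item_names)
    sips_table(df)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a synthetic cohort to a directory
#'
#' Writes `panel.csv`, `sips.csv`, `meta.csv` and a `truth.json` with the
#' generative parameters.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ema_table(cohort$panel, file.path(dir, "panel.csv"))
  write_sips_table(cohort$sips, file.path(dir, "sips.csv"))
  utils::write.csv(cohort$meta$data, file.path(dir, "meta.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    n_subjects = truth$n_subjects, items = truth$items, days = truth$days,
    prompts_per_day = truth$prompts_per_day,
    cross_coupling = truth$cross_coupling, lag_coupling = truth$lag_coupling,
    intercept_sd = truth$intercept_sd, noise_sd = truth$noise_sd,
    compliance = truth$compliance, likert_cuts = truth$likert_cuts,
    group_labels = as.list(truth$group_labels), seed = truth$seed
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' A two-community default coupling template
#'
#' Convenience constructor of cross/lag coupling matrices with two equal
#' communities: within-community contemporaneous partial association
#' `cross_within`, self-lag `lag_self` and within-community lag `lag_within`.
#' Binary items (e.g. `Being-Alone`) get zero couplings.
#'
#' @param items Item names.
#' @param cross_within,lag_self,lag_within Coupling strengths.
#' @return List with `cross` and `lag` matrices.
#' @export
community_couplings <- function(items = ema_item_names(),
                                cross_within = 0.18, lag_self = 0.25,
                                lag_within = 0.05) {
  lat <- setdiff(items, binary_ema_items())
  k <- length(items)
  cross <- matrix(0, k, k, dimnames = list(items, items))
  lag <- matrix(0, k, k, dimnames = list(items, items))
  half <- ceiling(length(lat) / 2)
  comm <- split(lat, rep(1:2, c(half, length(lat) - half)))
  for (cc in comm) {
    cross[cc, cc] <- cross_within
    lag[cc, cc] <- lag_within
  }
  diag(cross) <- 0
  diag(lag) <- 0
  di <- match(lat, items)
  lag[cbind(di, di)] <- lag_self
  list(cross = cross, lag = lag)
}
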