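#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline stages.
#'
#' @param fdr_q False-discovery-rate level for Benjamini-Hochberg pruning of
#'   edge p-values (one family per matrix kind). Default 0.05.
#' @param variance_retention_threshold Fraction of total variance a principal
#'   component must exceed to be retained. Default 0.10.
#' @param n_bundles Number of trajectory bundles for k-means, or `"auto"` to
#'   select k in 4..12 by mean silhouette width.
#' @param n_permutations Number of subject permutations in the bundle
#'   divergence test. Default 500.
#' @param rng_seed Integer seed used for every stochastic step (k-means
#'   restarts, permutations).
#' @param lag_rule How consecutive-prompt pairs are formed:
#'   `"same_day_consecutive"` (default; prompt t and t+1 of the same day, both
#'   completed, a missed intermediate prompt breaks the pair) or
#'   `"any_consecutive"` (adjacent completed prompts regardless of day).
#' @param length_transform Transform from edge weight to path length;
#'   only `"inverse_abs"` (length = 1/|weight|) is implemented.
#' @param k_subgroups Number of clinical subgroups for 1-D k-means. Default 2.
#' @param pca_scale Logical; standardize clinical items before PCA
#'   (correlation-matrix PCA) instead of the default covariance-matrix PCA.
#' @param ndr_diagonal Diagonal convention for the adjacency matrix fed to the
#'   network embedding: `"mean_offdiag"` (default) or `"zero"`.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config(n_permutations = 99, rng_seed = 1)
#' cfg$fdr_q
analysis_config <- function(fdr_q = 0.05,
                            variance_retention_threshold = 0.10,
                            n_bundles = "auto",
                            n_permutations = 500L,
                            rng_seed = 1L,
                            lag_rule = c("same_day_consecutive", "any_consecutive"),
                            length_transform = "inverse_abs",
                            k_subgroups = 2L,
                            pca_scale = FALSE,
                            ndr_diagonal = c("mean_offdiag", "zero")) {
  lag_rule <- match.arg(lag_rule)
  ndr_diagonal <- match.arg(ndr_diagonal)
  length_transform <- match.arg(length_transform)
  stopifnot(
    is.numeric(fdr_q), length(fdr_q) == 1L, fdr_q > 0, fdr_q < 1,
    is.numeric(variance_retention_threshold),
    variance_retention_threshold > 0, variance_retention_threshold < 1,
    is.numeric(n_permutations), n_permutations >= 1,
    is.numeric(rng_seed), length(rng_seed) == 1L,
    is.numeric(k_subgroups), k_subgroups >= 2
  )
  if (!identical(n_bundles, "auto")) {
    stopifnot(is.numeric(n_bundles), n_bundles >= 1)
    n_bundles <- as.integer(n_bundles)
  }
  structure(
    list(
      fdr_q = fdr_q,
      variance_retention_threshold = variance_retention_threshold,
      n_bundles = n_bundles,
      n_permutations = as.integer(n_permutations),
      rng_seed = as.integer(rng_seed),
      lag_rule = lag_rule,
      length_transform = length_transform,
      k_subgroups = as.integer(k_subgroups),
      pca_scale = isTRUE(pca_scale),
      ndr_diagonal = ndr_diagonal
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a key-value file
#'
#' Accepts a simple `key: value` (YAML-like) or `key = value` file with one
#' entry per line; keys mirror the arguments of [analysis_config()]. Unknown
#' keys are an error.
#'
#' @param path File path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("cannot parse config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    if (v %in% c("TRUE", "true", "FALSE", "false")) return(v %in% c("TRUE", "true"))
    v
  })
  names(args) <- keys
  do.call(analysis_config, args)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
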