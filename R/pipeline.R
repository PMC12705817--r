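#' Single-population behavioral tractography pipeline
#'
#' Runs the full analysis chain on one panel: mixed-model network estimation
#' with FDR pruning, adjacency-PCA embedding, 3D multilayer assembly,
#' interlayer shortest paths, bundle clustering, diffusion directions, and
#' longitudinal betweenness.
#'
#' @param panel An `ema_panel`.
#' @param config An [analysis_config()].
#' @return An object of class `bt_result` with elements `networks`,
#'   `embedding`, `mln`, `paths`, `bundles`, `diffusion`, `betweenness`.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(generative_spec(
#'   n_subjects = 30, items = ema_item_names()[1:8],
#'   cross_coupling = community_couplings(ema_item_names()[1:8])$cross,
#'   lag_coupling = community_couplings(ema_item_names()[1:8])$lag,
#'   compliance = 1, seed = 3))
#' res <- behavioral_tractography(coh$panel,
#'                                analysis_config(n_bundles = 4, rng_seed = 3))
#' res$bundles
#' }
behavioral_tractography <- function(panel, config = analysis_config()) {
  stopifnot(inherits(panel, "ema_panel"))
  networks <- build_networks(panel, config)
  embedding <- embed_network(networks$cross_sectional, config = config)
  mln <- assemble_3d(embedding, networks$multilayer, config$length_transform)
  paths <- shortest_interlayer_paths(mln)
  bundles <- if (length(paths$paths) >= 2L) {
    cluster_bundles(paths, k = config$n_bundles, seed = config$rng_seed)
  } else NULL
  structure(
    list(networks = networks, embedding = embedding, mln = mln,
         paths = paths, bundles = bundles,
         diffusion = diffusion_field(mln, paths),
         betweenness = longitudinal_betweenness(mln, paths),
         config = config),
    class = "bt_result"
  )
}

#' @export
print.bt_result <- function(x, ...) {
  cat("<bt_result>\n  ")
  print(x$networks$cross_sectional)
  cat("  ")
  print(x$embedding)
  cat("  ")
  print(x$paths)
  if (!is.null(x$bundles)) { cat("  "); print(x$bundles) }
  invisible(x)
}
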