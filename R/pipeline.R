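#' Run the full synthetic analysis pipeline
#'
#' One-call chain over the package's stages on synthetic data: sample a
#' labelled feature table (subtype preset by default), run the exhaustive
#' subset screen, select the top-weighted subset, and validate it by column
#' permutation. Returns a machine-readable report that
#' \code{jsonlite::write_json} can serialize directly.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param spec A \code{\link{synthetic_dataset_spec}}; default the subtype
#'   preset (\code{\link{table_preset_spec}}).
#' @param config A \code{\link{screen_config}}.
#' @param n_shuffles Shuffles for the selected-subset permutation stage.
#' @return List: \code{seed}, \code{n_cells}, \code{screen} (subset counts),
#'   \code{selection} (mask, coverage), \code{permutation}
#'   (false-positive fraction), plus the \code{l1_screen} object itself in
#'   \code{fit}.
#' @export
run_pipeline <- function(seed = 1, spec = NULL, config = screen_config(),
                         n_shuffles = 200) {
  if (is.null(spec)) spec <- table_preset_spec(seed = seed)
  tab <- sample_feature_table(spec)
  scr <- subset_screen(tab, config = config)
  sel <- tryCatch(weight_and_select(scr), error = function(e) NULL)
  perm_cfg <- screen_config(n_clusters = config$n_clusters,
                            alpha = config$alpha,
                            standardize = config$standardize,
                            seed = seed + 1L, n_shuffles = n_shuffles,
                            target_subset_size = config$target_subset_size)
  perm <- permutation_validation(tab, config = perm_cfg,
                                 variant = "selected",
                                 mask = if (!is.null(sel)) sel$mask else NULL)
  list(seed = seed,
       n_cells = nrow(tab$values),
       screen = list(n_subsets = nrow(scr$results),
                     n_significant = sum(scr$results$significant)),
       selection = if (is.null(sel)) NULL else
         list(mask = sel$mask, features = sel$features,
              coverage_count = sel$coverage_count,
              coverage_fraction = sel$coverage_fraction,
              selected_p = sel$selected_p),
       permutation = list(n_shuffles = n_shuffles,
                          fraction_significant = perm$fraction_significant),
       fit = scr)
}
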