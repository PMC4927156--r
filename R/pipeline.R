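#' Run the full screen pipeline
#'
#' Convenience driver chaining the pipeline stages in their fixed order:
#' positional masking, per-plate surface normalization, per-condition
#' power transformation, per-plate variance normalization, reliability
#' filtering, fitness scoring, per-condition FDR cutoffs, and phenotype
#' calling.
#'
#' @param screen A `sim_screen` (or a list with `colonies` and `plates`,
#'   see [normalize_screen()]).
#' @param mask Optional positional mask for [apply_position_mask()].
#' @param alpha Target per-condition FDR for phenotype calls (0.05).
#' @param coverage_threshold Reliability threshold for
#'   [filter_low_coverage()]; `NULL` skips the filter.
#' @param reference Reference scheme for [fitness_scores()].
#' @param ... Passed to [normalize_screen()].
#' @return A list: `normalized` (screen matrix, one column per plate),
#'   `scores` (stage `"score"`), `cutoffs`, `calls`, `surface_fits`,
#'   `power_transforms`.
#' @export
run_screen_pipeline <- function(screen, mask = NULL, alpha = 0.05,
                                coverage_threshold = 0.75,
                                reference = "batch_others", ...) {
  norm <- normalize_screen(screen, mask = mask, ...)
  m <- norm$matrix
  if (!is.null(coverage_threshold))
    m <- filter_low_coverage(m, threshold = coverage_threshold)
  scores <- fitness_scores(m, reference = reference)
  cutoffs <- fdr_cutoffs(scores, alpha = alpha,
                         min_scores = min(500L, nrow(scores$values)))
  calls <- call_phenotypes(scores, cutoffs)
  list(normalized = m, scores = scores, cutoffs = cutoffs, calls = calls,
       surface_fits = norm$surface_fits,
       power_transforms = norm$power_transforms)
}
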