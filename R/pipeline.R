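#' Run the portrayal pipeline on an expression cohort
#'
#' Convenience wrapper chaining the standard stages: [preprocess()],
#' [train_som()], [portraits()], group-mean portraits per subtype,
#' [summary_map()] and [detect_spots()].
#'
#' @param E an [expression_matrix()].
#' @param labels named subtype labels (defaults to the labels stored in `E`).
#' @param config a [pipeline_config()].
#' @return a list with `expression` (centered), `model`, `portraits`,
#'   `group_portraits`, `summary`, `spots`, `labels` and `config`.
#' @export
som_pipeline <- function(E, labels = E$sample_labels,
                         config = pipeline_config()) {
  if (is.null(labels)) stop("subtype labels are required")
  centered <- preprocess(E, quantile_normalize = config$quantile_normalize)
  model <- train_som(centered, rows = config$grid_rows,
                     cols = config$grid_cols, epochs = config$epochs,
                     seed = config$seed, radius_end = config$radius_end)
  P <- portraits(model)
  groups <- unique(labels)
  gp <- vapply(groups, function(g) group_mean_portrait(P, labels, g),
               numeric(nrow(P)))
  smap <- summary_map(gp)
  spots <- detect_spots(smap, model$rows, model$cols,
                        q = config$spot_quantile,
                        min_size = config$spot_min_size, model = model)
  list(expression = centered, model = model, portraits = P,
       group_portraits = gp, summary = smap, spots = spots,
       labels = labels, config = config)
}

#' Default synthetic-cohort pipeline run
#'
#' Generates the default synthetic cohort for a seed, runs [som_pipeline()]
#' at the package defaults and matches the detected spots to the planted
#' modules. This is the run underlying the package's benchmark numbers.
#'
#' @param seed integer seed for cohort and pipeline.
#' @param total_samples cohort size.
#' @param config a [pipeline_config()]; its seed is set to `seed`.
#' @return the [som_pipeline()] list, extended with `truth` and `match`
#'   (see [match_spots_to_modules()]).
#' @export
run_default_pipeline <- function(seed = 1L, total_samples = 300L,
                                 config = pipeline_config(seed = seed)) {
  cohort <- generate_cohort(default_mmml_spec(total_samples, seed = seed))
  pl <- som_pipeline(cohort$expression, config = config)
  pl$truth <- cohort$truth
  pl$match <- match_spots_to_modules(pl$spots, cohort$truth)
  pl
}

#' Gene signature of the spot matched to a planted module
#'
#' @param pl a [run_default_pipeline()] result.
#' @param module planted module letter.
#' @return a [signature()] of the matched spot's genes.
#' @export
matched_spot_signature <- function(pl, module) {
  letter <- pl$match$spot[pl$match$module == module]
  if (!length(letter) || is.na(letter))
    stop("no spot matched to module ", module)
  spot_signatures(pl$spots)[[letter]]
}
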