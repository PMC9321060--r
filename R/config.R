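#' Pipeline configuration
#'
#' Collects the tunable knobs of the pipeline in one validated object that
#' serializes losslessly to YAML. Defaults follow the package defaults: a
#' 50x50 metagene grid, 20 batch training epochs with the neighborhood radius
#' decaying linearly from half the grid edge to 1, spot segmentation at the
#' 0.85 map quantile with a 3-pixel minimum, and PAT activation at the 0.90
#' per-sample portrait quantile.
#'
#' @param grid_rows,grid_cols SOM grid dimensions (pixels).
#' @param epochs number of batch training epochs.
#' @param radius_end final neighborhood radius (grid units); the start radius
#'   is `max(grid_rows, grid_cols) / 2`.
#' @param spot_quantile map quantile above which pixels enter spots.
#' @param spot_min_size minimum spot size in pixels.
#' @param pat_quantile per-sample portrait quantile for PAT spot activation.
#' @param quantile_normalize apply quantile normalization before centering.
#' @param impute_missing impute missing input cells by gene means.
#' @param seed integer random seed for every stochastic stage.
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(grid_rows = 50L, grid_cols = 50L, epochs = 20L,
                            radius_end = 1, spot_quantile = 0.85,
                            spot_min_size = 3L, pat_quantile = 0.90,
                            quantile_normalize = FALSE,
                            impute_missing = FALSE, seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              epochs = as.integer(epochs),
              radius_end = as.numeric(radius_end),
              spot_quantile = as.numeric(spot_quantile),
              spot_min_size = as.integer(spot_min_size),
              pat_quantile = as.numeric(pat_quantile),
              quantile_normalize = isTRUE(quantile_normalize),
              impute_missing = isTRUE(impute_missing),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(grid_rows >= 1, grid_cols >= 1, grid_rows * grid_cols >= 4,
              epochs >= 1, radius_end > 0,
              spot_quantile > 0, spot_quantile < 1, spot_min_size >= 1,
              pat_quantile > 0, pat_quantile < 1)
  })
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
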