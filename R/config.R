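#' Pipeline configuration
#'
#' All tunable conventions in one serializable object. Every default is the
#' assay-faithful choice: raw MAD (no consistency constant), centre before
#' scale, type-7 percentile, strict `x > k`, four baseline frames, 99th
#' percentile threshold, 8-connectivity with 5-px minimum cluster area,
#' mean + 3 SD end-point rule, 50% mutual-blocking cutoff.
#'
#' @param percentile_type Quantile convention (1–9, see [stats::quantile()]).
#' @param percentile_prob Threshold percentile (default 0.99).
#' @param mad_constant MAD multiplier (default 1: raw MAD).
#' @param degenerate Degenerate-frame (MAD = 0) fallback policy.
#' @param n_baseline_frames Baseline frames pooled for the time-lapse
#'   threshold.
#' @param connectivity,min_area Cluster-counting settings.
#' @param endpoint_n_sd Control SDs above the control mean for end-point
#'   positivity.
#' @param blocking_threshold Percent cutoff for mutual blocking.
#' @param seed Default seed for any stochastic step.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(percentile_type = 7L, percentile_prob = 0.99,
                            mad_constant = 1, degenerate = "scale-cascade",
                            n_baseline_frames = 4L, connectivity = 8L,
                            min_area = 5L, endpoint_n_sd = 3,
                            blocking_threshold = 50, seed = 1L) {
  cfg <- list(percentile_type = as.integer(percentile_type),
              percentile_prob = as.numeric(percentile_prob),
              mad_constant = as.numeric(mad_constant),
              degenerate = degenerate,
              n_baseline_frames = as.integer(n_baseline_frames),
              connectivity = as.integer(connectivity),
              min_area = as.integer(min_area),
              endpoint_n_sd = as.numeric(endpoint_n_sd),
              blocking_threshold = as.numeric(blocking_threshold),
              seed = as.integer(seed))
  structure(cfg, class = "PipelineConfig")
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips losslessly through JSON.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_config()`: a `PipelineConfig`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
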