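#' Pipeline configuration with published defaults
#'
#' One place for every tunable of the pipeline, defaulting to the published
#' study settings: 0.16-degree cells, bisquare adaptive GW-PCA kernel,
#' raw-concentration scoring, IDW power 2, assignment threshold 0.5 with a
#' 10 km rescue buffer, threshold sweep over 0.5 / 0.66 / 0.75, and
#' leave-three-out cross-validation with 100 replicates. The drivers under
#' \code{analysis/} and \code{\link{leave_k_out_cv}} consume these values.
#'
#' @param ... overrides of any default, by name.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cell_size = 0.16,
    elements = canonical_elements(),
    kernel = "bisquare",
    adaptive = TRUE,
    bandwidth = NULL,          # NULL: select by cross-validation
    scoring_mode = "raw",
    idw_power = 2,
    hull_buffer_deg = 0,
    sigma = NULL,              # NULL: calibrate from training residuals
    sigma_reference = 9.696,   # published residual dispersion (as variance)
    sigma_mode = "variance",
    threshold = 0.5,
    thresholds = c(0.5, 0.66, 0.75),
    buffer_km = 10,
    cv_k = 3,
    cv_reps = 100,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}
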