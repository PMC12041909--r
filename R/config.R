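#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline, keyed by stage, with the
#' published acquisition/analysis values as defaults: the single-molecule
#' size filter (0.75, 1.25) px and density threshold 0.09 um^-2, the
#' 10-frame brightness interval, tracking radius 6 px, the 5-step minimum
#' trajectory length, the 12th-order even-polynomial profile fit, the
#' 0.1 mbar controller step, and the 0.05 significance level.
#'
#' @return Nested named list of stage parameters.
#' @export
pipeline_defaults <- function() {
  list(
    slb = list(detection_threshold = 50, size_min = 0.75, size_max = 1.25,
               density_threshold = 0.09, brightness_interval = 10L,
               search_radius = 6, min_steps = 5L, max_lag = 10L,
               n_fit_lags = 5L, immobile_cutoff = 0.01),
    fura = list(min_area = 20, smooth_sigma = 1, watershed_tolerance = 1,
                max_displacement = 15, join_match_limit = 25),
    motility = list(n_boot = 1000L, kinematics_window = 3L),
    immuno = list(min_area = 20),
    mech = list(profile_order = 12L, controller_step = 0.1,
                peak_floor = 0.3),
    stats = list(alpha = 0.05, notch_constant = 1.57)
  )
}

#' Load a run configuration with defaults
#'
#' Reads a YAML config keyed by stage and merges it over
#' [pipeline_defaults()]. Unknown stages or parameter names are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional nested list applied after the file (e.g. from
#'   script arguments).
#' @return Nested named list as from [pipeline_defaults()].
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- pipeline_defaults()
  apply_over <- function(cfg, new, where) {
    for (stage in names(new)) {
      if (!stage %in% names(cfg))
        stop("unknown config stage '", stage, "' in ", where)
      for (key in names(new[[stage]])) {
        if (!key %in% names(cfg[[stage]]))
          stop("unknown config key '", stage, ".", key, "' in ", where)
        cfg[[stage]][[key]] <- new[[stage]][[key]]
      }
    }
    cfg
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  if (!is.null(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  cfg
}
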