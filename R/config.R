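#' Pipeline configuration
#'
#' One object holds every tunable constant of the pipeline. Defaults are the
#' study values: 250 m modeling cells; spatial thinning on a 1000 m grid
#' with at most 4 points per coarse cell; pseudo-absences drawn where the
#' Bioclim envelope score falls below 0.05; 20 cross-validation iterations
#' holding out 20% of presences (plus a 10-iteration 80/20 pass for
#' importance/performance); covariate screening at |r| < 0.7; Brownian
#' bridge surfaces cut at 1e-8 with 100 sampled points per animal; telemetry
#' filtered at 36 h maximum gap, 50 m minimum step and 40 minimum fixes;
#' a 3 km dispersal radius; the 1st percentile of movement predictions at
#' locality points as the movement cutoff; and a 20% impervious-surface
#' ceiling.
#'
#' @param modeling_cell_size Modeling resolution, m.
#' @param thinning_grid_size Coarse thinning grid, m.
#' @param thinning_max_per_cell Maximum retained points per coarse cell.
#' @param pseudoabsence_envelope_threshold Bioclim score below which a cell
#'   is a pseudo-absence candidate.
#' @param cv_iterations Cross-validation iterations.
#' @param cv_test_fraction Presence fraction withheld per iteration.
#' @param importance_iterations Iterations of the separate 80/20 pass.
#' @param correlation_cutoff Pairwise |r| above which covariates are
#'   screened.
#' @param bbmm_cutoff Brownian bridge surface cutoff (probability mass).
#' @param bbmm_points_per_animal Random points sampled per bridge surface.
#' @param telemetry_max_gap_hours Maximum gap a bridge may span, hours.
#' @param telemetry_min_step_m Minimum step length retained, m.
#' @param telemetry_min_fixes Minimum fixes for an animal to be included.
#' @param dispersal_radius_m Dispersal reach per decade, m.
#' @param movement_percentile Percentile of movement predictions at
#'   locality points defining the movement cutoff.
#' @param impervious_cutoff Impervious-surface fraction above which cells
#'   are masked.
#' @param random_seed Seed applied to every stochastic stage.
#' @return A `gs_config` list.
#' @export
pipeline_config <- function(modeling_cell_size = 250,
                            thinning_grid_size = 1000,
                            thinning_max_per_cell = 4,
                            pseudoabsence_envelope_threshold = 0.05,
                            cv_iterations = 20,
                            cv_test_fraction = 0.2,
                            importance_iterations = 10,
                            correlation_cutoff = 0.7,
                            bbmm_cutoff = 1e-8,
                            bbmm_points_per_animal = 100,
                            telemetry_max_gap_hours = 36,
                            telemetry_min_step_m = 50,
                            telemetry_min_fixes = 40,
                            dispersal_radius_m = 3000,
                            movement_percentile = 0.01,
                            impervious_cutoff = 0.20,
                            random_seed = 1L) {
  cfg <- list(modeling_cell_size = modeling_cell_size,
              thinning_grid_size = thinning_grid_size,
              thinning_max_per_cell = thinning_max_per_cell,
              pseudoabsence_envelope_threshold = pseudoabsence_envelope_threshold,
              cv_iterations = cv_iterations,
              cv_test_fraction = cv_test_fraction,
              importance_iterations = importance_iterations,
              correlation_cutoff = correlation_cutoff,
              bbmm_cutoff = bbmm_cutoff,
              bbmm_points_per_animal = bbmm_points_per_animal,
              telemetry_max_gap_hours = telemetry_max_gap_hours,
              telemetry_min_step_m = telemetry_min_step_m,
              telemetry_min_fixes = telemetry_min_fixes,
              dispersal_radius_m = dispersal_radius_m,
              movement_percentile = movement_percentile,
              impervious_cutoff = impervious_cutoff,
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "gs_config")
}

validate_config <- function(cfg) {
  fracs <- c("pseudoabsence_envelope_threshold", "cv_test_fraction",
             "movement_percentile", "impervious_cutoff")
  for (f in fracs) {
    if (!(cfg[[f]] > 0 && cfg[[f]] < 1)) {
      stop("config field ", f, " must lie in (0, 1)", call. = FALSE)
    }
  }
  pos <- c("modeling_cell_size", "thinning_grid_size", "thinning_max_per_cell",
           "cv_iterations", "importance_iterations", "correlation_cutoff",
           "bbmm_cutoff", "bbmm_points_per_animal", "telemetry_max_gap_hours",
           "telemetry_min_step_m", "telemetry_min_fixes", "dispersal_radius_m")
  for (f in pos) {
    if (!(cfg[[f]] > 0)) stop("config field ", f, " must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Every run should log the resolved configuration (including the seed) so
#' results are reproducible from the config file alone.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `gs_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `gs_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
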