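#' Run configuration
#'
#' Bundles the tunable parameters of the whole pipeline: the seed-sphere
#' diameter used to select streamlines reaching the deep target (default
#' 1 mm), the tolerance windows around a (depth, angle) grid cell, the
#' geodesic radius and threshold of the local surface correlation, the
#' significance level of the goodness-of-fit suite, and the candidate grids
#' for parameter optimization.
#'
#' @param seed_sphere_diameter_mm sphere diameter in mm (default 1).
#' @param depth_tolerance_mm half-window on terminal depth, mm (default 0.5,
#'   half the 1 mm spacing of the default depth grid).
#' @param angle_tolerance_deg half-window on terminal angle, degrees
#'   (default 15, half the spacing of the default \{0, 30, 45\} degree grid).
#' @param correlation_radius_mm geodesic radius of the local-correlation
#'   neighborhood, mm (default 3).
#' @param correlation_threshold r threshold above which surface is counted
#'   as correlated, strictly inside (-1, 1) (default 0.5).
#' @param gof_alpha family significance level of the four-test
#'   goodness-of-fit suite (default 0.05; each test run at alpha/4).
#' @param rng_seed integer seed recorded with the run.
#' @param grid_depths_mm strictly increasing candidate depths, mm.
#' @param grid_angles_deg strictly increasing candidate angles, degrees.
#' @param density_smoothing_mm geodesic smoothing radius of terminal density
#'   maps, mm (default 2).
#' @return an object of class \code{run_config}.
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$correlation_threshold
run_config <- function(seed_sphere_diameter_mm = 1.0,
                       depth_tolerance_mm = 0.5,
                       angle_tolerance_deg = 15,
                       correlation_radius_mm = 3,
                       correlation_threshold = 0.5,
                       gof_alpha = 0.05,
                       rng_seed = 1L,
                       grid_depths_mm = c(2, 3),
                       grid_angles_deg = c(0, 30, 45),
                       density_smoothing_mm = 2) {
  cfg <- list(
    seed_sphere_diameter_mm = as.numeric(seed_sphere_diameter_mm),
    depth_tolerance_mm = as.numeric(depth_tolerance_mm),
    angle_tolerance_deg = as.numeric(angle_tolerance_deg),
    correlation_radius_mm = as.numeric(correlation_radius_mm),
    correlation_threshold = as.numeric(correlation_threshold),
    gof_alpha = as.numeric(gof_alpha),
    rng_seed = as.integer(rng_seed),
    grid_depths_mm = as.numeric(grid_depths_mm),
    grid_angles_deg = as.numeric(grid_angles_deg),
    density_smoothing_mm = as.numeric(density_smoothing_mm)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("seed_sphere_diameter_mm", "correlation_radius_mm")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("run_config: '", f, "' must be a positive finite length")
  }
  # tolerances and smoothing may be zero (exact windows, no smoothing)
  for (f in c("depth_tolerance_mm", "angle_tolerance_deg",
              "density_smoothing_mm")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop("run_config: '", f, "' must be a finite non-negative value")
  }
  if (cfg$correlation_threshold <= -1 || cfg$correlation_threshold >= 1)
    stop("run_config: 'correlation_threshold' must lie strictly in (-1, 1)")
  if (cfg$gof_alpha <= 0 || cfg$gof_alpha >= 1)
    stop("run_config: 'gof_alpha' must lie strictly in (0, 1)")
  for (g in c("grid_depths_mm", "grid_angles_deg")) {
    v <- cfg[[g]]
    if (length(v) == 0) stop("run_config: '", g, "' must be non-empty")
    if (any(!is.finite(v)) || any(diff(v) <= 0))
      stop("run_config: '", g, "' must be finite and strictly increasing")
  }
  if (any(cfg$grid_depths_mm <= 0))
    stop("run_config: grid depths must be positive")
  invisible(cfg)
}

#' Read / write a run configuration
#'
#' Configurations are stored as YAML; unknown fields are rejected so that a
#' typo in a parameter name cannot silently fall back to a default.
#'
#' @param path file path.
#' @param cfg a \code{run_config}.
#' @return \code{read_run_config}: a validated \code{run_config};
#'   \code{write_run_config}: \code{path}, invisibly.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("run_config: unknown field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
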