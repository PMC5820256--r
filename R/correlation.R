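#' Local correlation of two surface maps
#'
#' For every vertex, the Pearson correlation of the two maps over the
#' geodesic neighborhood of radius \code{radius_mm} (the vertex included).
#' Vertices whose neighborhood has fewer than 3 members, or zero variance
#' in either map, are flagged undefined (\code{NA}) and excluded from all
#' downstream area sums. The operation is symmetric in its two map
#' arguments.
#'
#' @param map_a,map_b \code{\link{surface_map}}s on the same surface.
#' @param surface the common \code{\link{labeled_surface}}.
#' @param radius_mm geodesic neighborhood radius, mm (> 0; default 3).
#' @param vertices optional integer subset of vertices at which to compute
#'   r (others left \code{NA}); used to restrict work to one region.
#' @param neighborhoods optional precomputed
#'   \code{\link{geodesic_neighborhoods}(surface, radius_mm, vertices)}.
#' @return an object of class \code{correlation_result}: \code{r_map}
#'   (correlation \code{\link{surface_map}}), plus copies of the surface's
#'   labels and vertex areas for area accounting, and \code{params}
#'   (filled by \code{\link{optimize_params}}).
#' @export
local_correlation <- function(map_a, map_b, surface, radius_mm = 3,
                              vertices = NULL, neighborhoods = NULL) {
  stopifnot(inherits(map_a, "surface_map"), inherits(map_b, "surface_map"),
            inherits(surface, "labeled_surface"), radius_mm > 0)
  nv <- nrow(surface$vertices)
  if (length(map_a$values) != nv || length(map_b$values) != nv)
    stop("local_correlation: maps and surface have different vertex counts")
  if (is.null(vertices)) vertices <- seq_len(nv)
  if (is.null(neighborhoods))
    neighborhoods <- geodesic_neighborhoods(surface, radius_mm, vertices)
  a <- map_a$values; b <- map_b$values
  r <- rep(NA_real_, nv)
  for (i in seq_along(vertices)) {
    idx <- neighborhoods[[i]]$index
    n <- length(idx)
    if (n < 3) next
    x <- a[idx]; y <- b[idx]
    sx <- sum(x); sy <- sum(y)
    vx <- sum(x * x) - sx * sx / n
    vy <- sum(y * y) - sy * sy / n
    if (vx <= 0 || vy <= 0) next
    r[vertices[i]] <- (sum(x * y) - sx * sy / n) / sqrt(vx * vy)
  }
  r <- pmin(1, pmax(-1, r))
  structure(list(r_map = surface_map(r, "correlation"),
                 labels = surface$labels,
                 vertex_areas = surface$vertex_areas,
                 radius_mm = radius_mm,
                 params = NULL),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ok <- !is.na(x$r_map$values)
  cat("correlation_result:", sum(ok), "of", length(ok),
      "vertices defined; median r =",
      if (any(ok)) sprintf("%.3f", stats::median(x$r_map$values[ok]))
      else "NA", "\n")
  invisible(x)
}

#' Correlated surface area within a region
#'
#' The summed vertex area, over the defined vertices of the region, where
#' local correlation strictly exceeds \code{threshold}. Monotone
#' non-increasing in the threshold.
#'
#' @param result a \code{\link{local_correlation}} result.
#' @param region integer region label present on the surface.
#' @param threshold correlation threshold, strictly inside (-1, 1)
#'   (default 0.5).
#' @return area in mm^2.
#' @export
correlated_area <- function(result, region, threshold = 0.5) {
  stopifnot(inherits(result, "correlation_result"),
            threshold > -1, threshold < 1)
  if (!region %in% result$labels)
    stop("correlated_area: unknown region ", region)
  r <- result$r_map$values
  sel <- result$labels == region & !is.na(r) & r > threshold
  sum(result$vertex_areas[sel])
}

#' Optimize (depth, angle) on a grid against histology
#'
#' For every cell of the (depth, angle) grid, filters each subject's
#' terminals by that window, builds the terminal density map, correlates it
#' locally with that subject's histological fluorescence map, and measures
#' the surface area of the region where r exceeds the configured threshold.
#' The objective is the arithmetic mean of that area across subjects; the
#' returned cell is the argmax, with ties broken toward smaller angle, then
#' smaller depth (logged). If every objective is zero the tie-break cell is
#' returned with a degenerate-objective warning.
#'
#' @param subjects list of subjects; each a list with either
#'   \code{terminals} (data frame from \code{\link{terminal_geometries}},
#'   already seed-selected) or \code{tractogram} plus \code{seed_center_mm}
#'   (selection and terminal geometry are then computed here), and
#'   \code{histo_map} (fluorescence \code{\link{surface_map}}).
#' @param surface the common \code{\link{labeled_surface}}.
#' @param region region label whose correlated area is maximized.
#' @param config a \code{\link{run_config}} (grids, tolerances, radii,
#'   threshold, smoothing).
#' @return an object of class \code{optimal_params}: \code{region},
#'   \code{depth_mm}, \code{angle_deg}, \code{mean_area_mm2}, and the full
#'   \code{objective} grid (data frame).
#' @export
optimize_params <- function(subjects, surface, region, config = run_config()) {
  stopifnot(length(subjects) >= 1, inherits(surface, "labeled_surface"))
  validate_run_config(config)
  region_vertices <- which(surface$labels == region)
  if (length(region_vertices) == 0)
    stop("optimize_params: unknown region ", region)

  terminals <- lapply(subjects, function(su) {
    if (!is.null(su$terminals)) return(su$terminals)
    if (is.null(su$tractogram) || is.null(su$seed_center_mm))
      stop("optimize_params: subject needs $terminals or $tractogram + ",
           "$seed_center_mm")
    sel <- select_by_seed(su$tractogram,
                          seed_sphere(su$seed_center_mm,
                                      config$seed_sphere_diameter_mm))
    terminal_geometries(sel, surface)
  })
  histo <- lapply(subjects, `[[`, "histo_map")

  nb_smooth <- geodesic_neighborhoods(surface, config$density_smoothing_mm)
  nb_corr <- geodesic_neighborhoods(surface, config$correlation_radius_mm,
                                    region_vertices)

  grid <- expand.grid(angle_deg = config$grid_angles_deg,
                      depth_mm = config$grid_depths_mm)  # angle varies fastest
  grid <- grid[order(grid$angle_deg, grid$depth_mm), ]
  grid$mean_area_mm2 <- NA_real_
  for (g in seq_len(nrow(grid))) {
    areas <- vapply(seq_along(subjects), function(s) {
      kept <- filter_by_params(terminals[[s]], grid$depth_mm[g],
                               grid$angle_deg[g],
                               config$depth_tolerance_mm,
                               config$angle_tolerance_deg)
      dm <- density_map(kept, surface, config$density_smoothing_mm,
                        neighborhoods = nb_smooth)
      cr <- local_correlation(dm, histo[[s]], surface,
                              config$correlation_radius_mm,
                              vertices = region_vertices,
                              neighborhoods = nb_corr)
      correlated_area(cr, region, config$correlation_threshold)
    }, numeric(1))
    grid$mean_area_mm2[g] <- mean(areas)
  }
  # ties toward smaller angle then smaller depth: rows are already in that
  # order, so the first strict maximum wins
  best <- which.max(grid$mean_area_mm2)
  if (all(grid$mean_area_mm2 == 0))
    ot_log("optimize_params: all objectives are zero for region ", region,
           "; returning the tie-break cell", level = "warn")
  ties <- sum(grid$mean_area_mm2 == grid$mean_area_mm2[best])
  if (ties > 1)
    ot_log("optimize_params: ", ties, " grid cells tied at the maximum; ",
           "tie broken toward smaller angle, then smaller depth")
  out <- structure(list(region = region,
                        depth_mm = grid$depth_mm[best],
                        angle_deg = grid$angle_deg[best],
                        mean_area_mm2 = grid$mean_area_mm2[best],
                        objective = grid),
                   class = "optimal_params")
  ot_log("optimize_params: region ", region, " -> depth ", out$depth_mm,
         " mm, angle ", out$angle_deg, " deg (mean area ",
         signif(out$mean_area_mm2, 5), " mm^2)")
  out
}

#' @export
print.optimal_params <- function(x, ...) {
  cat(sprintf(
    "optimal_params: region %s -> depth %.3g mm, angle %.3g deg (mean correlated area %.4g mm^2)\n",
    x$region, x$depth_mm, x$angle_deg, x$mean_area_mm2))
  invisible(x)
}

#' Whole-target connectivity report
#'
#' For each hemisphere: streamlines intersecting the whole target mask are
#' kept, each terminal is measured on the surface, and each region's
#' optimal (depth, angle) window is applied to the terminals of that
#' region. Reported per region:
#' \describe{
#'   \item{pct_of_all_fibers}{100 x region's filtered terminal count /
#'     total filtered count over the reported regions (sums to 100 per
#'     hemisphere);}
#'   \item{pct_region_surface_projecting}{100 x area of region vertices
#'     lying within the density smoothing radius (geodesically) of at
#'     least one filtered terminal vertex / total region area.}
#' }
#' With several hemispheres, the mean and the standard error of the mean
#' (n - 1 denominator) across hemispheres are reported.
#'
#' @param hemispheres list of hemispheres; each a list with
#'   \code{tractogram}, and either \code{target_mask} (a logical 3D array
#'   wrapped as a \code{\link{histology_block}}-geometry list with
#'   \code{data}, \code{in_plane_res_mm}, \code{slice_spacing_mm},
#'   \code{origin_mm} — any nonzero voxel counts) or \code{seed_center_mm}
#'   (a \code{\link{seed_sphere}} of the configured diameter is then used
#'   as the target).
#' @param surface the common \code{\link{labeled_surface}}.
#' @param params_by_region list of \code{\link{optimal_params}} (one per
#'   region to report).
#' @param config a \code{\link{run_config}}.
#' @return an object of class \code{connectivity_report}: data frame
#'   \code{table} with columns \code{region}, \code{depth_mm},
#'   \code{angle_deg}, \code{pct_of_all_fibers},
#'   \code{pct_of_all_fibers_sem}, \code{pct_region_surface_projecting},
#'   \code{pct_region_surface_projecting_sem}; plus the per-hemisphere
#'   matrices.
#' @export
connectivity_report <- function(hemispheres, surface, params_by_region,
                                config = run_config()) {
  stopifnot(length(hemispheres) >= 1,
            all(vapply(params_by_region, inherits, TRUE, "optimal_params")))
  validate_run_config(config)
  regions <- vapply(params_by_region, `[[`, numeric(1), "region")
  nb_proj <- geodesic_neighborhoods(surface, config$density_smoothing_mm)

  fib <- matrix(NA_real_, length(hemispheres), length(regions))
  surf <- matrix(NA_real_, length(hemispheres), length(regions))
  for (h in seq_along(hemispheres)) {
    hemi <- hemispheres[[h]]
    tg <- hemi$tractogram
    if (!is.null(hemi$target_mask)) {
      tg <- select_by_mask(tg, hemi$target_mask)
    } else if (!is.null(hemi$seed_center_mm)) {
      tg <- select_by_seed(tg, seed_sphere(hemi$seed_center_mm,
                                           config$seed_sphere_diameter_mm))
    } else stop("connectivity_report: hemisphere needs $target_mask or ",
                "$seed_center_mm")
    term <- terminal_geometries(tg, surface)
    counts <- numeric(length(regions))
    proj_area <- numeric(length(regions))
    for (j in seq_along(regions)) {
      p <- params_by_region[[j]]
      kept <- filter_by_params(term[term$region == regions[j], , drop = FALSE],
                               p$depth_mm, p$angle_deg,
                               config$depth_tolerance_mm,
                               config$angle_tolerance_deg)
      counts[j] <- nrow(kept)
      rv <- which(surface$labels == regions[j])
      if (nrow(kept) > 0) {
        near <- unique(unlist(lapply(unique(kept$vertex),
                                     function(v) nb_proj[[v]]$index)))
        proj_area[j] <- sum(surface$vertex_areas[intersect(near, rv)])
      }
      surf[h, j] <- 100 * proj_area[j] / sum(surface$vertex_areas[rv])
    }
    total <- sum(counts)
    if (total == 0) {
      ot_log("connectivity_report: hemisphere ", h,
             " kept no streamlines after filtering; reporting zeros",
             level = "warn")
      fib[h, ] <- 0
    } else fib[h, ] <- 100 * counts / total
  }

  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  tab <- data.frame(
    region = regions,
    depth_mm = vapply(params_by_region, `[[`, numeric(1), "depth_mm"),
    angle_deg = vapply(params_by_region, `[[`, numeric(1), "angle_deg"),
    pct_of_all_fibers = colMeans(fib),
    pct_of_all_fibers_sem = apply(fib, 2, sem),
    pct_region_surface_projecting = colMeans(surf),
    pct_region_surface_projecting_sem = apply(surf, 2, sem))
  structure(list(table = tab, fibers_by_hemisphere = fib,
                 surface_by_hemisphere = surf),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("connectivity_report (", nrow(x$fibers_by_hemisphere),
      " hemisphere(s)):\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

# Streamlines with >= 1 point inside a nonzero voxel of the target mask.
select_by_mask <- function(tg, mask) {
  stopifnot(inherits(tg, "tractogram"))
  res <- mask$in_plane_res_mm; sp <- mask$slice_spacing_mm
  dm <- dim(mask$data)
  keep <- vapply(tg$streamlines, function(s) {
    i <- floor((s[, 1] - mask$origin_mm[1]) / res) + 1L
    j <- floor((s[, 2] - mask$origin_mm[2]) / res) + 1L
    k <- round((s[, 3] - mask$origin_mm[3]) / sp) + 1L
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
    if (!any(ok)) return(FALSE)
    any(mask$data[cbind(i[ok], j[ok], k[ok])] > 0)
  }, logical(1))
  structure(list(streamlines = tg$streamlines[keep], ids = tg$ids[keep]),
            class = "tractogram")
}
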