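#' Per-vertex surface map
#'
#' A scalar field on the vertices of a \code{\link{labeled_surface}}:
#' terminal density, projected fluorescence, or local correlation. Density
#' and fluorescence maps must be non-negative; correlation maps may contain
#' \code{NA} at vertices where the coefficient is undefined.
#'
#' @param values numeric vector, one value per vertex.
#' @param kind \code{"density"}, \code{"fluorescence"} or
#'   \code{"correlation"}.
#' @return an object of class \code{surface_map}.
#' @export
surface_map <- function(values, kind = c("density", "fluorescence",
                                         "correlation")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind != "correlation") {
    if (any(is.na(values)))
      stop("surface_map: NA values only allowed in correlation maps")
    if (any(values < 0))
      stop("surface_map: ", kind, " maps must be non-negative")
  } else {
    ok <- values[!is.na(values)]
    if (any(ok < -1 - 1e-12 | ok > 1 + 1e-12))
      stop("surface_map: correlation values must lie in [-1, 1]")
  }
  structure(list(values = values, kind = kind), class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat("surface_map (", x$kind, "): ", length(x$values), " vertices, ",
      sum(!is.na(x$values)), " defined\n", sep = "")
  invisible(x)
}

#' Seed sphere
#'
#' The spherical region of interest centred on an injection site inside the
#' deep target, used to select the streamlines that reach it. The default
#' diameter is 1 mm.
#'
#' @param center_mm 3D center, mm, world space.
#' @param diameter_mm sphere diameter, mm (> 0).
#' @return an object of class \code{seed_sphere}.
#' @export
seed_sphere <- function(center_mm, diameter_mm = 1.0) {
  center_mm <- as.numeric(center_mm)
  stopifnot(length(center_mm) == 3, all(is.finite(center_mm)),
            diameter_mm > 0)
  structure(list(center_mm = center_mm, diameter_mm = diameter_mm),
            class = "seed_sphere")
}

#' Select streamlines intersecting a seed sphere
#'
#' Keeps exactly the streamlines having at least one point whose Euclidean
#' distance to the sphere center is \code{<=} the radius (boundary
#' inclusive). Order and ids are preserved; the empty result is allowed.
#' The operation is idempotent.
#'
#' @param tg a \code{\link{tractogram}}.
#' @param sphere a \code{\link{seed_sphere}}.
#' @return the selected \code{\link{tractogram}}.
#' @export
select_by_seed <- function(tg, sphere) {
  stopifnot(inherits(tg, "tractogram"), inherits(sphere, "seed_sphere"))
  r <- sphere$diameter_mm / 2
  keep <- vapply(tg$streamlines, function(s) {
    d2 <- (s[, 1] - sphere$center_mm[1])^2 +
          (s[, 2] - sphere$center_mm[2])^2 +
          (s[, 3] - sphere$center_mm[3])^2
    min(d2) <= r * r
  }, logical(1))
  out <- structure(list(streamlines = tg$streamlines[keep],
                        ids = tg$ids[keep]), class = "tractogram")
  ot_log("select_by_seed: ", length(tg$streamlines), " in, ",
         sum(keep), " kept (radius ", r, " mm)")
  out
}

#' Terminal cortical geometry of one streamline
#'
#' Finds the last crossing of the streamline through the cortical surface
#' before its terminal end, and measures there:
#' \describe{
#'   \item{depth_mm}{the arc length along the streamline from the surface
#'     crossing to the terminal point;}
#'   \item{angle_deg}{the angle between the terminal direction — the
#'     least-squares direction of the last \code{k} points — and the inward
#'     surface normal, interpolated barycentrically at the crossing point.
#'     A fiber leaving the cortex perpendicular to the surface has angle 0.}
#' }
#' The crossing is located by exact segment–triangle intersection, walking
#' the streamline backwards from the terminal so that the \emph{last}
#' crossing is found (a streamline grazing a sulcal bank twice is measured
#' at its final entry). The region is the label of the nearest vertex of
#' the crossed triangle.
#'
#' @param streamline an n x 3 matrix of points, mm.
#' @param surface a \code{\link{labeled_surface}}.
#' @param end which end is the cortical terminal: \code{"last"} (default)
#'   or \code{"first"}.
#' @param k number of terminal points defining the terminal direction
#'   (default 3; single-segment tangents are noisy at streamline step
#'   scale).
#' @return a one-row data frame with columns \code{crossing_x/y/z},
#'   \code{depth_mm}, \code{angle_deg}, \code{region}, \code{vertex} (the
#'   nearest surface vertex at the crossing).
#' @export
terminal_geometry <- function(streamline, surface, end = c("last", "first"),
                              k = 3) {
  end <- match.arg(end)
  s <- as.matrix(streamline)
  if (end == "first") s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
  np <- nrow(s)
  if (np < 2) stop("terminal_geometry: streamline has fewer than 2 points")

  hit <- NULL
  for (i in seq.int(np - 1, 1)) {     # walk backwards from the terminal
    hit <- segment_surface_crossing(s[i, ], s[i + 1, ], surface)
    if (!is.null(hit)) { seg_i <- i; break }
  }
  if (is.null(hit))
    stop("terminal_geometry: no surface crossing found along streamline")

  # depth: arc length from the crossing to the terminal point
  depth <- sqrt(sum((s[seg_i + 1, ] - hit$point)^2))
  if (seg_i + 1 < np) {
    rest <- s[(seg_i + 1):np, , drop = FALSE]
    depth <- depth + sum(sqrt(rowSums(diff(rest)^2)))
  }

  # terminal direction: least-squares line through the last k points,
  # oriented along travel
  kk <- min(k, np)
  tailpts <- s[(np - kk + 1):np, , drop = FALSE]
  dir <- ls_direction(tailpts)

  # inward normal: barycentric interpolation of vertex normals
  tri <- surface$triangles[hit$triangle, ]
  nrm <- hit$bary[1] * surface$normals[tri[1], ] +
         hit$bary[2] * surface$normals[tri[2], ] +
         hit$bary[3] * surface$normals[tri[3], ]
  nrm <- nrm / sqrt(sum(nrm^2))
  inward <- -nrm
  cosang <- sum(dir * inward)
  angle <- acos(min(1, max(-1, cosang))) * 180 / pi

  nearest <- tri[which.max(hit$bary)]
  data.frame(crossing_x = hit$point[1], crossing_y = hit$point[2],
             crossing_z = hit$point[3], depth_mm = depth,
             angle_deg = angle, region = surface$labels[nearest],
             vertex = nearest)
}

# Least-squares direction of a small point cloud, oriented from first to
# last point; falls back to the chord for degenerate clouds.
ls_direction <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 3)
  dir <- sv$v[, 1]
  chord <- pts[nrow(pts), ] - pts[1, ]
  if (sum(dir * chord) < 0) dir <- -dir
  if (sv$d[1] < 1e-12) {
    dir <- chord / sqrt(sum(chord^2))
  }
  dir
}

# Last intersection of segment a->b with the surface (largest parameter t),
# by vectorized Moller-Trumbore over bbox-prefiltered triangles.
# Returns NULL or list(point, triangle, bary, t).
segment_surface_crossing <- function(a, b, surface) {
  tr <- surface$triangles
  v <- surface$vertices
  lo <- pmin(a, b); hi <- pmax(a, b)
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  cand <- which(pmin(p1[, 1], p2[, 1], p3[, 1]) <= hi[1] &
                pmax(p1[, 1], p2[, 1], p3[, 1]) >= lo[1] &
                pmin(p1[, 2], p2[, 2], p3[, 2]) <= hi[2] &
                pmax(p1[, 2], p2[, 2], p3[, 2]) >= lo[2] &
                pmin(p1[, 3], p2[, 3], p3[, 3]) <= hi[3] &
                pmax(p1[, 3], p2[, 3], p3[, 3]) >= lo[3])
  if (length(cand) == 0) return(NULL)
  e1 <- p2[cand, , drop = FALSE] - p1[cand, , drop = FALSE]
  e2 <- p3[cand, , drop = FALSE] - p1[cand, , drop = FALSE]
  d <- b - a
  pvec <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                d[3] * e2[, 1] - d[1] * e2[, 3],
                d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- -sweep(p1[cand, , drop = FALSE], 2, a)   # a - p1
  u <- rowSums(tvec * pvec) / det
  qvec <- cross3(tvec, e1)
  vv <- as.vector(qvec %*% d) / det
  tt <- rowSums(qvec * e2) / det
  eps <- 1e-9
  inside <- ok & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps &
            tt >= -eps & tt <= 1 + eps
  if (!any(inside)) return(NULL)
  best <- which(inside)[which.max(tt[inside])]
  t_best <- min(1, max(0, tt[best]))
  pt <- a + t_best * d
  u_b <- min(1, max(0, u[best])); v_b <- min(1, max(0, vv[best]))
  list(point = pt, triangle = cand[best],
       bary = c(1 - u_b - v_b, u_b, v_b), t = t_best)
}

#' Terminal geometry for every streamline of a tractogram
#'
#' Applies \code{\link{terminal_geometry}} to each streamline; streamlines
#' with no surface crossing are excluded with a log entry rather than
#' failing the batch.
#'
#' @param tg a \code{\link{tractogram}}.
#' @param surface a \code{\link{labeled_surface}}.
#' @param end,k passed to \code{\link{terminal_geometry}}.
#' @return a data frame, one row per streamline with a crossing, with an
#'   \code{id} column carrying the streamline id.
#' @export
terminal_geometries <- function(tg, surface, end = "last", k = 3) {
  stopifnot(inherits(tg, "tractogram"))
  rows <- vector("list", length(tg$streamlines))
  n_skip <- 0
  for (i in seq_along(tg$streamlines)) {
    g <- tryCatch(terminal_geometry(tg$streamlines[[i]], surface, end, k),
                  error = function(e) NULL)
    if (is.null(g)) { n_skip <- n_skip + 1; next }
    g$id <- tg$ids[i]
    rows[[i]] <- g
  }
  if (n_skip > 0)
    ot_log("terminal_geometries: ", n_skip,
           " streamline(s) without surface crossing excluded")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(crossing_x = numeric(0), crossing_y = numeric(0),
                      crossing_z = numeric(0), depth_mm = numeric(0),
                      angle_deg = numeric(0), region = integer(0),
                      vertex = integer(0), id = integer(0))
  out
}

#' Filter terminals by a (depth, angle) window
#'
#' Keeps exactly the terminals with \code{|depth - depth_mm| <=
#' tol_depth_mm} and \code{|angle - angle_deg| <= tol_angle_deg}. With
#' infinite tolerances this is the identity.
#'
#' @param terminals data frame from \code{\link{terminal_geometries}} (any
#'   data frame with \code{depth_mm} and \code{angle_deg} columns).
#' @param depth_mm window center depth, mm.
#' @param angle_deg window center angle, degrees.
#' @param tol_depth_mm,tol_angle_deg half-window tolerances (>= 0).
#' @return the kept rows of \code{terminals}.
#' @export
filter_by_params <- function(terminals, depth_mm, angle_deg,
                             tol_depth_mm = 0.5, tol_angle_deg = 15) {
  stopifnot(tol_depth_mm >= 0, tol_angle_deg >= 0)
  keep <- abs(terminals$depth_mm - depth_mm) <= tol_depth_mm &
          abs(terminals$angle_deg - angle_deg) <= tol_angle_deg
  out <- terminals[keep, , drop = FALSE]
  ot_log("filter_by_params: (depth ", depth_mm, " mm, angle ", angle_deg,
         " deg, tol ", tol_depth_mm, "/", tol_angle_deg, "): ",
         nrow(terminals), " in, ", nrow(out), " kept")
  out
}

#' Terminal density map on the surface
#'
#' Each terminal deposits unit mass at its crossing vertex; with
#' \code{smoothing_mm > 0} the mass is spread over the geodesic neighborhood
#' of that radius with a truncated Gaussian kernel (sigma = radius / 2) and
#' renormalized per terminal, so total map mass equals the terminal count
#' exactly (to numerical precision).
#'
#' @param terminals data frame with a \code{vertex} column (from
#'   \code{\link{terminal_geometries}}).
#' @param surface a \code{\link{labeled_surface}}.
#' @param smoothing_mm geodesic smoothing radius, mm (>= 0; 0 = no
#'   smoothing).
#' @param neighborhoods optional precomputed
#'   \code{\link{geodesic_neighborhoods}(surface, smoothing_mm)} for all
#'   vertices, to amortize the Dijkstra pass over repeated calls.
#' @return a density \code{\link{surface_map}}.
#' @export
density_map <- function(terminals, surface, smoothing_mm = 0,
                        neighborhoods = NULL) {
  stopifnot(inherits(surface, "labeled_surface"), smoothing_mm >= 0)
  nv <- nrow(surface$vertices)
  vals <- numeric(nv)
  verts <- terminals$vertex
  if (length(verts) > 0) {
    if (smoothing_mm == 0) {
      tab <- table(verts)
      vals[as.integer(names(tab))] <- as.numeric(tab)
    } else {
      if (is.null(neighborhoods))
        neighborhoods <- geodesic_neighborhoods(surface, smoothing_mm)
      sigma <- smoothing_mm / 2
      counts <- table(verts)
      for (nm in names(counts)) {
        v <- as.integer(nm)
        nb <- neighborhoods[[v]]
        w <- exp(-0.5 * (nb$dist / sigma)^2)
        w <- w / sum(w)
        vals[nb$index] <- vals[nb$index] + as.numeric(counts[[nm]]) * w
      }
    }
  }
  ot_log("density_map: ", length(verts), " terminals, smoothing ",
         smoothing_mm, " mm, total mass ", sum(vals))
  surface_map(vals, "density")
}
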