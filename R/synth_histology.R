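#' Synthetic histology block from a cortical origin map
#'
#' Emulates a stack of segmented fluorescence sections. Each surface vertex
#' with positive weight in \code{origin_map} owns a cortical-ribbon
#' \emph{column}: the voxels lying within \code{tube_radius_mm} of the
#' segment running from the vertex down the inward normal to
#' \code{ribbon_depth_mm}, clipped to the vertex's Voronoi cell (its
#' nearest surface vertex must be the owning vertex). Clipping makes the
#' ground-truth cortical origin of every fluorescent voxel unambiguous,
#' which is what downstream confusion matrices need. Within the column of
#' vertex v, voxels become fluorescent independently with probability
#' proportional to the vertex weight and inversely proportional to the
#' column's voxel count, so the \emph{expected fluorescent volume under a
#' vertex is exactly proportional to its origin weight} regardless of local
#' mesh geometry — and the total volume is stable under resolution changes
#' (the per-voxel probability compensates the voxel count).
#'
#' Sections are slabs perpendicular to z, spaced \code{slice_spacing_mm}
#' apart (default 0.32 mm, i.e. every 8th 40-µm section), with square
#' in-plane pixels of side \code{in_plane_res_mm}.
#'
#' @param surface a \code{\link{labeled_surface}}.
#' @param origin_map a \code{\link{surface_map}} (or bare numeric vector) of
#'   non-negative per-vertex weights.
#' @param slice_spacing_mm distance between consecutive section centers, mm.
#' @param in_plane_res_mm in-plane pixel size, mm.
#' @param rng_seed integer seed driving the per-voxel sampling;
#'   deterministic for a fixed seed.
#' @param ribbon_depth_mm cortical ribbon thickness below the surface, mm.
#' @param tube_radius_mm lateral column radius, mm.
#' @return a \code{\link{histology_block}}; empty (all-background) when the
#'   origin map is identically zero.
#' @export
make_histology_block <- function(surface, origin_map, slice_spacing_mm = 0.32,
                                 in_plane_res_mm = 0.1, rng_seed = 1L,
                                 ribbon_depth_mm = 2.5,
                                 tube_radius_mm = 0.5) {
  stopifnot(inherits(surface, "labeled_surface"))
  w <- if (inherits(origin_map, "surface_map")) origin_map$values
       else as.numeric(origin_map)
  if (length(w) != nrow(surface$vertices))
    stop("make_histology_block: origin_map length must equal vertex count")
  if (any(w < 0)) stop("make_histology_block: origin_map must be non-negative")
  if (in_plane_res_mm > ribbon_depth_mm)
    ot_log("make_histology_block: in-plane resolution coarser than the ",
           "cortical ribbon; block will be heavily aliased", level = "warn")

  active <- which(w > 0)
  # block grid covering the surface plus the ribbon, with margin
  margin <- ribbon_depth_mm + tube_radius_mm + 0.5
  lo <- apply(surface$vertices, 2, min) - margin
  hi <- apply(surface$vertices, 2, max) + margin
  nx <- ceiling((hi[1] - lo[1]) / in_plane_res_mm)
  ny <- ceiling((hi[2] - lo[2]) / in_plane_res_mm)
  nz <- ceiling((hi[3] - lo[3]) / slice_spacing_mm) + 1L
  arr <- array(0L, dim = c(nx, ny, nz))
  origin <- c(lo[1], lo[2], lo[3])  # center of voxel (1,1,1) offset below

  if (length(active) > 0) {
    wmax <- max(w)
    r <- tube_radius_mm
    # pass 1: the ribbon column of every active vertex
    columns <- vector("list", length(active))
    for (ai in seq_along(active)) {
      v <- active[ai]
      p0 <- surface$vertices[v, ]
      d <- -surface$normals[v, ]                     # inward
      p1 <- p0 + d * ribbon_depth_mm
      blo <- pmin(p0, p1) - r; bhi <- pmax(p0, p1) + r
      i_r <- index_range(blo[1], bhi[1], lo[1], in_plane_res_mm, nx)
      j_r <- index_range(blo[2], bhi[2], lo[2], in_plane_res_mm, ny)
      k_r <- index_range(blo[3], bhi[3], lo[3], slice_spacing_mm, nz)
      if (!length(i_r) || !length(j_r) || !length(k_r)) next
      cx <- lo[1] + (i_r - 0.5) * in_plane_res_mm
      cy <- lo[2] + (j_r - 0.5) * in_plane_res_mm
      cz <- lo[3] + (k_r - 1) * slice_spacing_mm
      pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
      hit <- point_segment_distance(pts, p0, p1) <= r
      if (any(hit)) {
        nn <- nearest_vertex(pts[hit, , drop = FALSE], surface$vertices)
        hit[hit] <- nn$index == v                   # Voronoi clipping
      }
      if (!any(hit)) next
      columns[[ai]] <- as.matrix(expand.grid(i = i_r, j = j_r,
                                             k = k_r))[hit, , drop = FALSE]
    }
    # pass 2: per-voxel Bernoulli sampling at p = (w/wmax) * (m_min/m_v)
    m <- vapply(columns, function(cc) if (is.null(cc)) 0L else nrow(cc), 1L)
    if (any(m > 0)) {
      m_min <- min(m[m > 0])
      with_seed(rng_seed, {
        for (ai in seq_along(active)) {
          if (m[ai] == 0) next
          p <- (w[active[ai]] / wmax) * (m_min / m[ai])
          pick <- runif(m[ai]) <= p
          if (any(pick)) arr[columns[[ai]][pick, , drop = FALSE]] <- 1L
        }
      })
    }
  }
  blk <- histology_block(arr, in_plane_res_mm, slice_spacing_mm,
                         origin_mm = origin)
  ot_log("make_histology_block: ", sum(arr), " fluorescent voxels over ",
         nz, " sections")
  blk
}

index_range <- function(wlo, whi, origin, step, nmax) {
  i0 <- max(1L, floor((wlo - origin) / step))
  i1 <- min(nmax, ceiling((whi - origin) / step) + 1L)
  if (i0 > i1) integer(0) else seq.int(i0, i1)
}

point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(pts, 2, a)
  t <- pmin(1, pmax(0, (ap %*% ab) / len2))
  proj <- outer(as.vector(t), ab)
  sqrt(rowSums((ap - proj)^2))
}
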