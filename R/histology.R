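#' Histology block
#'
#' An ordered stack of segmented (binary) section images reconstituted into
#' a 3D volume with anisotropic voxels: square in-plane pixels of side
#' \code{in_plane_res_mm} and inter-slice spacing \code{slice_spacing_mm}
#' along z (the slicing axis). The default spacing, 0.32 mm, corresponds to
#' keeping every 8th 40-µm section. Gaps between sections are \emph{not}
#' interpolated: statistics are computed on the sampled slabs, each slab
#' standing for one inter-section interval, which is unbiased for volume
#' fractions.
#'
#' World coordinates: in-plane pixel (i, j) of slice k has its center at
#' \code{origin_mm + ((i - 0.5) res, (j - 0.5) res, (k - 1) spacing)}; the
#' first slice plane passes through \code{origin_mm[3]}.
#'
#' @param slices either a 3D array (x, y, slice) or a list of equally sized
#'   binary matrices.
#' @param in_plane_res_mm in-plane pixel size, mm (> 0).
#' @param slice_spacing_mm inter-slice spacing, mm (> 0, default 0.32).
#' @param origin_mm 3D world position registering the block (default
#'   origin).
#' @return an object of class \code{histology_block} with the binary array
#'   in \code{$data}.
#' @export
histology_block <- function(slices, in_plane_res_mm,
                            slice_spacing_mm = 0.32,
                            origin_mm = c(0, 0, 0)) {
  stopifnot(in_plane_res_mm > 0, slice_spacing_mm > 0,
            length(origin_mm) == 3)
  if (is.list(slices)) {
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1)
      stop("histology_block: slices have inconsistent shapes")
    arr <- array(0L, dim = c(dims[[1]], length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
    slices <- arr
  }
  if (length(dim(slices)) != 3)
    stop("histology_block: need a 3D array or a list of matrices")
  storage.mode(slices) <- "integer"
  if (any(!slices %in% c(0L, 1L)))
    stop("histology_block: slices must be binary (0/1)")
  structure(list(data = slices,
                 in_plane_res_mm = in_plane_res_mm,
                 slice_spacing_mm = slice_spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "histology_block")
}

#' @export
print.histology_block <- function(x, ...) {
  d <- dim(x$data)
  cat("histology_block:", d[1], "x", d[2], "pixels x", d[3], "slices,",
      sprintf("%.3g mm in-plane, %.3g mm spacing;", x$in_plane_res_mm,
              x$slice_spacing_mm),
      sum(x$data), "fluorescent voxels\n")
  invisible(x)
}

#' Fluorescent volume of a block
#'
#' Voxel count times the anisotropic voxel volume
#' (res^2 x spacing), in mm^3. Each section stands for one full
#' inter-section slab (single-slab convention: one slice's volume is
#' count x res^2 x spacing).
#'
#' @param block a \code{\link{histology_block}}.
#' @return volume in mm^3.
#' @export
fluorescent_volume <- function(block) {
  stopifnot(inherits(block, "histology_block"))
  sum(block$data) * block$in_plane_res_mm^2 * block$slice_spacing_mm
}

#' Segment fluorescence on each section
#'
#' Turns raw intensity sections into binary masks, either with one fixed
#' global threshold (pixels strictly above threshold are foreground) or
#' with Otsu's method computed per slice. A constant-intensity slice under
#' Otsu falls back to all-background with a warning.
#'
#' @param raw_slices list of numeric matrices (finite, non-negative
#'   intensities).
#' @param method \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold global threshold for \code{method = "fixed"}.
#' @return list of binary integer matrices, same shapes as the input.
#' @export
segment_slices <- function(raw_slices, method = c("otsu", "fixed"),
                           threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(raw_slices))
  for (sl in raw_slices)
    if (any(!is.finite(sl)) || any(sl < 0))
      stop("segment_slices: intensities must be finite and non-negative")
  if (method == "fixed") {
    if (is.null(threshold)) stop("segment_slices: fixed method needs a threshold")
    out <- lapply(raw_slices, function(sl) {
      m <- sl > threshold; storage.mode(m) <- "integer"; m
    })
  } else {
    out <- lapply(seq_along(raw_slices), function(k) {
      sl <- raw_slices[[k]]
      rng <- range(sl)
      if (diff(rng) == 0) {
        ot_log("segment_slices: slice ", k,
               " has constant intensity; Otsu undefined, returning ",
               "all-background", level = "warn")
        m <- matrix(0L, nrow(sl), ncol(sl))
        return(m)
      }
      th <- EBImage::otsu(sl, range = rng, levels = 256)
      m <- sl > th; storage.mode(m) <- "integer"; m
    })
  }
  ot_log("segment_slices (", method, "): ", length(raw_slices),
         " slices, ", sum(vapply(out, sum, 1)), " foreground pixels")
  out
}

#' Reconstitute a 3D block from segmented sections
#'
#' Stacks the binary masks into a \code{\link{histology_block}} with
#' anisotropic voxel size (res, res, spacing). The extent along the slicing
#' axis between the first and last slice centers is
#' \code{(n_slices - 1) * slice_spacing_mm}.
#'
#' @param masks list of binary matrices (>= 1, equal shapes).
#' @param in_plane_res_mm in-plane pixel size, mm.
#' @param slice_spacing_mm inter-slice spacing, mm.
#' @param origin_mm world position of the block.
#' @return a \code{\link{histology_block}}.
#' @export
reconstruct_block <- function(masks, in_plane_res_mm,
                              slice_spacing_mm = 0.32,
                              origin_mm = c(0, 0, 0)) {
  if (length(masks) < 1) stop("reconstruct_block: need at least one slice")
  blk <- histology_block(masks, in_plane_res_mm, slice_spacing_mm, origin_mm)
  ot_log("reconstruct_block: ", length(masks), " slices -> ",
         sum(blk$data), " fluorescent voxels, volume ",
         signif(fluorescent_volume(blk), 6), " mm^3")
  blk
}

#' Per-region fluorescence statistics
#'
#' For each region mask, computes the share of all fluorescent volume lying
#' in that region (\code{share_of_total_pct}) and the fraction of the
#' region's volume that is fluorescent (\code{fraction_of_region_pct}).
#' Fluorescent voxels outside every region are reported in an
#' \code{"unassigned"} row, so shares always sum to 100.
#'
#' @param block a \code{\link{histology_block}}.
#' @param region_volumes named list of logical/0-1 arrays in block space
#'   (same dimensions as the block), pairwise disjoint.
#' @return a data frame with columns \code{region},
#'   \code{share_of_total_pct}, \code{fraction_of_region_pct} (NA for the
#'   unassigned row).
#' @export
region_stats <- function(block, region_volumes) {
  stopifnot(inherits(block, "histology_block"), is.list(region_volumes),
            length(region_volumes) >= 1, !is.null(names(region_volumes)))
  fl <- block$data > 0
  total <- sum(fl)
  if (total == 0)
    stop("region_stats: zero total fluorescence; distribution undefined")
  cover <- array(0L, dim = dim(block$data))
  rows <- lapply(names(region_volumes), function(nm) {
    rv <- region_volumes[[nm]]
    if (!all(dim(rv) == dim(block$data)))
      stop("region_stats: region mask '", nm, "' shape mismatch")
    rv <- rv > 0
    cover <<- cover + rv
    inter <- sum(fl & rv)
    data.frame(region = nm,
               share_of_total_pct = 100 * inter / total,
               fraction_of_region_pct =
                 if (sum(rv) > 0) 100 * inter / sum(rv) else NA_real_)
  })
  if (any(cover > 1L)) stop("region_stats: region masks are not disjoint")
  out <- do.call(rbind, rows)
  unassigned <- total - sum(fl & (cover > 0L))
  out <- rbind(out, data.frame(region = "unassigned",
                               share_of_total_pct = 100 * unassigned / total,
                               fraction_of_region_pct = NA_real_))
  rownames(out) <- NULL
  ot_log("region_stats: ", total, " fluorescent voxels over ",
         length(region_volumes), " regions (", unassigned, " unassigned)")
  out
}

# World coordinates of the centers of all fluorescent voxels.
fluorescent_voxel_centers <- function(block) {
  idx <- which(block$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3))
  cbind(block$origin_mm[1] + (idx[, 1] - 0.5) * block$in_plane_res_mm,
        block$origin_mm[2] + (idx[, 2] - 0.5) * block$in_plane_res_mm,
        block$origin_mm[3] + (idx[, 3] - 1) * block$slice_spacing_mm)
}

#' Project block fluorescence onto the cortical surface
#'
#' Every fluorescent voxel assigns its volume (res^2 x spacing) to the
#' nearest surface vertex, provided that vertex lies within
#' \code{max_assign_dist_mm} (default 3 mm — a cap that limits leakage
#' across sulci). The resulting map's total mass equals the assigned
#' fluorescent volume; the unassigned volume is logged, and assigned +
#' unassigned always equals the block's total fluorescent volume.
#'
#' @param block a \code{\link{histology_block}} registered to surface
#'   space.
#' @param surface a \code{\link{labeled_surface}}.
#' @param max_assign_dist_mm assignment cap, mm (>= 0).
#' @return a fluorescence \code{\link{surface_map}} (mm^3 per vertex), with
#'   attribute \code{"unassigned_mm3"}.
#' @export
fluorescence_to_surface <- function(block, surface, max_assign_dist_mm = 3) {
  stopifnot(inherits(block, "histology_block"),
            inherits(surface, "labeled_surface"), max_assign_dist_mm >= 0)
  nv <- nrow(surface$vertices)
  vals <- numeric(nv)
  pts <- fluorescent_voxel_centers(block)
  vol <- block$in_plane_res_mm^2 * block$slice_spacing_mm
  unassigned <- 0
  if (nrow(pts) > 0) {
    nn <- nearest_vertex(pts, surface$vertices)
    ok <- nn$dist <= max_assign_dist_mm
    unassigned <- sum(!ok) * vol
    if (any(ok)) {
      tab <- table(nn$index[ok])
      vals[as.integer(names(tab))] <- as.numeric(tab) * vol
    }
  }
  ot_log("fluorescence_to_surface: ", nrow(pts), " voxels, ",
         signif(sum(vals), 6), " mm^3 assigned, ",
         signif(unassigned, 6), " mm^3 unassigned")
  out <- surface_map(vals, "fluorescence")
  attr(out, "unassigned_mm3") <- unassigned
  out
}

# Nearest vertex (index and distance) for each query point, chunked to
# bound memory.
nearest_vertex <- function(pts, vertices, chunk = 20000L) {
  n <- nrow(pts)
  index <- integer(n); dist <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(vertices^2), "+") -
      2 * block %*% t(vertices)
    j <- max.col(-d2, ties.method = "first")
    index[s:e] <- j
    dist[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(block)), j)]))
  }
  list(index = index, dist = dist)
}
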