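#' Synthetic labeled cortical surface
#'
#' Builds a folded sheet — a triangulated regular grid, sinusoidally
#' displaced in z — partitioned into \code{n_regions} contiguous labeled
#' patches. A folded sheet (rather than a sphere) is used deliberately: its
#' normals vary with position, so the angle between a streamline terminal
#' and the local normal is not degenerate with location and angle filtering
#' is genuinely exercised.
#'
#' The sheet spans \code{extent_mm} x \code{extent_mm} in x-y with fold
#' amplitude \code{fold_amplitude_mm} and wavelength \code{fold_wavelength_mm}
#' (defaults 20 mm, 2 mm, 10 mm: a patch of gyral-scale folding at macaque
#' dimensions). Outward normals point to the +z side; the brain interior is
#' below. Regions are geodesic Voronoi cells of \code{n_regions} randomly
#' chosen seed vertices, hence contiguous. Deterministic for a fixed
#' \code{rng_seed}.
#'
#' @param n_regions number of labeled patches (>= 1), labels 1..n_regions.
#' @param mesh_resolution vertices per grid side (>= 3).
#' @param rng_seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param extent_mm sheet side length, mm.
#' @param fold_amplitude_mm fold amplitude, mm.
#' @param fold_wavelength_mm fold wavelength, mm.
#' @return a \code{\link{labeled_surface}}.
#' @export
#' @examples
#' s <- make_labeled_surface(6, mesh_resolution = 15, rng_seed = 1)
#' table(s$labels)
make_labeled_surface <- function(n_regions, mesh_resolution = 20,
                                 rng_seed = 1L, extent_mm = 20,
                                 fold_amplitude_mm = 2,
                                 fold_wavelength_mm = 10) {
  stopifnot(n_regions >= 1, mesh_resolution >= 3)
  nv_side <- as.integer(mesh_resolution)
  if (n_regions > nv_side^2)
    stop("make_labeled_surface: n_regions exceeds vertex count")

  xs <- seq(0, extent_mm, length.out = nv_side)
  grid <- expand.grid(x = xs, y = xs)
  k <- 2 * pi / fold_wavelength_mm
  z <- fold_amplitude_mm * sin(k * grid$x) * cos(k * grid$y)
  vertices <- cbind(grid$x, grid$y, z)

  # two triangles per grid cell, counter-clockwise seen from +z (outward)
  idx <- function(i, j) (j - 1L) * nv_side + i
  tris <- vector("list", (nv_side - 1L)^2)
  t_i <- 0L
  for (j in seq_len(nv_side - 1L)) {
    for (i in seq_len(nv_side - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      t_i <- t_i + 1L
      tris[[t_i]] <- rbind(c(a, b, c_), c(a, c_, d))
    }
  }
  triangles <- do.call(rbind, tris)

  labels <- with_seed(rng_seed, {
    surf0 <- labeled_surface(vertices, triangles)
    seeds <- sample(nrow(vertices), n_regions)
    g <- mesh_edge_graph(surf0)
    d <- igraph::distances(g, v = seeds)
    as.integer(apply(d, 2, which.min))
  })

  out <- labeled_surface(vertices, triangles, labels)
  ot_log("make_labeled_surface: ", nrow(vertices), " vertices, ",
         n_regions, " regions, seed ", rng_seed)
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, making every generator a pure function of
# (parameters, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Vertices on the topological boundary of the mesh (incident to an edge
# belonging to a single triangle).
boundary_vertices <- function(surface) {
  tr <- surface$triangles
  e_from <- c(tr[, 1], tr[, 2], tr[, 3])
  e_to   <- c(tr[, 2], tr[, 3], tr[, 1])
  key <- paste(pmin(e_from, e_to), pmax(e_from, e_to))
  cnt <- table(key)
  once <- names(cnt)[cnt == 1]
  if (length(once) == 0) return(integer(0))
  parts <- do.call(rbind, strsplit(once, " "))
  sort(unique(as.integer(parts)))
}
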