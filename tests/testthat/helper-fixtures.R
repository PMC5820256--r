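# Shared fixtures and independent oracles. Everything is generated in code;
# heavier fixtures are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small folded test surface with 6 regions.
test_surface <- function() {
  cached("surf18", make_labeled_surface(6, mesh_resolution = 18,
                                        rng_seed = 3))
}

# A flat sheet (zero fold amplitude): normals exactly +z, analytic cases.
flat_surface <- function() {
  cached("flat", make_labeled_surface(1, mesh_resolution = 11, rng_seed = 1,
                                      extent_mm = 10,
                                      fold_amplitude_mm = 0))
}

# Icosphere of radius 1 by midpoint subdivision of an icosahedron.
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!exists(key, envir = mid_cache)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        assign(key, nrow(v), envir = mid_cache)
      }
      get(key, envir = mid_cache)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = v, triangles = f)
}

# --- independent oracles ----------------------------------------------------

# Brute-force min point-to-center distance per streamline.
oracle_min_dist <- function(tg, center) {
  vapply(tg$streamlines, function(s)
    min(sqrt(rowSums(sweep(s, 2, center)^2))), numeric(1))
}

# Independent terminal-geometry oracle: walk a dense resampling of the
# streamline, tracking the *signed distance to the mesh* (closest point on
# any triangle, signed by that triangle's normal); the last sign change is
# the final surface crossing, refined by bisection-style fine sampling.
# Depth is arc length from the refined crossing to the terminal; the
# normal is interpolated barycentrically on the crossing triangle.
# Entirely separate code path from the package's exact ray-triangle
# intersection.
oracle_terminal_geometry <- function(streamline, surface, step = 0.002) {
  s <- as.matrix(streamline)
  segs <- diff(s)
  lens <- sqrt(rowSums(segs^2))
  arc <- c(0, cumsum(lens))
  at <- function(t) {
    vapply(1:3, function(j) approx(arc, s[, j], t)$y, numeric(1))
  }
  coarse_t <- seq(0, arc[length(arc)], by = 0.2)
  coarse_d <- vapply(coarse_t, function(t)
    signed_mesh_distance(at(t), surface)$d, numeric(1))
  flips <- which(coarse_d[-1] <= 0 & coarse_d[-length(coarse_d)] > 0)
  if (length(flips) == 0) return(NULL)
  lo <- coarse_t[flips[length(flips)]]
  hi <- coarse_t[flips[length(flips)] + 1]
  fine_t <- seq(lo, hi, by = step)
  fine_d <- vapply(fine_t, function(t)
    signed_mesh_distance(at(t), surface)$d, numeric(1))
  f <- which(fine_d[-1] <= 0 & fine_d[-length(fine_d)] > 0)
  if (length(f) == 0) return(NULL)
  i <- f[length(f)]
  frac <- fine_d[i] / (fine_d[i] - fine_d[i + 1])
  cross_arc <- fine_t[i] + frac * step
  cross_pt <- at(cross_arc)
  depth <- arc[length(arc)] - cross_arc

  sd <- signed_mesh_distance(cross_pt, surface)
  tri <- surface$triangles[sd$triangle, ]
  bc <- barycentric(sd$closest, surface$vertices[tri[1], ],
                    surface$vertices[tri[2], ], surface$vertices[tri[3], ])
  bc <- pmin(1, pmax(0, bc))
  nrm <- bc[1] * surface$normals[tri[1], ] +
         bc[2] * surface$normals[tri[2], ] + bc[3] * surface$normals[tri[3], ]
  nrm <- nrm / sqrt(sum(nrm^2))
  tangent <- at(arc[length(arc)]) - at(arc[length(arc)] - 0.01)
  tangent <- tangent / sqrt(sum(tangent^2))
  ang <- acos(min(1, max(-1, sum(tangent * -nrm)))) * 180 / pi
  list(depth_mm = depth, angle_deg = ang)
}

# Distance from a point to the mesh: closest point over nearby triangles
# (Ericson's closest-point-on-triangle), signed by the closest triangle's
# outward normal.
signed_mesh_distance <- function(p, surface) {
  tr <- surface$triangles
  v <- surface$vertices
  ctr <- (v[tr[, 1], ] + v[tr[, 2], ] + v[tr[, 3], ]) / 3
  d2c <- colSums((t(ctr) - p)^2)
  cand <- which(d2c <= (sqrt(min(d2c)) + 2)^2)
  best <- list(d2 = Inf)
  for (ti in cand) {
    cp <- closest_point_triangle(p, v[tr[ti, 1], ], v[tr[ti, 2], ],
                                 v[tr[ti, 3], ])
    d2 <- sum((p - cp)^2)
    if (d2 < best$d2) best <- list(d2 = d2, closest = cp, triangle = ti)
  }
  tg <- triangle_geometry(v, tr[best$triangle, , drop = FALSE])
  sgn <- sign(sum((p - best$closest) * tg$normals[1, ]))
  if (sgn == 0) sgn <- 1
  list(d = sgn * sqrt(best$d2), closest = best$closest,
       triangle = best$triangle)
}

closest_point_triangle <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c_
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c_)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(b + (c_ - b) * w)
  }
  den <- va + vb + vc
  a + ab * (vb / den) + ac * (vc / den)
}

barycentric <- function(p, a, b, c_) {
  v0 <- b - a; v1 <- c_ - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

# Breadth-first geodesic neighborhood oracle (edge-walk Dijkstra by hand).
oracle_neighborhood <- function(surface, v0, radius) {
  nv <- nrow(surface$vertices)
  adj <- vector("list", nv)
  tr <- surface$triangles
  for (r in seq_len(nrow(tr))) {
    for (a in 1:3) {
      v <- tr[r, a]
      adj[[v]] <- union(adj[[v]], tr[r, -a])
    }
  }
  dist <- rep(Inf, nv); dist[v0] <- 0
  frontier <- v0
  done <- logical(nv)
  while (length(frontier) > 0) {
    u <- frontier[which.min(dist[frontier])]
    frontier <- setdiff(frontier, u)
    if (done[u]) next
    done[u] <- TRUE
    for (w in adj[[u]]) {
      dd <- dist[u] + sqrt(sum((surface$vertices[u, ] -
                                  surface$vertices[w, ])^2))
      if (dd < dist[w]) {
        dist[w] <- dd
        if (dd <= radius) frontier <- union(frontier, w)
      }
    }
  }
  which(dist <= radius)
}

# Direct two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two-subject synthetic recovery experiment on one common-space surface.
# Per seed, each subject gets a fresh tractogram and a matched histological
# reference built through the full generator -> block -> projection
# pipeline: the fluorescence block is generated from the density of that
# subject's true pathway origins, mirroring the real design where histology
# and tractography image the same pathway.
recovery_setup <- function() {
  cached("recovery", {
    list(cfg = run_config(),
         surf = make_labeled_surface(6, mesh_resolution = 18,
                                     rng_seed = 42))
  })
}

recover_params <- function(setup, seed, depth_jitter = 0, angle_jitter = 0,
                           histo_res_mm = 0.2) {
  subs <- lapply(1:2, function(sj) {
    tr <- make_tractogram(
      setup$surf,
      tract_ground_truth(2, 30, n_true = 50, n_decoy = 50,
                         depth_jitter_mm = depth_jitter,
                         angle_jitter_deg = angle_jitter),
      rng_seed = seed * 10 + sj)
    origin <- density_map(
      data.frame(vertex = tr$truth$vertex[tr$truth$family == "true"]),
      setup$surf, smoothing_mm = setup$cfg$density_smoothing_mm)
    blk <- make_histology_block(setup$surf,
                                surface_map(origin$values, "fluorescence"),
                                in_plane_res_mm = histo_res_mm,
                                rng_seed = seed)
    sel <- select_by_seed(tr$tractogram,
                          seed_sphere(tr$seed_center_mm,
                                      setup$cfg$seed_sphere_diameter_mm))
    list(terminals = terminal_geometries(sel, setup$surf),
         histo_map = fluorescence_to_surface(blk, setup$surf))
  })
  opt <- optimize_params(subs, setup$surf, 1, setup$cfg)
  c(depth = opt$depth_mm, angle = opt$angle_deg)
}
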