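#' Ground truth for a synthetic tractogram
#'
#' Parameters of the planted cortico-subcortical pathway: terminal depth
#' below the cortical surface crossing, terminal angle to the inward normal,
#' counts of pathway and decoy streamlines, jitter scales, the deep seed
#' center emulating an injection site, and the cortical region of origin.
#'
#' @param true_depth_mm planted terminal depth, mm (>= 0).
#' @param true_angle_deg planted terminal angle to the inward normal,
#'   degrees, in [0, 90).
#' @param n_true number of pathway streamlines.
#' @param n_decoy number of decoy streamlines (split into three equal
#'   families: miss the seed sphere, wrong depth, wrong angle — each
#'   violating exactly one filter clause).
#' @param depth_jitter_mm,angle_jitter_deg Gaussian jitter SDs applied to
#'   the planted depth and angle of pathway streamlines (>= 0).
#' @param seed_center_mm 3D seed center, mm; \code{NULL} to place it 8 mm
#'   beneath the surface centroid when the tractogram is generated.
#' @param origin_region region label of pathway terminals.
#' @return an object of class \code{tract_ground_truth}.
#' @export
tract_ground_truth <- function(true_depth_mm = 2, true_angle_deg = 30,
                               n_true = 50, n_decoy = 50,
                               depth_jitter_mm = 0, angle_jitter_deg = 0,
                               seed_center_mm = NULL, origin_region = 1L) {
  stopifnot(true_depth_mm >= 0, true_angle_deg >= 0, true_angle_deg < 90,
            depth_jitter_mm >= 0, angle_jitter_deg >= 0,
            n_true >= 0, n_decoy >= 0)
  structure(list(true_depth_mm = true_depth_mm,
                 true_angle_deg = true_angle_deg,
                 n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
                 depth_jitter_mm = depth_jitter_mm,
                 angle_jitter_deg = angle_jitter_deg,
                 seed_center_mm = seed_center_mm,
                 origin_region = as.integer(origin_region)),
            class = "tract_ground_truth")
}

#' Synthetic tractogram with annotated ground truth
#'
#' Plants \code{n_true} pathway streamlines running from the deep seed
#' center up through the cortical surface at a vertex of the origin region:
#' the final run of each streamline is a straight segment that pierces the
#' surface at the chosen vertex and ends at the planted depth below it, with
#' terminal direction at the planted angle to the inward vertex normal
#' (jitter added per streamline). Decoys come in three equal families, each
#' violating exactly one selection clause while satisfying the others:
#' \describe{
#'   \item{miss_sphere}{correct terminal geometry but starting > 2 mm away
#'     from the seed center (never enters the default 1 mm sphere);}
#'   \item{wrong_depth}{passes through the seed, terminal depth displaced by
#'     1.25–2.5 mm;}
#'   \item{wrong_angle}{passes through the seed, terminal angle displaced by
#'     +31–55 degrees.}
#' }
#' Decoy terminals land on random cortical vertices of any region. All
#' terminal vertices are taken off the mesh boundary. The returned
#' annotations carry, per streamline, the planted depth, angle, terminal
#' vertex, region, family and whether the streamline touches the seed — so
#' any downstream confusion matrix can be computed without re-deriving the
#' geometry. Deterministic for a fixed \code{rng_seed}.
#'
#' @param surface a \code{\link{labeled_surface}}.
#' @param truth a \code{\link{tract_ground_truth}}.
#' @param rng_seed integer seed.
#' @return a list with \code{tractogram} (a \code{\link{tractogram}}),
#'   \code{truth} (annotation data frame), and \code{seed_center_mm}.
#' @export
make_tractogram <- function(surface, truth, rng_seed = 1L) {
  stopifnot(inherits(surface, "labeled_surface"),
            inherits(truth, "tract_ground_truth"))
  if (!truth$origin_region %in% surface$labels)
    stop("make_tractogram: origin_region ", truth$origin_region,
         " not present on surface")
  interior <- setdiff(seq_len(nrow(surface$vertices)),
                      boundary_vertices(surface))
  origin_pool <- interior[surface$labels[interior] == truth$origin_region]
  if (length(origin_pool) == 0)
    stop("make_tractogram: origin_region has no interior vertices")

  center <- truth$seed_center_mm
  if (is.null(center)) {
    centroid <- colMeans(surface$vertices)
    center <- centroid - c(0, 0, 8)
  }

  res <- with_seed(rng_seed, {
    n_t <- truth$n_true; n_d <- truth$n_decoy
    fam_d <- rep(c("miss_sphere", "wrong_depth", "wrong_angle"),
                 length.out = n_d)
    families <- c(rep("true", n_t), fam_d)
    n <- n_t + n_d
    sl <- vector("list", n)
    ann <- data.frame(id = seq_len(n), family = families,
                      vertex = NA_integer_, region = NA_integer_,
                      depth_mm = NA_real_, angle_deg = NA_real_,
                      in_sphere = NA)
    for (i in seq_len(n)) {
      fam <- families[i]
      v <- if (fam == "true") sample(origin_pool, 1) else sample(interior, 1)
      depth <- truth$true_depth_mm
      angle <- truth$true_angle_deg
      if (fam == "true") {
        depth <- max(0.05, depth + rnorm(1, 0, truth$depth_jitter_mm))
        angle <- min(89, max(0, angle + rnorm(1, 0, truth$angle_jitter_deg)))
      } else if (fam == "wrong_depth") {
        off <- runif(1, 1.25, 2.5)
        depth <- if (depth - off >= 0.3) depth - off else depth + off
      } else if (fam == "wrong_angle") {
        # capped at 75 degrees: near-tangent terminals make the surface
        # crossing itself ill-posed on a folded sheet
        angle <- min(75, angle + runif(1, 31, 55))
      }
      start <- center
      if (fam == "miss_sphere") {
        # keep every sampled point > 1 mm from the seed center (the default
        # sphere radius is 0.5 mm), retrying the start offset if needed
        for (try in 1:50) {
          phi <- runif(1, 0, 2 * pi)
          start <- center + c(cos(phi), sin(phi), 0) * runif(1, 3, 6)
          cand <- plant_streamline(surface, v, depth, angle, start)
          d2 <- sqrt(rowSums(sweep(cand, 2, center)^2))
          if (min(d2) > 1) break
        }
        sl[[i]] <- cand
      } else {
        sl[[i]] <- plant_streamline(surface, v, depth, angle, start)
      }
      ann$vertex[i] <- v
      ann$region[i] <- surface$labels[v]
      ann$depth_mm[i] <- depth
      ann$angle_deg[i] <- angle
      ann$in_sphere[i] <- fam != "miss_sphere"
    }
    list(tg = tractogram(sl), ann = ann)
  })
  ot_log("make_tractogram: ", truth$n_true, " pathway + ", truth$n_decoy,
         " decoy streamlines, seed ", rng_seed)
  list(tractogram = res$tg, truth = res$ann, seed_center_mm = center)
}

# One streamline from `start` that pierces the surface at vertex `v` and ends
# `depth` mm beyond it along a direction at `angle` degrees to the inward
# vertex normal. The final run is straight (last points collinear) so the
# planted depth and angle are exact under arc-length/least-squares recovery.
plant_streamline <- function(surface, v, depth, angle, start,
                             overshoot_mm = 1.0) {
  p <- surface$vertices[v, ]
  n_out <- surface$normals[v, ]
  tang <- random_tangent(n_out)
  a <- angle * pi / 180
  dir <- cos(a) * (-n_out) + sin(a) * tang   # unit, into the cortex
  p_out <- p - dir * overshoot_mm            # on the outward side
  terminal <- p + dir * depth
  # straight final run sampled at ~0.25 mm steps (>= 4 points)
  n_steps <- max(4L, ceiling((overshoot_mm + depth) / 0.25))
  tt <- seq(0, 1, length.out = n_steps)
  run <- outer(1 - tt, p_out) + outer(tt, terminal)
  approach <- rbind(start, start * 0.4 + p_out * 0.6)
  rbind(approach, run)
}

# A uniformly random unit vector orthogonal to `n`.
random_tangent <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- ref - sum(ref * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  phi <- runif(1, 0, 2 * pi)
  cos(phi) * t1 + sin(phi) * t2
}
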