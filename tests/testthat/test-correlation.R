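test_that("local correlation is 1 for identical maps and -1 for anti-identical maps", {
  surf <- test_surface()
  set.seed(60)
  a <- surface_map(runif(nrow(surf$vertices)), "density")
  r_same <- local_correlation(a, a, surf, radius_mm = 3)
  ok <- !is.na(r_same$r_map$values)
  expect_gt(sum(ok), 0)
  expect_true(all(abs(r_same$r_map$values[ok] - 1) < 1e-12))

  b <- surface_map(pmax(0, 2 - a$values), "density")  # -a + constant
  r_anti <- local_correlation(a, b, surf, radius_mm = 3)
  ok2 <- !is.na(r_anti$r_map$values)
  expect_true(all(abs(r_anti$r_map$values[ok2] + 1) < 1e-12))

  # symmetry in the two map arguments
  c_ <- surface_map(runif(nrow(surf$vertices)), "density")
  r_ab <- local_correlation(a, c_, surf, 3)
  r_ba <- local_correlation(c_, a, surf, 3)
  expect_equal(r_ab$r_map$values, r_ba$r_map$values)

  # a constant map has zero variance everywhere -> all undefined
  const <- surface_map(rep(2, nrow(surf$vertices)), "density")
  r_const <- local_correlation(a, const, surf, 3)
  expect_true(all(is.na(r_const$r_map$values)))
})

test_that("per-vertex r equals the direct Pearson formula on oracle neighborhoods", {
  surf <- cached("surf_oracle",
                 make_labeled_surface(3, mesh_resolution = 23, rng_seed = 5))
  expect_gte(nrow(surf$vertices), 500)
  set.seed(61)
  a <- surface_map(runif(nrow(surf$vertices)), "density")
  b <- surface_map(runif(nrow(surf$vertices)), "density")
  res <- local_correlation(a, b, surf, radius_mm = 2.5)
  probe <- sample(nrow(surf$vertices), 40)
  for (v in probe) {
    nb <- oracle_neighborhood(surf, v, 2.5)
    r_oracle <- if (length(nb) >= 3) oracle_pearson(a$values[nb],
                                                    b$values[nb])
                else NA_real_
    if (is.na(r_oracle) || is.na(res$r_map$values[v])) {
      expect_identical(is.na(r_oracle), is.na(res$r_map$values[v]))
    } else {
      expect_lt(abs(res$r_map$values[v] - r_oracle), 1e-10)
    }
  }
})

test_that("correlated area sums the right vertex areas and is monotone in the threshold", {
  surf <- test_surface()
  nv <- nrow(surf$vertices)
  r <- rep(NA_real_, nv)
  set.seed(62)
  reg1 <- which(surf$labels == 1)
  r[reg1] <- rep(c(0.6, 0.4), length.out = length(reg1))
  res <- structure(list(r_map = surface_map(r, "correlation"),
                        labels = surf$labels,
                        vertex_areas = surf$vertex_areas,
                        radius_mm = 3, params = NULL),
                   class = "correlation_result")
  hi <- reg1[seq_along(reg1) %% 2 == 1]   # the 0.6 vertices
  expect_equal(correlated_area(res, 1, 0.5), sum(surf$vertex_areas[hi]))
  # r = 1 everywhere -> full region area
  res1 <- res; res1$r_map$values <- rep(1, nv)
  expect_equal(correlated_area(res1, 2, 0.5),
               sum(surf$vertex_areas[surf$labels == 2]))
  # all-undefined -> zero
  resna <- res; resna$r_map$values <- rep(NA_real_, nv)
  expect_equal(correlated_area(resna, 1, 0.5), 0)
  # monotone non-increasing in the threshold
  th <- seq(-0.9, 0.9, by = 0.2)
  areas <- vapply(th, function(x) correlated_area(res, 1, x), numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_error(correlated_area(res, 99, 0.5), "unknown region")
})

test_that("grid optimization returns the single cell of a one-cell grid", {
  setup <- recovery_setup()
  cfg1 <- run_config(grid_depths_mm = 3, grid_angles_deg = 45)
  out <- make_tractogram(setup$surf, tract_ground_truth(2, 30, 10, 10),
                         rng_seed = 77)
  histo <- surface_map(as.numeric(setup$surf$labels == 1), "fluorescence")
  sel <- select_by_seed(out$tractogram, seed_sphere(out$seed_center_mm, 1))
  sub <- list(terminals = terminal_geometries(sel, setup$surf),
              histo_map = histo)
  expect_warning(opt <- optimize_params(list(sub), setup$surf, 1, cfg1),
                 "all objectives are zero")
  expect_equal(opt$depth_mm, 3)
  expect_equal(opt$angle_deg, 45)
})

test_that("grid optimization recovers planted parameters on two-subject data", {
  setup <- recovery_setup()
  hits <- vapply(1:3, function(seed) {
    p <- recover_params(setup, seed)
    p["depth"] == 2 && p["angle"] == 30
  }, logical(1))
  expect_true(all(hits))
})

test_that("connectivity report reproduces a planted regional fiber split", {
  surf <- test_surface()
  cfg <- run_config()
  # plant 50/30/20 streamlines into regions 1, 2, 3 with per-region params
  counts <- c(50, 30, 20)
  params <- list()
  tgs <- list()
  set.seed(70)
  interior <- setdiff(seq_len(nrow(surf$vertices)),
                      optotract:::boundary_vertices(surf))
  center <- colMeans(surf$vertices) - c(0, 0, 8)
  sl <- list()
  for (j in 1:3) {
    pool <- interior[surf$labels[interior] == j]
    for (i in seq_len(counts[j])) {
      v <- sample(pool, 1)
      sl[[length(sl) + 1]] <- optotract:::plant_streamline(
        surf, v, depth = 2, angle = 10, start = center)
    }
    params[[j]] <- structure(list(region = j, depth_mm = 2, angle_deg = 10,
                                  mean_area_mm2 = NA_real_,
                                  objective = NULL),
                             class = "optimal_params")
  }
  tg <- tractogram(sl)
  hemi <- list(tractogram = tg, seed_center_mm = center)
  rep1 <- connectivity_report(list(hemi), surf, params, cfg)
  expect_equal(rep1$table$pct_of_all_fibers, c(50, 30, 20))
  expect_equal(sum(rep1$table$pct_of_all_fibers), 100)
  expect_true(all(rep1$table$pct_region_surface_projecting > 0))
  expect_true(all(rep1$table$pct_region_surface_projecting <= 100))

  # terminals at every vertex of a region -> that region projects over 100%
  pool1 <- which(surf$labels == 1)
  sl_all <- lapply(pool1[pool1 %in% interior], function(v)
    optotract:::plant_streamline(surf, v, 2, 10, center))
  # cover also boundary vertices of the region via smoothing radius
  repA <- connectivity_report(
    list(list(tractogram = tractogram(sl_all), seed_center_mm = center)),
    surf, params[1], cfg)
  expect_equal(repA$table$pct_region_surface_projecting, 100,
               tolerance = 1e-9)

  # empty kept set -> zeros with a warning
  far <- tractogram(list(rbind(c(100, 100, 100), c(101, 101, 101))))
  expect_warning(
    rep0 <- connectivity_report(
      list(list(tractogram = far, seed_center_mm = center)),
      surf, params, cfg),
    "no streamlines|zeros")
  expect_true(all(rep0$table$pct_of_all_fibers == 0))
})
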