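test_that("synthetic surface partitions into contiguous non-empty regions deterministically", {
  s <- make_labeled_surface(6, mesh_resolution = 15, rng_seed = 0)
  expect_setequal(unique(s$labels), 1:6)
  expect_true(all(table(s$labels) >= 1))
  # contiguity: each region induces one connected component of the edge graph
  g <- optotract:::mesh_edge_graph(s)
  for (reg in 1:6) {
    sub <- igraph::induced_subgraph(g, which(s$labels == reg))
    expect_equal(igraph::components(sub)$no, 1)
  }
  s2 <- make_labeled_surface(6, mesh_resolution = 15, rng_seed = 0)
  expect_identical(s$vertices, s2$vertices)
  expect_identical(s$labels, s2$labels)

  s1 <- make_labeled_surface(1, mesh_resolution = 8, rng_seed = 2)
  expect_true(all(s1$labels == 1L))
  expect_error(make_labeled_surface(100, mesh_resolution = 5, rng_seed = 1),
               "exceeds vertex count")
})

test_that("zero-jitter tractogram annotations pass the exact planted window and only them", {
  surf <- test_surface()
  out <- make_tractogram(surf, tract_ground_truth(2, 30, n_true = 50,
                                                  n_decoy = 50),
                         rng_seed = 7)
  ann <- out$truth
  expect_equal(nrow(ann), 100)
  # selection clause: exactly the non-miss-sphere families touch the seed
  sel <- select_by_seed(out$tractogram,
                        seed_sphere(out$seed_center_mm, 1))
  expect_setequal(sel$ids, ann$id[ann$in_sphere])
  # zero-tolerance window on the annotations keeps exactly the n_true
  in_sel <- ann[ann$in_sphere, ]
  kept <- filter_by_params(data.frame(depth_mm = in_sel$depth_mm,
                                      angle_deg = in_sel$angle_deg,
                                      id = in_sel$id),
                           2, 30, tol_depth_mm = 0, tol_angle_deg = 0)
  expect_setequal(kept$id, ann$id[ann$family == "true"])

  # n_true = 0 -> the filter yields an empty set
  out0 <- make_tractogram(surf, tract_ground_truth(2, 30, n_true = 0,
                                                   n_decoy = 9),
                          rng_seed = 8)
  sel0 <- select_by_seed(out0$tractogram,
                         seed_sphere(out0$seed_center_mm, 1))
  term0 <- terminal_geometries(sel0, surf)
  expect_equal(nrow(filter_by_params(term0, 2, 30, 0.5, 15)), 0)
})

test_that("measured pipeline recovers exactly the planted streamlines at zero jitter", {
  surf <- test_surface()
  out <- make_tractogram(surf, tract_ground_truth(2, 30, n_true = 30,
                                                  n_decoy = 30),
                         rng_seed = 12)
  sel <- select_by_seed(out$tractogram, seed_sphere(out$seed_center_mm, 1))
  term <- terminal_geometries(sel, surf)
  kept <- filter_by_params(term, 2, 30, 0.5, 15)
  expect_setequal(kept$id, out$truth$id[out$truth$family == "true"])
  # measured geometry agrees with the planted values to float precision
  tru <- out$truth[match(kept$id, out$truth$id), ]
  expect_equal(kept$depth_mm, tru$depth_mm, tolerance = 1e-6)
  expect_equal(kept$angle_deg, tru$angle_deg, tolerance = 1e-5)
})

test_that("with jitter at half tolerance most planted streamlines still pass", {
  surf <- test_surface()
  pass <- vapply(1:20, function(seed) {
    out <- make_tractogram(surf,
                           tract_ground_truth(2, 30, n_true = 40,
                                              n_decoy = 0,
                                              depth_jitter_mm = 0.25,
                                              angle_jitter_deg = 7.5),
                           rng_seed = seed)
    ann <- out$truth
    mean(abs(ann$depth_mm - 2) <= 0.5 & abs(ann$angle_deg - 30) <= 15)
  }, numeric(1))
  expect_gte(mean(pass), 0.90)
})

test_that("histology generator is faithful to the origin map", {
  surf <- test_surface()
  om <- surface_map(as.numeric(surf$labels == 1), "fluorescence")
  blk <- make_histology_block(surf, om, rng_seed = 1)
  pts <- optotract:::fluorescent_voxel_centers(blk)
  nn <- optotract:::nearest_vertex(pts, surf$vertices)
  expect_gte(mean(surf$labels[nn$index] == 1), 0.95)

  # all-zero origin map -> empty block
  blk0 <- make_histology_block(surf, numeric(nrow(surf$vertices)),
                               rng_seed = 1)
  expect_equal(sum(blk0$data), 0)

  # doubling the in-plane resolution conserves fluorescent volume within 5%
  blk2 <- make_histology_block(surf, om, in_plane_res_mm = 0.05,
                               rng_seed = 1)
  expect_lt(abs(fluorescent_volume(blk2) / fluorescent_volume(blk) - 1),
            0.05)

  # determinism
  expect_identical(blk$data,
                   make_histology_block(surf, om, rng_seed = 1)$data)
})

test_that("Poisson spike counts match the count distribution across seeds", {
  expected <- 18.2 * 60
  hits <- vapply(1:100, function(s) {
    rec <- make_spike_trains(list(spike_ground_truth(18.2, 1)),
                             rng_seed = s)$records[[1]]
    n_off <- sum(rec$spike_times_s < 60)
    abs(n_off - expected) <= 3 * sqrt(expected)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("a multiplier of 1 leaves ON and OFF rates equal within sampling error", {
  rec <- make_spike_trains(list(
    spike_ground_truth(18.2, 1, period_durations_s = c(300, 300, 300))),
    rng_seed = 5)$records[[1]]
  t <- rec$spike_times_s
  r_off <- sum(t < 300) / 300
  r_on <- sum(t >= 300 & t < 600) / 300
  # difference of two Poisson rates: sd ~ sqrt(2 * 18.2 / 300)
  expect_lt(abs(r_on - r_off), 4 * sqrt(2 * 18.2 / 300))
})

test_that("gamma renewal trains have the theoretical ISI coefficient of variation", {
  rec <- make_spike_trains(list(
    spike_ground_truth(20, 1, process = "gamma", gamma_shape = 10,
                       period_durations_s = c(250, 1, 1))),
    rng_seed = 9)$records[[1]]
  isi <- diff(rec$spike_times_s[rec$spike_times_s < 250])
  expect_gte(length(isi), 4000)
  cv <- sd(isi) / mean(isi)
  expect_lt(abs(cv - 1 / sqrt(10)) / (1 / sqrt(10)), 0.15)
})

test_that("spike generators are pure functions of parameters and seed", {
  a <- make_spike_trains(list(spike_ground_truth(10, 1.3)), rng_seed = 3)
  b <- make_spike_trains(list(spike_ground_truth(10, 1.3)), rng_seed = 3)
  expect_identical(a$records[[1]]$spike_times_s,
                   b$records[[1]]$spike_times_s)
  # and they do not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(make_spike_trains(
    list(spike_ground_truth(10, 1)), rng_seed = 99)); x2 <- runif(1)
  expect_identical(x1, x2)
})
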