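test_that("TCK round trip preserves streamline count and coordinates", {
  set.seed(10)
  sl <- lapply(1:5, function(i) matrix(rnorm(3 * (i + 2), sd = 10),
                                       ncol = 3))
  tg <- tractogram(sl)
  path <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(tg, path)
  r1 <- read_tractogram(path)
  expect_length(r1$streamlines, 5)
  # a second round trip of what the writer produced is value-exact
  path2 <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(r1, path2)
  r2 <- read_tractogram(path2)
  expect_identical(r1$streamlines, r2$streamlines)
  # and the first read matches the input at float32 precision
  for (i in 1:5)
    expect_equal(r1$streamlines[[i]], sl[[i]], tolerance = 1e-6)
})

test_that("TRK with a non-RAS voxel-order header yields the same world coordinates as TCK", {
  set.seed(11)
  sl <- lapply(1:4, function(i) matrix(runif(12, 5, 40), ncol = 3))
  tg <- tractogram(sl)
  tck <- withr::local_tempfile(fileext = ".tck")
  trk <- withr::local_tempfile(fileext = ".trk")
  write_tractogram(tg, tck)
  # LPS-oriented affine with anisotropic voxels: on-disk voxel-mm values
  # differ completely from world mm, the reader must undo the convention
  aff <- rbind(c(-0.5, 0, 0, 50), c(0, -0.5, 0, 60), c(0, 0, 1.2, -10),
               c(0, 0, 0, 1))
  write_tractogram(tg, trk, affine = aff, voxel_size = c(0.5, 0.5, 1.2),
                   dim = c(128L, 128L, 64L))
  a <- read_tractogram(tck)
  b <- read_tractogram(trk)
  expect_length(b$streamlines, 4)
  for (i in 1:4)
    expect_lt(max(abs(a$streamlines[[i]] - b$streamlines[[i]])), 1e-4)
})

test_that("malformed, truncated and empty tractogram files raise named errors", {
  p <- withr::local_tempfile(fileext = ".tck")
  file.create(p)
  expect_error(read_tractogram(p), "empty")

  writeLines(c("mrtrix tracks", "datatype: Float64LE", "file: . 60", "END"), p)
  expect_error(read_tractogram(p), "datatype")

  tg <- tractogram(list(matrix(1:12, ncol = 3)))
  p2 <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(tg, p2)
  full <- readBin(p2, "raw", file.info(p2)$size)
  p3 <- withr::local_tempfile(fileext = ".tck")
  writeBin(full[1:(length(full) - 13)], p3)   # drop the Inf terminator
  expect_error(read_tractogram(p3), "truncated|format")

  p4 <- withr::local_tempfile(fileext = ".trk")
  writeBin(charToRaw("NOTATRACKFILE"), p4)
  expect_error(read_tractogram(p4), "id_string")
})

test_that("surface OFF round trip preserves topology, labels and coordinates", {
  surf <- test_surface()
  path <- withr::local_tempfile(fileext = ".off")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_identical(back$triangles, surf$triangles)
  expect_identical(back$labels, surf$labels)
  expect_equal(back$vertices, surf$vertices, tolerance = 0)
  expect_equal(back$vertex_areas, surf$vertex_areas)
})

test_that("unit icosphere mesh area approximates 4*pi and labels validate", {
  ico <- icosphere(3)
  surf <- labeled_surface(ico$vertices, ico$triangles,
                          labels = rep(1L, nrow(ico$vertices)))
  expect_lt(abs(sum(surf$vertex_areas) - 4 * pi) / (4 * pi), 0.02)
  # outward normals: pointing away from the origin for a centered sphere
  expect_true(all(rowSums(surf$normals * ico$vertices) > 0))

  flipped <- ico$triangles
  flipped[7, ] <- flipped[7, c(2, 1, 3)]
  expect_error(labeled_surface(ico$vertices, flipped), "orientation")
  expect_error(labeled_surface(ico$vertices, ico$triangles,
                               labels = rep(1L, 5)),
               "does not match vertex count")
})

test_that("spike CSV round trip, boundary and validation cases", {
  pb <- data.frame(period = c("OFF", "ON", "POST"),
                   start_s = c(0, 60, 120), end_s = c(60, 120, 180))
  r1 <- spike_record("a", sort(runif(10, 0, 180)), pb)
  r2 <- spike_record("b", sort(runif(10, 0, 180)), pb)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spikes(list(r1, r2), path)
  back <- read_spikes(path)
  expect_length(back, 2)
  expect_equal(back[["a"]]$spike_times_s, r1$spike_times_s)
  expect_equal(back[["b"]]$period_bounds_s$end_s, pb$end_s)

  expect_error(spike_record("c", c(1, 200), pb), "outside all periods")
  expect_error(spike_record("c", c(5, 5), pb), "strictly increasing")

  # unit listed only in the periods sidecar -> empty record allowed
  sp <- data.frame(unit_id = "a", time_s = c(1, 2))
  pp <- rbind(cbind(unit_id = "a", pb), cbind(unit_id = "empty", pb))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(sp, p2, row.names = FALSE)
  pfile <- paste0(p2, ".periods.csv")
  write.csv(pp, pfile, row.names = FALSE)
  back2 <- read_spikes(p2)
  expect_length(back2[["empty"]]$spike_times_s, 0)
})

test_that("run_config validates invariants and round-trips through YAML", {
  cfg <- run_config(correlation_radius_mm = 4, grid_depths_mm = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)

  expect_error(run_config(correlation_threshold = 1), "strictly in")
  expect_error(run_config(gof_alpha = 0), "strictly in")
  expect_error(run_config(grid_depths_mm = c(2, 2)), "strictly increasing")
  expect_error(run_config(grid_depths_mm = numeric(0)), "non-empty")
  expect_error(run_config(seed_sphere_diameter_mm = -1), "positive")
})

test_that("histology blocks round-trip through NIfTI with geometry intact", {
  arr <- array(0L, c(8, 7, 5))
  arr[2:4, 3:5, 2:3] <- 1L
  blk <- histology_block(arr, in_plane_res_mm = 0.1,
                         slice_spacing_mm = 0.32,
                         origin_mm = c(1.5, -2, 0.7))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_histology_block(blk, path)
  back <- read_histology_block(path)
  expect_identical(back$data, blk$data)
  expect_equal(back$in_plane_res_mm, 0.1, tolerance = 1e-6)
  expect_equal(back$slice_spacing_mm, 0.32, tolerance = 1e-6)
  expect_equal(back$origin_mm, blk$origin_mm, tolerance = 1e-5)
})
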