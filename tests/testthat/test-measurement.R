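test_that("jitter enumerates the 3x3x3 neighbourhood deterministically", {
  j <- jitter_centroids(c(5, 5, 5))
  expect_equal(nrow(j), 27)
  expect_equal(nrow(dplyr::distinct(j, i, j, k)), 27)
  expect_equal(range(j$i), c(4, 6))
  expect_equal(range(j$j), c(4, 6))
  expect_equal(range(j$k), c(4, 6))
  # the unjittered centre appears exactly once
  expect_equal(sum(j$di == 0 & j$dj == 0 & j$dk == 0), 1)
  # deterministic lexicographic offset order
  expect_equal(unlist(j[1, c("di", "dj", "dk")]), c(di = -1L, dj = -1L, dk = -1L))
  expect_equal(unlist(j[27, c("di", "dj", "dk")]), c(di = 1L, dj = 1L, dk = 1L))
  expect_identical(j, jitter_centroids(c(5, 5, 5)))
})

test_that("jitter at the grid edge raises a boundary error", {
  expect_error(jitter_centroids(c(1, 5, 5), dim = c(9, 9, 9)),
               class = "voinoise_boundary_error")
  expect_error(jitter_centroids(c(5, 5, 9), dim = c(9, 9, 9)),
               class = "voinoise_boundary_error")
  expect_silent(jitter_centroids(c(2, 2, 2), dim = c(9, 9, 9)))
})

test_that("a shape fully inside a wide lumen yields two kept SD estimates", {
  vol <- cylinder_volume(dim = c(41, 41, 41), radius_mm = 13)
  mask <- segment_airway(vol, c(21, 21, 21))
  m <- measure_at(vol, mask, c(21, 21, 21), radius_from_area(1.0))
  expect_equal(m$shape, c("circle", "sphere"))
  expect_false(any(m$excluded))
  expect_equal(m$noise_hu, c(0, 0))   # noiseless lumen
  expect_lt(m$n_voxels[1], m$n_voxels[2])
})

test_that("a centre close to the wall excludes both shapes", {
  vol <- cylinder_volume(dim = c(41, 41, 41), radius_mm = 12)
  mask <- segment_airway(vol, c(21, 21, 21))
  # centre 11 mm off-axis: the sphere necessarily crosses the wall
  m <- measure_at(vol, mask, c(32, 21, 21), radius_from_area(1.0))
  expect_true(all(m$excluded))
  expect_true(all(is.na(m$noise_hu)))
})

test_that("a protruding sphere excludes the circle too (coupled exclusion)", {
  # air slab three slices thick: the circle fits in the centre slice, but the
  # sphere spans +/- 5 slices and must leave the segmentation
  vals <- array(0, c(41, 41, 41))
  vals[, , 20:22] <- -1000
  vol <- ct_volume(vals, c(1, 1, 1))
  mask <- segment_airway(vol, c(21, 21, 21))
  r <- radius_from_area(1.0)
  circ <- select_circle(vol, c(21, 21, 21), r)
  expect_true(all(vol$values[as.matrix(circ)] == -1000))  # circle is inside
  m <- measure_at(vol, mask, c(21, 21, 21), r)
  expect_true(all(m$excluded))
  expect_true(all(is.na(m$noise_hu)))
})

test_that("evaluate_scan keeps 27 paired measurements and ties break low", {
  vol <- cylinder_volume(dim = c(41, 41, 75), radius_mm = 13)
  mask <- segment_airway(vol, c(21, 21, 38))
  lm <- structure(list(ridge_slice = 20L, ridge_point = c(21L, 21L, 20L),
                       cranial = "+k"), class = "carina_landmark")
  sc <- evaluate_scan(vol, mask, lm, scan_id = "cyl")
  expect_s3_class(sc, "scan_measurements")
  expect_equal(unname(sc$rejections_by_height), c(0L, 0L, 0L))
  expect_equal(sc$height_cm, 1.0)                 # tie -> lowest height
  expect_equal(nrow(sc$measurements), 54)
  expect_equal(sum(sc$measurements$shape == "circle"), 27)
  expect_equal(sum(sc$measurements$shape == "sphere"), 27)
  expect_equal(sc$true_noise_hu, 0)
})

test_that("a lumen narrowing above the carina drives the height choice", {
  # wide where the 1.0 cm sphere reaches (ridge at 20, slices <= 36), too
  # narrow above: the 1.5 and 2.0 cm spheres must cross the wall
  vol <- cylinder_volume(dim = c(41, 41, 75),
                         radius_mm = function(k) if (k <= 36) 13 else 3)
  mask <- segment_airway(vol, c(21, 21, 30))
  lm <- structure(list(ridge_slice = 20L, ridge_point = c(21L, 21L, 20L),
                       cranial = "+k"), class = "carina_landmark")
  sc <- evaluate_scan(vol, mask, lm, scan_id = "narrow")
  expect_equal(sc$height_cm, 1.0)
  expect_equal(sc$rejections_by_height[["1.0"]], 0L)
  expect_gt(sc$rejections_by_height[["1.5"]], 0L)
  expect_gt(sc$rejections_by_height[["2.0"]], 0L)
})

test_that("kept and excluded positions always sum to 27 and stay coupled", {
  # 6.5 mm lumen: the unjittered shapes fit, diagonal jitters cross the wall
  vol <- cylinder_volume(dim = c(41, 41, 75), radius_mm = 6.5)
  mask <- segment_airway(vol, c(21, 21, 38))
  lm <- structure(list(ridge_slice = 20L, ridge_point = c(21L, 21L, 20L),
                       cranial = "+k"), class = "carina_landmark")
  sc <- evaluate_scan(vol, mask, lm, scan_id = "tight")
  tab <- sc$measurements
  excl_by_pos <- tapply(tab$excluded, list(tab$position, tab$shape), unique)
  expect_true(all(excl_by_pos[, "circle"] == excl_by_pos[, "sphere"]))
  n_excl <- sum(excl_by_pos[, "circle"])
  expect_gt(n_excl, 0L)
  expect_lt(n_excl, 27L)
  expect_equal(sum(!excl_by_pos[, "circle"]) + n_excl, 27L)
  expect_true(all(is.na(tab$noise_hu[tab$excluded])))
  expect_true(all(!is.na(tab$noise_hu[!tab$excluded])))
})

test_that("no placeable height is a scan failure", {
  vol <- cylinder_volume(dim = c(41, 41, 75), radius_mm = 13,
                         k_range = c(1, 25))
  mask <- segment_airway(vol, c(21, 21, 20))
  lm <- structure(list(ridge_slice = 20L, ridge_point = c(21L, 21L, 20L),
                       cranial = "+k"), class = "carina_landmark")
  expect_error(evaluate_scan(vol, mask, lm), class = "voinoise_scan_failure")
})
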