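test_that("noiseless cylinder is segmented exactly and eroded per the oracle", {
  vol <- cylinder_volume(dim = c(17, 17, 17), spacing = c(1, 1, 1),
                         radius_mm = 5)
  mask <- segment_airway(vol, c(9, 9, 9))
  expect_equal(mask$crop_origin, c(1L, 1L, 1L))
  # grown region equals the thresholded air within the image
  expect_identical(mask$mask_full[1:17, 1:17, 1:17], vol$values < -500)
  expect_false(any(mask$mask_full[18:61, , ]))
  # erosion matches the brute-force 27-neighbourhood oracle (window includes
  # a 2-voxel all-background margin, so window-edge behaviour is identical)
  win <- mask$mask_full[1:19, 1:19, 1:19]
  expect_identical(mask$mask_eroded[1:19, 1:19, 1:19], brute_erode(win))
  # eroded mask is the cylinder minus a one-voxel shell, hence strictly inside
  expect_true(sum(mask$mask_eroded) < sum(mask$mask_full))
  expect_true(all(which(mask$mask_eroded) %in% which(mask$mask_full)))
})

test_that("a seed outside the air raises a seed error", {
  vol <- cylinder_volume(dim = c(17, 17, 17), radius_mm = 4)
  expect_error(segment_airway(vol, c(1, 1, 1)), class = "voinoise_seed_error")
})

test_that("a segmentation filling the whole crop warns about leakage", {
  vol <- ct_volume(array(-1000, c(63, 63, 63)), c(1, 1, 1))
  expect_warning(segment_airway(vol, c(32, 32, 32)),
                 class = "voinoise_leak_warning")
})

test_that("true noise is the sample SD over the eroded mask", {
  vol <- ct_volume(array(-1000, c(5, 5, 5)), c(1, 1, 1))
  mask <- segment_airway(vol, c(3, 3, 3))
  expect_equal(true_noise(vol, mask), 0)
  # closed-form sample SD on three selected voxels
  mask$mask_eroded <- array(FALSE, c(61, 61, 61))
  mask$mask_eroded[1:3, 1, 1] <- TRUE
  vol$values[1:3, 1, 1] <- c(-1000, -998, -1002)
  expect_equal(true_noise(vol, mask), 2.0)
  mask$mask_eroded[2:3, 1, 1] <- FALSE
  expect_error(true_noise(vol, mask), class = "voinoise_undefined_sd")
})

test_that("true noise recovers an injected iid sigma within the sampling bound", {
  # eroded mask of a 15^3 air cube has 13^3 = 2197 voxels; the SD estimate
  # should sit within 4*sigma/sqrt(2n) of sigma essentially always
  sigma <- 33
  bound <- 4 * sigma / sqrt(2 * 13^3)
  set.seed(42)
  misses <- 0L
  for (rep in 1:50) {
    vol <- ct_volume(array(-1000 + rnorm(15^3, 0, sigma), c(15, 15, 15)),
                     c(1, 1, 1))
    mask <- segment_airway(vol, c(8, 8, 8))
    expect_equal(sum(mask$mask_eroded), 13^3)
    if (abs(true_noise(vol, mask) - sigma) > bound) misses <- misses + 1L
  }
  expect_lte(misses, 1L)
})

test_that("carina ridge is found at the constructed bifurcation slice", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  mask <- segment_airway(ph$volume, ph$seed_voxel)
  lm <- detect_carina(mask)
  expect_equal(lm$ridge_slice, ph$carina_slice)
  expect_equal(lm$ridge_point[1:2], c(41L, 41L))   # tracheal axis
  # noisy phantom: same landmark (air/tissue contrast >> sigma)
  phn <- generate_phantom(phantom_spec(noise_sigma = 33, seed = 5))
  maskn <- segment_airway(phn$volume, phn$seed_voxel)
  expect_equal(detect_carina(maskn)$ridge_slice, phn$carina_slice)
})

test_that("carina detection survives z-flip with the cranial flag", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  d <- dim(ph$volume$values)
  flipped <- ct_volume(ph$volume$values[, , d[3]:1], ph$volume$spacing)
  seed <- ph$seed_voxel
  seed[3] <- d[3] - seed[3] + 1L
  mask <- segment_airway(flipped, seed)
  lm <- detect_carina(mask, cranial = "-k")
  expect_equal(lm$ridge_slice, d[3] - ph$carina_slice + 1L)
})

test_that("carina detection is invariant to in-plane translation", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  d <- dim(ph$volume$values)
  shifted <- array(ph$spec$hu_parenchyma, d)
  shifted[4:d[1], 1:(d[2] - 2), ] <-
    ph$volume$values[1:(d[1] - 3), 3:d[2], ]
  svol <- ct_volume(shifted, ph$volume$spacing)
  seed <- ph$seed_voxel + c(3L, -2L, 0L)
  lm0 <- detect_carina(segment_airway(ph$volume, ph$seed_voxel))
  lm1 <- detect_carina(segment_airway(svol, seed))
  expect_equal(lm1$ridge_slice, lm0$ridge_slice)
  expect_equal(lm1$ridge_point[1:2], lm0$ridge_point[1:2] + c(3L, -2L))
})

test_that("a straight cylinder has no detectable bifurcation", {
  vol <- cylinder_volume(dim = c(31, 31, 41), radius_mm = 8)
  mask <- segment_airway(vol, c(16, 16, 21))
  expect_error(detect_carina(mask), class = "voinoise_no_bifurcation")
})

test_that("height-to-slice conversion rounds to the nearest slice", {
  vol <- cylinder_volume(dim = c(41, 41, 61), spacing = c(1, 1, 0.7),
                         radius_mm = 12)
  mask <- segment_airway(vol, c(21, 21, 31))
  lm <- structure(list(ridge_slice = 25L, ridge_point = c(21L, 21L, 25L),
                       cranial = "+k"), class = "carina_landmark")
  # 10 mm / 0.7 mm = 14.29 -> slice offset 14
  expect_equal(measurement_center(mask, lm, 1.0, vol$spacing), c(21L, 21L, 39L))
  # exact division with 1.0 mm slices
  voli <- cylinder_volume(dim = c(41, 41, 61), spacing = c(1, 1, 1),
                          radius_mm = 12)
  maski <- segment_airway(voli, c(21, 21, 31))
  expect_equal(measurement_center(maski, lm, 2.0, voli$spacing),
               c(21L, 21L, 45L))
  # centroid tracks the cylinder axis at every height
  for (h in c(1.0, 1.5, 2.0)) {
    expect_equal(measurement_center(maski, lm, h, voli$spacing)[1:2],
                 c(21L, 21L))
  }
})

test_that("unplaceable or empty measurement slices raise placement errors", {
  vol <- cylinder_volume(dim = c(41, 41, 61), spacing = c(1, 1, 1),
                         radius_mm = 12, k_range = c(1, 40))
  mask <- segment_airway(vol, c(21, 21, 31))
  lm_far <- structure(list(ridge_slice = 55L, ridge_point = c(21L, 21L, 55L),
                           cranial = "+k"), class = "carina_landmark")
  expect_error(measurement_center(mask, lm_far, 2.0, vol$spacing),
               class = "voinoise_placement_error")
  lm_mid <- structure(list(ridge_slice = 25L, ridge_point = c(21L, 21L, 25L),
                           cranial = "+k"), class = "carina_landmark")
  expect_error(measurement_center(mask, lm_mid, 2.0, vol$spacing),
               class = "voinoise_placement_error")   # air stops at slice 40
})
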