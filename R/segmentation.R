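#' Segment tracheal air around a seed point
#'
#' Grows a 26-connected region of sub-threshold (air) voxels from a seed
#' point, restricted to a 61 x 61 x 61 voxel crop centred on the seed (the
#' crop is shifted inward at image borders and zero-padded when the image is
#' smaller than the crop). The segmentation boundary is then removed with a
#' morphological erosion (full 3 x 3 x 3 cube) to avoid partial-volume edge
#' artifacts: `mask_full` is the grown region, `mask_eroded` the ground-truth
#' region used for the true noise level.
#'
#' @param volume A [ct_volume()].
#' @param seed Voxel index `c(i, j, k)` inside the tracheal air.
#' @param hu_threshold Voxels with HU strictly below this are air
#'   (default -500 HU, separating lumen at about -1000 HU from wall and
#'   parenchyma at both clinical noise regimes).
#' @return An `airway_mask`: list with `crop_origin` (full-volume index of
#'   crop voxel (1,1,1)), `crop_size` (61), `mask_full`, `mask_eroded`
#'   (61^3 logical arrays), `dim_full`, `hu_threshold` and `seed`.
#' @details A seed whose HU is not below the threshold raises a
#'   `voinoise_seed_error`. If the grown region touches all six crop faces a
#'   `voinoise_leak_warning` is emitted (suspected leak out of the airway).
#' @export
segment_airway <- function(volume, seed, hu_threshold = -500) {
  stopifnot(inherits(volume, "ct_volume"))
  seed <- check_center(volume, seed)
  if (!is.numeric(hu_threshold) || length(hu_threshold) != 1L) {
    abort("`hu_threshold` must be a single number.",
          class = "voinoise_invalid_parameter")
  }
  if (volume$values[seed[1], seed[2], seed[3]] >= hu_threshold) {
    abort(sprintf("Seed voxel HU (%.1f) is not below the air threshold (%.1f).",
                  volume$values[seed[1], seed[2], seed[3]], hu_threshold),
          class = "voinoise_seed_error")
  }
  cs <- 61L
  half <- 30L
  d <- dim(volume$values)
  lo <- seed - half
  hi <- seed + half
  shift_up <- pmax(0L, 1L - lo)
  lo <- lo + shift_up; hi <- hi + shift_up
  shift_dn <- pmax(0L, hi - d)
  # never shift past the first voxel; images smaller than the crop get padded
  adj <- pmin(shift_dn, lo - 1L)
  lo <- lo - adj; hi <- hi - adj
  nv <- pmin(hi, d) - lo + 1L                      # valid (in-image) extent
  air <- array(FALSE, c(cs, cs, cs))
  air[seq_len(nv[1]), seq_len(nv[2]), seq_len(nv[3])] <-
    volume$values[lo[1]:(lo[1] + nv[1] - 1L),
                  lo[2]:(lo[2] + nv[2] - 1L),
                  lo[3]:(lo[3] + nv[3] - 1L)] < hu_threshold
  seed_crop <- seed - lo + 1L
  mask_full <- flood_fill_26(air, seed_crop)
  faces <- c(any(mask_full[1, , ]), any(mask_full[cs, , ]),
             any(mask_full[, 1, ]), any(mask_full[, cs, ]),
             any(mask_full[, , 1]), any(mask_full[, , cs]))
  if (all(faces)) {
    warn("Segmentation touches all six crop faces; possible leak out of the airway.",
         class = "voinoise_leak_warning")
  }
  structure(list(crop_origin = lo, crop_size = cs,
                 mask_full = mask_full, mask_eroded = erode_box3(mask_full),
                 dim_full = d, hu_threshold = hu_threshold, seed = seed),
            class = "airway_mask")
}

#' @export
print.airway_mask <- function(x, ...) {
  cat(sprintf("<airway_mask> crop origin (%d, %d, %d), %d voxels (%d after erosion)\n",
              x$crop_origin[1], x$crop_origin[2], x$crop_origin[3],
              sum(x$mask_full), sum(x$mask_eroded)))
  invisible(x)
}

# map full-volume voxel coords (n x 3 matrix) to TRUE where inside mask_full
in_mask_full <- function(mask, coords) {
  rel <- cbind(coords[, 1] - mask$crop_origin[1] + 1L,
               coords[, 2] - mask$crop_origin[2] + 1L,
               coords[, 3] - mask$crop_origin[3] + 1L)
  ok <- rel[, 1] >= 1L & rel[, 1] <= mask$crop_size &
        rel[, 2] >= 1L & rel[, 2] <= mask$crop_size &
        rel[, 3] >= 1L & rel[, 3] <= mask$crop_size
  res <- logical(nrow(rel))
  res[ok] <- mask$mask_full[rel[ok, , drop = FALSE]]
  res
}

#' Ground-truth noise level of a scan
#'
#' The noise level is the sample standard deviation of the HU values over the
#' eroded trachea segmentation, the largest homogeneous air region available
#' and therefore the per-scan reference ("true noise") against which ROI/VOI
#' measurements are compared.
#'
#' @param volume A [ct_volume()].
#' @param mask An `airway_mask` from [segment_airway()].
#' @return True noise in HU (single number).
#' @export
true_noise <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "airway_mask"))
  idx <- which(mask$mask_eroded)
  if (length(idx) < 2L) {
    abort("Fewer than 2 voxels in the eroded mask; SD undefined.",
          class = "voinoise_undefined_sd")
  }
  rel <- arrayInd(idx, dim(mask$mask_eroded))
  coords <- cbind(rel[, 1] + mask$crop_origin[1] - 1L,
                  rel[, 2] + mask$crop_origin[2] - 1L,
                  rel[, 3] + mask$crop_origin[3] - 1L)
  sd(volume$values[coords])
}

#' Locate the carina ridge in a segmented airway
#'
#' The carina ridge is defined operationally from the axial topology of the
#' lumen: the most caudal slice whose in-plane cross-section is a single
#' 8-connected component while the next caudal slice already shows two or
#' more components (the main bronchi). The landmark point is the in-plane
#' centroid of that single component.
#'
#' @param mask An `airway_mask`.
#' @param cranial Which direction of the k axis is cranial: `"+k"` (default,
#'   increasing slice index towards the head) or `"-k"` for feet-first /
#'   flipped volumes.
#' @return A `carina_landmark`: list with `ridge_slice` (full-volume axial
#'   index), `ridge_point` (full-volume voxel index on the ridge) and
#'   `cranial`.
#' @export
detect_carina <- function(mask, cranial = c("+k", "-k")) {
  stopifnot(inherits(mask, "airway_mask"))
  cranial <- match.arg(cranial)
  cs <- mask$crop_size
  ncomp <- integer(cs)
  for (c in seq_len(cs)) {
    ncomp[c] <- components_2d(mask$mask_full[, , c])$n
  }
  if (cranial == "+k") {
    cand <- which(ncomp[-1] == 1L & ncomp[-cs] >= 2L) + 1L  # slice c, c-1 caudal
    ridge_crop <- if (length(cand)) min(cand) else NA_integer_
  } else {
    cand <- which(ncomp[-cs] == 1L & ncomp[-1] >= 2L)       # slice c, c+1 caudal
    ridge_crop <- if (length(cand)) max(cand) else NA_integer_
  }
  if (is.na(ridge_crop)) {
    abort("No bifurcation found: no axial slice shows the 2-to-1 component transition.",
          class = "voinoise_no_bifurcation")
  }
  cen <- components_2d(mask$mask_full[, , ridge_crop])$centroid
  structure(list(
    ridge_slice = ridge_crop + mask$crop_origin[3] - 1L,
    ridge_point = c(as.integer(floor(cen[1] + 0.5)) + mask$crop_origin[1] - 1L,
                    as.integer(floor(cen[2] + 0.5)) + mask$crop_origin[2] - 1L,
                    ridge_crop + mask$crop_origin[3] - 1L),
    cranial = cranial), class = "carina_landmark")
}

#' Measurement isocenter at a fixed height above the carina
#'
#' Converts a height in cm above the carina ridge into an axial slice
#' (rounding to the nearest slice, ties towards cranial) and returns the
#' in-plane centroid of the lumen cross-section in that slice, rounded to the
#' nearest voxel.
#'
#' @param mask An `airway_mask`.
#' @param landmark A `carina_landmark` from [detect_carina()].
#' @param height_cm Height above the ridge in cm (the standard choices are
#'   1.0, 1.5 and 2.0).
#' @param spacing Voxel spacing in mm (length-3; the z component is used).
#' @return Voxel index `c(i, j, k)` of the measurement centre.
#' @export
measurement_center <- function(mask, landmark, height_cm, spacing) {
  stopifnot(inherits(mask, "airway_mask"), inherits(landmark, "carina_landmark"))
  if (!is.numeric(height_cm) || length(height_cm) != 1L || height_cm <= 0) {
    abort("`height_cm` must be a single positive number.",
          class = "voinoise_invalid_parameter")
  }
  dk <- floor(10 * height_cm / spacing[3] + 0.5)   # ties round towards cranial
  dir <- if (landmark$cranial == "+k") 1L else -1L
  k_full <- landmark$ridge_slice + dir * as.integer(dk)
  c_crop <- k_full - mask$crop_origin[3] + 1L
  if (c_crop < 1L || c_crop > mask$crop_size || k_full < 1L ||
      k_full > mask$dim_full[3]) {
    abort(sprintf("Measurement slice at %.1f cm above the carina falls outside the crop.",
                  height_cm),
          class = "voinoise_placement_error")
  }
  comp <- components_2d(mask$mask_full[, , c_crop])
  if (comp$n < 1L) {
    abort(sprintf("Empty lumen cross-section at %.1f cm above the carina.", height_cm),
          class = "voinoise_placement_error")
  }
  c(as.integer(floor(comp$centroid[1] + 0.5)) + mask$crop_origin[1] - 1L,
    as.integer(floor(comp$centroid[2] + 0.5)) + mask$crop_origin[2] - 1L,
    as.integer(k_full))
}

#' Export an airway mask as a NIfTI label map
#'
#' Writes the 61^3 crop with label 1 for the eroded ground-truth region and
#' label 2 for the eroded-away boundary shell.
#'
#' @param mask An `airway_mask`.
#' @param path Output NIfTI path.
#' @param spacing Voxel spacing in mm of the source volume.
#' @return `path`, invisibly.
#' @export
write_airway_mask <- function(mask, path, spacing) {
  stopifnot(inherits(mask, "airway_mask"))
  labels <- array(0L, dim(mask$mask_full))
  labels[mask$mask_full] <- 2L
  labels[mask$mask_eroded] <- 1L
  img <- RNifti::asNifti(labels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
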