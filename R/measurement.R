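#' The 27 jittered measurement positions
#'
#' Simulates the imprecision of repeated manual placement by moving the
#' measurement centre by one voxel in every combination of the i, j and k
#' directions: the full 3 x 3 x 3 neighbourhood, 27 unique positions
#' including the unjittered centre, in deterministic lexicographic order of
#' the offsets. No randomness is involved.
#'
#' @param center Voxel index `c(i, j, k)`.
#' @param dim Optional grid dimensions; when supplied, a centre on the grid
#'   edge (so that some offset would leave the grid) raises a
#'   `voinoise_boundary_error`.
#' @return A tibble with 27 rows: offsets `di`, `dj`, `dk` and absolute
#'   positions `i`, `j`, `k`.
#' @export
jitter_centroids <- function(center, dim = NULL) {
  center <- as.integer(center)
  if (length(center) != 3L) {
    abort("`center` must be a voxel index (i, j, k).",
          class = "voinoise_invalid_parameter")
  }
  if (!is.null(dim)) {
    if (any(center - 1L < 1L) || any(center + 1L > dim)) {
      abort("Jitter neighbourhood extends past the grid boundary.",
            class = "voinoise_boundary_error")
    }
  }
  g <- expand.grid(dk = -1:1, dj = -1:1, di = -1:1)   # di slowest: lexicographic
  tibble(di = as.integer(g$di), dj = as.integer(g$dj), dk = as.integer(g$dk),
         i = center[1] + as.integer(g$di),
         j = center[2] + as.integer(g$dj),
         k = center[3] + as.integer(g$dk))
}

#' Measure ROI and VOI noise at one position
#'
#' Builds the circular ROI and spherical VOI voxel sets at a common centre
#' and radius and estimates noise as the sample SD of the HU values in each.
#' Containment rule: if either shape contains any voxel outside the
#' pre-erosion trachea segmentation, both shapes are excluded at this
#' position (mimicking a human rejecting a measurement that touches the
#' wall) and no SD is reported for either.
#'
#' @param volume A [ct_volume()].
#' @param mask An `airway_mask` from [segment_airway()].
#' @param center Voxel index `c(i, j, k)` of the shared shape centre.
#' @param radius_mm Shape radius in mm.
#' @return A tibble with two rows (`shape` = "circle", "sphere") and columns
#'   `i`, `j`, `k`, `n_voxels`, `noise_hu` (NA when excluded), `excluded`.
#' @export
measure_at <- function(volume, mask, center, radius_mm) {
  circ <- select_circle(volume, center, radius_mm)
  sph <- select_sphere(volume, center, radius_mm)
  circ_m <- as.matrix(circ)
  sph_m <- as.matrix(sph)
  contained <- all(in_mask_full(mask, circ_m)) && all(in_mask_full(mask, sph_m))
  if (contained) {
    noise <- c(sd(volume$values[circ_m]), sd(volume$values[sph_m]))
  } else {
    noise <- c(NA_real_, NA_real_)
  }
  tibble(shape = c("circle", "sphere"),
         i = as.integer(center[1]), j = as.integer(center[2]),
         k = as.integer(center[3]),
         n_voxels = c(nrow(circ), nrow(sph)),
         noise_hu = noise,
         excluded = !contained)
}

# Fast path used at cohort scale: measures all jitter positions of one
# height with precomputed linear-index templates. Semantics identical to
# measure_at(); the circle voxel set is a subset of the sphere set at equal
# radius, so sphere containment implies circle containment.
measure_positions <- function(volume, mask, pos, radius_mm) {
  v <- volume$values
  d <- dim(v)
  sp <- volume$spacing
  offC <- shape_offsets("circle", radius_mm, sp)
  offS <- shape_offsets("sphere", radius_mm, sp)
  ext <- c(floor(radius_mm / sp[1]), floor(radius_mm / sp[2]),
           floor(radius_mm / sp[3]))
  if (any(pos$i - ext[1] < 1 | pos$i + ext[1] > d[1] |
          pos$j - ext[2] < 1 | pos$j + ext[2] > d[2] |
          pos$k - ext[3] < 1 | pos$k + ext[3] > d[3])) {
    abort("Sphere extends past the grid boundary at a jittered position.",
          class = "voinoise_boundary_error")
  }
  nx <- d[1]; nxy <- d[1] * d[2]
  cs <- mask$crop_size; csxy <- cs * cs
  linC <- offC[, "di"] + offC[, "dj"] * nx + offC[, "dk"] * nxy
  linS <- offS[, "di"] + offS[, "dj"] * nx + offS[, "dk"] * nxy
  mlinS <- offS[, "di"] + offS[, "dj"] * cs + offS[, "dk"] * csxy
  org <- mask$crop_origin
  mf <- mask$mask_full
  n <- nrow(pos)
  noiseC <- rep(NA_real_, n); noiseS <- rep(NA_real_, n)
  excl <- logical(n)
  for (p in seq_len(n)) {
    rel <- c(pos$i[p] - org[1] + 1L, pos$j[p] - org[2] + 1L,
             pos$k[p] - org[3] + 1L)
    # a voxel outside the crop is outside the segmentation: excluded
    if (any(rel - ext < 1L) || any(rel + ext > cs)) {
      excl[p] <- TRUE
      next
    }
    mbase <- rel[1] + (rel[2] - 1L) * cs + (rel[3] - 1L) * csxy
    if (!all(mf[mbase + mlinS])) {
      excl[p] <- TRUE
      next
    }
    base <- pos$i[p] + (pos$j[p] - 1L) * nx + (pos$k[p] - 1L) * nxy
    noiseC[p] <- sd(v[base + linC])
    noiseS[p] <- sd(v[base + linS])
  }
  list(noise_circle = noiseC, noise_sphere = noiseS, excluded = excl,
       n_circle = nrow(offC), n_sphere = nrow(offS))
}

#' Simulated repeated noise measurement for one scan
#'
#' Runs the full per-scan measurement protocol: for each candidate height
#' above the carina (1.0, 1.5, 2.0 cm) the lumen centroid is computed,
#' jittered to 27 positions, and ROI/VOI noise measured at each with the
#' containment exclusion rule. The height with the fewest rejected positions
#' is kept for the scan (ties resolved towards the lowest height, closest to
#' the carina); the ground-truth noise from the eroded segmentation is
#' attached.
#'
#' @param volume A [ct_volume()].
#' @param mask An `airway_mask`.
#' @param landmark A `carina_landmark`.
#' @param area_cm2 ROI area defining the shared radius (default 1.0 cm^2).
#' @param heights_cm Candidate heights above the carina ridge, in cm.
#' @param scan_id Identifier carried into the output table.
#' @return A `scan_measurements` object: list with `scan_id`, chosen
#'   `height_cm`, `measurements` (tibble of 27 positions x 2 shapes for the
#'   chosen height), `rejections_by_height` and `true_noise_hu`.
#' @export
evaluate_scan <- function(volume, mask, landmark, area_cm2 = 1.0,
                          heights_cm = c(1.0, 1.5, 2.0), scan_id = "scan") {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "airway_mask"),
            inherits(landmark, "carina_landmark"))
  radius <- radius_from_area(area_cm2)
  d <- dim(volume$values)
  per_height <- list()
  rejections <- rep(NA_integer_, length(heights_cm))
  names(rejections) <- format(heights_cm)
  for (h in seq_along(heights_cm)) {
    center <- tryCatch(
      measurement_center(mask, landmark, heights_cm[h], volume$spacing),
      voinoise_placement_error = function(e) NULL)
    if (is.null(center)) next
    pos <- jitter_centroids(center, dim = d)
    res <- measure_positions(volume, mask, pos, radius)
    np <- nrow(pos)
    tab <- tibble(
      height_cm = heights_cm[h],
      position = rep(seq_len(np), each = 2L),
      di = rep(pos$di, each = 2L), dj = rep(pos$dj, each = 2L),
      dk = rep(pos$dk, each = 2L),
      shape = rep(c("circle", "sphere"), np),
      i = rep(pos$i, each = 2L), j = rep(pos$j, each = 2L),
      k = rep(pos$k, each = 2L),
      n_voxels = rep(c(res$n_circle, res$n_sphere), np),
      noise_hu = as.vector(rbind(res$noise_circle, res$noise_sphere)),
      excluded = rep(res$excluded, each = 2L))
    per_height[[h]] <- tab
    rejections[h] <- sum(res$excluded)
  }
  if (all(is.na(rejections))) {
    abort("No measurement height could be placed inside the crop for this scan.",
          class = "voinoise_scan_failure")
  }
  best <- which(rejections == min(rejections, na.rm = TRUE))[1]  # tie: lowest height
  tn <- true_noise(volume, mask)
  meas <- per_height[[best]]
  meas$scan_id <- scan_id
  meas$true_noise_hu <- tn
  meas <- meas[, c("scan_id", "height_cm", "position", "di", "dj", "dk",
                   "shape", "i", "j", "k", "n_voxels", "noise_hu",
                   "excluded", "true_noise_hu")]
  structure(list(scan_id = scan_id, height_cm = heights_cm[best],
                 measurements = meas, rejections_by_height = rejections,
                 true_noise_hu = tn),
            class = "scan_measurements")
}

#' @export
print.scan_measurements <- function(x, ...) {
  cat(sprintf("<scan_measurements> %s: height %.1f cm, true noise %.2f HU, %d/27 positions excluded\n",
              x$scan_id, x$height_cm, x$true_noise_hu,
              sum(x$measurements$excluded[x$measurements$shape == "circle"])))
  invisible(x)
}
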