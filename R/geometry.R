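#' Radius of the measurement shapes from a target ROI area
#'
#' Both the circular ROI and the spherical VOI use the same radius, derived
#' from a fixed in-plane area (1.0 cm^2 by convention for tracheal noise
#' measurements): `r = sqrt(100 * area / pi)` millimetres.
#'
#' @param area_cm2 Target circle area in cm^2; must be a single positive value.
#' @return Radius in millimetres.
#' @examples
#' radius_from_area(1.0)          # 5.6419 mm
#' sphere_volume_cm3(radius_from_area(1.0))  # ~0.75 cm^3
#' @export
radius_from_area <- function(area_cm2) {
  if (!is.numeric(area_cm2) || length(area_cm2) != 1L || !is.finite(area_cm2) ||
      area_cm2 <= 0) {
    abort("`area_cm2` must be a single positive finite number.",
          class = "voinoise_invalid_parameter")
  }
  sqrt(100 * area_cm2 / pi)
}

#' Volume of a sphere in cm^3 given its radius in mm
#'
#' @param radius_mm Sphere radius in millimetres.
#' @return Volume in cm^3.
#' @export
sphere_volume_cm3 <- function(radius_mm) {
  if (!is.numeric(radius_mm) || any(radius_mm <= 0)) {
    abort("`radius_mm` must be positive.", class = "voinoise_invalid_parameter")
  }
  (4 / 3) * pi * (radius_mm / 10)^3
}

# Integer voxel offsets whose centres lie within radius_mm of the origin.
# kind = "circle" restricts to the axial plane (dk = 0). Cached per
# (kind, radius, spacing) since the template is reused for every jitter
# position of a scan.
shape_offsets <- function(kind, radius_mm, spacing) {
  key <- paste(kind, format(radius_mm, digits = 12),
               paste(format(spacing, digits = 12), collapse = "x"), sep = "|")
  hit <- .voinoise_cache[[key]]
  if (!is.null(hit)) return(hit)
  ni <- floor(radius_mm / spacing[1])
  nj <- floor(radius_mm / spacing[2])
  nk <- if (kind == "sphere") floor(radius_mm / spacing[3]) else 0L
  g <- expand.grid(di = -ni:ni, dj = -nj:nj, dk = -nk:nk)
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9   # tolerance for exact-boundary voxels
  off <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(off) <- "integer"
  rownames(off) <- NULL
  .voinoise_cache[[key]] <- off
  off
}

check_center <- function(volume, center) {
  d <- dim(volume$values)
  if (length(center) != 3L || any(center < 1L) || any(center > d)) {
    abort("`center` must be a voxel index (i, j, k) inside the grid.",
          class = "voinoise_invalid_parameter")
  }
  as.integer(center)
}

# shared implementation of the two voxel selectors
select_shape <- function(volume, center, radius_mm, kind) {
  stopifnot(inherits(volume, "ct_volume"))
  center <- check_center(volume, center)
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0) {
    abort("`radius_mm` must be a single positive number.",
          class = "voinoise_invalid_parameter")
  }
  d <- dim(volume$values)
  sp <- volume$spacing
  ext <- c(floor(radius_mm / sp[1]), floor(radius_mm / sp[2]),
           if (kind == "sphere") floor(radius_mm / sp[3]) else 0)
  if (any(center - ext < 1) || any(center + ext > d)) {
    abort(sprintf("%s of radius %.3f mm at (%d, %d, %d) extends past the grid boundary.",
                  if (kind == "sphere") "Sphere" else "Circle",
                  radius_mm, center[1], center[2], center[3]),
          class = "voinoise_boundary_error")
  }
  off <- shape_offsets(kind, radius_mm, sp)
  tibble(i = center[1] + unname(off[, "di"]),
         j = center[2] + unname(off[, "dj"]),
         k = center[3] + unname(off[, "dk"]))
}

#' Select voxels of a circular ROI / spherical VOI
#'
#' Voxel membership uses the centre-in criterion: a voxel belongs to the shape
#' when its centre lies within `radius_mm` of the centre voxel's centre,
#' measured in physical millimetres with the per-axis voxel spacing. The
#' circle is confined to the centre's axial slice; the sphere spans slices.
#' With anisotropic spacing the voxel count therefore depends on the
#' reconstruction geometry (field of view and slice increment).
#'
#' @param volume A [ct_volume()].
#' @param center Voxel index `c(i, j, k)` (1-based) of the shape centre.
#' @param radius_mm Shape radius in millimetres (shared by ROI and VOI; see
#'   [radius_from_area()]).
#' @return A tibble with integer columns `i`, `j`, `k`, one row per selected
#'   voxel.
#' @details A shape that would extend past the image boundary raises a
#'   `voinoise_boundary_error`; this is a hard error, distinct from the
#'   trachea-containment exclusion handled by [measure_at()].
#' @export
select_circle <- function(volume, center, radius_mm) {
  select_shape(volume, center, radius_mm, "circle")
}

#' @rdname select_circle
#' @export
select_sphere <- function(volume, center, radius_mm) {
  select_shape(volume, center, radius_mm, "sphere")
}
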