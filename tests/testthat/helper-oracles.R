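# Independent brute-force oracles and small fixture builders.
# The oracles deliberately re-derive everything with plain loops so they
# share no code with the implementation they check.

# all voxels whose centre lies within radius_mm of the centre voxel's
# centre, via an explicit triple loop over the whole grid
brute_select <- function(volume, center, radius_mm, kind) {
  d <- dim(volume$values)
  sp <- volume$spacing
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (kind == "circle" && k != center[3]) next
    dist <- sqrt(((i - center[1]) * sp[1])^2 + ((j - center[2]) * sp[2])^2 +
                   ((k - center[3]) * sp[3])^2)
    if (dist <= radius_mm + 1e-9) out <- rbind(out, c(i, j, k))
  }
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# voxel kept iff all 27 cells of its 3x3x3 neighbourhood are foreground
brute_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    keep <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !mask[ii, jj, kk]) keep <- FALSE
    }
    out[i, j, k] <- keep
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# axis-aligned air cylinder (air_hu inside, bg_hu outside) along k; the
# per-slice radius may be a function of k for narrowing geometries
cylinder_volume <- function(dim = c(41, 41, 41), spacing = c(1, 1, 1),
                            radius_mm = 12, axis = NULL, air_hu = -1000,
                            bg_hu = 0, k_range = NULL) {
  axis <- axis %||% (dim[1:2] + 1) / 2
  k_range <- k_range %||% c(1, dim[3])
  r_of_k <- if (is.function(radius_mm)) radius_mm else function(k) radius_mm
  dx2 <- ((seq_len(dim[1]) - axis[1]) * spacing[1])^2
  dy2 <- ((seq_len(dim[2]) - axis[2]) * spacing[2])^2
  D2 <- outer(dx2, dy2, `+`)
  vals <- array(bg_hu, dim)
  for (k in k_range[1]:k_range[2]) {
    sl <- matrix(bg_hu, dim[1], dim[2])
    sl[D2 <= r_of_k(k)^2] <- air_hu
    vals[, , k] <- sl
  }
  ct_volume(vals, spacing)
}
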