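# Low-level binary-morphology primitives on 3-D logical arrays.
# All work on a zero-padded copy so neighbourhood lookups need no bounds
# checks; outside-the-grid counts as background.

pad_false <- function(mask) {
  d <- dim(mask)
  P <- array(FALSE, d + 2L)
  P[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  P
}

neighbor_offsets_26 <- function(pd) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  as.integer(g$di + g$dj * pd[1] + g$dk * pd[1] * pd[2])
}

# 26-connected flood fill from a seed voxel; returns the connected component
# of TRUE voxels containing the seed, as a logical array of dim(mask).
flood_fill_26 <- function(mask, seed) {
  d <- dim(mask)
  P <- pad_false(mask)
  pd <- dim(P)
  offs <- neighbor_offsets_26(pd)
  seedl <- (seed[1] + 1L) + seed[2] * pd[1] + seed[3] * pd[1] * pd[2]
  visited <- array(FALSE, pd)
  if (!P[seedl]) return(array(FALSE, d))
  visited[seedl] <- TRUE
  frontier <- seedl
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, offs, `+`)))
    cand <- cand[P[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# Erosion with the full 3x3x3 cube: a voxel survives iff its entire
# 27-neighbourhood is foreground (grid boundary counts as background).
erode_box3 <- function(mask) {
  d <- dim(mask)
  P <- pad_false(mask)
  pd <- dim(P)
  interior <- as.vector(
    outer(outer(2:(d[1] + 1L), (2:(d[2] + 1L) - 1L) * pd[1], `+`),
          (2:(d[3] + 1L) - 1L) * pd[1] * pd[2], `+`)
  )
  keep <- P[interior]
  for (o in neighbor_offsets_26(pd)) {
    keep <- keep & P[interior + o]
  }
  array(keep, d)
}

# Number of 8-connected components in a 2-D logical matrix, plus the
# centroid (row, col) of the foreground.
components_2d <- function(m) {
  d <- dim(m)
  P <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  P[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  pd <- dim(P)
  offs <- as.integer(outer(-1:1, (-1:1) * pd[1], `+`))
  offs <- offs[offs != 0L]
  todo <- which(P)
  if (!length(todo)) return(list(n = 0L, centroid = c(NA_real_, NA_real_)))
  visited <- logical(length(P))
  n <- 0L
  for (s in todo) {
    if (visited[s]) next
    n <- n + 1L
    visited[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      cand <- unique(as.vector(outer(frontier, offs, `+`)))
      cand <- cand[P[cand] & !visited[cand]]
      visited[cand] <- TRUE
      frontier <- cand
    }
  }
  idx <- arrayInd(todo, pd)
  list(n = n, centroid = c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1))
}
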