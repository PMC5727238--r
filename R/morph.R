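# Small binary 3D morphology toolbox: 6-neighbourhood dilation, cube
# erosion, and border-seeded flood fill (for cavity inclusion in
# volumetry). All operate on logical 3D arrays via lattice shifts.

shift_array <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by >= 0) seq(1 + by, n) else seq_len(n + by)
  ix <- function(sel) switch(axis,
    `1` = a[sel, , , drop = FALSE],
    `2` = a[, sel, , drop = FALSE],
    `3` = a[, , sel, drop = FALSE])
  if (axis == 1L) out[dst, , ] <- ix(src)
  if (axis == 2L) out[, dst, ] <- ix(src)
  if (axis == 3L) out[, , dst] <- ix(src)
  out
}

dilate6 <- function(a) {
  out <- a
  for (ax in 1:3) {
    out <- out | shift_array(a, ax, 1L) | shift_array(a, ax, -1L)
  }
  out
}

# Erosion by a (2r+1)^3 cube: a voxel survives iff the whole cube fits.
erode_cube <- function(a, radius) {
  out <- a
  for (ax in 1:3) {
    acc <- out
    for (by in seq_len(radius)) {
      acc <- acc & shift_array(out, ax, by) & shift_array(out, ax, -by)
    }
    out <- acc
  }
  out
}

# All `open` voxels reachable from the grid border through the 6-connected
# `open` set.
flood_from_border <- function(open) {
  d <- dim(open)
  reach <- array(FALSE, dim = d)
  reach[c(1, d[1]), , ] <- TRUE
  reach[, c(1, d[2]), ] <- TRUE
  reach[, , c(1, d[3])] <- TRUE
  reach <- reach & open
  repeat {
    grown <- dilate6(reach) & open
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  reach
}

# Fill internal cavities: anything not 6-connected to the border through
# the background becomes foreground.
fill_holes3d <- function(mask) {
  outside <- flood_from_border(!mask)
  !outside
}
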