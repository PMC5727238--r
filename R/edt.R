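# Exact Euclidean distance transform on 2D/3D logical grids, via the
# separable lower-envelope-of-parabolas algorithm applied along each axis.
# Used to compute staining depth (distance from the organ surface) in the
# phantom generator and signed distances for slice-mask interpolation.

# 1D squared distance transform of a sampled function f (lower envelope).
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2L:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1L:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Apply dt1d along one axis of an array of squared distances.
dt_axis <- function(g, axis) {
  d <- dim(g)
  perm <- c(axis, setdiff(seq_along(d), axis))
  gp <- aperm(g, perm)
  m <- matrix(gp, nrow = d[axis])
  nonzero <- colSums(m != 0) > 0
  for (j in which(nonzero)) {
    m[, j] <- dt1d(m[, j])
  }
  gp <- array(m, dim = d[perm])
  aperm(gp, order(perm))
}

#' Euclidean distance transform
#'
#' Exact Euclidean distance (in voxels) from each `TRUE` voxel of a 2D or 3D
#' logical mask to the nearest `FALSE` voxel, computed with the separable
#' squared-distance algorithm. `FALSE` voxels get distance 0. Distances are
#' measured within the grid only: a mask touching the border is not
#' considered exposed to an implicit outside background.
#'
#' @param mask Logical 2D matrix or 3D array.
#' @return Numeric array of distances, same shape as `mask`. If `mask` is
#'   all `TRUE` the distances are `Inf`.
#' @export
distance_transform <- function(mask) {
  if (!is.logical(mask) || !(length(dim(mask)) %in% c(2L, 3L))) {
    stop("'mask' must be a logical 2D or 3D array", call. = FALSE)
  }
  d <- dim(mask)
  # big finite stand-in for +Inf so the envelope arithmetic stays finite
  big <- (sum(d) + 1)^2
  g <- array(ifelse(mask, big, 0), dim = d)
  for (ax in seq_along(d)) g <- dt_axis(g, ax)
  g[g >= big] <- Inf
  sqrt(g)
}

# Signed distance of a 2D mask: positive inside (distance to nearest
# background voxel), negative outside (minus distance to nearest foreground
# voxel). Zero only for degenerate all-one/all-zero planes' far field.
signed_distance2d <- function(mask) {
  inside <- distance_transform(mask)
  outside <- distance_transform(!mask)
  ifelse(mask, inside, -outside)
}
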