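# Pre-decomposition image processing: median filtering for noise
# reduction, rigid alignment of the two energy volumes (the decomposition
# is voxel-wise, so the volumes must agree voxel for voxel), and sample
# masks interpolated from sparse manual slice annotations.

#' Median filter a volume
#'
#' Each voxel is replaced by the median of its cubic
#' `(2*radius+1)^3` neighbourhood; edges are handled by reflection.
#' Radius 0 is the identity. Median filtering is edge-preserving, which is
#' why it is the denoising step of choice before voxel-wise decomposition.
#'
#' @param vol An `attenuation_volume`.
#' @param radius Non-negative integer neighbourhood radius in voxels.
#' @return The filtered `attenuation_volume`.
#' @export
median_filter <- function(vol, radius = 1L) {
  stopifnot(is_attenuation_volume(vol))
  if (length(radius) != 1L || is.na(radius) || radius < 0 ||
      radius != round(radius)) {
    stop("'radius' must be a non-negative integer", call. = FALSE)
  }
  radius <- as.integer(radius)
  if (radius == 0L) return(vol)
  d <- dim(vol$data)
  if (any(d < 2L * radius + 1L)) {
    stop("volume too small for the requested filter radius", call. = FALSE)
  }
  # reflect-pad, then gather the k = (2r+1)^3 shifted copies column-wise
  refl <- function(n) c(seq(radius + 1L, 2L, by = -1L), seq_len(n),
                        seq(n - 1L, n - radius, by = -1L))
  pad <- vol$data[refl(d[1]), refl(d[2]), refl(d[3])]
  offs <- seq(-radius, radius)
  k <- length(offs)^3
  n <- prod(d)
  neigh <- matrix(0, nrow = n, ncol = k)
  col <- 1L
  for (dz in offs) for (dy in offs) for (dx in offs) {
    neigh[, col] <- pad[radius + dx + seq_len(d[1]),
                        radius + dy + seq_len(d[2]),
                        radius + dz + seq_len(d[3])]
    col <- col + 1L
  }
  mid <- (k + 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    sort.int(neigh[i, ], partial = mid)[mid]
  }, numeric(1))
  attenuation_volume(array(med, dim = d), vol$voxel_size_um, vol$spectrum)
}

# Normalized cross-correlation between a resampled moving volume and the
# fixed volume over valid (in-field) voxels, optionally on a subsampled
# lattice for speed.
ncc_objective <- function(moving, fixed, par, stride = 1L) {
  d <- dim(fixed$data)
  tf <- rigid_transform(par[1:3], par[4:6])
  Minv <- solve(transform_matrix(tf, d))
  ix <- seq(1L, d[1], by = stride)
  iy <- seq(1L, d[2], by = stride)
  iz <- seq(1L, d[3], by = stride)
  g <- cbind(
    rep.int(ix, length(iy) * length(iz)),
    rep.int(rep(iy, each = length(ix)), length(iz)),
    rep(iz, each = length(ix) * length(iy))
  )
  src <- t(Minv[1:3, 1:3] %*% t(g) + Minv[1:3, 4])
  mv <- trilinear_sample(moving$data, src, fill = NA_real_)
  fv <- fixed$data[g[, 1] + (g[, 2] - 1) * d[1] + (g[, 3] - 1) * d[1] * d[2]]
  ok <- !is.na(mv)
  if (sum(ok) < 32L) return(-Inf)
  a <- mv[ok] - mean(mv[ok])
  b <- fv[ok] - mean(fv[ok])
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(-Inf)
  sum(a * b) / den
}

# Integer-voxel translation estimate via FFT cross-correlation.
fft_translation <- function(moving, fixed) {
  a <- fixed$data - mean(fixed$data)
  b <- moving$data - mean(moving$data)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  d <- dim(a)
  peak <- arrayInd(which.max(cc), d) - 1L
  shift <- ifelse(peak > d / 2, peak - d, peak)
  as.numeric(shift)
}

#' Rigidly register two volumes
#'
#' Estimates the rigid transform (translation + rotation) that maps the
#' moving volume onto the fixed one by maximising normalized
#' cross-correlation (NCC); the two spectra scale tissues differently, so a
#' correlation metric is used rather than plain intensity difference. The
#' search is coarse-to-fine: an FFT cross-correlation gives the integer
#' translation, Nelder-Mead refines all six parameters on a subsampled
#' lattice, and a final full-resolution polish follows.
#'
#' @param moving,fixed `attenuation_volume`s of equal shape.
#' @param options List of options: `stride` (coarse subsampling, default 2),
#'   `maxit` (iterations per refinement, default 300), `min_ncc`
#'   (convergence floor on the final NCC, default 0.5).
#' @return List with `transform` (a [rigid_transform()]), `resampled` (the
#'   moving volume resampled into the fixed frame), `ncc` (final metric),
#'   and `converged` (FALSE flags a failed registration rather than
#'   silently returning the identity).
#' @export
register_rigid <- function(moving, fixed, options = list()) {
  stopifnot(is_attenuation_volume(moving), is_attenuation_volume(fixed))
  check_same_shape(moving, fixed)
  opts <- modifyList(list(stride = 2L, maxit = 300L, min_ncc = 0.5), options)
  d <- dim(fixed$data)

  t0 <- fft_translation(moving, fixed)
  par <- c(t0, 0, 0, 0)
  obj <- function(p, stride) -ncc_objective(moving, fixed, p, stride)
  fit <- optim(par, obj, stride = opts$stride, method = "Nelder-Mead",
               control = list(maxit = opts$maxit, reltol = 1e-9))
  fit <- optim(fit$par, obj, stride = 1L, method = "Nelder-Mead",
               control = list(maxit = opts$maxit, reltol = 1e-10))
  par <- fit$par
  ang <- ((par[4:6] + 180) %% 360) - 180
  ang[ang == -180] <- 180
  tf <- rigid_transform(par[1:3], ang)
  ncc <- -fit$value
  resampled <- apply_rigid_transform(moving, tf,
                                     fill = min(moving$data, na.rm = TRUE))
  list(transform = tf, resampled = resampled, ncc = ncc,
       converged = is.finite(ncc) && ncc >= opts$min_ncc)
}

#' Interpolate a 3D mask from sparse slice annotations
#'
#' Reconstructs a full 3D sample mask from hand-drawn 2D masks on a few
#' z-slices. Annotated slices are reproduced exactly; slices in between are
#' obtained by linearly blending the signed distance transforms of the
#' bracketing annotations and thresholding at zero, which interpolates the
#' contour shape rather than the raw pixels. Outside the annotated range
#' the nearest annotated mask is extended unchanged.
#'
#' @param annotations List of `list(index =, mask =)` pairs: 1-based slice
#'   index and logical 2D matrix. Indices must be strictly increasing and
#'   all masks the same shape.
#' @param n_slices Total number of z-slices of the output mask.
#' @return Logical 3D array of dimension `c(dim(mask), n_slices)`.
#' @export
interpolate_masks <- function(annotations, n_slices) {
  if (length(annotations) < 1L) {
    stop("at least one annotated slice is required", call. = FALSE)
  }
  idx <- vapply(annotations, function(a) as.integer(a$index), integer(1))
  if (any(diff(idx) <= 0)) {
    stop("annotated slice indices must be strictly increasing", call. = FALSE)
  }
  if (idx[1] < 1L || tail(idx, 1) > n_slices) {
    stop("annotated slice indices out of range", call. = FALSE)
  }
  d2 <- dim(annotations[[1]]$mask)
  masks <- lapply(annotations, function(a) {
    m <- a$mask
    if (!is.logical(m)) m <- m > 0
    if (!identical(dim(m), d2)) {
      stop("all annotated masks must have the same shape", call. = FALSE)
    }
    m
  })
  out <- array(FALSE, dim = c(d2, n_slices))
  sdf <- lapply(masks, signed_distance2d)
  for (z in seq_len(n_slices)) {
    if (z <= idx[1]) {
      out[, , z] <- masks[[1]]
    } else if (z >= tail(idx, 1)) {
      out[, , z] <- masks[[length(masks)]]
    } else if (z %in% idx) {
      out[, , z] <- masks[[match(z, idx)]]
    } else {
      hi <- which(idx > z)[1]
      lo <- hi - 1L
      w <- (z - idx[lo]) / (idx[hi] - idx[lo])
      blend <- (1 - w) * sdf[[lo]] + w * sdf[[hi]]
      out[, , z] <- blend > 0
    }
  }
  out
}
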