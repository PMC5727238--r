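# Rigid 3D transforms in voxel coordinates. Convention (fixed and
# documented): intrinsic z-y-x Euler angles in degrees, rotation about the
# volume centre, then translation in voxels. A transform maps a point p to
#   R %*% (p - c) + c + t,     R = Rz(az) %*% Ry(ay) %*% Rx(ax),
# with c = (dim + 1) / 2 the volume centre in 1-based voxel coordinates.

#' Create a rigid transform
#'
#' @param translation Numeric length-3 translation in voxels (x, y, z).
#' @param angles_deg Numeric length-3 intrinsic z-y-x Euler angles in
#'   degrees, given in the order (az, ay, ax); each must lie in (-180, 180].
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform(c(3, -2, 1), c(2, 0, 0))
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            angles_deg = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  angles_deg <- as.numeric(angles_deg)
  if (length(translation) != 3L || length(angles_deg) != 3L ||
      any(!is.finite(c(translation, angles_deg)))) {
    stop("translation and angles must be finite length-3 numerics",
         call. = FALSE)
  }
  if (any(angles_deg <= -180 | angles_deg > 180)) {
    stop("angles must lie in (-180, 180] degrees", call. = FALSE)
  }
  structure(list(translation = translation, angles_deg = angles_deg),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> t = (%.3f, %.3f, %.3f) vox, angles z-y-x = (%.3f, %.3f, %.3f) deg\n",
    x$translation[1], x$translation[2], x$translation[3],
    x$angles_deg[1], x$angles_deg[2], x$angles_deg[3]))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler z-y-x angles (degrees) from a rotation matrix.
euler_from_rotation <- function(R) {
  ay <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ay)) > 1e-10) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else {           # gimbal lock; fold everything into az
    ax <- 0
    az <- atan2(-R[1, 2], R[2, 2])
  }
  c(az, ay, ax) * 180 / pi
}

# 4x4 homogeneous matrix of a transform acting on 1-based voxel coordinates
# of a volume with dimensions d.
transform_matrix <- function(tf, d) {
  ctr <- (d + 1) / 2
  R <- rotation_matrix(tf$angles_deg)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- ctr + tf$translation - R %*% ctr
  M
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b, dim)` returns the 4x4 matrix of "apply `b`,
#' then `a`" for volumes of dimension `dim`; `transform_deviation` measures
#' how far a composed matrix is from the identity as (translation error at
#' the volume centre in voxels, rotation angle in degrees).
#'
#' @param a,b `rigid_transform` objects.
#' @param dim Volume dimensions the transforms act on.
#' @return `compose_transforms`: a 4x4 matrix; `transform_deviation`: named
#'   numeric vector with elements `translation_vox` and `rotation_deg`.
#' @export
compose_transforms <- function(a, b, dim) {
  transform_matrix(a, dim) %*% transform_matrix(b, dim)
}

#' @rdname compose_transforms
#' @param M A 4x4 rigid motion matrix in voxel coordinates.
#' @export
transform_deviation <- function(M, dim) {
  ctr <- c((dim + 1) / 2, 1)
  tvec <- (M %*% ctr)[1:3] - ctr[1:3]
  R <- M[1:3, 1:3]
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  c(translation_vox = sqrt(sum(tvec^2)), rotation_deg = ang)
}

invert_transform_matrix <- function(M) solve(M)

# Trilinear sampling of a 3D array at arbitrary voxel coordinates.
# coords: n x 3 matrix (1-based). Out-of-grid samples get `fill` (NA allowed).
trilinear_sample <- function(arr, coords, fill = NA_real_) {
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x0 >= 1 & y0 >= 1 & z0 >= 1 &
    (x0 + (fx > 0)) <= d[1] & (y0 + (fy > 0)) <= d[2] & (z0 + (fz > 0)) <= d[3]
  out <- rep(fill, nrow(coords))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  # clamp the +1 neighbour for samples sitting exactly on the last plane
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  nxy <- d[1] * d[2]
  at <- function(i, j, k) arr[i + (j - 1) * d[1] + (k - 1) * nxy]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Resample a volume under a rigid transform
#'
#' Applies a rigid motion to an attenuation volume by pull-back trilinear
#' interpolation: the output voxel at position q takes the input value at
#' the pre-image of q under the transform. An integer translation therefore
#' shifts image content by exactly that many voxels. Voxels whose pre-image
#' falls outside the grid are set to `fill` (typically the air attenuation).
#'
#' @param vol An `attenuation_volume`.
#' @param tf A `rigid_transform`.
#' @param fill Value for out-of-field voxels.
#' @return The resampled `attenuation_volume`.
#' @export
apply_rigid_transform <- function(vol, tf, fill = 0) {
  stopifnot(is_attenuation_volume(vol), inherits(tf, "rigid_transform"))
  d <- dim(vol$data)
  if (all(tf$translation == 0) && all(tf$angles_deg == 0)) {
    return(vol)  # exact identity, bit-preserving
  }
  Minv <- invert_transform_matrix(transform_matrix(tf, d))
  # fast path: pure integer translation is a lattice shift, no interpolation
  if (all(tf$angles_deg == 0) && all(tf$translation == round(tf$translation))) {
    src <- sweep(voxel_grid(d), 2, tf$translation)
  } else {
    g <- voxel_grid(d)
    src <- t(Minv[1:3, 1:3] %*% t(g) + Minv[1:3, 4])
  }
  vals <- trilinear_sample(vol$data, src, fill = fill)
  attenuation_volume(array(vals, dim = d), vol$voxel_size_um, vol$spectrum)
}
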