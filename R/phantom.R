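# Synthetic dual-energy phantom generator. Stands in for the study's scans:
# a calibration phantom (PMMA rod + tube of staining solution in air) and an
# organ-like sample ("heart" and "lung" compartments inside an ellipsoidal
# surface) whose stain fraction follows a diffusion-from-surface profile
# growing with staining time. Ground truth is emitted alongside the volumes,
# and noise-free voxel values satisfy the basis mixture equations exactly,
# so decomposition accuracy can be measured against programmed truth.

#' Noise and artifact specification
#'
#' @param sigma Standard deviation of i.i.d. Gaussian noise added to the
#'   reconstructed attenuation (mm^-1); >= 0.
#' @param beta Cupping (beam-hardening stand-in) strength, `|beta| < 1`;
#'   0 disables the bias. See [add_cupping_bias()].
#' @param seed Integer RNG seed; identical specs and seeds give
#'   bit-identical volumes.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, beta = 0, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || abs(beta) >= 1) {
    stop("'beta' must satisfy |beta| < 1", call. = FALSE)
  }
  structure(list(sigma = sigma, beta = beta, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Diffusion-from-surface staining profile
#'
#' Half-space diffusion solution for the stain fraction at a given depth
#' below the sample surface after staining time `t`:
#' `min(F_max, F_surface * erfc(depth / (2 * sqrt(D * t))))`.
#' By convention the profile is 0 for `t = 0` at positive depth and equals
#' `min(F_max, F_surface)` at depth 0. `F_surface` is expressed relative to
#' the calibration staining solution and may exceed 1 (local accumulation
#' above the bath concentration).
#'
#' @param depth Depth below the surface in voxels; >= 0, vectorised.
#' @param D Diffusion coefficient in voxel^2/min; >= 0.
#' @param t Staining time in minutes; >= 0.
#' @param f_surface Stain fraction maintained at the surface.
#' @param f_max Saturation cap on the fraction.
#' @return Stain fraction(s), same length as `depth`.
#' @examples
#' diffusion_profile(0:10, D = 1, t = 30, f_surface = 1)
#' @export
diffusion_profile <- function(depth, D, t, f_surface, f_max = Inf) {
  if (any(depth < 0) || anyNA(depth)) {
    stop("'depth' must be non-negative", call. = FALSE)
  }
  if (t < 0) stop("'t' must be non-negative", call. = FALSE)
  if (D < 0) stop("'D' must be non-negative", call. = FALSE)
  if (f_surface < 0) stop("'f_surface' must be non-negative", call. = FALSE)
  scale <- 2 * sqrt(D * t)
  f <- if (scale == 0) {
    ifelse(depth == 0, f_surface, 0)
  } else {
    f_surface * erfc(depth / scale)
  }
  pmin(f, f_max)
}

#' Organ phantom specification
#'
#' Parametric description of the organ-like sample: an ellipsoidal outer
#' surface split by a plane into a "heart" and a "lung" compartment, with
#' per-compartment diffusion coefficients, surface fractions and saturation
#' caps, an optional cylindrical container wall, and a shrinkage history.
#' Defaults emulate an iodine-in-ethanol staining experiment in which the
#' stain diffuses faster into the heart and locally accumulates above the
#' bath concentration (cap 1.3), while the lung takes up stain more slowly.
#'
#' @param shape Grid dimensions in voxels, length 3.
#' @param voxel_size_um Voxel edge length in micrometres.
#' @param organ_semiaxes Ellipsoid semi-axes in voxels (x, y, z).
#' @param organ_center Ellipsoid centre in voxel coordinates; default grid
#'   centre.
#' @param split_offset Signed offset (voxels, along x) of the heart/lung
#'   split plane from the organ centre; the heart is the `x <= centre +
#'   offset` side.
#' @param D Named vector `c(heart = , lung = )` of diffusion coefficients in
#'   voxel^2/min.
#' @param f_surface Named vector of per-compartment surface stain fractions
#'   (relative to the calibration solution; may exceed 1).
#' @param f_max Named vector of per-compartment saturation caps.
#' @param container `NULL`, or `list(r_inner =, r_outer =)` in voxels for a
#'   z-axis cylindrical PMMA container wall around the sample.
#' @param shrinkage_history Numeric vector of volume ratios already applied
#'   (bookkeeping; see [apply_shrinkage()]).
#' @return An object of class `organ_phantom_spec`.
#' @export
organ_phantom_spec <- function(shape = c(64, 64, 64),
                               voxel_size_um = 20,
                               organ_semiaxes = c(24, 20, 16),
                               organ_center = (shape + 1) / 2,
                               split_offset = -3,
                               D = c(heart = 2, lung = 0.5),
                               f_surface = c(heart = 1.5, lung = 1.0),
                               f_max = c(heart = 1.3, lung = 1.0),
                               container = NULL,
                               shrinkage_history = numeric()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  comp <- c("heart", "lung")
  for (v in list(D, f_surface, f_max)) {
    if (!all(comp %in% names(v)) || any(v[comp] < 0)) {
      stop("'D', 'f_surface' and 'f_max' need non-negative 'heart' and ",
           "'lung' entries", call. = FALSE)
    }
  }
  if (any(organ_semiaxes <= 0) || length(organ_semiaxes) != 3L) {
    stop("'organ_semiaxes' must be 3 positive numbers", call. = FALSE)
  }
  if (any(organ_center - organ_semiaxes < 1) ||
      any(organ_center + organ_semiaxes > shape)) {
    stop("organ ellipsoid does not fit inside the grid", call. = FALSE)
  }
  if (!is.null(container)) {
    if (is.null(container$r_inner) || is.null(container$r_outer) ||
        container$r_inner >= container$r_outer) {
      stop("'container' must be list(r_inner, r_outer) with r_inner < r_outer",
           call. = FALSE)
    }
  }
  structure(
    list(shape = shape, voxel_size_um = voxel_size_um,
         organ_semiaxes = as.numeric(organ_semiaxes),
         organ_center = as.numeric(organ_center),
         split_offset = split_offset,
         D = D[comp], f_surface = f_surface[comp], f_max = f_max[comp],
         container = container, shrinkage_history = shrinkage_history),
    class = "organ_phantom_spec"
  )
}

#' Shrink an organ phantom
#'
#' Scales all linear dimensions of the organ by `s^(1/3)` about the organ
#' centroid so the enclosed volume scales by the ratio `s`, emulating the
#' sample shrinkage observed between staining rounds (ethanol-based stains
#' dehydrate the tissue). The applied ratio is appended to the spec's
#' shrinkage history.
#'
#' @param spec An `organ_phantom_spec`.
#' @param s Volume ratio, `0 < s <= 1.25`; `s = 1` leaves geometry unchanged.
#' @return The rescaled `organ_phantom_spec`.
#' @export
apply_shrinkage <- function(spec, s) {
  stopifnot(inherits(spec, "organ_phantom_spec"))
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0 || s > 1.25) {
    stop("'s' must be a volume ratio in (0, 1.25]", call. = FALSE)
  }
  k <- s^(1 / 3)
  spec$organ_semiaxes <- spec$organ_semiaxes * k
  spec$split_offset <- spec$split_offset * k
  spec$shrinkage_history <- c(spec$shrinkage_history, s)
  spec
}

# Rasterize the spec into organ/heart/lung/container masks.
rasterize_organ <- function(spec) {
  d <- spec$shape
  g <- voxel_grid(d)
  ctr <- spec$organ_center
  ax <- spec$organ_semiaxes
  u <- sweep(g, 2, ctr)
  inside <- (u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2 <= 1
  organ <- array(inside, dim = d)
  heart <- organ & array(g[, 1] <= ctr[1] + spec$split_offset, dim = d)
  lung <- organ & !heart
  container <- array(FALSE, dim = d)
  if (!is.null(spec$container)) {
    r2 <- u[, 1]^2 + u[, 2]^2
    wall <- r2 >= spec$container$r_inner^2 & r2 <= spec$container$r_outer^2
    container <- array(wall, dim = d) & !organ
  }
  list(organ = organ, heart = heart, lung = lung, container = container)
}

#' Generate a stained-organ dual-energy phantom
#'
#' Rasterizes the organ spec, computes the true stain fraction at staining
#' time `t_min` from the diffusion profile applied to the Euclidean
#' distance-from-surface, and emits the low- and high-energy attenuation
#' volumes as exact basis mixtures (unstained tissue uses the PMMA basis, so
#' the truth lies in the decomposition's span):
#' `mu = mu_stain * F_stain + mu_PMMA * F_PMMA + mu_air * F_air`, followed by
#' optional cupping bias, rigid misalignment of the HE volume, and Gaussian
#' noise.
#'
#' @param spec An [organ_phantom_spec()].
#' @param calset A [calibration_set()]; must pass [conditioning()].
#' @param t_min Staining time in minutes.
#' @param noise A [noise_spec()].
#' @param he_misalignment Optional [rigid_transform()] applied to the HE
#'   volume to emulate inter-scan motion (what registration must undo).
#' @return List with elements `le`, `he` (`attenuation_volume`s) and
#'   `truth`, a `ground_truth` object holding the F fields, compartment
#'   masks, staining depth, applied transform and shrinkage history.
#' @examples
#' ph <- make_organ_phantom(organ_phantom_spec(shape = c(32, 32, 32),
#'                                             organ_semiaxes = c(12, 10, 8)),
#'                          default_calibration_set(), t_min = 60)
#' range(ph$truth$f_stain)
#' @export
make_organ_phantom <- function(spec, calset, t_min,
                               noise = noise_spec(),
                               he_misalignment = NULL) {
  stopifnot(inherits(spec, "organ_phantom_spec"),
            inherits(noise, "noise_spec"))
  if (!is.numeric(t_min) || length(t_min) != 1L || is.na(t_min) || t_min < 0) {
    stop("'t_min' must be a single non-negative time", call. = FALSE)
  }
  check_calset_conditioning(calset)
  masks <- rasterize_organ(spec)
  d <- spec$shape
  depth <- distance_transform(masks$organ)

  f_stain <- array(0, dim = d)
  for (comp in c("heart", "lung")) {
    m <- masks[[comp]]
    if (any(m)) {
      f_stain[m] <- diffusion_profile(depth[m], D = spec$D[[comp]],
                                      t = t_min,
                                      f_surface = spec$f_surface[[comp]],
                                      f_max = spec$f_max[[comp]])
    }
  }
  f_pmma <- array(0, dim = d)
  f_pmma[masks$organ] <- pmax(0, 1 - pmin(f_stain[masks$organ], 1))
  f_pmma[masks$container] <- 1
  f_air <- array(0, dim = d)
  f_air[!masks$organ & !masks$container] <- 1

  A <- basis_matrix(calset)
  le <- A[1, 1] * f_stain + A[1, 2] * f_pmma + A[1, 3] * f_air
  he <- A[2, 1] * f_stain + A[2, 2] * f_pmma + A[2, 3] * f_air
  vol_le <- attenuation_volume(le, spec$voxel_size_um, "LE")
  vol_he <- attenuation_volume(he, spec$voxel_size_um, "HE")

  if (noise$beta != 0) {
    vol_le <- add_cupping_bias(vol_le, noise$beta)
    vol_he <- add_cupping_bias(vol_he, noise$beta)
  }
  if (!is.null(he_misalignment)) {
    vol_he <- apply_rigid_transform(vol_he, he_misalignment,
                                    fill = calset$air[2])
  }
  if (noise$sigma > 0) {
    with_seed(noise$seed, {
      vol_le$data <- vol_le$data + rnorm(length(le), sd = noise$sigma)
      vol_he$data <- vol_he$data + rnorm(length(he), sd = noise$sigma)
    })
  }
  truth <- structure(
    list(f_stain = f_stain, f_pmma = f_pmma, f_air = f_air,
         organ_mask = masks$organ, heart_mask = masks$heart,
         lung_mask = masks$lung, container_mask = masks$container,
         depth = depth, transform = he_misalignment,
         shrinkage_history = spec$shrinkage_history, t_min = t_min),
    class = "ground_truth"
  )
  list(le = vol_le, he = vol_he, truth = truth)
}

#' Calibration phantom geometry
#'
#' A PMMA rod and a tube of staining solution, both cylinders along z,
#' surrounded by air.
#'
#' @param shape Grid dimensions, length 3.
#' @param voxel_size_um Voxel edge length in micrometres.
#' @param rod_center,tube_center (x, y) cylinder axis positions in voxels;
#'   defaults place them side by side.
#' @param rod_radius,tube_radius Cylinder radii in voxels.
#' @return A list describing the geometry, for [make_calibration_phantom()].
#' @export
calibration_phantom_geometry <- function(shape = c(64, 64, 32),
                                         voxel_size_um = 20,
                                         rod_center = c(0.30, 0.50) * shape[1:2],
                                         rod_radius = 0.15 * shape[1],
                                         tube_center = c(0.72, 0.50) * shape[1:2],
                                         tube_radius = 0.12 * shape[1]) {
  list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
       rod_center = rod_center, rod_radius = rod_radius,
       tube_center = tube_center, tube_radius = tube_radius)
}

#' Generate a dual-energy calibration phantom
#'
#' Voxels are labelled air (0), PMMA rod (1) or staining solution (2) and
#' carry the corresponding basis coefficient per spectrum, plus Gaussian
#' noise. The label field is returned so calibration regions can be selected
#' for [estimate_basis()] round trips.
#'
#' @param geometry A [calibration_phantom_geometry()].
#' @param calset A [calibration_set()] supplying the basis coefficients.
#' @param noise A [noise_spec()].
#' @return List with `le`, `he` (`attenuation_volume`s) and `labels`
#'   (integer array).
#' @export
make_calibration_phantom <- function(geometry, calset,
                                     noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  d <- geometry$shape
  for (nm in c("rod", "tube")) {
    ctr <- geometry[[paste0(nm, "_center")]]
    r <- geometry[[paste0(nm, "_radius")]]
    if (ctr[1] - r < 1 || ctr[1] + r > d[1] ||
        ctr[2] - r < 1 || ctr[2] + r > d[2]) {
      stop("calibration phantom ", nm, " does not fit inside the grid",
           call. = FALSE)
    }
  }
  gap <- sqrt(sum((geometry$rod_center - geometry$tube_center)^2))
  if (gap <= geometry$rod_radius + geometry$tube_radius) {
    stop("rod and tube overlap", call. = FALSE)
  }
  g <- voxel_grid(d)
  in_cyl <- function(ctr, r) {
    (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 <= r^2
  }
  labels <- array(0L, dim = d)
  labels[in_cyl(geometry$rod_center, geometry$rod_radius)] <- 1L
  labels[in_cyl(geometry$tube_center, geometry$tube_radius)] <- 2L
  A <- basis_matrix(calset)  # columns stain, pmma, air
  lut <- function(row) c(A[row, 3], A[row, 2], A[row, 1])[labels + 1L]
  le <- array(lut(1), dim = d)
  he <- array(lut(2), dim = d)
  if (noise$sigma > 0) {
    with_seed(noise$seed, {
      le <- le + rnorm(length(le), sd = noise$sigma)
      he <- he + rnorm(length(he), sd = noise$sigma)
    })
  }
  list(le = attenuation_volume(le, geometry$voxel_size_um, "LE"),
       he = attenuation_volume(he, geometry$voxel_size_um, "HE"),
       labels = labels)
}

#' Radial cupping bias
#'
#' Multiplicative radial bias emulating the cupping appearance of beam
#' hardening: `mu'(x) = mu(x) * (1 - beta * (1 - r(x)/R))` with `r` the
#' distance from `center` and `R` the largest in-grid distance from it.
#' Positive `beta` depresses the centre of the volume; `beta = 0` is the
#' identity.
#'
#' @param vol An `attenuation_volume`.
#' @param beta Cupping strength, `|beta| < 1`.
#' @param center Bias centre in voxel coordinates; default grid centre.
#' @return The biased `attenuation_volume`.
#' @export
add_cupping_bias <- function(vol, beta, center = NULL) {
  stopifnot(is_attenuation_volume(vol))
  if (abs(beta) >= 1) stop("'beta' must satisfy |beta| < 1", call. = FALSE)
  if (beta == 0) return(vol)
  d <- dim(vol$data)
  if (is.null(center)) center <- (d + 1) / 2
  g <- voxel_grid(d)
  r <- sqrt(rowSums(sweep(g, 2, center)^2))
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  R <- max(sqrt(rowSums(sweep(corners, 2, center)^2)))
  vol$data <- vol$data * array(1 - beta * (1 - r / R), dim = d)
  vol
}
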