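# The basic container: a reconstructed 3D attenuation volume for one energy
# spectrum. Values are effective polychromatic linear attenuation
# coefficients in mm^-1 on a regular grid with isotropic voxels; the voxel
# edge length is carried in micrometres. Array axes are (x, y, z) with voxel
# centres at integer coordinates; slice k of the array is the z = k plane.

#' Create an attenuation volume
#'
#' @param data 3D numeric array of attenuation coefficients (mm^-1).
#' @param voxel_size_um Isotropic voxel edge length in micrometres; must be
#'   a single positive number.
#' @param spectrum Optional label for the energy spectrum (e.g. `"LE"`,
#'   `"HE"`, or a kVp string).
#' @return An object of class `attenuation_volume`.
#' @examples
#' vol <- attenuation_volume(array(0.1, c(8, 8, 8)), voxel_size_um = 5)
#' dim(vol)
#' @export
attenuation_volume <- function(data, voxel_size_um, spectrum = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop("'data' must be a 3D numeric array", call. = FALSE)
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0) {
    stop("'voxel_size_um' must be a single positive number", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         spectrum = spectrum),
    class = "attenuation_volume"
  )
}

#' @export
dim.attenuation_volume <- function(x) dim(x$data)

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<attenuation_volume> %d x %d x %d voxels, %.3g um/voxel%s\n",
    d[1], d[2], d[3], x$voxel_size_um,
    if (!is.null(x$spectrum)) paste0(", spectrum ", x$spectrum) else ""))
  rng <- range(x$data, finite = TRUE)
  cat(sprintf("  attenuation range [%.4g, %.4g] mm^-1\n", rng[1], rng[2]))
  invisible(x)
}

is_attenuation_volume <- function(x) inherits(x, "attenuation_volume")

as_volume_data <- function(x) {
  if (is_attenuation_volume(x)) x$data else x
}

# Masks are plain logical 3D arrays; this checks congruence with a volume.
check_congruent <- function(vol, mask, what = "mask") {
  if (!is.null(mask) && !identical(dim(as_volume_data(vol)), dim(mask))) {
    stop(what, " must have the same dimensions as the volume", call. = FALSE)
  }
  invisible(TRUE)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(as_volume_data(a)), dim(as_volume_data(b)))) {
    stop("volumes must have identical dimensions", call. = FALSE)
  }
  invisible(TRUE)
}

# Integer voxel-centre coordinate grid of a 3D array, as an n x 3 matrix.
voxel_grid <- function(d) {
  cbind(
    x = rep.int(seq_len(d[1]), d[2] * d[3]),
    y = rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    z = rep(seq_len(d[3]), each = d[1] * d[2])
  )
}
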