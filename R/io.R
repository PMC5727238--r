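# Volume and mask I/O. Two on-disk forms are supported:
#   * NRRD (raw encoding, little endian): canonical, carries voxel size in
#     its header ("spacings", micrometres). Written/parsed directly — the
#     header is plain text and the payload raw binary.
#   * Multi-page TIFF + YAML sidecar: slice k of the stack is the z = k
#     plane; the sidecar carries voxel_size_um (required) and an optional
#     linear "scale" applied to integer-valued stacks.
# Missing voxel-size metadata is an error, never a silent default.

#' Write a volume to disk
#'
#' Dispatches on the file extension: `.nrrd` writes raw little-endian NRRD
#' with the voxel size in the header; `.tif`/`.tiff` writes a 16-bit
#' integer multi-page TIFF plus a `<path>.yaml` sidecar carrying the voxel
#' size and the affine `scale`/`offset` mapping the stored integers back to
#' attenuation. NRRD round-trips doubles bit-exactly; the TIFF path
#' quantises to 1/65535 of the data range.
#'
#' @param vol An `attenuation_volume`.
#' @param path Output path ending in `.nrrd`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_attenuation_volume(vol))
  ext <- tolower(tools::file_ext(path))
  d <- dim(vol$data)
  if (ext == "nrrd") {
    con <- file(path, "wb")
    on.exit(close(con))
    sp <- vol$voxel_size_um
    header <- c(
      "NRRD0004",
      "# attenuation volume, values mm^-1, spacings um",
      "type: double",
      "dimension: 3",
      sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
      sprintf("spacings: %.10g %.10g %.10g", sp, sp, sp),
      "endian: little",
      "encoding: raw",
      ""
    )
    writeLines(header, con)
    writeBin(as.vector(vol$data), con, size = 8L, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    # 16-bit integer stack; the affine map back to attenuation lives in the
    # sidecar (value = stored * scale + offset)
    rng <- range(vol$data, finite = TRUE)
    span <- diff(rng)
    if (span == 0) span <- 1
    norm <- (vol$data - rng[1]) / span
    slices <- lapply(seq_len(d[3]), function(k) {
      # TIFF pages are row x col matrices; store (y, x) per z-plane
      t(norm[, , k])
    })
    tiff::writeTIFF(slices, path, bits.per.sample = 16L)
    yaml::write_yaml(list(voxel_size_um = vol$voxel_size_um,
                          scale = span / 65535, offset = rng[1],
                          axis_order = "zyx", units = "mm^-1"),
                     paste0(path, ".yaml"), precision = 15L)
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path,
                                       call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header: ", path,
                                 call. = FALSE)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  if (!identical(fields$encoding, "raw")) {
    stop("only raw-encoded NRRD is supported", call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  if (length(sizes) != 3L) stop("expected a 3D NRRD volume", call. = FALSE)
  if (is.null(fields$spacings)) {
    stop("NRRD header lacks voxel spacings; refusing to guess a voxel size",
         call. = FALSE)
  }
  sp <- as.numeric(strsplit(fields$spacings, " ")[[1]])
  size_bytes <- switch(fields$type, double = 8L, float = 4L,
                       stop("unsupported NRRD type: ", fields$type,
                            call. = FALSE))
  n <- prod(sizes)
  vals <- readBin(con, "double", n = n, size = size_bytes,
                  endian = if (identical(fields$endian, "big")) "big"
                           else "little")
  if (length(vals) != n) stop("NRRD payload shorter than header sizes",
                              call. = FALSE)
  attenuation_volume(array(vals, dim = sizes), voxel_size_um = sp[1])
}

read_tiff_stack <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) {
    stop("TIFF volume requires a voxel-size sidecar: ", sidecar,
         call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$voxel_size_um)) {
    stop("sidecar lacks voxel_size_um; refusing to guess a voxel size",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  ok <- vapply(pages, function(p) identical(dim(p), d2), logical(1))
  if (!all(ok)) stop("inconsistent slice shapes in TIFF stack: ", path,
                     call. = FALSE)
  arr <- array(0, dim = c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  if (!is.null(meta$scale)) arr <- arr * meta$scale
  if (!is.null(meta$offset)) arr <- arr + meta$offset
  attenuation_volume(arr, voxel_size_um = meta$voxel_size_um)
}

#' Read a volume from disk
#'
#' Counterpart of [write_volume()]. `.nrrd` files must carry voxel
#' spacings; TIFF stacks must have a `<path>.yaml` sidecar with
#' `voxel_size_um` and may carry a linear `scale` applied to the stored
#' values (the contract for 16-bit integer stacks).
#'
#' @param path Path to a `.nrrd` file or TIFF stack.
#' @return An `attenuation_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = read_nrrd(path),
    tif = ,
    tiff = read_tiff_stack(path),
    stop("unsupported volume format: .", ext, call. = FALSE)
  )
}

#' Read and write binary masks as 8-bit TIFF stacks
#'
#' @param mask Logical 3D array.
#' @param path TIFF path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a logical
#'   array.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  slices <- lapply(seq_len(dim(mask)[3]), function(k) {
    t(mask[, , k]) * 1.0
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(FALSE, dim = c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) > 0.5
  arr
}

#' Read and write rigid transforms as YAML
#'
#' Stores the translation (voxels) and intrinsic z-y-x Euler angles
#' (degrees) with the axis order stated in the file.
#'
#' @param tf A [rigid_transform()].
#' @param path YAML path.
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  yaml::write_yaml(list(translation_vox = tf$translation,
                        angles_deg = tf$angles_deg,
                        rotation_order = "intrinsic z-y-x about volume centre"),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- yaml::read_yaml(path)
  rigid_transform(as.numeric(unlist(obj$translation_vox)),
                  as.numeric(unlist(obj$angles_deg)))
}

#' Write a fraction map to disk
#'
#' One NRRD per material plus the residual, written as
#' `<prefix>_stain.nrrd`, `<prefix>_pmma.nrrd`, `<prefix>_air.nrrd`,
#' `<prefix>_residual.nrrd`. Not-computed voxels are stored as NaN (the
#' validity mask is recoverable as `!is.nan()`).
#'
#' @param fmap A `fraction_map`.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_fraction_map <- function(fmap, prefix) {
  stopifnot(inherits(fmap, "fraction_map"))
  fields <- c(stain = "f_stain", pmma = "f_pmma", air = "f_air",
              residual = "residual")
  paths <- character(0)
  for (nm in names(fields)) {
    p <- paste0(prefix, "_", nm, ".nrrd")
    write_volume(attenuation_volume(fmap[[fields[[nm]]]],
                                    fmap$voxel_size_um), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
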