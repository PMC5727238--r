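# Downstream quantification: sample volumetry by voxel counting (internal
# cavities included), relative-volume and mean-attenuation time courses,
# 2D correlation histograms of the two energy channels, and per-tissue
# stain-uptake summaries from fraction maps. Tabular results are tibbles.

#' Sample volume by voxel counting
#'
#' Thresholds away air, removes the container voxels, fills internal
#' cavities (holes and chambers inside the sample count toward its total
#' volume), and returns `filled voxel count * voxel_size^3`.
#'
#' @param vol An `attenuation_volume` (typically the low-energy one).
#' @param threshold Attenuation threshold (mm^-1); voxels with values
#'   `>= threshold` are sample candidates.
#' @param container_mask Optional logical array of container voxels to
#'   delete before thresholding.
#' @param voxel_size_um Voxel size override in micrometres; defaults to the
#'   volume's own.
#' @return Sample volume in cubic micrometres.
#' @examples
#' v <- attenuation_volume(array(0.2, c(10, 10, 10)), 2)
#' sample_volume(v, threshold = 0.1)  # 1000 voxels * 8 um^3
#' @export
sample_volume <- function(vol, threshold, container_mask = NULL,
                          voxel_size_um = NULL) {
  stopifnot(is_attenuation_volume(vol))
  if (!is.finite(threshold)) stop("'threshold' must be finite", call. = FALSE)
  check_congruent(vol, container_mask, "container_mask")
  vs <- if (is.null(voxel_size_um)) vol$voxel_size_um else voxel_size_um
  if (!is.numeric(vs) || vs <= 0) {
    stop("voxel size must be positive", call. = FALSE)
  }
  binary <- vol$data >= threshold
  if (!is.null(container_mask)) binary[container_mask] <- FALSE
  filled <- fill_holes3d(binary)
  sum(filled) * vs^3
}

#' Relative-volume time series
#'
#' Normalises a series of volume measurements to the first (baseline) time
#' point, the form in which staining-induced sample shrinkage is reported.
#'
#' @param measurements Data frame (or tibble) with columns `time_min` and
#'   `volume_um3`; times must be strictly increasing and the first row is
#'   the baseline.
#' @return A tibble of class `volume_time_series` with columns `time_min`,
#'   `volume_um3`, `relative_volume`.
#' @export
relative_volume_series <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!all(c("time_min", "volume_um3") %in% names(m)) || nrow(m) < 1L) {
    stop("'measurements' needs columns time_min and volume_um3 and >= 1 row",
         call. = FALSE)
  }
  if (any(diff(m$time_min) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(m$volume_um3 < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (m$volume_um3[1] == 0) {
    stop("baseline volume is zero; cannot normalise", call. = FALSE)
  }
  out <- tibble::tibble(
    time_min = m$time_min,
    volume_um3 = m$volume_um3,
    relative_volume = m$volume_um3 / m$volume_um3[1]
  )
  class(out) <- c("volume_time_series", class(out))
  out
}

#' Mean attenuation over a mask
#'
#' @param vol An `attenuation_volume`.
#' @param mask Non-empty logical array congruent with the volume.
#' @return Arithmetic mean attenuation (mm^-1).
#' @export
mean_attenuation <- function(vol, mask) {
  stopifnot(is_attenuation_volume(vol))
  check_congruent(vol, mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mean(vol$data[mask])
}

#' Two-dimensional correlation histogram
#'
#' Joint histogram of the (LE, HE) attenuation pairs over a mask: the
#' number of voxels with a given combination of low- and high-energy
#' effective attenuation coefficients. Material phases appear as clusters.
#' Out-of-range values are clipped into the edge bins, so the total count
#' always equals the mask cardinality.
#'
#' @param vol_le,vol_he Congruent `attenuation_volume`s.
#' @param mask Optional logical array; default all voxels.
#' @param edges_le,edges_he Optional strictly increasing bin edge vectors.
#'   If omitted, `n_bins` equal-width bins span the 0.1-99.9 percentile
#'   range of each channel.
#' @param n_bins Number of bins per channel for automatic edges.
#' @return Object of class `correlation_histogram2d`: `counts` (matrix,
#'   LE bins in rows), `edges_le`, `edges_he`, `n_voxels`.
#' @export
correlation_histogram2d <- function(vol_le, vol_he, mask = NULL,
                                    edges_le = NULL, edges_he = NULL,
                                    n_bins = 256L) {
  stopifnot(is_attenuation_volume(vol_le), is_attenuation_volume(vol_he))
  check_same_shape(vol_le, vol_he)
  check_congruent(vol_le, mask)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(vol_le$data))
  a <- vol_le$data[mask]
  b <- vol_he$data[mask]
  auto_edges <- function(x) {
    rng <- quantile(x, c(0.001, 0.999), names = FALSE)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1e-6)
    seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  if (is.null(edges_le)) edges_le <- auto_edges(a)
  if (is.null(edges_he)) edges_he <- auto_edges(b)
  for (e in list(edges_le, edges_he)) {
    if (any(diff(e) <= 0)) {
      stop("bin edges must be strictly increasing", call. = FALSE)
    }
  }
  nb_le <- length(edges_le) - 1L
  nb_he <- length(edges_he) - 1L
  ia <- pmin(pmax(findInterval(a, edges_le, rightmost.closed = TRUE), 1L), nb_le)
  ib <- pmin(pmax(findInterval(b, edges_he, rightmost.closed = TRUE), 1L), nb_he)
  counts <- matrix(tabulate((ib - 1L) * nb_le + ia, nbins = nb_le * nb_he),
                   nrow = nb_le, ncol = nb_he)
  structure(
    list(counts = counts, edges_le = edges_le, edges_he = edges_he,
         n_voxels = length(a)),
    class = "correlation_histogram2d"
  )
}

#' @export
print.correlation_histogram2d <- function(x, ...) {
  cat(sprintf("<correlation_histogram2d> %d x %d bins, %d voxels\n",
              nrow(x$counts), ncol(x$counts), x$n_voxels))
  invisible(x)
}

#' Tidy a 2D correlation histogram
#'
#' @param hist A `correlation_histogram2d`.
#' @return Tibble with bin centres `mu_le`, `mu_he` and `count`, one row
#'   per bin.
#' @export
tidy_histogram <- function(hist) {
  stopifnot(inherits(hist, "correlation_histogram2d"))
  ctr <- function(e) (head(e, -1) + tail(e, -1)) / 2
  tibble::tibble(
    mu_le = rep(ctr(hist$edges_le), times = ncol(hist$counts)),
    mu_he = rep(ctr(hist$edges_he), each = nrow(hist$counts)),
    count = as.vector(hist$counts)
  )
}

#' Per-tissue stain uptake summary
#'
#' Mean and maximum stain fraction per tissue label at a staining time,
#' e.g. to compare heart against lung uptake. A label whose mask is empty
#' is reported with zero count rather than dropped.
#'
#' @param fmap A [decompose_volume()] `fraction_map`.
#' @param tissue_masks Named list of disjoint logical arrays, one per
#'   tissue label.
#' @param t_min Staining time in minutes (annotation only).
#' @return Tibble with columns `tissue`, `time_min`, `mean_f_stain`,
#'   `max_f_stain`, `n_voxels`.
#' @export
uptake_summary <- function(fmap, tissue_masks, t_min) {
  stopifnot(inherits(fmap, "fraction_map"))
  if (is.null(names(tissue_masks)) || any(!nzchar(names(tissue_masks)))) {
    stop("'tissue_masks' must be a named list", call. = FALSE)
  }
  acc <- array(0L, dim = dim(fmap$f_stain))
  for (m in tissue_masks) {
    check_congruent(fmap$f_stain, m, "tissue mask")
    acc <- acc + m
  }
  if (any(acc > 1L)) stop("tissue masks overlap", call. = FALSE)
  rows <- lapply(names(tissue_masks), function(nm) {
    m <- tissue_masks[[nm]] & fmap$computed
    n <- sum(m)
    tibble::tibble(
      tissue = nm, time_min = t_min,
      mean_f_stain = if (n > 0) mean(fmap$f_stain[m]) else NA_real_,
      max_f_stain = if (n > 0) max(fmap$f_stain[m]) else NA_real_,
      n_voxels = n
    )
  })
  do.call(rbind, rows)
}
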