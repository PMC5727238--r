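# End-to-end driver: for each staining time point, register the HE volume
# onto the LE volume, median-filter, decompose into fraction maps, and
# accumulate the quantification tables (sample volume, mean attenuation,
# per-tissue uptake, correlation histograms). A manifest with the config
# hash, seed and output checksums makes reruns verifiable.

#' Pipeline configuration
#'
#' @param time_points List of `list(time_min =, le =, he =)` entries, file
#'   paths per staining time (strictly increasing times).
#' @param calibration Path to a calibration YAML, or a `calibration_set`.
#' @param out_dir Output directory (created if missing).
#' @param mode Decomposition mode, see [decompose_volume()].
#' @param median_radius Median filter radius in voxels (0 disables).
#' @param threshold Volumetry threshold in mm^-1, or `NULL` to use the
#'   midpoint between the air and PMMA LE coefficients.
#' @param container_mask Optional path to a container mask TIFF.
#' @param tissue_masks Optional named list of tissue mask TIFF paths.
#' @param register Logical: register HE onto LE per time point.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic option.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(time_points, calibration, out_dir,
                            mode = "three_material_soft",
                            median_radius = 1L, threshold = NULL,
                            container_mask = NULL, tissue_masks = NULL,
                            register = TRUE, seed = 1L) {
  if (length(time_points) < 1L) {
    stop("at least one time point is required", call. = FALSE)
  }
  times <- vapply(time_points, function(tp) as.numeric(tp$time_min),
                  numeric(1))
  if (any(diff(times) <= 0)) {
    stop("time points must have strictly increasing time_min", call. = FALSE)
  }
  structure(
    list(time_points = time_points, calibration = calibration,
         out_dir = out_dir, mode = mode, median_radius = median_radius,
         threshold = threshold, container_mask = container_mask,
         tissue_masks = tissue_masks, register = register,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

pipeline_fail <- function(stage, path, msg) {
  stop(sprintf("pipeline stage '%s' failed on '%s': %s", stage,
               if (is.null(path)) "<memory>" else path, msg), call. = FALSE)
}

require_file <- function(stage, path) {
  if (!file.exists(path)) pipeline_fail(stage, path, "file does not exist")
  path
}

#' Run the full dual-energy analysis pipeline
#'
#' Executes, per staining time point: read LE/HE volumes, rigid
#' registration of HE onto LE, median filtering, constrained material
#' decomposition, and quantification. Writes fraction maps (NRRD), CSV
#' tables, a correlation histogram per time point, and a JSON run manifest
#' with the seed, config hash and MD5 checksums of all numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a report list: `volumes` (a `volume_time_series`
#'   tibble), `attenuation` (tibble of mean attenuations), `uptake`
#'   (tibble or `NULL`), `fraction_maps` (list of output prefixes),
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  calset <- if (inherits(config$calibration, "calibration_set")) {
    config$calibration
  } else {
    read_calibration(require_file("calibrate", config$calibration))
  }
  check_calset_conditioning(calset)
  threshold <- if (is.null(config$threshold)) {
    (calset$air[1] + calset$pmma[1]) / 2
  } else config$threshold

  container <- if (!is.null(config$container_mask)) {
    read_mask(require_file("masks", config$container_mask))
  } else NULL
  tissue <- if (!is.null(config$tissue_masks)) {
    lapply(config$tissue_masks, function(p) read_mask(require_file("masks", p)))
  } else NULL

  vol_rows <- list(); att_rows <- list(); upt_rows <- list()
  prefixes <- character(0)
  for (tp in config$time_points) {
    le <- tryCatch(read_volume(require_file("read", tp$le)),
                   error = function(e) pipeline_fail("read", tp$le,
                                                     conditionMessage(e)))
    he <- tryCatch(read_volume(require_file("read", tp$he)),
                   error = function(e) pipeline_fail("read", tp$he,
                                                     conditionMessage(e)))
    reg_diag <- NULL
    if (isTRUE(config$register)) {
      reg <- register_rigid(he, le)
      if (!reg$converged) {
        pipeline_fail("register", tp$he,
                      sprintf("registration did not converge (ncc = %.3f)",
                              reg$ncc))
      }
      he <- reg$resampled
      reg_diag <- list(translation = reg$transform$translation,
                       angles_deg = reg$transform$angles_deg, ncc = reg$ncc)
    }
    if (config$median_radius > 0) {
      le <- median_filter(le, config$median_radius)
      he <- median_filter(he, config$median_radius)
    }
    fmap <- decompose_volume(le, he, calset, mode = config$mode)
    tag <- sprintf("t%04d", round(tp$time_min))
    prefix <- file.path(config$out_dir, paste0("fractions_", tag))
    write_fraction_map(fmap, prefix)
    prefixes <- c(prefixes, prefix)

    vol <- sample_volume(le, threshold, container_mask = container)
    sample_mask <- le$data >= threshold
    if (!is.null(container)) sample_mask[container] <- FALSE
    vol_rows[[tag]] <- data.frame(time_min = tp$time_min, volume_um3 = vol)
    att_rows[[tag]] <- data.frame(time_min = tp$time_min,
                                  mean_attenuation_le = mean_attenuation(le, sample_mask),
                                  ncc = if (is.null(reg_diag)) NA_real_ else reg_diag$ncc)
    hist <- correlation_histogram2d(le, he, mask = sample_mask)
    utils::write.csv(tidy_histogram(hist),
                     file.path(config$out_dir, paste0("histogram_", tag, ".csv")),
                     row.names = FALSE)
    if (!is.null(tissue)) {
      upt_rows[[tag]] <- uptake_summary(fmap, tissue, tp$time_min)
    }
  }

  volumes <- relative_volume_series(do.call(rbind, vol_rows))
  attenuation <- tibble::as_tibble(do.call(rbind, att_rows))
  uptake <- if (length(upt_rows)) do.call(rbind, upt_rows) else NULL
  utils::write.csv(volumes, file.path(config$out_dir, "volume_series.csv"),
                   row.names = FALSE)
  utils::write.csv(attenuation,
                   file.path(config$out_dir, "mean_attenuation.csv"),
                   row.names = FALSE)
  if (!is.null(uptake)) {
    utils::write.csv(uptake, file.path(config$out_dir, "uptake.csv"),
                     row.names = FALSE)
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file, precision = 15L)
  numeric_outputs <- sort(list.files(config$out_dir, full.names = TRUE,
                                     pattern = "\\.(csv|nrrd)$"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dectmix")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(tools::md5sum(numeric_outputs))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unlink(cfg_file)
  invisible(list(volumes = volumes, attenuation = attenuation,
                 uptake = uptake, fraction_maps = prefixes,
                 manifest_path = manifest_path))
}
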