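# ggplot2 views of the quantification results.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   labs scale_fill_viridis_c theme_minimal .data
NULL

#' Plot a relative-volume time series
#'
#' @param object A `volume_time_series` from [relative_volume_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot volume_time_series
#' @export
autoplot.volume_time_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_min, y = .data$relative_volume)) +
    geom_line(colour = "grey40") +
    geom_point() +
    labs(x = "staining time (min)", y = "relative volume (V / V0)") +
    theme_minimal()
}

#' Plot a 2D correlation histogram
#'
#' Log-scaled joint counts of the low- vs high-energy attenuation pairs;
#' material phases appear as clusters.
#'
#' @param object A `correlation_histogram2d`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_histogram2d
#' @export
autoplot.correlation_histogram2d <- function(object, ...) {
  df <- tidy_histogram(object)
  df <- df[df$count > 0, ]
  ggplot(df, aes(x = .data$mu_le, y = .data$mu_he,
                 fill = log10(.data$count))) +
    geom_raster() +
    scale_fill_viridis_c(name = "log10 voxels") +
    labs(x = "low-energy attenuation (mm^-1)",
         y = "high-energy attenuation (mm^-1)") +
    theme_minimal()
}

#' Plot one slice of a fraction map
#'
#' @param fmap A `fraction_map`.
#' @param z Slice index.
#' @param field Which field to show (`"f_stain"`, `"f_pmma"`, `"f_air"`,
#'   `"residual"`).
#' @return A ggplot.
#' @export
plot_fraction_slice <- function(fmap, z, field = "f_stain") {
  stopifnot(inherits(fmap, "fraction_map"),
            field %in% c("f_stain", "f_pmma", "f_air", "residual"))
  sl <- fmap[[field]][, , z]
  df <- data.frame(
    x = rep(seq_len(nrow(sl)), ncol(sl)),
    y = rep(seq_len(ncol(sl)), each = nrow(sl)),
    value = as.vector(sl)
  )
  ggplot(df[!is.nan(df$value), ],
         aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = field) +
    labs(x = "x (voxels)", y = "y (voxels)",
         title = sprintf("%s, slice z = %d", field, z)) +
    theme_minimal()
}
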