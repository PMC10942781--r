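# ggplot2 views of the main result types.

#' Plot a sheet excitation-density map
#'
#' Raster of the excitation density over propagation (s) and thickness (t),
#' on a square-root scale to make side lobes visible.
#'
#' @param sheet a `sheet_profile`.
#' @return a ggplot.
#' @export
plot_sheet <- function(sheet) {
  stopifnot(inherits(sheet, "sheet_profile"))
  df <- data.frame(
    s_um = rep(sheet$s_um, each = length(sheet$t_um)),
    t_um = rep(sheet$t_um, times = length(sheet$s_um)),
    E = as.vector(sheet$E))
  ggplot2::ggplot(df, ggplot2::aes(x = s_um, y = t_um, fill = sqrt(E))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(sqrt(E))) +
    ggplot2::labs(x = "propagation s (µm)", y = "thickness t (µm)",
                  title = sprintf("%s excitation sheet", gsub("_", "-", sheet$mode))) +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot an en-face plane of a volume
#'
#' @param volume a `volume`.
#' @param depth_um depth of the plane (um).
#' @return a ggplot.
#' @export
plot_enface <- function(volume, depth_um) {
  img <- extract_enface(volume, depth_um)
  px <- volume$voxel_pitch_um
  df <- data.frame(
    x_um = volume$origin_um[1] + px[1] * (rep(seq_len(nrow(img)), times = ncol(img)) - 1),
    y_um = volume$origin_um[2] + px[2] * (rep(seq_len(ncol(img)), each = nrow(img)) - 1),
    intensity = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(x = x_um, y = y_um, fill = intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "X (µm)", y = "Y (µm)",
                  title = sprintf("en-face plane at %.1f µm depth", depth_um)) +
    ggplot2::theme_minimal()
}

#' Plot per-bead resolution measurements
#'
#' @param report a `resolution_report` from [measure_fwhm_3d()].
#' @return a ggplot of per-axis FWHM distributions.
#' @export
plot_resolution <- function(report) {
  stopifnot(inherits(report, "resolution_report"))
  df <- data.frame(
    axis = rep(c("x", "y", "z"), each = nrow(report)),
    fwhm_um = c(report$fwhm_x_um, report$fwhm_y_um, report$fwhm_z_um))
  ggplot2::ggplot(df, ggplot2::aes(x = axis, y = fwhm_um)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "FWHM (µm)", title = "bead-measured resolution") +
    ggplot2::theme_minimal()
}

#' Plot the per-bin contrast-to-noise profile of a depth estimate
#'
#' @param depth result of [estimate_imaging_depth()].
#' @param cnr_threshold threshold line to draw (default 1).
#' @return a ggplot.
#' @export
plot_depth_profile <- function(depth, cnr_threshold = 1) {
  bins <- attr(depth, "bins")
  stopifnot(!is.null(bins))
  df <- data.frame(depth_um = (bins$bin_lo_um + bins$bin_hi_um) / 2, cnr = bins$cnr)
  ggplot2::ggplot(df, ggplot2::aes(x = depth_um, y = cnr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cnr_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = as.numeric(depth), colour = "red", linetype = 3) +
    ggplot2::labs(x = "depth (µm)", y = "nuclear CNR",
                  title = sprintf("imaging depth %.0f µm", as.numeric(depth))) +
    ggplot2::theme_minimal()
}
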