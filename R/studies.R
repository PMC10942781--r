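# End-to-end characterization studies. These fix the study conditions the
# toolkit is characterized under: a bead phantom for resolution, a layered
# skin phantom for imaging depth, and the default optics for the sheet.
# Problem sizes are desk-scale (tens of um per side) so each study runs in
# seconds to a couple of minutes on one CPU; the methods vignette discusses
# what that does and does not demonstrate.

#' Characterize the default excitation sheet
#'
#' Builds the Bessel-Gauss beam for the given optics, forms the scanned one-
#' and two-photon sheets, and reports their metrics (design thickness, DOF,
#' side-lobe fraction).
#'
#' @param cfg an [optical_config()] (default: the calibrated defaults).
#' @param scan_range_um galvo scan range used for the sheet (default 40).
#' @return a two-row tibble (one per mode) of [sheet_metrics()].
#' @export
characterize_sheet <- function(cfg = optical_config(), scan_range_um = 40) {
  field <- bessel_gauss_field(cfg)
  rbind(sheet_metrics(make_sheet(field, scan_range_um, "one_photon")),
        sheet_metrics(make_sheet(field, scan_range_um, "two_photon")))
}

#' End-to-end bead resolution study
#'
#' Renders a sub-resolution bead phantom, acquires it obliquely with the
#' system's 0.9 um detection PSF and noise, deskews, and measures per-bead
#' FWHM in all three axes at the known bead positions. With 0.5 um beads and
#' a 0.9 um system PSF the expected reading is just under 1 um per axis
#' (PSF convolved with the bead profile).
#'
#' @param seed RNG seed for the phantom and the camera noise.
#' @param n_beads number of beads (default 8).
#' @param noise logical; camera noise on (default TRUE).
#' @return a `resolution_report`.
#' @export
bead_resolution_study <- function(seed = 1, n_beads = 8, noise = TRUE) {
  spec <- phantom_spec("beads", dims_um = c(12, 12, 6), n_beads = n_beads,
                       bead_intensity = 4000)
  ph <- generate_beads(spec, seed = seed)
  p <- 0.15
  # sweep in and out of the bead gel so every bead is fully covered
  geom <- acquisition_geometry(tilt_deg = 45, step_um = p, fps = 400,
                               frame_shape = c(u = 80, v = 56),
                               pixel_pitch_um = p, x0_um = -6)
  atten <- attenuation_config(l_ex_um = 1e9,
                              channels = tibble::tibble(name = c("shg", "fluor"),
                                                        emission_nm = c(385, 515),
                                                        l_em_um = c(1e9 - 1, 1e9),
                                                        gain = c(1, 1)),
                              mode = "two_photon", background = 2,
                              read_noise_sd = 3, photon_scale = 1)
  n_frames <- floor((12 - geom$x0_um) / p) + 1L
  strips <- acquire_strip(ph, geom, atten, n_frames = n_frames,
                          channels = "fluor", noise = noise, seed = seed + 1,
                          n_taps = 9, oob = "zero")
  vol <- deskew(strips$fluor, geom, interp = "linear")
  measure_fwhm_3d(vol, ph$centers, window_um = 2.5)
}

#' Imaging-depth study on the skin phantom
#'
#' Renders the layered skin phantom with nuclei at all depths, acquires it
#' with the requested excitation mode and the calibrated skin attenuation,
#' deskews, and estimates the imaging depth as the contrast-to-noise
#' crossing (threshold 1, 5 um bins). The two-photon configuration reaches
#' roughly three times deeper than the one-photon comparison.
#'
#' @param seed RNG seed.
#' @param mode `"two_photon"` or `"one_photon"`.
#' @param cnr_threshold CNR threshold (default 1).
#' @param photon_scale override of the calibrated surface photon scale
#'   (default: the [skin_attenuation()] default).
#' @return the estimated vertical imaging depth (um) with the per-bin CNR
#'   table as attribute `bins`.
#' @export
imaging_depth_study <- function(seed = 1, mode = c("two_photon", "one_photon"),
                                cnr_threshold = 1, photon_scale = NULL) {
  mode <- match.arg(mode)
  spec <- phantom_spec("skin", dims_um = c(40, 24, 92), epidermis_um = 10,
                       dermis_sep_um = 7)
  ph <- generate_tissue(spec, seed = seed)
  p <- 0.5
  geom <- acquisition_geometry(tilt_deg = 45, step_um = 1, fps = 400,
                               frame_shape = c(u = 48, v = 256),
                               pixel_pitch_um = p)
  atten <- if (is.null(photon_scale)) skin_attenuation(mode) else
    skin_attenuation(mode, photon_scale = photon_scale)
  ext <- dim(ph$fluor) * ph$voxel_pitch_um
  xreach <- (geom$frame_shape[["v"]] - 1) * p * cos(pi / 4)
  # the oblique sweep is deeper than the block is long: enter and exit the
  # block so every (X, Z) voxel is sampled
  geom$x0_um <- -ceiling(xreach)
  n_frames <- floor((ext[1] - geom$x0_um) / geom$step_um) + 1L
  strips <- acquire_strip(ph, geom, atten, n_frames = n_frames,
                          channels = "fluor", noise = TRUE, seed = seed + 1,
                          n_taps = 3, oob = "zero")
  vol <- deskew(strips$fluor, geom, interp = "linear")
  nuc <- ph$centers[ph$centers$channel == "fluor", ]
  estimate_imaging_depth(vol, nuc, cnr_threshold = cnr_threshold, bin_um = 5)
}
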