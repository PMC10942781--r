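# Disk formats: multipage TIFF for image stacks (16-bit raw frames, 32-bit
# float volumes/sheets) with JSON sidecars for geometry and provenance, and
# YAML for configuration. Masked voxels are stored as NaN in float TIFFs.

#' Write raw strips to a run directory
#'
#' One multipage 16-bit TIFF per channel (`strip_<channel>.tiff`, pages =
#' frames) plus a JSON sidecar (`sidecar.json`) with the geometry, stage
#' positions, seed and saturation counts.
#'
#' @param strips named list of `raw_strip` objects (one per channel), as
#'   returned by [acquire_strip()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_strips <- function(strips, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(strips)) {
    s <- strips[[ch]]
    pages <- lapply(seq_len(dim(s$frames)[3]), function(i)
      pmin(pmax(s$frames[, , i], 0), 65535) / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0("strip_", ch, ".tiff")),
                    bits.per.sample = 16L)
  }
  s1 <- strips[[1]]
  side <- list(geometry = unclass(s1$geometry),
               stage_x_um = s1$stage_x_um,
               channels = names(strips),
               noise = s1$noise,
               seed = s1$seed,
               saturated_pixels = lapply(strips, function(s) s$saturated_pixels))
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read raw strips from a run directory
#'
#' @param dir a directory written by [write_strips()].
#' @return a named list of `raw_strip` objects.
#' @export
read_strips <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  g <- side$geometry
  geom <- acquisition_geometry(tilt_deg = g$tilt_deg, step_um = g$step_um,
                               fps = g$fps, frame_shape = unlist(g$frame_shape),
                               pixel_pitch_um = g$pixel_pitch_um,
                               bytes_per_pixel = g$bytes_per_pixel,
                               strip_width_um = g$strip_width_um,
                               oblique_extent_um = g$oblique_extent_um,
                               x0_um = g$x0_um)
  out <- lapply(side$channels, function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0("strip_", ch, ".tiff")), all = TRUE)
    frames <- array(0, c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * 65535
    structure(list(frames = round(frames), stage_x_um = side$stage_x_um,
                   geometry = geom, channel = ch, noise = isTRUE(side$noise),
                   seed = side$seed,
                   saturated_pixels = side$saturated_pixels[[ch]]),
              class = "raw_strip")
  })
  names(out) <- side$channels
  out
}

#' Write a volume as a 32-bit float multipage TIFF with sidecar
#'
#' Pages are Z planes. TIFF float samples are defined on [0, 1], so finite
#' intensities are affinely mapped onto [0.25, 1] and masked voxels stored as
#' exactly 0; the affine scale, pixel pitch and origin go to `<path>.json`
#' and the mapping is inverted on read.
#'
#' @param volume a `volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  d <- dim(volume$intensity)
  fin <- volume$intensity[!is.na(volume$intensity)]
  lo <- if (length(fin)) min(fin) else 0
  hi <- if (length(fin)) max(fin) else 1
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- volume$intensity[, , k]
    enc <- 0.25 + 0.75 * (m - lo) / span
    enc[is.na(m)] <- 0
    enc
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_pitch_um = volume$voxel_pitch_um,
                            origin_um = volume$origin_um,
                            channel = volume$channel,
                            scale = list(lo = lo, span = span)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return a `volume`.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  masked <- arr < 0.125  # sentinel 0, data begin at 0.25
  arr <- side$scale$lo + (arr - 0.25) / 0.75 * side$scale$span
  arr[masked] <- NA_real_
  new_volume(arr, side$voxel_pitch_um, side$origin_um,
             if (is.null(side$channel)) NA_character_ else side$channel)
}

#' Write a patch set to a directory with a CSV manifest
#'
#' Patches are written as individual 16-bit TIFFs named `patch_<id>.tiff`
#' after rescaling to the set's global maximum; the manifest records crop
#' origins and augmentation tags.
#'
#' @param ps a `patch_set`.
#' @param dir output directory.
#' @return the manifest tibble, invisibly.
#' @export
write_patches <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(1e-12, max(vapply(ps$patches, max, numeric(1))))
  for (i in seq_along(ps$patches))
    tiff::writeTIFF(pmax(ps$patches[[i]], 0) / mx,
                    file.path(dir, sprintf("patch_%05d.tiff", i)),
                    bits.per.sample = 16L)
  write.csv(ps$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(ps$manifest)
}

#' Read an optical configuration from YAML
#'
#' The YAML keys mirror the [optical_config()] argument names exactly.
#'
#' @param path YAML file.
#' @return an `optical_config`.
#' @export
read_optical_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(optical_config, y)
}

#' Write an optical configuration to YAML
#'
#' @param cfg an `optical_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_optical_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$paraxial_valid <- NULL
  y$emission_wavelength_nm <- as.list(y$emission_wavelength_nm)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write an RGB image as an 8-bit TIFF
#'
#' @param rgb array (rows x cols x 3) in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_tiff <- function(rgb, path) {
  tiff::writeTIFF(pmin(pmax(rgb, 0), 1), path, bits.per.sample = 8L)
  invisible(path)
}
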