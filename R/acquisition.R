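#' Acquisition geometry of the oblique strip scan
#'
#' Frame `i` of a strip samples the specimen on the tilted plane
#' `{X = x_i + v p cos(theta), Y = u p, Z = v p sin(theta)}` where `p` is the
#' sample-space pixel pitch, `u` runs along the galvo-scanned sheet width and
#' `v` along the oblique sheet propagation direction; the stage advances the
#' specimen by `step_um` between frames. Defaults reproduce the instrument's
#' 600 um x 170 um field of view at 1850 x 512 pixels, 1 um steps, 400
#' frames/s and 2 bytes per pixel.
#'
#' @param tilt_deg sheet tilt from the horizontal surface (default 45).
#' @param step_um stage step between frames (default 1).
#' @param fps frame rate in frames per second (default 400).
#' @param frame_shape integer c(u, v) pixels (default 1850 x 512).
#' @param pixel_pitch_um sample-space pixel pitch (default 600/1850).
#' @param bytes_per_pixel camera bytes per pixel (default 2).
#' @param strip_width_um strip width covered by the u axis (default 600).
#' @param oblique_extent_um extent covered by the v axis along the tilted
#'   plane (default 170).
#' @param x0_um stage position of the first frame (default 0).
#' @return an `acquisition_geometry`.
#' @export
acquisition_geometry <- function(tilt_deg = 45, step_um = 1, fps = 400,
                                 frame_shape = c(u = 1850, v = 512),
                                 pixel_pitch_um = 600 / 1850,
                                 bytes_per_pixel = 2,
                                 strip_width_um = NULL,
                                 oblique_extent_um = NULL,
                                 x0_um = 0) {
  if (tilt_deg <= 0 || tilt_deg > 90) stop_domain("tilt must satisfy 0 < tilt <= 90 degrees")
  if (step_um <= 0 || fps <= 0 || pixel_pitch_um <= 0)
    stop_domain("step, frame rate and pixel pitch must be positive")
  frame_shape <- as.integer(frame_shape)
  if (is.null(strip_width_um)) strip_width_um <- frame_shape[1] * pixel_pitch_um
  if (is.null(oblique_extent_um)) oblique_extent_um <- frame_shape[2] * pixel_pitch_um
  if (abs(strip_width_um - frame_shape[1] * pixel_pitch_um) > 0.01 * strip_width_um)
    stop_domain("strip width must equal frame_shape u x pixel pitch within 1%")
  structure(list(tilt_deg = tilt_deg, step_um = step_um, fps = fps,
                 frame_shape = setNames(frame_shape, c("u", "v")),
                 pixel_pitch_um = pixel_pitch_um,
                 bytes_per_pixel = bytes_per_pixel,
                 strip_width_um = strip_width_um,
                 oblique_extent_um = oblique_extent_um,
                 x0_um = x0_um),
            class = "acquisition_geometry")
}

#' Attenuation and camera-noise model
#'
#' Single-scattering Beer-Lambert attenuation on ballistic paths measured
#' vertically from the tissue surface. Two-photon excitation loses ballistic
#' photons twice per excitation event, so the excitation factor is
#' `exp(-2 d / l_ex)`; one-photon excitation decays as `exp(-d / l_ex)`.
#' Emitted photons decay as `exp(-d / l_em)` with an emission scattering
#' length that grows with wavelength - the reason red-emitting nuclear dyes
#' image deeper than green-emitting ones. The scattering lengths are
#' calibrations, not measured tissue constants (see the methods vignette).
#'
#' @param l_ex_um excitation scattering length (um).
#' @param channels tibble with columns `name`, `emission_nm`, `l_em_um`,
#'   `gain`; `l_em_um` must increase with `emission_nm`.
#' @param mode `"two_photon"` or `"one_photon"`.
#' @param background mean background level (photons) added to every pixel.
#' @param read_noise_sd camera read noise standard deviation (counts).
#' @param baseline camera digital offset (counts) added to every pixel after
#'   noise, keeping the read-noise distribution clear of the zero clip
#'   (default 100, a typical sCMOS offset).
#' @param photon_scale conversion from phantom density x excitation weight to
#'   expected photon counts.
#' @return an `attenuation_config`.
#' @export
attenuation_config <- function(l_ex_um = 100,
                               channels = tibble::tibble(
                                 name = c("shg", "fluor"),
                                 emission_nm = c(385, 515),
                                 l_em_um = c(30, 50),
                                 gain = c(1, 1)),
                               mode = c("two_photon", "one_photon"),
                               background = 0,
                               read_noise_sd = 10,
                               baseline = 100,
                               photon_scale = 1) {
  mode <- match.arg(mode)
  if (l_ex_um <= 0 || any(channels$l_em_um <= 0))
    stop_domain("scattering lengths must be positive")
  o <- order(channels$emission_nm)
  if (is.unsorted(channels$l_em_um[o]))
    stop_domain("emission scattering length must increase with wavelength")
  structure(list(l_ex_um = l_ex_um, channels = channels, mode = mode,
                 background = background, read_noise_sd = read_noise_sd,
                 baseline = baseline, photon_scale = photon_scale),
            class = "attenuation_config")
}

#' Skin attenuation presets
#'
#' Calibrated defaults for the fresh-skin imaging-depth comparison: the
#' two-photon configuration (770 nm excitation, proflavine emission 515 nm)
#' and the one-photon light-sheet comparison (blue excitation, same
#' fluorophore). Scattering lengths are calibrated so the contrast-to-noise
#' crossing depths land near 64 um (two photon) and 20 um (one photon).
#'
#' @param mode `"two_photon"` or `"one_photon"`.
#' @param photon_scale expected surface photon count per unit density.
#' @return an `attenuation_config`.
#' @export
skin_attenuation <- function(mode = c("two_photon", "one_photon"),
                             photon_scale = 125) {
  mode <- match.arg(mode)
  attenuation_config(
    l_ex_um = if (mode == "two_photon") 100 else 8,
    channels = tibble::tibble(name = c("shg", "fluor"),
                              emission_nm = c(385, 515),
                              l_em_um = c(30, 50),
                              gain = c(1, 1)),
    mode = mode, background = 0, read_noise_sd = 10,
    photon_scale = photon_scale)
}

#' Depth-dependent attenuation factor
#'
#' @param depth_um depth below the surface (um, vector allowed).
#' @param cfg an [attenuation_config()].
#' @param channel channel name or index into `cfg$channels`.
#' @return the dimensionless signal attenuation, 1 at the surface and
#'   strictly decreasing with depth.
#' @examples
#' cfg <- attenuation_config(l_ex_um = 1e12)  # emission-only decay
#' attenuated_signal(50, cfg, "fluor")        # ~ exp(-1)
#' @export
attenuated_signal <- function(depth_um, cfg, channel = "fluor") {
  stopifnot(inherits(cfg, "attenuation_config"))
  if (any(depth_um < 0)) stop_domain("depth must be non-negative")
  ch <- if (is.character(channel)) match(channel, cfg$channels$name) else channel
  if (is.na(ch)) stop_domain("unknown channel: ", channel)
  m <- if (cfg$mode == "two_photon") 2 else 1
  exp(-m * depth_um / cfg$l_ex_um - depth_um / cfg$channels$l_em_um[ch])
}

#' Simulate one oblique strip acquisition
#'
#' The forward imaging model: each frame samples the phantom by trilinear
#' interpolation on its tilted plane, weighted across the sheet thickness by
#' Gaussian-weighted taps along the plane normal, scaled by the excitation
#' sheet's axial profile (when given), the Beer-Lambert attenuation and the
#' channel gain, blurred in-frame by the detection point spread function, and
#' finally subjected to Poisson photon noise plus Gaussian read noise and
#' 16-bit quantization (noise off gives deterministic, unquantized frames).
#'
#' A point emitter at world (X0, Y0, Z0) is brightest in frame
#' `i* = round((X0 - Z0 cot(theta) - x0) / step)`.
#'
#' The detection PSF is an isotropic Gaussian whose FWHM defaults to the
#' system's measured 0.9 um resolution: it is applied in-frame on the (u, v)
#' axes and out-of-plane through the thickness taps (`n_taps` Gaussian
#' weights at offsets of one tap-sigma). When a `sheet` is supplied, the
#' out-of-plane sigma is the larger of the PSF sigma and the sheet thickness
#' sigma, and the sheet's on-axis profile modulates excitation along v.
#'
#' @param phantom a `phantom`.
#' @param geom an [acquisition_geometry()].
#' @param atten an [attenuation_config()].
#' @param n_frames number of frames; default sweeps the phantom interior.
#' @param channels character vector of channels to render; names must match
#'   `atten$channels$name`, with `"fluor"` reading the fluorophore field and
#'   `"shg"` the SHG field.
#' @param sheet optional `sheet_profile` modulating excitation along v.
#' @param psf_fwhm_um detection PSF FWHM (default 0.9).
#' @param n_taps number of thickness taps (odd; default 5).
#' @param noise logical; apply Poisson + read noise and 16-bit quantization.
#' @param seed RNG seed for the noise (required when `noise = TRUE`).
#' @param oob `"error"` (default) to reject planes that leave the phantom,
#'   `"zero"` to treat outside samples as empty.
#' @return a named list of `raw_strip` objects, one per channel, each with
#'   frames array (u x v x n), per-frame stage positions, geometry and noise
#'   metadata including the count of saturated pixels.
#' @export
acquire_strip <- function(phantom, geom, atten, n_frames = NULL,
                          channels = c("fluor", "shg"), sheet = NULL,
                          psf_fwhm_um = 0.9, n_taps = 5L, noise = TRUE,
                          seed = NULL, oob = c("error", "zero")) {
  stopifnot(inherits(phantom, "phantom"), inherits(geom, "acquisition_geometry"),
            inherits(atten, "attenuation_config"))
  oob <- match.arg(oob)
  if (noise && is.null(seed)) stop_domain("noise = TRUE requires a seed")
  th <- geom$tilt_deg * pi / 180
  p <- geom$pixel_pitch_um
  nu <- geom$frame_shape[["u"]]; nv <- geom$frame_shape[["v"]]
  pitch <- phantom$voxel_pitch_um
  ext <- dim(phantom$fluor) * pitch
  zmax <- (nv - 1) * p * sin(th)
  if (zmax > ext[3] + 1e-9)
    stop_domain(sprintf("oblique extent reaches depth %.1f um but phantom is %.1f um deep; enlarge the phantom or reduce frame_shape v", zmax, ext[3]))
  if ((nu - 1) * p > ext[2] + 1e-9)
    stop_domain(sprintf("frame width %.1f um exceeds phantom y extent %.1f um", (nu - 1) * p, ext[2]))
  xreach <- (nv - 1) * p * cos(th)
  if (is.null(n_frames))
    n_frames <- max(1L, floor((ext[1] - xreach - geom$x0_um) / geom$step_um) + 1L)
  stage_x <- geom$x0_um + (seq_len(n_frames) - 1) * geom$step_um
  if (oob == "error") {
    if (stage_x[1] < -1e-9 || stage_x[n_frames] + xreach > ext[1] + 1e-9)
      stop_domain(sprintf("frames sample X in [%.1f, %.1f] um but phantom spans [0, %.1f] um; adjust x0/n_frames or use oob = \"zero\"",
                          stage_x[1], stage_x[n_frames] + xreach, ext[1]))
  }
  # thickness taps along the plane normal (sin th, 0, -cos th)
  psf_sig <- psf_fwhm_um / (2 * sqrt(2 * log(2)))
  tap_sig <- psf_sig
  if (!is.null(sheet)) {
    sm <- sheet_metrics(sheet)
    tap_sig <- max(psf_sig, sm$profile_fwhm_um / (2 * sqrt(2 * log(2))), na.rm = TRUE)
  }
  n_taps <- as.integer(n_taps)
  stopifnot(n_taps >= 1L, n_taps %% 2L == 1L)
  # taps span +/- 2 sigma of the out-of-plane Gaussian
  toff <- if (n_taps == 1L) 0 else seq(-2, 2, length.out = n_taps) * tap_sig
  tw <- exp(-toff^2 / (2 * max(tap_sig, 1e-12)^2)); tw <- tw / sum(tw)
  # excitation profile along v (sheet propagation axis), centred on the frame
  w_v <- rep(1, nv)
  if (!is.null(sheet)) {
    it0 <- which.min(abs(sheet$t_um))
    s_frame <- ((seq_len(nv) - 1) - (nv - 1) / 2) * p
    w_v <- approx(sheet$s_um, sheet$E[it0, ], xout = s_frame, rule = 2)$y
  }
  u_idx <- seq_len(nu) - 1
  v_idx <- seq_len(nv) - 1
  yy <- rep(u_idx * p, times = nv)
  vv <- rep(v_idx, each = nu)
  xoff <- vv * p * cos(th)
  zz <- vv * p * sin(th)
  sigpx <- psf_sig / p
  kpsf <- gaussian_kernel(sigpx)
  ch_idx <- match(channels, atten$channels$name)
  if (anyNA(ch_idx)) stop_domain("channels must name entries of atten$channels")
  out <- lapply(channels, function(chn) {
    field <- if (chn == "shg") phantom$shg else phantom$fluor
    gain <- atten$channels$gain[match(chn, atten$channels$name)]
    frames <- array(0, c(nu, nv, n_frames))
    for (i in seq_len(n_frames)) {
      acc <- numeric(nu * nv)
      for (k in seq_len(n_taps)) {
        xs <- stage_x[i] + xoff + toff[k] * sin(th)
        zs <- zz - toff[k] * cos(th)
        att <- attenuated_signal(pmax(zs - phantom$surface_z_um, 0), atten, chn)
        att[zs < phantom$surface_z_um] <- 1
        samp <- trilinear_sample(field, xs / pitch[1], yy / pitch[2], zs / pitch[3])
        acc <- acc + tw[k] * samp * att
      }
      fr <- matrix(acc, nu, nv) * rep(w_v, each = nu)
      fr <- convolve_dim(convolve_dim(fr, kpsf, 1L), kpsf, 2L)
      frames[, , i] <- gain * atten$photon_scale * fr
    }
    frames
  })
  names(out) <- channels
  saturated <- setNames(integer(length(channels)), channels)
  if (noise) {
    out <- with_seed(seed, lapply(out, function(frames) {
      n <- length(frames)
      counts <- rpois(n, lambda = pmax(frames, 0) + atten$background) +
        rnorm(n, 0, atten$read_noise_sd)
      counts <- round(counts) + atten$baseline
      array(pmin(pmax(counts, 0), 65535), dim(frames))
    }))
    for (j in seq_along(out)) saturated[j] <- sum(out[[j]] >= 65535)
  }
  lapply(setNames(seq_along(channels), channels), function(j) {
    structure(list(frames = out[[j]], stage_x_um = stage_x, geometry = geom,
                   channel = channels[j], noise = noise, seed = seed,
                   saturated_pixels = saturated[[j]]),
              class = "raw_strip")
  })
}

#' @export
print.raw_strip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<raw_strip> channel '%s' | %d frames of %d x %d px | step %g um | noise %s\n",
              x$channel, d[3], d[1], d[2], x$geometry$step_um,
              if (x$noise) "on" else "off"))
  invisible(x)
}
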