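#' Optical configuration for the Bessel-beam excitation arm
#'
#' Bundles the parameters of the illumination and detection optics in sample
#' space. The excitation beam is modelled as a Bessel-Gauss beam produced by a
#' thin annular pupil: the annulus is centred at `illumination_na` and its
#' radial profile is Gaussian with a full width at half maximum of
#' `illumination_na_fractional_width * illumination_na` (in NA units). The
#' fractional width is the one free parameter of the beam model; its default
#' is calibrated so that the scanned two-photon sheet reaches a depth of field
#' of about 180 um at NA 0.34 and 770 nm (see `scripts/calibrate.R`).
#'
#' @param excitation_wavelength_nm excitation wavelength in nm (default 770).
#' @param illumination_na effective illumination numerical aperture
#'   (default 0.34).
#' @param illumination_na_fractional_width annulus FWHM as a fraction of the
#'   illumination NA (calibrated default 0.0235).
#' @param detection_na detection numerical aperture (default 0.42).
#' @param medium_ri refractive index of the immersion medium (default 1.45,
#'   matched to the quartz sample-holder window).
#' @param emission_wavelength_nm named vector of per-channel emission
#'   wavelengths in nm; defaults cover proflavine (515), propidium iodide
#'   (640) and second harmonic generation at half of 770 nm (385).
#' @param back_aperture_ring_diameter_mm ring diameter at the objective back
#'   aperture in mm (default 6.8).
#' @param objective_focal_length_mm objective focal length in mm (default 10,
#'   a 20x objective at 200 mm reference tube length).
#' @param grid sampling specification: list with `r_max_um`, `r_pitch_um`
#'   (transverse axis) and `s_max_um`, `s_pitch_um` (propagation axis).
#' @return an object of class `optical_config`.
#' @export
optical_config <- function(excitation_wavelength_nm = 770,
                           illumination_na = 0.34,
                           illumination_na_fractional_width = 0.0235,
                           detection_na = 0.42,
                           medium_ri = 1.45,
                           emission_wavelength_nm = c(proflavine = 515, pi = 640, shg = 385),
                           back_aperture_ring_diameter_mm = 6.8,
                           objective_focal_length_mm = 10,
                           grid = list(r_max_um = 60, r_pitch_um = 0.05,
                                       s_max_um = 240, s_pitch_um = 2)) {
  if (excitation_wavelength_nm <= 0 || any(emission_wavelength_nm <= 0))
    stop_domain("wavelengths must be positive")
  for (na in c(illumination_na, detection_na))
    if (na <= 0 || na >= medium_ri)
      stop_domain("numerical apertures must satisfy 0 < NA < medium refractive index")
  if (illumination_na_fractional_width <= 0)
    stop_domain("annulus fractional width must be positive")
  lam_um <- excitation_wavelength_nm / 1000
  nyquist <- lam_um / (4 * illumination_na)
  if (grid$r_pitch_um > nyquist)
    stop_domain(sprintf("grid too coarse: transverse pitch %.3f um exceeds the Nyquist pitch %.3f um",
                        grid$r_pitch_um, nyquist))
  paraxial <- back_aperture_ring_diameter_mm <= 2 * objective_focal_length_mm
  if (!paraxial)
    warning("ring diameter exceeds 2x the focal length; paraxial NA arithmetic degrades")
  structure(list(
    excitation_wavelength_nm = excitation_wavelength_nm,
    illumination_na = illumination_na,
    illumination_na_fractional_width = illumination_na_fractional_width,
    detection_na = detection_na,
    medium_ri = medium_ri,
    emission_wavelength_nm = emission_wavelength_nm,
    back_aperture_ring_diameter_mm = back_aperture_ring_diameter_mm,
    objective_focal_length_mm = objective_focal_length_mm,
    grid = grid,
    paraxial_valid = paraxial
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> lambda_ex %g nm | NA_ill %.3g (annulus width %.3g%%) | NA_det %.3g | n %.3g\n",
              x$excitation_wavelength_nm, x$illumination_na,
              100 * x$illumination_na_fractional_width, x$detection_na, x$medium_ri))
  invisible(x)
}

#' Paraxial effective numerical aperture of an annular beam
#'
#' The effective NA of a thin ring of diameter `ring_diameter_mm` entering an
#' objective of focal length `objective_focal_length_mm` is, paraxially, the
#' ring radius divided by the focal length. A warning is issued above NA 0.5
#' where the small-angle approximation degrades.
#'
#' @param ring_diameter_mm beam ring diameter at the back aperture (mm).
#' @param objective_focal_length_mm objective focal length (mm).
#' @return the dimensionless effective NA.
#' @examples
#' effective_na(6.8, 10)  # 0.34
#' @export
effective_na <- function(ring_diameter_mm, objective_focal_length_mm) {
  if (ring_diameter_mm < 0 || objective_focal_length_mm <= 0)
    stop_domain("ring diameter must be >= 0 and focal length > 0")
  na <- (ring_diameter_mm / 2) / objective_focal_length_mm
  if (na > 0.5)
    warning(sprintf("effective NA %.3g exceeds 0.5; paraxial approximation degrades", na))
  na
}

#' Focal-region Bessel-Gauss beam of the annular-pupil illumination
#'
#' Computes the scalar excitation field in the focal region by a Debye-type
#' quadrature over the annular pupil: each pupil zone of numerical aperture
#' `nu` contributes a conical wave `J0(2 pi nu r / lambda)` with defocus phase
#' `exp(-i pi s nu^2 / (n lambda))`, weighted by the Gaussian ring profile.
#' At the focal plane the radial intensity is proportional to
#' `J0(2 pi NA r / lambda)^2` under a Gaussian envelope; the annulus width
#' sets the axial extent of the Bessel zone.
#'
#' @param cfg an [optical_config()].
#' @param s_um propagation positions (um) at which to sample the field;
#'   default spans `cfg$grid`.
#' @return a `beam_field` with a complex amplitude matrix (rows = radial
#'   positions, columns = propagation positions), normalized to unit total
#'   power in the focal plane.
#' @export
bessel_gauss_field <- function(cfg, s_um = NULL) {
  stopifnot(inherits(cfg, "optical_config"))
  lam <- cfg$excitation_wavelength_nm / 1000
  na0 <- cfg$illumination_na
  sig <- cfg$illumination_na_fractional_width * na0 / (2 * sqrt(2 * log(2)))
  g <- cfg$grid
  r <- seq(0, g$r_max_um, by = g$r_pitch_um)
  if (is.null(s_um)) s_um <- seq(-g$s_max_um, g$s_max_um, by = g$s_pitch_um)
  na_lo <- max(na0 - 6 * sig, 1e-5)
  na_hi <- min(na0 + 6 * sig, cfg$medium_ri * 0.999)
  nag <- seq(na_lo, na_hi, length.out = 601)
  dna <- nag[2] - nag[1]
  amp <- exp(-(nag - na0)^2 / (2 * sig^2))
  jmat <- besselJ(2 * pi * outer(r, nag) / lam, 0)              # nr x n_na
  phase <- exp(-1i * pi * outer(nag^2, s_um) / (cfg$medium_ri * lam)) # n_na x ns
  u <- jmat %*% (phase * (amp * nag * dna))
  # unit total power in the plane nearest focus
  i0 <- which.min(abs(s_um))
  p0 <- sum(Mod(u[, i0])^2 * 2 * pi * r) * g$r_pitch_um
  u <- u / sqrt(p0)
  structure(list(amplitude = u, r_um = r, s_um = s_um,
                 pitch_um = g$r_pitch_um, representation = "radial",
                 wavelength_um = lam, medium_ri = cfg$medium_ri, config = cfg),
            class = "beam_field")
}

#' Resample a radial beam field onto a 2-D transverse grid
#'
#' Produces a single-plane Cartesian complex field, e.g. as input to the
#' FFT-based angular-spectrum propagator [propagate()].
#'
#' @param field a radial `beam_field`.
#' @param s_um propagation position to extract (nearest sampled plane used).
#' @param extent_um half-width of the square output grid (um).
#' @param pitch_um output pixel pitch (um); default the field's radial pitch.
#' @return a transverse `beam_field` (complex matrix over x/y).
#' @export
as_transverse <- function(field, s_um = 0, extent_um = 20, pitch_um = NULL) {
  stopifnot(inherits(field, "beam_field"), field$representation == "radial")
  if (is.null(pitch_um)) pitch_um <- field$pitch_um
  k <- which.min(abs(field$s_um - s_um))
  x <- seq(-extent_um, extent_um, by = pitch_um)
  rr <- sqrt(outer(x^2, x^2, "+"))
  re <- approx(field$r_um, Re(field$amplitude[, k]), xout = rr, rule = 2)$y
  im <- approx(field$r_um, Im(field$amplitude[, k]), xout = rr, rule = 2)$y
  u <- matrix(complex(real = re, imaginary = im), length(x), length(x))
  structure(list(amplitude = u, x_um = x, s_um = field$s_um[k],
                 pitch_um = pitch_um, representation = "transverse",
                 wavelength_um = field$wavelength_um,
                 medium_ri = field$medium_ri, config = field$config),
            class = "beam_field")
}

#' Propagate a beam field by a finite distance
#'
#' Transverse (2-D) fields are propagated with the non-paraxial angular
#' spectrum of plane waves: each spatial frequency `(fx, fy)` acquires the
#' phase `exp(i 2 pi d sqrt((n/lambda)^2 - fx^2 - fy^2))`; evanescent
#' components are suppressed. The operator is unitary on propagating waves, so
#' total power is conserved. The grid is zero-padded (factor 2) by default to
#' limit wrap-around aliasing. Radial fields produced by
#' [bessel_gauss_field()] are re-evaluated exactly at the shifted plane by the
#' same pupil quadrature.
#'
#' @param field a `beam_field`.
#' @param distance_um propagation distance (um, may be negative).
#' @param pad logical; zero-pad transverse grids before the FFT (default TRUE).
#' @return the propagated `beam_field` on the original grid.
#' @export
propagate <- function(field, distance_um, pad = TRUE) {
  stopifnot(inherits(field, "beam_field"), is.finite(distance_um))
  if (field$representation == "radial") {
    cfg <- field$config
    return(bessel_gauss_field(cfg, s_um = field$s_um + distance_um))
  }
  u <- field$amplitude
  n0 <- nrow(u)
  if (pad) {
    npad <- 2L * n0
    up <- matrix(0 + 0i, npad, npad)
    o <- n0 %/% 2L
    up[(o + 1):(o + n0), (o + 1):(o + n0)] <- u
    u <- up
  }
  n <- nrow(u)
  fx <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1)) / (n * field$pitch_um)
  f2 <- outer(fx^2, fx^2, "+")
  kz2 <- (field$medium_ri / field$wavelength_um)^2 - f2
  h <- ifelse(kz2 > 0, exp(2i * pi * distance_um * sqrt(pmax(kz2, 0))), 0 + 0i)
  u <- fft(fft(u) * h, inverse = TRUE) / length(u)
  if (pad) {
    o <- n0 %/% 2L
    u <- u[(o + 1):(o + n0), (o + 1):(o + n0)]
  }
  out <- field
  out$amplitude <- u
  out$s_um <- field$s_um + distance_um
  out
}

# Total power of a transverse field (sum |U|^2 * pixel area).
field_power <- function(field) {
  stopifnot(inherits(field, "beam_field"))
  if (field$representation == "transverse")
    sum(Mod(field$amplitude)^2) * field$pitch_um^2
  else {
    i0 <- which.min(abs(field$s_um))
    sum(Mod(field$amplitude[, i0])^2 * 2 * pi * field$r_um) * field$pitch_um
  }
}

#' Build the scanned excitation sheet from a beam field
#'
#' The sheet excitation density over the propagation axis `s` and the
#' thickness axis `t` is the scan-axis average of the beam intensity (one
#' photon) or of its square (two photon): scanning the beam along y turns the
#' radial intensity `I(r, s)` into the line average of `I(sqrt(t^2 + y^2), s)`
#' over the scan range. `scan_range_um = 0` returns the unscanned map, i.e.
#' the beam's own cross-section, for which the two-photon map is exactly the
#' elementwise square of the one-photon map.
#'
#' @param field a radial `beam_field`.
#' @param scan_range_um full scan range along y (um); 0 for unscanned.
#' @param mode `"one_photon"` or `"two_photon"`.
#' @param t_max_um half-extent of the thickness axis (um).
#' @param t_pitch_um thickness-axis pitch; default the field's radial pitch.
#' @return a `sheet_profile`: excitation density map `E` (rows = t, columns =
#'   s), normalized to unit maximum, plus the focal-plane beam profile it was
#'   built from.
#' @export
make_sheet <- function(field, scan_range_um = 40,
                       mode = c("two_photon", "one_photon"),
                       t_max_um = 8, t_pitch_um = NULL) {
  stopifnot(inherits(field, "beam_field"), field$representation == "radial",
            scan_range_um >= 0)
  mode <- match.arg(mode)
  if (is.null(t_pitch_um)) t_pitch_um <- field$pitch_um
  t <- seq(-t_max_um, t_max_um, by = t_pitch_um)
  intensity <- Mod(field$amplitude)^2
  i0 <- which.min(abs(field$s_um))
  beam_profile <- intensity[, i0]
  if (scan_range_um == 0) {
    e1 <- matrix(0, length(t), length(field$s_um))
    for (k in seq_along(field$s_um))
      e1[, k] <- approx(field$r_um, intensity[, k], xout = abs(t), rule = 2)$y
    e <- if (mode == "two_photon") e1^2 else e1
  } else {
    y <- seq(0, scan_range_um / 2, by = field$pitch_um)
    rq <- sqrt(outer(t^2, y^2, "+"))
    r <- field$r_um
    idx <- findInterval(rq, r)
    idx[idx >= length(r)] <- length(r) - 1L
    frac <- (rq - r[idx]) / field$pitch_um
    e <- matrix(0, length(t), length(field$s_um))
    for (k in seq_along(field$s_um)) {
      ik <- intensity[, k]
      samp <- ik[idx] * (1 - frac) + ik[idx + 1L] * frac
      if (mode == "two_photon") samp <- samp^2
      e[, k] <- rowMeans(matrix(samp, length(t), length(y)))
    }
  }
  e <- e / max(e)
  structure(list(E = e, t_um = t, s_um = field$s_um, mode = mode,
                 scan_range_um = scan_range_um,
                 t_pitch_um = t_pitch_um,
                 s_pitch_um = if (length(field$s_um) > 1) diff(field$s_um[1:2]) else NA_real_,
                 beam_profile = beam_profile / max(beam_profile),
                 beam_r_um = field$r_um),
            class = "sheet_profile")
}

#' Analytic Gaussian light sheet
#'
#' The cross-section of a cylindrical-lens Gaussian sheet of waist `w0`:
#' `E(t, s) = (w0 / w(s))^(2m) exp(-2 m t^2 / w(s)^2)` with
#' `w(s) = w0 sqrt(1 + (s / zR)^2)`, `zR = pi w0^2 n / lambda`, and `m` = 1
#' (one photon) or 2 (two photon). Serves as the closed-form comparator for
#' depth-of-field measurements: the one-photon on-axis density halves exactly
#' at `s = zR`, so its DOF is `2 zR = 2 pi w0^2 n / lambda`.
#'
#' @param w0_um beam waist (um).
#' @param wavelength_um wavelength in the medium reference (um).
#' @param medium_ri refractive index.
#' @param mode `"one_photon"` or `"two_photon"`.
#' @param t_max_um,t_pitch_um,s_max_um,s_pitch_um grid specification (um).
#' @return a `sheet_profile`.
#' @export
gaussian_sheet <- function(w0_um, wavelength_um = 0.77, medium_ri = 1.45,
                           mode = c("one_photon", "two_photon"),
                           t_max_um = 6, t_pitch_um = 0.02,
                           s_max_um = NULL, s_pitch_um = NULL) {
  mode <- match.arg(mode)
  zr <- pi * w0_um^2 * medium_ri / wavelength_um
  if (is.null(s_max_um)) s_max_um <- 6 * zr
  if (is.null(s_pitch_um)) s_pitch_um <- s_max_um / 400
  t <- seq(-t_max_um, t_max_um, by = t_pitch_um)
  s <- seq(-s_max_um, s_max_um, by = s_pitch_um)
  w <- w0_um * sqrt(1 + (s / zr)^2)
  m <- if (mode == "two_photon") 2 else 1
  e <- sapply(seq_along(s), function(k) (w0_um / w[k])^(2 * m) * exp(-2 * m * t^2 / w[k]^2))
  e <- e / max(e)
  structure(list(E = e, t_um = t, s_um = s, mode = mode, scan_range_um = 0,
                 t_pitch_um = t_pitch_um, s_pitch_um = s_pitch_um,
                 beam_profile = NULL, beam_r_um = NULL),
            class = "sheet_profile")
}

#' Sheet metrics: thickness, depth of field and side-lobe fraction
#'
#' All quantities are full widths at half maximum obtained by linear
#' interpolation of the half-max crossings:
#' \itemize{
#'   \item `profile_fwhm_um` - FWHM along the thickness axis of the sheet's
#'     excitation-density map at focus (the plane of maximal on-axis density).
#'   \item `thickness_fwhm_um` - the design sheet thickness: the central-lobe
#'     FWHM of the underlying excitation-beam intensity at focus. For sheets
#'     without a stored beam profile (e.g. analytic comparators) it equals
#'     `profile_fwhm_um`.
#'   \item `dof_um` - FWHM of the on-axis (t = 0) excitation density along
#'     the propagation axis.
#'   \item `side_lobe_fraction` - fraction of the focal thickness profile's
#'     integrated density lying beyond the first local minimum outside the
#'     central lobe (within the sampled support).
#' }
#'
#' @param sheet a `sheet_profile`.
#' @return a one-row tibble.
#' @export
sheet_metrics <- function(sheet) {
  stopifnot(inherits(sheet, "sheet_profile"))
  e <- sheet$E
  if (max(e) <= 0) stop_domain("sheet is identically zero; metrics undefined")
  it0 <- which.min(abs(sheet$t_um))
  onaxis <- e[it0, ]
  k0 <- which.max(onaxis)
  prof <- e[, k0]
  profile_fwhm <- fwhm_profile(sheet$t_um, prof)$fwhm
  dof <- if (length(sheet$s_um) > 2) fwhm_profile(sheet$s_um, onaxis)$fwhm else NA_real_
  # side lobes: first local minimum beyond the central peak of the |t| profile
  half <- prof[it0:length(prof)]
  imin <- NA_integer_
  for (i in 2:(length(half) - 1)) {
    if (half[i] < half[i - 1] && half[i] <= half[i + 1]) { imin <- i; break }
  }
  slf <- if (is.na(imin)) 0 else sum(half[(imin + 1):length(half)]) / sum(half)
  thickness <- profile_fwhm
  if (!is.null(sheet$beam_profile)) {
    bp <- c(rev(sheet$beam_profile[-1]), sheet$beam_profile)
    br <- c(-rev(sheet$beam_r_um[-1]), sheet$beam_r_um)
    thickness <- fwhm_profile(br, bp)$fwhm
  }
  tibble::tibble(
    mode = sheet$mode,
    thickness_fwhm_um = thickness,
    profile_fwhm_um = profile_fwhm,
    dof_um = dof,
    side_lobe_fraction = slf
  )
}

#' @export
print.sheet_profile <- function(x, ...) {
  cat(sprintf("<sheet_profile> %s | t: %d samples @ %.3g um | s: %d samples | scan %g um\n",
              x$mode, length(x$t_um), x$t_pitch_um, length(x$s_um), x$scan_range_um))
  invisible(x)
}
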