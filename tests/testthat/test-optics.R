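test_that("paraxial effective NA reproduces the ring arithmetic", {
  expect_equal(effective_na(6.8, 10), 0.34)
  expect_equal(effective_na(0, 10), 0)
  expect_warning(na1 <- effective_na(20, 10), "paraxial")
  expect_equal(na1, 1)
  expect_error(effective_na(6.8, 0), "focal length")
})

test_that("optical_config validates physics and sampling", {
  expect_error(optical_config(illumination_na = 1.5), "NA < medium")
  expect_error(optical_config(excitation_wavelength_nm = -1), "positive")
  expect_error(optical_config(grid = list(r_max_um = 60, r_pitch_um = 1,
                                          s_max_um = 240, s_pitch_um = 2)),
               "Nyquist")
  expect_warning(optical_config(back_aperture_ring_diameter_mm = 25), "paraxial")
})

test_that("focal Bessel-Gauss profile matches the analytic J0^2 oracle", {
  f <- default_field()
  i0 <- which.min(abs(f$s_um))
  prof <- Mod(f$amplitude[, i0])^2
  expect_equal(which.max(prof), 1L)  # on-axis maximum at r = 0
  # oracle: root of J0(x)^2 = 1/2 gives the half-width in scaled units
  xh <- uniroot(function(x) besselJ(x, 0)^2 - 0.5, c(0.5, 2), tol = 1e-10)$root
  lam <- 0.77; na <- 0.34
  fwhm_ref <- 2 * xh * lam / (2 * pi * na)
  full <- c(rev(prof[-1]), prof)
  rr <- c(-rev(f$r_um[-1]), f$r_um)
  fwhm_sim <- fwhm_profile(rr, full)$fwhm
  expect_lt(abs(fwhm_sim - fwhm_ref) / fwhm_ref, 0.02)
  # the first null of J0 is filled only by the finite annulus width,
  # to order (delta NA / NA)^2 of the peak
  r_zero <- 2.404826 * lam / (2 * pi * na)
  i_zero <- prof[which.min(abs(f$r_um - r_zero))]
  expect_lt(i_zero / max(prof), 1e-3)
})

test_that("central-lobe thickness scales as lambda / NA", {
  grid <- list(r_max_um = 15, r_pitch_um = 0.04, s_max_um = 20, s_pitch_um = 10)
  fw <- vapply(c(0.25, 0.45), function(na) {
    f <- bessel_gauss_field(optical_config(illumination_na = na, grid = grid))
    i0 <- which.min(abs(f$s_um))
    prof <- Mod(f$amplitude[, i0])^2
    fwhm_profile(c(-rev(f$r_um[-1]), f$r_um), c(rev(prof[-1]), prof))$fwhm
  }, numeric(1))
  expect_lt(abs(fw[1] / fw[2] - 0.45 / 0.25) / (0.45 / 0.25), 0.02)
})

test_that("angular-spectrum propagation is unitary and matches Gaussian optics", {
  # plane wave: modulus unchanged everywhere (no padding so the support wraps)
  x <- seq(-20, 20, by = 0.25)
  pw <- structure(list(amplitude = matrix(1 + 0i, length(x), length(x)),
                       x_um = x, s_um = 0, pitch_um = 0.25,
                       representation = "transverse", wavelength_um = 0.77,
                       medium_ri = 1.45, config = NULL), class = "beam_field")
  pw2 <- propagate(pw, 17, pad = FALSE)
  expect_true(max(abs(Mod(pw2$amplitude) - 1)) < 1e-10)
  # Gaussian beam: width after one Rayleigh range grows by sqrt(2)
  w0 <- 2; lam <- 0.77; n <- 1.45
  x <- seq(-40, 40, by = 0.2)
  g <- structure(list(amplitude = exp(-outer(x^2, x^2, "+") / w0^2) + 0i,
                      x_um = x, s_um = 0, pitch_um = 0.2,
                      representation = "transverse", wavelength_um = lam,
                      medium_ri = n, config = NULL), class = "beam_field")
  zr <- pi * w0^2 * n / lam
  p0 <- opentoplsm:::field_power(g)
  g2 <- propagate(g, zr)
  expect_lt(abs(opentoplsm:::field_power(g2) / p0 - 1), 0.001)
  prof <- Mod(g2$amplitude[, which.min(abs(x))])^2
  w_meas <- fwhm_profile(x, prof)$fwhm / sqrt(2 * log(2))
  expect_lt(abs(w_meas / (w0 * sqrt(2)) - 1), 0.01)
})

test_that("radial propagation re-evaluates the Debye field at the shifted plane", {
  f <- default_field()
  f2 <- propagate(f, 50)
  expect_equal(f2$s_um, f$s_um + 50)
  # shifting back reproduces the original amplitudes
  f3 <- propagate(f2, -50)
  expect_equal(f3$amplitude, f$amplitude, tolerance = 1e-10)
})

test_that("two-photon sheet is the square of the one-photon sheet before scanning", {
  f <- default_field()
  s1 <- make_sheet(f, 0, "one_photon", t_max_um = 4)
  s2 <- make_sheet(f, 0, "two_photon", t_max_um = 4)
  e1 <- s1$E / max(s1$E)
  expect_equal(s2$E, e1^2 / max(e1^2), tolerance = 1e-10)
  # and therefore nowhere exceeds it after common normalization
  expect_true(all(s2$E <= e1 + 1e-12))
})

test_that("scanned two-photon sheet suppresses side lobes relative to one-photon", {
  m1 <- sheet_metrics(default_sheet("one_photon"))
  m2 <- sheet_metrics(default_sheet("two_photon"))
  expect_lt(m2$side_lobe_fraction, m1$side_lobe_fraction)
})

test_that("Gaussian sheet DOF equals twice the Rayleigh range", {
  w0 <- 1.5; lam <- 0.77; n <- 1.45
  sh <- gaussian_sheet(w0, lam, n, "one_photon")
  m <- sheet_metrics(sh)
  expect_lt(abs(m$dof_um / (2 * pi * w0^2 * n / lam) - 1), 0.02)
})

test_that("Bessel sheet outlives a Gaussian sheet of equal central thickness", {
  m2 <- sheet_metrics(default_sheet("two_photon"))
  w0 <- m2$thickness_fwhm_um / sqrt(2 * log(2))
  mg <- sheet_metrics(gaussian_sheet(w0, 0.77, 1.45, "one_photon"))
  expect_gt(m2$dof_um, mg$dof_um)
})

test_that("depth of field grows as the annulus narrows", {
  grid <- list(r_max_um = 30, r_pitch_um = 0.05, s_max_um = 400, s_pitch_um = 4)
  dofs <- vapply(c(0.015, 0.0235, 0.04), function(w) {
    f <- bessel_gauss_field(optical_config(illumination_na_fractional_width = w,
                                           grid = grid))
    sheet_metrics(make_sheet(f, 40, "two_photon", t_max_um = 3))$dof_um
  }, numeric(1))
  expect_true(all(diff(dofs) < 0))
})

test_that("degenerate sheets are handled explicitly", {
  # single-pixel-wide sheet: thickness collapses to one grid pitch
  t <- seq(-2, 2, by = 0.1)
  e <- matrix(0, length(t), 3)
  e[which(t == 0), ] <- 1
  sh <- structure(list(E = e, t_um = t, s_um = c(-1, 0, 1), mode = "one_photon",
                       scan_range_um = 0, t_pitch_um = 0.1, s_pitch_um = 1,
                       beam_profile = NULL, beam_r_um = NULL),
                  class = "sheet_profile")
  expect_equal(sheet_metrics(sh)$profile_fwhm_um, 0.1, tolerance = 1e-10)
  sh$E[] <- 0
  expect_error(sheet_metrics(sh), "identically zero")
})
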