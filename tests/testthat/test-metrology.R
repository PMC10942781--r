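test_that("FWHM estimator is exact on noiseless Gaussian spots", {
  # sigma = 0.4 um -> FWHM = 2.3548 * 0.4 = 0.9419 um, within 2%
  vol <- gaussian_spot_volume(c(3, 3, 3), 0.4, c(6, 6, 6))
  rep <- measure_fwhm_3d(vol, matrix(c(3, 3, 3), 1), window_um = 2)
  expect_equal(nrow(rep), 1L)
  ref <- 2 * sqrt(2 * log(2)) * 0.4
  for (f in c(rep$fwhm_x_um, rep$fwhm_y_um, rep$fwhm_z_um))
    expect_lt(abs(f / ref - 1), 0.02)
  # unbiased across the relevant sigma range
  for (sig in c(0.3, 0.6, 1.0, 1.5)) {
    v <- gaussian_spot_volume(c(6, 6, 6), sig, c(12, 12, 12), pitch = 0.15)
    r <- measure_fwhm_3d(v, matrix(c(6, 6, 6), 1), window_um = 4 * sig)
    expect_lt(abs(r$fwhm_x_um / (2 * sqrt(2 * log(2)) * sig) - 1), 0.02)
  }
  # Gaussian-fit route agrees with the crossing route
  rg <- measure_fwhm_3d(vol, matrix(c(3, 3, 3), 1), window_um = 2,
                        method = "gaussian")
  expect_lt(abs(rg$fwhm_x_um / ref - 1), 0.02)
})

test_that("half-max crossings are symmetric for a symmetric profile", {
  x <- seq(-5, 5, by = 0.1)
  y <- exp(-x^2 / (2 * 1.2^2))
  r <- fwhm_profile(x, y)
  expect_equal(abs(r$left), abs(r$right), tolerance = 1e-9)
})

test_that("beads too close together are excluded, not mismeasured", {
  vol <- gaussian_spot_volume(rbind(c(3, 3, 3), c(3.8, 3, 3), c(8, 8, 8)),
                              0.4, c(11, 11, 11))
  rep <- measure_fwhm_3d(vol, rbind(c(3, 3, 3), c(3.8, 3, 3), c(8, 8, 8)),
                         window_um = 2, min_sep_um = 2.7)
  expect_equal(nrow(rep), 1L)
  expect_equal(attr(rep, "excluded"), 2L)
})

test_that("imaging-depth estimate matches the analytic exponential crossing", {
  # nuclei on a grid, intensity A exp(-z / l) over unit-sd background noise
  l <- 20; amp <- 30; thr <- 2
  pitch <- 1
  d <- c(40, 40, 100)
  arr <- array(with_seed_fixture(5, rnorm(prod(d))), d)
  zs <- seq(5, 95, by = 5)
  centers <- expand.grid(x_um = c(10, 20, 30), y_um = c(10, 20, 30), z_um = zs)
  for (i in seq_len(nrow(centers))) {
    cv <- unlist(centers[i, ]) / pitch + 1
    arr[cv[1] + (-1:1), cv[2] + (-1:1), cv[3] + (-1:1)] <-
      amp * exp(-centers$z_um[i] / l)
  }
  vol <- opentoplsm:::new_volume(arr, rep(pitch, 3), c(0, 0, 0), "f")
  centers$radius_um <- 1.5
  est <- estimate_imaging_depth(vol, centers, cnr_threshold = thr, bin_um = 5)
  analytic <- l * log(amp / thr)  # sd(background) = 1
  expect_lt(abs(as.numeric(est) - analytic), 5 + 1e-9)  # within one bin
  # monotone in the decay length: slower decay images deeper
  arr2 <- array(with_seed_fixture(5, rnorm(prod(d))), d)
  for (i in seq_len(nrow(centers))) {
    cv <- unlist(centers[i, 1:3]) / pitch + 1
    arr2[cv[1] + (-1:1), cv[2] + (-1:1), cv[3] + (-1:1)] <-
      amp * exp(-centers$z_um[i] / (2 * l))
  }
  vol2 <- opentoplsm:::new_volume(arr2, rep(pitch, 3), c(0, 0, 0), "f")
  est2 <- estimate_imaging_depth(vol2, centers, cnr_threshold = thr, bin_um = 5)
  expect_gte(as.numeric(est2), as.numeric(est))
  expect_error(estimate_imaging_depth(vol, centers[0, ], 1), "no ground-truth")
})

test_that("throughput reproduces the strip-rate arithmetic", {
  expect_equal(throughput(600, 400, 1), 0.24)
  expect_equal(throughput(600, 0, 1), 0)
  expect_equal(throughput(600, 400, 2), 2 * throughput(600, 400, 1))
  expect_error(throughput(0, 400, 1), "positive")
})

test_that("acquisition budget reproduces the printed 1 cm^2 arithmetic", {
  geom <- acquisition_geometry()
  b <- acquisition_budget(10000, 10000, geom)
  expect_equal(b$strips, 17L)                     # ceil(10 mm / 600 um)
  expect_equal(b$frames_per_strip, 10000L)
  expect_equal(b$frames, 170000L)
  expect_equal(b$time_s, 425)
  expect_equal(b$throughput_mm2_s, 0.24)
  # budget self-consistency and throughput duality on the tiled area
  expect_equal(b$time_s * geom$fps, b$frames)
  tiled_area_mm2 <- b$strips * geom$strip_width_um * 10000 / 1e6
  expect_equal(tiled_area_mm2 / b$time_s, b$throughput_mm2_s)
  # rounded report: 7 min, and 318 GB from the 7-min frame count
  r <- budget_report(b, geom)
  expect_equal(r$time_min, 7)
  expect_equal(r$frames_reported, 168000)
  expect_equal(r$gb_per_channel, 318)
  # zero area is a zero budget, not an error
  z <- acquisition_budget(0, 10000, geom)
  expect_equal(z$frames, 0L)
  expect_equal(z$bytes_per_channel, 0)
  # bytes scale linearly with pixel depth
  geom4 <- acquisition_geometry(bytes_per_pixel = 4)
  b4 <- acquisition_budget(10000, 10000, geom4)
  expect_equal(b4$bytes_per_channel, 2 * b$bytes_per_channel)
  # strip overlap inflates the strip count
  bo <- acquisition_budget(10000, 10000, geom, overlap_frac = 0.1)
  expect_gt(bo$strips, b$strips)
})
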