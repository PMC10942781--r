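test_that("tilted-plane depths project onto the vertical by sin(tilt)", {
  expect_equal(tilted_depth_to_vertical(90, 45), 90 * sin(pi / 4))
  expect_equal(tilted_depth_to_vertical(90, 45, round_um = TRUE), 64)
  expect_equal(tilted_depth_to_vertical(28, 45, round_um = TRUE), 20)
  expect_equal(tilted_depth_to_vertical(37.2, 90), 37.2)
  expect_error(tilted_depth_to_vertical(-1, 45), "non-negative")
  expect_error(tilted_depth_to_vertical(10, 120), "tilt")
})

test_that("zero tilt deskew is a bitwise restack", {
  frames <- array(runif(20 * 15 * 8), c(20, 15, 8))
  geom <- acquisition_geometry(tilt_deg = 45, step_um = 1, fps = 400,
                               frame_shape = c(u = 20, v = 15),
                               pixel_pitch_um = 0.5)
  st <- structure(list(frames = frames, stage_x_um = 0:7, geometry = geom,
                       channel = "fluor", noise = FALSE, seed = NULL,
                       saturated_pixels = 0L), class = "raw_strip")
  geom0 <- geom; geom0$tilt_deg <- 0
  vol <- deskew(st, geom0, interp = "nearest")
  expect_identical(vol$intensity, aperm(frames, c(3, 1, 2)))
  # and doing it again is still the identity
  st2 <- st; st2$frames <- aperm(vol$intensity, c(2, 3, 1))
  expect_identical(deskew(st2, geom0)$intensity, vol$intensity)
})

test_that("acquire then deskew localizes a point emitter at its world position", {
  ph <- delta_phantom(c(50, 8, 20), dims_um = c(80, 16, 25))
  geom <- small_geometry(u = 32, v = 70, x0 = -25)
  st <- acquire_strip(ph, geom, no_attenuation(), n_frames = 106,
                      channels = "fluor", noise = FALSE, oob = "zero")
  for (itp in c("nearest", "linear")) {
    vol <- deskew(st$fluor, geom, interp = itp)
    tol <- if (itp == "nearest") vol$voxel_pitch_um else vol$voxel_pitch_um / 2
    err <- abs(centroid_world(vol) - c(50, 8, 20))
    expect_true(all(err <= tol + 1e-9), info = itp)
  }
})

test_that("deskew preserves flat fields and total intensity", {
  # constant slab: interior voxels stay constant within 0.5%
  d <- c(120, 24, 48)  # 60 x 12 x 24 um at 0.5 um pitch
  ph <- structure(list(fluor = array(1, d), shg = array(0, d),
                       voxel_pitch_um = rep(0.5, 3), surface_z_um = 0,
                       centers = tibble::tibble(), provenance = list()),
                  class = "phantom")
  geom <- small_geometry(u = 24, v = 24, step = 0.5, x0 = -9)
  st <- acquire_strip(ph, geom, no_attenuation(), n_frames = 78,
                      channels = "fluor", noise = FALSE, oob = "zero", n_taps = 1)
  vol <- deskew(st$fluor, geom, interp = "linear")
  # stay clear of the slab's X = 0 face, which the oblique in-frame blur
  # smears across ~1 um
  interior <- vol$intensity[30:50, 6:18, 8:16]
  expect_lt(max(abs(interior / mean(interior) - 1)), 0.005)
  # total intensity conserved when the output lattice matches the step
  emi <- delta_phantom(c(15, 6, 6), dims_um = c(30, 12, 12))
  g2 <- small_geometry(u = 24, v = 32, step = 0.5, x0 = -12)
  st2 <- acquire_strip(emi, g2, no_attenuation(), n_frames = 85,
                       channels = "fluor", noise = FALSE, oob = "zero")
  v2 <- deskew(st2$fluor, g2, interp = "linear")
  expect_lt(abs(sum(v2$intensity, na.rm = TRUE) / sum(st2$fluor$frames) - 1), 0.01)
})

test_that("deskew validates stage metadata", {
  frames <- array(0, c(4, 4, 3))
  geom <- acquisition_geometry(frame_shape = c(u = 4, v = 4), pixel_pitch_um = 0.5,
                               strip_width_um = 2)
  st <- structure(list(frames = frames, stage_x_um = c(0, 2, 1), geometry = geom,
                       channel = "x", noise = FALSE, seed = NULL,
                       saturated_pixels = 0L), class = "raw_strip")
  expect_error(deskew(st, geom), "strictly increasing")
  st$stage_x_um <- NULL
  expect_error(deskew(st, geom), "stage positions")
})

test_that("stitching is exact on identity, constants and known shifts", {
  # single volume: bitwise identity
  a <- array(runif(8 * 6 * 4), c(8, 6, 4))
  va <- opentoplsm:::new_volume(a, rep(1, 3), c(0, 0, 0), "fluor")
  expect_identical(stitch(list(va)), va)
  # constant volumes blend seamlessly
  vb <- opentoplsm:::new_volume(array(3, c(8, 6, 4)), rep(1, 3), c(5, 0, 0), "fluor")
  vc <- opentoplsm:::new_volume(array(3, c(8, 6, 4)), rep(1, 3), c(0, 0, 0), "fluor")
  mos <- stitch(list(vc, vb))
  expect_true(all(abs(mos$intensity - 3) < 1e-12, na.rm = TRUE))
  # associativity on constants
  vd <- opentoplsm:::new_volume(array(3, c(8, 6, 4)), rep(1, 3), c(10, 0, 0), "fluor")
  m1 <- stitch(list(stitch(list(vc, vb)), vd))
  m2 <- stitch(list(vc, vb, vd))
  expect_equal(dim(m1$intensity), dim(m2$intensity))
  expect_true(all(abs(m1$intensity - m2$intensity) < 1e-9, na.rm = TRUE))
  # known shift recovered by cross-correlation despite a wrong nominal offset
  big <- with_seed_fixture(7, array(runif(40 * 8 * 6), c(40, 8, 6)))
  v1 <- opentoplsm:::new_volume(big[1:24, , ], rep(1, 3), c(0, 0, 0), "f")
  v2 <- opentoplsm:::new_volume(big[17:40, , ], rep(1, 3), c(14, 0, 0), "f")  # truth: 16
  mos2 <- stitch(list(v1, v2), registration = "xcorr", search_vox = 4)
  refined <- attr(mos2, "offsets")$refined_um[2, 1]
  expect_lte(abs(refined - 16), 1)
  # non-overlapping volumes fall back with a warning
  vfar <- opentoplsm:::new_volume(big[1:10, , ], rep(1, 3), c(200, 0, 0), "f")
  expect_warning(stitch(list(v1, vfar), registration = "xcorr"), "no overlap")
})

test_that("en-face extraction interpolates in depth and propagates the mask", {
  arr <- array(0, c(5, 4, 3))
  for (k in 1:3) arr[, , k] <- k          # linear ramp in Z
  arr[2, 2, ] <- NA                        # masked column
  vol <- opentoplsm:::new_volume(arr, c(1, 1, 2), c(0, 0, 0), "f")
  expect_identical(extract_enface(vol, 2), arr[, , 2])     # exact plane
  mid <- extract_enface(vol, 3)                            # halfway: mean of 2,3
  expect_equal(mid[1, 1], 2.5)
  expect_true(is.na(mid[2, 2]))
  expect_error(extract_enface(vol, 7), "outside")
})
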