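test_that("Beer-Lambert attenuation follows the closed form", {
  cfg <- attenuation_config()
  expect_equal(attenuated_signal(0, cfg, "fluor"), 1)
  # excitation off: pure emission decay, e^-1 at one emission length
  em_only <- attenuation_config(l_ex_um = 1e12)
  l_em <- em_only$channels$l_em_um[em_only$channels$name == "fluor"]
  expect_equal(attenuated_signal(l_em, em_only, "fluor"), exp(-1), tolerance = 1e-6)
  # two-photon decays twice as fast in the excitation term
  one <- attenuation_config(mode = "one_photon")
  two <- attenuation_config(mode = "two_photon")
  d <- 30
  expect_equal(attenuated_signal(d, two, "fluor") / attenuated_signal(d, one, "fluor"),
               exp(-d / two$l_ex_um))
  # longer emission wavelength (longer l_em) -> more signal at any depth
  longer <- attenuation_config(channels = tibble::tibble(
    name = c("shg", "fluor"), emission_nm = c(385, 515),
    l_em_um = c(30, 100), gain = c(1, 1)))
  expect_gt(attenuated_signal(d, longer, "fluor"), attenuated_signal(d, cfg, "fluor"))
  expect_error(attenuated_signal(-1, cfg), "non-negative")
  expect_error(attenuation_config(channels = tibble::tibble(
    name = c("a", "b"), emission_nm = c(400, 600), l_em_um = c(50, 30),
    gain = c(1, 1))), "increase with wavelength")
})

test_that("empty phantom with noise off renders exactly zero frames", {
  ph <- delta_phantom(matrix(numeric(0), 0, 3), dims_um = c(20, 10, 10))
  geom <- small_geometry(u = 20, v = 20)
  st <- acquire_strip(ph, geom, no_attenuation(), n_frames = 10,
                      channels = "fluor", noise = FALSE)
  expect_true(all(st$fluor$frames == 0))
})

test_that("a point emitter lands in the frame the plane geometry predicts", {
  # X0 = 50, Z0 = 20, x0 = 0, step 1 um, 45 degrees -> frame 30 (0-based)
  ph <- delta_phantom(c(50, 10, 20), dims_um = c(80, 20, 25))
  geom <- small_geometry(u = 40, v = 70, x0 = 0)
  st <- acquire_strip(ph, geom, no_attenuation(), n_frames = 70,
                      channels = "fluor", noise = FALSE, oob = "zero")
  mx <- which(st$fluor$frames == max(st$fluor$frames), arr.ind = TRUE)[1, ]
  expect_equal(mx[[3]] - 1L, 30L)                          # frame index
  expect_equal(mx[[1]] - 1L, round(10 / 0.5))              # u = Y / p
  expect_equal(mx[[2]] - 1L, round(20 / (0.5 * sin(pi / 4))))  # v = Z / (p sin)
})

test_that("noise-free pixel values are exactly linear in channel gain", {
  ph <- delta_phantom(c(10, 5, 5), dims_um = c(25, 10, 10))
  geom <- small_geometry(u = 20, v = 25, x0 = 0)
  att1 <- no_attenuation()
  att2 <- no_attenuation()
  att2$channels$gain <- att2$channels$gain * 2
  s1 <- acquire_strip(ph, geom, att1, n_frames = 18, channels = "fluor",
                      noise = FALSE, oob = "zero")
  s2 <- acquire_strip(ph, geom, att2, n_frames = 18, channels = "fluor",
                      noise = FALSE, oob = "zero")
  expect_equal(s2$fluor$frames, 2 * s1$fluor$frames, tolerance = 1e-12)
})

test_that("forward mapping predicts the rendered argmax for random emitters", {
  pitch <- 0.5; p <- 0.5
  n_em <- 20
  pts <- with_seed_local <- local({
    set.seed(42)
    cbind(runif(n_em, 8, 40), runif(n_em, 3, 17), runif(n_em, 2, 18))
  })
  # snap to voxel centers so the ground truth is unambiguous
  pts <- round(pts / pitch) * pitch
  keep <- !duplicated(round(pts / 2.5))  # enforce separation
  pts <- pts[keep, , drop = FALSE]
  ph <- delta_phantom(pts, dims_um = c(50, 20, 20), pitch = pitch)
  geom <- small_geometry(u = 40, v = 56, x0 = -20)
  st <- acquire_strip(ph, geom, no_attenuation(), n_frames = 72,
                      channels = "fluor", noise = FALSE, oob = "zero",
                      n_taps = 1)
  th <- pi / 4
  for (i in seq_len(nrow(pts))) {
    i_star <- round((pts[i, 1] - pts[i, 3] / tan(th) - geom$x0_um) / geom$step_um)
    u_star <- round(pts[i, 2] / p)
    v_star <- round(pts[i, 3] / (p * sin(th)))
    win_u <- (u_star - 2):(u_star + 2) + 1
    win_v <- (v_star - 2):(v_star + 2) + 1
    win_f <- (i_star - 2):(i_star + 2) + 1
    sub <- st$fluor$frames[win_u, win_v, win_f]
    am <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    expect_true(all(abs(am - 3) <= 1),
                info = sprintf("emitter %d offset (%d,%d,%d)", i,
                               am[1] - 3, am[2] - 3, am[3] - 3))
  }
})

test_that("seeded noise is bit-reproducible and 16-bit bounded", {
  ph <- delta_phantom(c(10, 5, 5), dims_um = c(25, 10, 10), value = 1e7)
  geom <- small_geometry(u = 20, v = 25, x0 = 0)
  att <- no_attenuation(read_noise_sd = 5, background = 3)
  a <- acquire_strip(ph, geom, att, n_frames = 18, channels = "fluor",
                     noise = TRUE, seed = 99, oob = "zero")
  b <- acquire_strip(ph, geom, att, n_frames = 18, channels = "fluor",
                     noise = TRUE, seed = 99, oob = "zero")
  expect_identical(a$fluor$frames, b$fluor$frames)
  c_ <- acquire_strip(ph, geom, att, n_frames = 18, channels = "fluor",
                      noise = TRUE, seed = 100, oob = "zero")
  expect_false(identical(a$fluor$frames, c_$fluor$frames))
  expect_true(all(a$fluor$frames >= 0 & a$fluor$frames <= 65535))
  expect_true(a$fluor$frames[1] == round(a$fluor$frames[1]))
  # the bright voxel saturates and is reported, never silently clipped
  expect_gt(a$fluor$saturated_pixels, 0)
})

test_that("nuclear signal fades monotonically with depth when attenuation is on", {
  spec <- phantom_spec("skin", dims_um = c(30, 20, 60), epidermis_um = 12,
                       dermis_sep_um = 6)
  ph <- generate_tissue(spec, seed = 3)
  att <- skin_attenuation("two_photon")
  geom <- small_geometry(u = 20, v = 168, x0 = -60)
  st <- acquire_strip(ph, geom, att, n_frames = 91, channels = "fluor",
                      noise = FALSE, n_taps = 1, oob = "zero")
  # v indexes depth on the tilted plane; the brightest nuclear signal per
  # 15 um depth bin must fall with depth (max is robust to the random
  # per-bin nuclear density)
  z_v <- (seq_len(168) - 1) * 0.5 * sin(pi / 4)
  max_v <- apply(st$fluor$frames, 2, max)
  m <- tapply(max_v, cut(z_v, seq(0, 60, by = 15)), max)
  expect_true(all(diff(m) < 0))
})

test_that("out-of-bounds planes are an explicit error by default", {
  ph <- delta_phantom(c(10, 5, 5), dims_um = c(20, 10, 10))
  geom <- small_geometry(u = 20, v = 25, x0 = -5)
  expect_error(acquire_strip(ph, geom, no_attenuation(), n_frames = 10,
                             channels = "fluor", noise = FALSE),
               "adjust x0")
  deep <- small_geometry(u = 20, v = 40)
  expect_error(acquire_strip(ph, deep, no_attenuation(), n_frames = 5,
                             channels = "fluor", noise = FALSE),
               "phantom is")
})
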