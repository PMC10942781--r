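# Shared fixtures, memoized across test files (helpers are sourced once per
# test session).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_field <- function() memo("field", bessel_gauss_field(optical_config()))

default_sheet <- function(mode) {
  memo(paste0("sheet_", mode), make_sheet(default_field(), 40, mode))
}

# Attenuation config that effectively switches attenuation off.
no_attenuation <- function(...) {
  attenuation_config(l_ex_um = 1e9,
                     channels = tibble::tibble(name = c("shg", "fluor"),
                                               emission_nm = c(385, 515),
                                               l_em_um = c(1e9 - 1, 1e9),
                                               gain = c(1, 1)),
                     mode = "two_photon", ...)
}

# Phantom with isolated bright voxels at the given world points (um).
delta_phantom <- function(points_um, dims_um, pitch = 0.5, value = 1000) {
  d <- as.integer(round(dims_um / pitch))
  fluor <- array(0, d)
  pts <- matrix(points_um, ncol = 3)
  for (i in seq_len(nrow(pts))) {
    v <- round(pts[i, ] / pitch)
    fluor[v[1] + 1, v[2] + 1, v[3] + 1] <- value
  }
  structure(list(fluor = fluor, shg = array(0, d),
                 voxel_pitch_um = rep(pitch, 3), surface_z_um = 0,
                 centers = tibble::tibble(x_um = pts[, 1], y_um = pts[, 2],
                                          z_um = pts[, 3]),
                 provenance = list(preset = "delta", seed = NA)),
            class = "phantom")
}

# Small geometry helper for phantom-sized acquisitions.
small_geometry <- function(u, v, pitch = 0.5, step = 1, x0 = 0, tilt = 45) {
  acquisition_geometry(tilt_deg = tilt, step_um = step, fps = 400,
                       frame_shape = c(u = u, v = v), pixel_pitch_um = pitch,
                       x0_um = x0)
}

# World-space location of a volume's maximum-intensity voxel.
argmax_world <- function(vol) {
  iv <- vol$intensity
  iv[is.na(iv)] <- -Inf
  am <- which(iv == max(iv), arr.ind = TRUE)[1, ]
  vol$origin_um + (am - 1) * vol$voxel_pitch_um
}

# Intensity-weighted centroid near the maximum (threshold at 20% of peak).
centroid_world <- function(vol) {
  iv <- vol$intensity
  iv[is.na(iv)] <- 0
  idx <- which(iv > 0.2 * max(iv), arr.ind = TRUE)
  w <- iv[idx]
  cen <- colSums(idx * w) / sum(w)
  vol$origin_um + (cen - 1) * vol$voxel_pitch_um
}

with_seed_fixture <- function(seed, expr) opentoplsm:::with_seed(seed, expr)

# Synthetic volume containing isotropic Gaussian spots of width sigma (um)
# at the given centers, on a clean background.
gaussian_spot_volume <- function(centers_um, sigma_um, dims_um, pitch = 0.1,
                                 amplitude = 100, bg = 0) {
  d <- as.integer(round(dims_um / pitch))
  arr <- array(bg, d)
  ax <- (seq_len(d[1]) - 1) * pitch
  ay <- (seq_len(d[2]) - 1) * pitch
  az <- (seq_len(d[3]) - 1) * pitch
  cm <- matrix(centers_um, ncol = 3)
  for (i in seq_len(nrow(cm))) {
    gx <- exp(-(ax - cm[i, 1])^2 / (2 * sigma_um^2))
    gy <- exp(-(ay - cm[i, 2])^2 / (2 * sigma_um^2))
    gz <- exp(-(az - cm[i, 3])^2 / (2 * sigma_um^2))
    arr <- arr + amplitude * outer(outer(gx, gy), gz)
  }
  opentoplsm:::new_volume(arr, rep(pitch, 3), c(0, 0, 0), "fluor")
}

withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("opentoplsm-test-")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}
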