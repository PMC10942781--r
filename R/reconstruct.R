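#' Convert a depth measured in the tilted image plane to vertical depth
#'
#' Distances measured along the 45-degree-tilted sheet plane project onto the
#' vertical by `sin(tilt)`: 90 um along the tilted plane is 64 um below the
#' surface at 45 degrees.
#'
#' @param d_tilted_um distance along the tilted plane (um, vector allowed).
#' @param tilt_deg tilt from the horizontal, in (0, 90].
#' @param round_um round the result to the nearest micron (default FALSE).
#' @return vertical depth in um.
#' @examples
#' tilted_depth_to_vertical(90, 45, round_um = TRUE)  # 64
#' @export
tilted_depth_to_vertical <- function(d_tilted_um, tilt_deg, round_um = FALSE) {
  if (any(d_tilted_um < 0)) stop_domain("tilted depth must be non-negative")
  if (tilt_deg <= 0 || tilt_deg > 90) stop_domain("tilt must satisfy 0 < tilt <= 90 degrees")
  d <- d_tilted_um * sin(tilt_deg * pi / 180)
  if (round_um) round(d) else d
}

new_volume <- function(intensity, pitch_um, origin_um, channel = NA_character_) {
  structure(list(intensity = intensity, voxel_pitch_um = pitch_um,
                 origin_um = origin_um, channel = channel),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<volume> %d x %d x %d voxels @ (%g, %g, %g) um | origin (%g, %g, %g) | %.1f%% masked\n",
              d[1], d[2], d[3], x$voxel_pitch_um[1], x$voxel_pitch_um[2], x$voxel_pitch_um[3],
              x$origin_um[1], x$origin_um[2], x$origin_um[3],
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Deskew an oblique strip into a world-coordinate volume
#'
#' Inverts the acquisition mapping by gather (pull) resampling: every output
#' voxel (X, Y, Z) is pulled from frame space via `v = Z / (p sin(theta))`,
#' `u = Y / p` and frame index `i = (X - Z cot(theta) - x0) / step`. The
#' output grid has pitch `(p, p, p sin(theta))`, so `u` and `v` land exactly
#' on pixels and only the frame index is interpolated (nearest or linear).
#' Voxels outside the swept swath are masked `NA`, never zero-filled. A tilt
#' of exactly 0 degenerates the mapping and is returned as a pure restack:
#' the frame stack relabelled (frame, u, v) -> (X, Y, Z) bitwise.
#'
#' @param strip a `raw_strip`.
#' @param geom the acquisition geometry (default: the strip's own).
#' @param interp `"linear"` (default) or `"nearest"`.
#' @return a `volume`.
#' @export
deskew <- function(strip, geom = strip$geometry, interp = c("linear", "nearest")) {
  stopifnot(inherits(strip, "raw_strip"))
  interp <- match.arg(interp)
  frames <- strip$frames
  nu <- dim(frames)[1]; nv <- dim(frames)[2]; nf <- dim(frames)[3]
  x <- strip$stage_x_um
  if (is.null(x) || length(x) != nf) stop_domain("missing or inconsistent stage positions")
  if (nf > 1 && any(diff(x) <= 0)) stop_domain("stage positions must be strictly increasing")
  if (geom$tilt_deg == 0) {
    vol <- aperm(frames, c(3, 1, 2))
    return(new_volume(vol, c(geom$step_um, geom$pixel_pitch_um, geom$pixel_pitch_um),
                      c(x[1], 0, 0), strip$channel))
  }
  th <- geom$tilt_deg * pi / 180
  p <- geom$pixel_pitch_um
  step <- geom$step_um
  x0 <- x[1]
  xmax <- x[nf] + (nv - 1) * p * cos(th)
  nx <- floor((xmax - x0) / p) + 1L
  out <- array(NA_real_, c(nx, nu, nv))
  a_idx <- seq_len(nx) - 1
  for (k in seq_len(nv) - 1L) {
    f <- (a_idx * p - k * p * cos(th)) / step   # fractional frame index, 0-based
    fk <- frames[, k + 1L, ]                    # nu x nf
    if (interp == "nearest") {
      fi <- round(f)
      ok <- fi >= 0 & fi <= nf - 1
      if (!any(ok)) next
      sl <- matrix(NA_real_, nx, nu)
      sl[ok, ] <- t(fk[, fi[ok] + 1L, drop = FALSE])
      out[, , k + 1L] <- sl
    } else {
      f0 <- floor(f)
      w <- f - f0
      ok <- f0 >= 0 & f0 <= nf - 2
      edge <- abs(f - (nf - 1)) < 1e-9          # exactly the last frame
      sl <- matrix(NA_real_, nx, nu)
      if (any(ok))
        sl[ok, ] <- (1 - w[ok]) * t(fk[, f0[ok] + 1L, drop = FALSE]) +
                    w[ok] * t(fk[, f0[ok] + 2L, drop = FALSE])
      if (any(edge)) sl[edge, ] <- t(fk[, nf, drop = FALSE])
      out[, , k + 1L] <- sl
    }
  }
  new_volume(out, c(p, p, p * sin(th)), c(x0, 0, 0), strip$channel)
}

#' Stitch volumes into a mosaic
#'
#' Places each volume on the union grid at its nominal offset (from the
#' volume origins, or `nominal_offsets_um`), optionally refines each
#' consecutive pair's offset by maximizing the normalized cross-correlation
#' of the overlap over integer-voxel shifts, and blends overlaps by linear
#' feathering (weights ramp linearly with distance from each volume's valid
#' border, so two constant inputs merge seamlessly).
#'
#' @param volumes list of `volume` objects with identical voxel pitch.
#' @param nominal_offsets_um optional matrix (one row per volume) of world
#'   offsets overriding the volume origins.
#' @param registration `"none"` or `"xcorr"`.
#' @param search_vox half-width of the integer shift search (default 4).
#' @param feather_um feather ramp width (default 5 voxels' worth).
#' @return a `volume` on the union grid; an attribute `offsets` records the
#'   nominal and refined offsets per volume.
#' @export
stitch <- function(volumes, nominal_offsets_um = NULL,
                   registration = c("none", "xcorr"),
                   search_vox = 4L, feather_um = NULL) {
  registration <- match.arg(registration)
  stopifnot(length(volumes) >= 1)
  if (length(volumes) == 1L) return(volumes[[1]])
  pitch <- volumes[[1]]$voxel_pitch_um
  for (v in volumes)
    if (any(abs(v$voxel_pitch_um - pitch) > 1e-9))
      stop_domain("all volumes must share a voxel pitch")
  if (is.null(feather_um)) feather_um <- 5 * pitch[1]
  offs <- if (is.null(nominal_offsets_um))
    t(vapply(volumes, function(v) v$origin_um, numeric(3)))
  else nominal_offsets_um
  nominal <- offs
  # snap offsets to the voxel lattice
  offs_vox <- round(sweep(offs, 2, pitch, "/"))
  if (registration == "xcorr") {
    for (j in 2:length(volumes)) {
      ref <- volumes[[j - 1]]; mov <- volumes[[j]]
      base <- offs_vox[j, ] - offs_vox[j - 1, ]
      best <- c(0, 0, 0); best_cc <- -Inf
      for (dx in -search_vox:search_vox) {
        sh <- base + c(dx, 0, 0)
        cc <- overlap_ncc(ref$intensity, mov$intensity, sh)
        if (!is.na(cc) && cc > best_cc) { best_cc <- cc; best <- c(dx, 0, 0) }
      }
      if (!is.finite(best_cc)) {
        warning("no overlap between volumes ", j - 1, " and ", j,
                "; falling back to nominal offsets")
      } else offs_vox[j, ] <- offs_vox[j, ] + best
    }
  }
  d <- t(vapply(volumes, function(v) dim(v$intensity), integer(3)))
  lo <- apply(offs_vox, 2, min)
  hi <- vapply(1:3, function(ax) max(offs_vox[, ax] + d[, ax]), numeric(1))
  nd <- as.integer(hi - lo)
  acc <- array(0, nd); wacc <- array(0, nd)
  fvox <- max(1, round(feather_um / pitch[1]))
  for (j in seq_along(volumes)) {
    intens <- volumes[[j]]$intensity
    valid <- !is.na(intens)
    w <- feather_weights(valid, fvox)
    o <- offs_vox[j, ] - lo
    ix <- (o[1] + 1):(o[1] + d[j, 1])
    iy <- (o[2] + 1):(o[2] + d[j, 2])
    iz <- (o[3] + 1):(o[3] + d[j, 3])
    vals <- ifelse(valid, intens, 0)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + vals * w
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + w
  }
  mosaic <- ifelse(wacc > 0, acc / pmax(wacc, .Machine$double.eps), NA_real_)
  out <- new_volume(mosaic, pitch, lo * pitch, volumes[[1]]$channel)
  attr(out, "offsets") <- list(nominal_um = nominal,
                               refined_um = sweep(offs_vox, 2, pitch, "*"))
  out
}

# Normalized cross-correlation of the overlap of two arrays when `b` is
# shifted by integer voxels `sh` relative to `a`. NA outside valid data.
overlap_ncc <- function(a, b, sh) {
  da <- dim(a); db <- dim(b)
  lo_a <- pmax(1, 1 + sh); hi_a <- pmin(da, db + sh)
  if (any(hi_a - lo_a < 2)) return(NA_real_)
  lo_b <- lo_a - sh; hi_b <- hi_a - sh
  av <- a[lo_a[1]:hi_a[1], lo_a[2]:hi_a[2], lo_a[3]:hi_a[3]]
  bv <- b[lo_b[1]:hi_b[1], lo_b[2]:hi_b[2], lo_b[3]:hi_b[3]]
  ok <- !is.na(av) & !is.na(bv)
  if (sum(ok) < 8) return(NA_real_)
  av <- av[ok]; bv <- bv[ok]
  sa <- sd(av); sb <- sd(bv)
  if (sa == 0 || sb == 0) return(0)
  mean((av - mean(av)) * (bv - mean(bv))) / (sa * sb)
}

# Linear feather weights: distance (in voxels, capped at fvox) to the nearest
# invalid/border voxel along each axis, normalized to (0, 1].
feather_weights <- function(valid, fvox) {
  d <- dim(valid)
  rx <- pmin(seq_len(d[1]), d[1] + 1 - seq_len(d[1]), fvox + 1) / (fvox + 1)
  ry <- pmin(seq_len(d[2]), d[2] + 1 - seq_len(d[2]), fvox + 1) / (fvox + 1)
  rz <- pmin(seq_len(d[3]), d[3] + 1 - seq_len(d[3]), fvox + 1) / (fvox + 1)
  w <- outer(outer(rx, ry), rz)
  w[!valid] <- 0
  w
}

#' Extract an en-face plane at constant depth
#'
#' @param volume a `volume`.
#' @param depth_um depth below the volume origin (um).
#' @param interp `"linear"` (default) or `"nearest"`.
#' @return a matrix (X x Y); masked voxels stay `NA`.
#' @export
extract_enface <- function(volume, depth_um, interp = c("linear", "nearest")) {
  stopifnot(inherits(volume, "volume"))
  interp <- match.arg(interp)
  pz <- volume$voxel_pitch_um[3]
  nz <- dim(volume$intensity)[3]
  zf <- (depth_um - volume$origin_um[3]) / pz
  if (zf < -1e-9 || zf > nz - 1 + 1e-9)
    stop_domain(sprintf("depth %.2f um outside volume extent [%.2f, %.2f] um",
                        depth_um, volume$origin_um[3], volume$origin_um[3] + (nz - 1) * pz))
  if (interp == "nearest" || abs(zf - round(zf)) < 1e-9)
    return(volume$intensity[, , round(zf) + 1L])
  k0 <- floor(zf)
  w <- zf - k0
  (1 - w) * volume$intensity[, , k0 + 1L] + w * volume$intensity[, , k0 + 2L]
}
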