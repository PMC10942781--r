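#' Measure 3-D full width at half maximum at known bead positions
#'
#' Extracts axis-aligned intensity profiles through each supplied bead
#' center (after snapping to the local intensity maximum), subtracts a
#' background estimated from the profile ends, and measures the FWHM by
#' linear interpolation of the half-maximum crossings. A Gaussian-fit
#' estimator is available as a cross-check. Beads closer to each other than
#' `min_sep_um` (3x the expected FWHM by default) or whose profiles lack
#' half-max crossings are excluded and reported.
#'
#' @param volume a `volume`.
#' @param centers_um matrix or data frame of world bead centers (columns
#'   x/y/z in um; a phantom `$centers` tibble works directly).
#' @param window_um half-length of each profile (default 3).
#' @param min_sep_um minimum bead separation (default 2.7, 3x a 0.9 um FWHM).
#' @param method `"interp"` (default) or `"gaussian"`.
#' @return a `resolution_report`: tibble with one row per measured bead
#'   (fwhm_x/y/z_um) and attributes `summary` (per-axis mean and sd) and
#'   `excluded` (count).
#' @export
measure_fwhm_3d <- function(volume, centers_um, window_um = 3,
                            min_sep_um = 2.7, method = c("interp", "gaussian")) {
  stopifnot(inherits(volume, "volume"))
  method <- match.arg(method)
  if (is.data.frame(centers_um)) {
    nm <- intersect(c("x_um", "y_um", "z_um"), names(centers_um))
    centers_um <- as.matrix(centers_um[, nm])
  }
  centers_um <- matrix(as.numeric(centers_um), ncol = 3)
  pitch <- volume$voxel_pitch_um
  d <- dim(volume$intensity)
  excluded <- 0L
  keep <- rep(TRUE, nrow(centers_um))
  if (nrow(centers_um) > 1) {
    dm <- as.matrix(stats::dist(centers_um))
    diag(dm) <- Inf
    keep <- apply(dm, 1, min) >= min_sep_um
    excluded <- sum(!keep)
  }
  rows <- list()
  for (i in which(keep)) {
    cv <- round((centers_um[i, ] - volume$origin_um) / pitch)  # 0-based
    # snap to the local maximum within 2 voxels
    lo <- pmax(cv - 2, 0); hi <- pmin(cv + 2, d - 1)
    sub <- volume$intensity[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1, drop = FALSE]
    if (all(is.na(sub))) { excluded <- excluded + 1L; next }
    am <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cv <- lo + am - 1L
    fw <- numeric(3)
    ok <- TRUE
    for (ax in 1:3) {
      nwin <- ceiling(window_um / pitch[ax])
      idx <- (cv[ax] - nwin):(cv[ax] + nwin)
      inb <- idx >= 0 & idx <= d[ax] - 1
      idx <- idx[inb]
      coord <- idx * pitch[ax]
      prof <- switch(ax,
        volume$intensity[idx + 1, cv[2] + 1, cv[3] + 1],
        volume$intensity[cv[1] + 1, idx + 1, cv[3] + 1],
        volume$intensity[cv[1] + 1, cv[2] + 1, idx + 1])
      good <- !is.na(prof)
      prof <- prof[good]; coord <- coord[good]
      if (length(prof) < 5) { ok <- FALSE; break }
      bg <- median(c(head(prof, 2), tail(prof, 2)))
      if (method == "interp") {
        r <- fwhm_profile(coord, prof, baseline = bg)
        fw[ax] <- r$fwhm
      } else {
        pk <- which.max(prof)
        ssr <- function(par) {
          mu <- par[1] + par[2] * exp(-(coord - par[3])^2 / (2 * par[4]^2))
          sum((prof - mu)^2)
        }
        fit <- stats::optim(c(bg, max(prof) - bg, coord[pk], window_um / 4),
                            ssr, method = "BFGS",
                            control = list(reltol = 1e-12, maxit = 500))
        fw[ax] <- 2 * sqrt(2 * log(2)) * abs(fit$par[4])
      }
      if (!is.finite(fw[ax]) || fw[ax] <= 0) { ok <- FALSE; break }
    }
    if (!ok) { excluded <- excluded + 1L; next }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x_um = centers_um[i, 1], y_um = centers_um[i, 2], z_um = centers_um[i, 3],
      fwhm_x_um = fw[1], fwhm_y_um = fw[2], fwhm_z_um = fw[3])
  }
  rep_tbl <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                   fwhm_x_um = numeric(0), fwhm_y_um = numeric(0), fwhm_z_um = numeric(0))
  summary <- tibble::tibble(
    axis = c("x", "y", "z"),
    mean_um = c(mean(rep_tbl$fwhm_x_um), mean(rep_tbl$fwhm_y_um), mean(rep_tbl$fwhm_z_um)),
    sd_um = c(sd(rep_tbl$fwhm_x_um), sd(rep_tbl$fwhm_y_um), sd(rep_tbl$fwhm_z_um)),
    n = nrow(rep_tbl))
  structure(rep_tbl, class = c("resolution_report", class(rep_tbl)),
            summary = summary, excluded = excluded, method = method)
}

#' @export
print.resolution_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<resolution_report> %d beads (%d excluded), method '%s'\n",
              s$n[1], attr(x, "excluded"), attr(x, "method")))
  for (i in 1:3)
    cat(sprintf("  FWHM %s: %.3f +/- %.3f um\n", s$axis[i], s$mean_um[i], s$sd_um[i]))
  invisible(x)
}

#' Estimate the imaging depth from a reconstructed tissue volume
#'
#' Operationalizes "imaging depth" as the deepest depth bin, contiguous from
#' the surface, in which the nuclear contrast-to-noise ratio
#' `(mean nuclear - mean background) / sd background` stays at or above the
#' threshold. Nuclear voxels are those within 0.8x the nuclear radius of a
#' ground-truth center; background voxels are those farther than 2x the
#' radius from every center.
#'
#' @param volume a `volume` (depth = Z).
#' @param nuclei_um tibble of ground-truth nuclei with `x_um`, `y_um`,
#'   `z_um` and `radius_um` (a phantom `$centers` works directly).
#' @param cnr_threshold minimum CNR (default 1).
#' @param bin_um depth bin width (default 5).
#' @return imaging depth in vertical um (the lower edge of the last accepted
#'   bin); attribute `bins` holds the per-bin CNR table.
#' @export
estimate_imaging_depth <- function(volume, nuclei_um, cnr_threshold = 1, bin_um = 5) {
  stopifnot(inherits(volume, "volume"), cnr_threshold > 0)
  if (NROW(nuclei_um) == 0) stop_domain("no ground-truth nuclei supplied")
  pitch <- volume$voxel_pitch_um
  d <- dim(volume$intensity)
  rad <- if ("radius_um" %in% names(nuclei_um)) nuclei_um$radius_um else rep(2.5, NROW(nuclei_um))
  nuc_mask <- array(FALSE, d)
  excl_mask <- array(FALSE, d)
  mark <- function(mask, cx, cy, cz, r) {
    cv <- (c(cx, cy, cz) - volume$origin_um) / pitch
    rv <- r / pitch
    lo <- pmax(floor(cv - rv), 0); hi <- pmin(ceiling(cv + rv), d - 1)
    if (any(lo > hi)) return(mask)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx2 <- ((xs - cv[1]) / rv[1])^2
    dy2 <- ((ys - cv[2]) / rv[2])^2
    dz2 <- ((zs - cv[3]) / rv[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    mask[xs + 1, ys + 1, zs + 1] <- mask[xs + 1, ys + 1, zs + 1] | inside
    mask
  }
  for (i in seq_len(NROW(nuclei_um))) {
    nuc_mask <- mark(nuc_mask, nuclei_um$x_um[i], nuclei_um$y_um[i], nuclei_um$z_um[i],
                     0.8 * rad[i])
    excl_mask <- mark(excl_mask, nuclei_um$x_um[i], nuclei_um$y_um[i], nuclei_um$z_um[i],
                      2 * rad[i])
  }
  z_um <- volume$origin_um[3] + (seq_len(d[3]) - 1) * pitch[3]
  zbin <- floor(z_um / bin_um)
  bins <- sort(unique(zbin))
  rows <- lapply(bins, function(b) {
    ks <- which(zbin == b)
    sl <- volume$intensity[, , ks, drop = FALSE]
    nm <- nuc_mask[, , ks, drop = FALSE]
    bm <- !excl_mask[, , ks, drop = FALSE]
    nuc <- sl[nm & !is.na(sl)]
    bg <- sl[bm & !is.na(sl)]
    cnr <- if (length(nuc) >= 5 && length(bg) >= 20 && sd(bg) > 0)
      (mean(nuc) - mean(bg)) / sd(bg) else NA_real_
    tibble::tibble(bin_lo_um = b * bin_um, bin_hi_um = (b + 1) * bin_um,
                   n_nuclear = length(nuc), n_background = length(bg), cnr = cnr)
  })
  bins_tbl <- do.call(rbind, rows)
  ok <- !is.na(bins_tbl$cnr) & bins_tbl$cnr >= cnr_threshold
  depth <- 0
  for (i in seq_along(ok)) {
    if (!isTRUE(ok[i])) break
    depth <- bins_tbl$bin_hi_um[i]
  }
  structure(depth, bins = bins_tbl)
}

#' Areal imaging throughput
#'
#' Throughput = strip width x frame rate x stage step: the area of fresh
#' specimen surface swept per second.
#'
#' @param strip_width_um strip width (um).
#' @param fps frame rate (1/s).
#' @param step_um stage step per frame (um).
#' @return throughput in mm^2/s.
#' @examples
#' throughput(600, 400, 1)  # 0.24
#' @export
throughput <- function(strip_width_um, fps, step_um) {
  if (strip_width_um <= 0 || step_um <= 0 || fps < 0)
    stop_domain("strip width and step must be positive, fps non-negative")
  strip_width_um * fps * step_um / 1e6
}

#' Acquisition time and data budget for a rectangular area
#'
#' The area is tiled into `ceil(W / strip_width)` strips of
#' `ceil(L / step)` frames each (no inter-strip overlap unless
#' `overlap_frac > 0`); imaging time is frames / fps and the raw data volume
#' is frames x pixels x bytes per pixel, with decimal gigabytes
#' (1 GB = 1e9 bytes).
#'
#' @param area_w_um,area_l_um area width (across strips) and length (along
#'   the stage scan), in um.
#' @param geom an [acquisition_geometry()].
#' @param overlap_frac inter-strip overlap fraction (default 0).
#' @return a one-row tibble: strips, frames, time_s, bytes_per_channel,
#'   gb_per_channel, throughput_mm2_s.
#' @export
acquisition_budget <- function(area_w_um, area_l_um, geom = acquisition_geometry(),
                               overlap_frac = 0) {
  if (area_w_um < 0 || area_l_um < 0) stop_domain("area must be non-negative")
  if (area_w_um == 0 || area_l_um == 0)
    return(tibble::tibble(strips = 0L, frames_per_strip = 0L, frames = 0L,
                          time_s = 0, bytes_per_channel = 0, gb_per_channel = 0,
                          throughput_mm2_s = throughput(geom$strip_width_um, geom$fps, geom$step_um)))
  eff_width <- geom$strip_width_um * (1 - overlap_frac)
  strips <- as.integer(ceiling(area_w_um / eff_width))
  fpstrip <- as.integer(ceiling(area_l_um / geom$step_um))
  frames <- strips * fpstrip
  px <- prod(geom$frame_shape)
  bytes <- frames * px * geom$bytes_per_pixel
  tibble::tibble(strips = strips, frames_per_strip = fpstrip, frames = frames,
                 time_s = frames / geom$fps,
                 bytes_per_channel = bytes, gb_per_channel = bytes / 1e9,
                 throughput_mm2_s = throughput(geom$strip_width_um, geom$fps, geom$step_um))
}

#' Rounded reporting of an acquisition budget
#'
#' Reports the budget the way it is quoted in practice: imaging time rounded
#' to whole minutes, and the per-channel data size recomputed from that
#' rounded time (`minutes x 60 s x fps` frames times bytes per frame),
#' rounded to whole decimal gigabytes. For 1 cm^2 at the default geometry
#' this yields 7 min and 318 GB per channel.
#'
#' @param budget a tibble from [acquisition_budget()].
#' @param geom the geometry used for the budget.
#' @return a one-row tibble: time_min, frames_reported, gb_per_channel,
#'   throughput_mm2_s.
#' @export
budget_report <- function(budget, geom = acquisition_geometry()) {
  time_min <- round(budget$time_s / 60)
  frames_rep <- time_min * 60 * geom$fps
  bytes <- frames_rep * prod(geom$frame_shape) * geom$bytes_per_pixel
  tibble::tibble(time_min = time_min, frames_reported = frames_rep,
                 gb_per_channel = round(bytes / 1e9),
                 throughput_mm2_s = budget$throughput_mm2_s)
}
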