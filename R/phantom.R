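#' Synthetic specimen specification
#'
#' Describes a seeded synthetic specimen: a bead grid for resolution
#' metrology or one of the tissue-like presets that emulate the structures
#' the microscope is used on. Two voxel fields are generated: a fluorophore
#' density (nuclear labelling) and an SHG-scatterer density (fibrillar
#' collagen). Lengths are in um; the z axis is depth below the tissue
#' surface, positive downward.
#'
#' Presets:
#' \describe{
#'   \item{beads}{sub-resolution fluorescent microspheres (default 0.5 um) in
#'     a clear gel, for point-spread-function measurement.}
#'   \item{skin}{a nucleus-dense epidermis over a sparser dermis; collagen
#'     (SHG) strictly below the epidermis-dermis boundary.}
#'   \item{bcc_nest}{dermis with ellipsoidal tumour-cell nests whose nuclear
#'     number density is a controlled multiple of the background.}
#'   \item{pancreas_normal}{clusters of small acinar cell rings.}
#'   \item{pancreas_duct}{a duct: a single ring of cuboidal epithelial
#'     nuclei surrounded by dense SHG-expressing fibrous tissue.}
#'   \item{pdac}{irregular, distorted gland rings amid strong desmoplastic
#'     SHG stroma.}
#'   \item{prostate_gland}{a large gland ring with weak SHG between glands.}
#' }
#'
#' @param preset one of the preset names above.
#' @param dims_um volume extent (x, y, z) in um.
#' @param voxel_pitch_um isotropic voxel pitch (um); default 0.1 for beads,
#'   0.5 for tissue.
#' @param ... preset parameters overriding the defaults, e.g. `n_beads`,
#'   `bead_diameter_um`, `epidermis_um`, `wall_cells`, `duct_radius_um`,
#'   `nucleus_radius_um`, `labeling` ("uniform" or "membrane_bright"),
#'   `nest_density_ratio`, `n_fibers`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("beads", "skin", "bcc_nest", "pancreas_normal",
                                    "pancreas_duct", "pdac", "prostate_gland"),
                         dims_um = NULL, voxel_pitch_um = NULL, ...) {
  preset <- match.arg(preset)
  defaults <- list(
    beads = list(dims_um = c(16, 16, 8), voxel_pitch_um = 0.1, n_beads = 9,
                 bead_diameter_um = 0.5, bead_intensity = 1000,
                 arrangement = "random", min_sep_um = 3),
    skin = list(dims_um = c(40, 24, 90), voxel_pitch_um = 0.5, epidermis_um = 15,
                nucleus_radius_um = 2.5, epi_sep_um = 5.5, dermis_sep_um = 8,
                nuclear_intensity = 1, labeling = "uniform", n_fibers = 40,
                fiber_intensity = 1),
    bcc_nest = list(dims_um = c(60, 40, 40), voxel_pitch_um = 0.5,
                    nucleus_radius_um = 2, n_nests = 2, nest_radius_um = 10,
                    nest_density_ratio = 4, background_sep_um = 10,
                    nuclear_intensity = 1, labeling = "uniform", n_fibers = 20,
                    fiber_intensity = 1),
    pancreas_normal = list(dims_um = c(60, 60, 30), voxel_pitch_um = 0.5,
                           n_acini = 5, acinus_radius_um = 8, cells_per_acinus = 8,
                           nucleus_radius_um = 2.2, nuclear_intensity = 1,
                           labeling = "membrane_bright", membrane_contrast = 3,
                           n_fibers = 10, fiber_intensity = 0.5),
    pancreas_duct = list(dims_um = c(60, 60, 30), voxel_pitch_um = 0.5,
                         duct_radius_um = 15, wall_cells = 24,
                         nucleus_radius_um = 2.2, nuclear_intensity = 1,
                         labeling = "membrane_bright", membrane_contrast = 3,
                         collagen_margin_um = 4, n_fibers = 40, fiber_intensity = 1),
    pdac = list(dims_um = c(80, 80, 30), voxel_pitch_um = 0.5, n_glands = 4,
                gland_radius_um = 12, wall_cells = 20, irregularity = 0.45,
                nucleus_radius_um = 2.6, nuclear_intensity = 1,
                labeling = "membrane_bright", membrane_contrast = 3,
                n_fibers = 80, fiber_intensity = 1.5),
    prostate_gland = list(dims_um = c(90, 90, 30), voxel_pitch_um = 0.5,
                          gland_radius_um = 30, wall_cells = 40,
                          nucleus_radius_um = 2.4, nuclear_intensity = 1,
                          labeling = "uniform", n_fibers = 15, fiber_intensity = 0.4)
  )[[preset]]
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop_domain("unknown parameters for preset '", preset, "': ",
                               paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (!is.null(dims_um)) defaults$dims_um <- dims_um
  if (!is.null(voxel_pitch_um)) defaults$voxel_pitch_um <- voxel_pitch_um
  lens <- unlist(defaults[grepl("_um$", names(defaults))])
  if (any(lens <= 0)) stop_domain("all lengths must be positive")
  structure(c(list(preset = preset), defaults), class = "phantom_spec")
}

new_phantom <- function(fluor, shg, pitch, spec, seed, centers) {
  structure(list(fluor = fluor, shg = shg,
                 voxel_pitch_um = rep(pitch, length.out = 3),
                 surface_z_um = 0,
                 centers = centers,
                 provenance = list(preset = spec$preset, spec = unclass(spec),
                                   seed = seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$fluor)
  cat(sprintf("<phantom> preset '%s' | %d x %d x %d voxels @ %g um | %d objects\n",
              x$provenance$preset, d[1], d[2], d[3], x$voxel_pitch_um[1],
              nrow(x$centers)))
  invisible(x)
}

# Dart-throwing Poisson-disc placement: uniform candidates inside [lo, hi]
# per axis, accepted when at least `min_sep` from all accepted points.
poisson_disc <- function(n, lo, hi, min_sep, max_attempts = 20000L) {
  pts <- matrix(NA_real_, 0, 3)
  if (n <= 0 || any(hi <= lo)) return(pts)
  attempts <- 0L
  while (nrow(pts) < n && attempts < max_attempts) {
    cand <- lo + runif(3) * (hi - lo)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep)
      pts <- rbind(pts, cand)
    attempts <- attempts + 1L
  }
  if (nrow(pts) < n)
    warning(sprintf("poisson-disc placement achieved %d of %d points", nrow(pts), n))
  pts
}

# Render a sphere of radius R (um) centred at `center` (um) into `field`
# (modified in place semantics via return). Partial-volume weighting by 4^3
# subvoxel supersampling of boundary voxels. Returns list(field, mass).
render_sphere <- function(field, center, radius, pitch, value = 1,
                          style = c("uniform", "membrane_bright"),
                          membrane_contrast = 3, ss = 4L) {
  style <- match.arg(style)
  d <- dim(field)
  cv <- center / pitch  # 0-based voxel coords
  rv <- radius / pitch
  lo <- pmax(floor(cv - rv - 1), 0)
  hi <- pmin(ceiling(cv + rv + 1), d - 1)
  if (any(lo > hi)) return(list(field = field, mass = 0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  grid <- expand.grid(x = xs, y = ys, z = zs)
  dx <- grid$x - cv[1]; dy <- grid$y - cv[2]; dz <- grid$z - cv[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  vals <- numeric(nrow(grid))
  inner <- dist <= rv - 1
  outer_ <- dist >= rv + 1
  edge <- !inner & !outer_
  if (style == "uniform") {
    vals[inner] <- value
    if (any(edge)) {
      off <- (seq_len(ss) - 0.5) / ss - 0.5
      sub <- as.matrix(expand.grid(off, off, off))
      ei <- which(edge)
      cover <- numeric(length(ei))
      for (m in seq_len(nrow(sub))) {
        dd <- sqrt((dx[ei] + sub[m, 1])^2 + (dy[ei] + sub[m, 2])^2 + (dz[ei] + sub[m, 3])^2)
        cover <- cover + (dd <= rv)
      }
      vals[ei] <- value * cover / nrow(sub)
    }
  } else {
    # membrane-bright nucleus: dim core, bright shell peaking at the boundary
    core <- value / membrane_contrast
    shell_sig <- max(rv * 0.18, 0.5)
    inside <- dist <= rv + 0.5
    vals[inside] <- core + (value - core) * exp(-(dist[inside] - rv * 0.85)^2 / (2 * shell_sig^2))
    ramp <- dist > rv - 0.5 & dist <= rv + 0.5
    vals[ramp] <- vals[ramp] * (rv + 0.5 - dist[ramp])
  }
  idx <- 1 + grid$x + grid$y * d[1] + grid$z * d[1] * d[2]
  field[idx] <- field[idx] + vals
  list(field = field, mass = sum(vals))
}

# Deposit anisotropic line segments (collagen fibres) then blur by 1 voxel.
render_fibers <- function(shg, n, pitch, z_range_um, length_um, value,
                          orientation_spread = 0.3) {
  d <- dim(shg)
  ext <- d * pitch
  margin <- 3 * pitch
  deposit <- array(0, d)
  for (f in seq_len(n)) {
    theta <- runif(1, 0, 2 * pi)
    dzdir <- rnorm(1, 0, orientation_spread)
    dir <- c(cos(theta), sin(theta), dzdir)
    dir <- dir / sqrt(sum(dir^2))
    start <- c(runif(1, margin, ext[1] - margin),
               runif(1, margin, ext[2] - margin),
               runif(1, z_range_um[1] + margin, z_range_um[2] - margin))
    steps <- seq(0, length_um, by = pitch / 2)
    pts <- t(start + outer(dir, steps))
    vox <- round(pts / pitch)
    ok <- vox[, 1] >= 2 & vox[, 1] <= d[1] - 3 &
          vox[, 2] >= 2 & vox[, 2] <= d[2] - 3 &
          vox[, 3] >= (z_range_um[1] / pitch + 2) & vox[, 3] <= d[3] - 3 &
          vox[, 3] * pitch <= z_range_um[2] - 2 * pitch
    vox <- vox[ok, , drop = FALSE]
    if (!nrow(vox)) next
    idx <- 1 + vox[, 1] + vox[, 2] * d[1] + vox[, 3] * d[1] * d[2]
    deposit[idx] <- deposit[idx] + value
  }
  blur3d(deposit, 1)
}

#' Generate a bead phantom
#'
#' Renders sub-resolution microspheres as uniform spheres with
#' partial-volume-weighted edges (4^3 subvoxel supersampling), and returns
#' the ground-truth bead centers alongside the voxel data so downstream
#' metrology never has to re-detect them.
#'
#' @param spec a `phantom_spec` with preset "beads".
#' @param seed integer seed; identical (spec, seed) gives bit-identical output.
#' @return a `phantom`; `$centers` holds one row per bead with its integrated
#'   mass.
#' @export
generate_beads <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), spec$preset == "beads")
  pitch <- spec$voxel_pitch_um
  d <- as.integer(round(spec$dims_um / pitch))
  fluor <- array(0, d)
  shg <- array(0, d)
  radius <- spec$bead_diameter_um / 2
  if (radius < pitch / 2)
    stop_domain("bead diameter below one voxel; reduce the voxel pitch")
  centers <- tibble::tibble(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                            radius_um = numeric(0), channel = character(0),
                            structure = character(0), mass = numeric(0))
  if (spec$n_beads > 0) {
    margin <- radius + 2 * pitch
    pts <- with_seed(seed, {
      if (identical(spec$arrangement, "grid")) {
        nside <- ceiling(spec$n_beads^(1 / 3))
        g <- expand.grid(x = seq_len(nside), y = seq_len(nside), z = seq_len(nside))
        g <- as.matrix(g[seq_len(spec$n_beads), ])
        sweep(sweep(g - 0.5, 2, spec$dims_um / nside, "*"), 2, 0, "+")
      } else {
        poisson_disc(spec$n_beads, rep(margin, 3), spec$dims_um - margin,
                     spec$min_sep_um)
      }
    })
    overlap <- nrow(pts) > 1 &&
      min(stats::dist(pts)) < spec$bead_diameter_um
    if (overlap) warning("bead density forces overlapping spheres; overlaps are summed")
    for (i in seq_len(nrow(pts))) {
      res <- render_sphere(fluor, pts[i, ], radius, pitch, spec$bead_intensity)
      fluor <- res$field
      centers <- rbind(centers, tibble::tibble(
        x_um = pts[i, 1], y_um = pts[i, 2], z_um = pts[i, 3],
        radius_um = radius, channel = "fluor", structure = "bead",
        mass = res$mass))
    }
  }
  new_phantom(fluor, shg, pitch, spec, seed, centers)
}

#' Generate a tissue-like phantom
#'
#' Builds the preset-specific nuclear (fluorescence) and collagen (SHG)
#' fields. Nuclear positions use Poisson-disc sampling with a minimum
#' separation of one nuclear diameter, so densely packed regions stay free of
#' unrealistic overlaps while remaining fully seeded. Preset guarantees:
#' skin has zero SHG above the epidermis-dermis boundary; duct and gland
#' presets place exactly `wall_cells` nucleus centers on the ring;
#' `bcc_nest` nests have a nuclear number density a controlled multiple of
#' background; membrane-bright labelling peaks at the nuclear boundary shell.
#'
#' @param spec a `phantom_spec` with a tissue preset.
#' @param seed integer seed.
#' @return a `phantom` with ground-truth `$centers`.
#' @export
generate_tissue <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), spec$preset != "beads")
  pitch <- spec$voxel_pitch_um
  d <- as.integer(round(spec$dims_um / pitch))
  if (any(d < 8))
    stop_domain("grid too small for preset '", spec$preset,
                "': need at least ", paste(8 * pitch, collapse = " x "), " um per axis")
  fluor <- array(0, d)
  shg <- array(0, d)
  rows <- list()
  style <- if (!is.null(spec$labeling)) spec$labeling else "uniform"
  rnuc <- spec$nucleus_radius_um
  add_nuclei <- function(pts, structure, value = spec$nuclear_intensity) {
    for (i in seq_len(nrow(pts))) {
      res <- render_sphere(fluor, pts[i, ], rnuc, pitch, value, style = style,
                           membrane_contrast = if (!is.null(spec$membrane_contrast))
                             spec$membrane_contrast else 3)
      fluor <<- res$field
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        x_um = pts[i, 1], y_um = pts[i, 2], z_um = pts[i, 3],
        radius_um = rnuc, channel = "fluor", structure = structure,
        mass = res$mass)
    }
  }
  ring_points <- function(center, radius, ncells, plane_z, jitter = 0) {
    ang <- 2 * pi * (seq_len(ncells) - 1) / ncells
    cbind(center[1] + radius * cos(ang),
          center[2] + radius * sin(ang),
          plane_z + if (jitter > 0) rnorm(ncells, 0, jitter) else 0)
  }
  ext <- spec$dims_um
  margin <- rnuc + 2 * pitch
  with_seed(seed, {
    switch(spec$preset,
      skin = {
        eb <- spec$epidermis_um
        # dart throwing saturates near ~55% of the close-packing density
        epi <- poisson_disc(
          n = floor(0.5 * prod(ext[1:2]) * (eb - 2 * margin) / spec$epi_sep_um^3),
          lo = c(margin, margin, margin), hi = c(ext[1] - margin, ext[2] - margin, eb - margin),
          min_sep = spec$epi_sep_um)
        add_nuclei(epi, "epidermis_nucleus")
        derm <- poisson_disc(
          n = floor(0.5 * prod(ext[1:2]) * (ext[3] - eb - 2 * margin) / spec$dermis_sep_um^3),
          lo = c(margin, margin, eb + margin), hi = ext - margin,
          min_sep = spec$dermis_sep_um)
        add_nuclei(derm, "dermis_nucleus")
        # collagen only below the boundary; fibre cores kept >= 3 voxels below
        # it and the blur kernel is truncated at 3 voxels, so the field is
        # exactly zero above the boundary by construction
        shg <- shg + render_fibers(shg * 0, spec$n_fibers, pitch,
                                    c(eb + 3 * pitch, ext[3]),
                                    length_um = ext[1] / 2,
                                    value = spec$fiber_intensity)
      },
      bcc_nest = {
        nests <- poisson_disc(spec$n_nests, rep(spec$nest_radius_um + margin, 3),
                              ext - spec$nest_radius_um - margin,
                              2.2 * spec$nest_radius_um)
        in_nest <- function(p) {
          if (!nrow(nests)) return(FALSE)
          any(sqrt(colSums((t(nests) - p)^2)) <= spec$nest_radius_um)
        }
        sep_bg <- spec$background_sep_um
        n_bg <- floor(0.5 * prod(ext) / sep_bg^3)
        bg <- poisson_disc(n_bg, rep(margin, 3), ext - margin, sep_bg)
        keep <- !apply(bg, 1, in_nest)
        add_nuclei(bg[keep, , drop = FALSE], "background_nucleus")
        v_nest <- 4 / 3 * pi * spec$nest_radius_um^3
        dens_bg <- sum(keep) / (prod(ext) - nrow(nests) * v_nest)
        # fill each nest to the requested multiple of the achieved background
        # number density; candidates are darts inside the nest sphere
        r_eff <- spec$nest_radius_um - rnuc
        for (i in seq_len(nrow(nests))) {
          n_in <- ceiling(spec$nest_density_ratio * dens_bg * v_nest)
          sep_nest <- max(2 * rnuc,
                          (0.5 * 4 / 3 * pi * r_eff^3 / n_in)^(1 / 3))
          pts <- matrix(NA_real_, 0, 3)
          tries <- 0L
          while (nrow(pts) < n_in && tries < 20000L) {
            u <- runif(3, -1, 1)
            tries <- tries + 1L
            if (sum(u^2) > 1) next
            cand <- nests[i, ] + u * r_eff
            if (nrow(pts) == 0 ||
                min(sqrt(colSums((t(pts) - cand)^2))) >= sep_nest)
              pts <- rbind(pts, cand)
          }
          add_nuclei(pts, "nest_nucleus")
        }
        shg <- shg + render_fibers(shg * 0, spec$n_fibers, pitch,
                                   c(0, ext[3]), ext[1] / 2, spec$fiber_intensity)
      },
      pancreas_normal = {
        rm_xy <- spec$acinus_radius_um + margin
        acs <- poisson_disc(spec$n_acini,
                            c(rm_xy, rm_xy, margin),
                            c(ext[1] - rm_xy, ext[2] - rm_xy, ext[3] - margin),
                            2.1 * spec$acinus_radius_um)
        for (i in seq_len(nrow(acs)))
          add_nuclei(ring_points(acs[i, ], spec$acinus_radius_um,
                                 spec$cells_per_acinus, acs[i, 3]), "acinar_nucleus")
        shg <- shg + render_fibers(shg * 0, spec$n_fibers, pitch,
                                    c(0, ext[3]), ext[1] / 3, spec$fiber_intensity)
      },
      pancreas_duct = {
        center <- ext / 2
        pts <- ring_points(center, spec$duct_radius_um, spec$wall_cells, center[3])
        add_nuclei(pts, "duct_wall_nucleus")
        # dense fibrous tissue surrounding the duct
        fib <- render_fibers(shg * 0, spec$n_fibers, pitch, c(0, ext[3]),
                             ext[1] / 2, spec$fiber_intensity)
        xs <- (seq_len(d[1]) - 1) * pitch; ys <- (seq_len(d[2]) - 1) * pitch
        rad2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
        inside <- rad2 <= (spec$duct_radius_um + spec$collagen_margin_um)^2
        for (k in seq_len(d[3])) { sl <- fib[, , k]; sl[inside] <- 0; fib[, , k] <- sl }
        shg <- shg + fib
      },
      pdac = {
        rm_xy <- spec$gland_radius_um * (1 + spec$irregularity) + margin
        gl <- poisson_disc(spec$n_glands,
                           c(rm_xy, rm_xy, margin),
                           c(ext[1] - rm_xy, ext[2] - rm_xy, ext[3] - margin),
                           2.1 * spec$gland_radius_um)
        for (i in seq_len(nrow(gl))) {
          ncl <- spec$wall_cells
          ang <- 2 * pi * (seq_len(ncl) - 1) / ncl
          ph <- runif(2, 0, 2 * pi)
          rmod <- spec$gland_radius_um *
            (1 + spec$irregularity * (0.6 * sin(2 * ang + ph[1]) + 0.4 * sin(3 * ang + ph[2])))
          pts <- cbind(gl[i, 1] + rmod * cos(ang), gl[i, 2] + rmod * sin(ang), gl[i, 3])
          pts[, 1] <- pmin(pmax(pts[, 1], margin), ext[1] - margin)
          pts[, 2] <- pmin(pmax(pts[, 2], margin), ext[2] - margin)
          add_nuclei(pts, "cancer_gland_nucleus")
        }
        shg <- shg + render_fibers(shg * 0, spec$n_fibers, pitch,
                                    c(0, ext[3]), ext[1] / 2, spec$fiber_intensity)
      },
      prostate_gland = {
        center <- ext / 2
        pts <- ring_points(center, spec$gland_radius_um, spec$wall_cells, center[3])
        add_nuclei(pts, "gland_wall_nucleus")
        shg <- shg + render_fibers(shg * 0, spec$n_fibers, pitch,
                                    c(0, ext[3]), ext[1] / 2, spec$fiber_intensity)
      })
  })
  centers <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                   radius_um = numeric(0), channel = character(0),
                   structure = character(0), mass = numeric(0))
  new_phantom(fluor, shg, pitch, spec, seed, centers)
}

#' Generate a phantom from a specification
#'
#' Dispatches to [generate_beads()] or [generate_tissue()] by preset.
#'
#' @inheritParams generate_tissue
#' @return a `phantom`.
#' @export
generate_phantom <- function(spec, seed = 1) {
  if (spec$preset == "beads") generate_beads(spec, seed) else generate_tissue(spec, seed)
}
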