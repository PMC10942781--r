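#' Crop an image into fixed-size patches
#'
#' Row-major tiling at the given stride; partial edge tiles are dropped and
#' their count recorded in the manifest metadata. This is the patch pipeline
#' used to assemble style-transfer training sets (512 x 512 by default).
#'
#' @param image numeric matrix.
#' @param size patch side length in pixels (default 512).
#' @param stride tiling stride (default `size`, i.e. non-overlapping).
#' @return a `patch_set`: list with `patches` (list of size x size matrices),
#'   a `manifest` tibble (id, row0, col0, tag, parent) and `dropped` (count
#'   of partial edge tiles).
#' @export
extract_patches <- function(image, size = 512L, stride = size) {
  stopifnot(is.matrix(image), size >= 1, stride >= 1)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < size || nc < size)
    stop_domain(sprintf("image %d x %d smaller than patch size %d", nr, nc, size))
  r0 <- seq(0L, nr - size, by = stride)
  c0 <- seq(0L, nc - size, by = stride)
  n_rows_total <- length(seq(0L, nr - 1L, by = stride))
  n_cols_total <- length(seq(0L, nc - 1L, by = stride))
  dropped <- n_rows_total * n_cols_total - length(r0) * length(c0)
  patches <- vector("list", length(r0) * length(c0))
  rows <- integer(0); cols <- integer(0)
  k <- 0L
  for (i in r0) for (j in c0) {
    k <- k + 1L
    patches[[k]] <- image[(i + 1):(i + size), (j + 1):(j + size)]
    rows[k] <- i; cols[k] <- j
  }
  manifest <- tibble::tibble(id = seq_len(k), row0 = rows, col0 = cols,
                             tag = "identity", parent = seq_len(k))
  structure(list(patches = patches, manifest = manifest, dropped = dropped,
                 size = size, stride = stride),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d (%d edge tiles dropped)\n",
              length(x$patches), x$size, x$size, x$dropped))
  invisible(x)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_aug <- function(m, tag) {
  switch(tag,
         identity = m,
         rot90 = rot90cw(m),
         rot180 = rot90cw(rot90cw(m)),
         rot270 = rot90cw(rot90cw(rot90cw(m))),
         flip_v = m[nrow(m):1, , drop = FALSE],
         flip_h = m[, ncol(m):1, drop = FALSE],
         stop_domain("unknown augmentation tag: ", tag))
}

#' Six-fold patch augmentation
#'
#' Expands every patch into the fixed, reproducible sequence
#' identity, rot90, rot180, rot270, flip_v, flip_h - exactly six outputs per
#' input, the factor that turns 2,387 source crops into 14,322 training
#' patches.
#'
#' @param ps a `patch_set`.
#' @return a `patch_set` with `6 * n` patches; each manifest row's `parent`
#'   and `tag` trace it to its source crop.
#' @export
augment_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  tags <- c("identity", "rot90", "rot180", "rot270", "flip_v", "flip_h")
  n <- length(ps$patches)
  patches <- vector("list", 6L * n)
  rows <- list()
  k <- 0L
  for (i in seq_len(n)) {
    for (tg in tags) {
      k <- k + 1L
      patches[[k]] <- apply_aug(ps$patches[[i]], tg)
      rows[[k]] <- tibble::tibble(id = k, row0 = ps$manifest$row0[i],
                                  col0 = ps$manifest$col0[i], tag = tg, parent = i)
    }
  }
  structure(list(patches = patches, manifest = do.call(rbind, rows),
                 dropped = ps$dropped, size = ps$size, stride = ps$stride),
            class = "patch_set")
}

#' Stain configuration for the deterministic virtual H&E renderer
#'
#' Per-stain RGB optical-density vectors following the standard H&E
#' color-deconvolution basis: hematoxylin (applied to the nuclear
#' fluorescence channel) and eosin (applied to the SHG/stromal channel).
#'
#' @param od_hematoxylin,od_eosin length-3 non-negative RGB optical-density
#'   vectors.
#' @param scale_nuclear,scale_stromal per-channel concentration scalings.
#' @param white length-3 white level of the simulated brightfield.
#' @param normalize normalize the OD vectors to unit length (default FALSE,
#'   keeping the conventional published values).
#' @return a `stain_config`.
#' @export
stain_config <- function(od_hematoxylin = c(0.650, 0.704, 0.286),
                         od_eosin = c(0.070, 0.990, 0.110),
                         scale_nuclear = 1, scale_stromal = 1,
                         white = c(1, 1, 1), normalize = FALSE) {
  if (any(od_hematoxylin < 0) || any(od_eosin < 0))
    stop_domain("optical-density vectors must be non-negative")
  if (normalize) {
    od_hematoxylin <- od_hematoxylin / sqrt(sum(od_hematoxylin^2))
    od_eosin <- od_eosin / sqrt(sum(od_eosin^2))
  }
  structure(list(od_hematoxylin = od_hematoxylin, od_eosin = od_eosin,
                 scale_nuclear = scale_nuclear, scale_stromal = scale_stromal,
                 white = white),
            class = "stain_config")
}

#' Deterministic virtual H&E rendering of a two-channel image
#'
#' A pixel-wise Beer-Lambert transmission model: the nuclear channel acts as
#' a hematoxylin concentration and the SHG channel as an eosin
#' concentration, so each RGB band transmits
#' `T_b = white_b * exp(-(c_nuc OD_H,b + c_str OD_E,b))`. Nuclei come out
#' purple, collagenous stroma pink, and empty pixels white - a deterministic
#' stand-in at the point where a trained style-transfer network would
#' otherwise take over (see the methods vignette).
#'
#' Channels are rescaled to [0, 1] by their own maxima before scaling, so
#' the rendering depends only on relative contrast.
#'
#' @param fluor nuclear-channel image (matrix).
#' @param shg SHG-channel image, same shape.
#' @param cfg a [stain_config()].
#' @return an array (rows x cols x 3) of RGB values in [0, 1].
#' @export
virtual_he <- function(fluor, shg, cfg = stain_config()) {
  stopifnot(inherits(cfg, "stain_config"))
  if (!all(dim(fluor) == dim(shg)))
    stop_domain("fluorescence and SHG images must have identical shape")
  norm01 <- function(m) {
    m[is.na(m)] <- 0
    mx <- max(m)
    if (mx > 0) m / mx else m
  }
  cn <- cfg$scale_nuclear * norm01(fluor)
  cs <- cfg$scale_stromal * norm01(shg)
  out <- array(0, c(nrow(fluor), ncol(fluor), 3))
  for (b in 1:3)
    out[, , b] <- cfg$white[b] *
      exp(-(cn * cfg$od_hematoxylin[b] + cs * cfg$od_eosin[b]))
  out
}
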