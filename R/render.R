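#' Render a culture to raster images
#'
#' Draws every branch polyline onto a grayscale field at the requested line
#' width (a square brush of Chebyshev radius `floor(line_width/2)` around the
#' rasterized centerline), adds Gaussian noise, and also returns a noise-free
#' per-cell label image recording ground-truth pixel ownership; pixels covered
#' by more than one cell carry the reserved multi-label value 65535.
#'
#' @param culture an `astro_culture`.
#' @param line_width brush width in pixels (>= 1).
#' @param noise_sd s.d. of additive Gaussian intensity noise.
#' @param background background intensity.
#' @param foreground branch intensity before noise.
#' @param seed optional seed for the noise draw (noise is the only randomness).
#' @return list with `image` (numeric matrix, nrow = field height, intensities
#'   clipped to >= 0), `labels` (integer matrix; 0 background, cell id, or
#'   65535 for overlap), `threshold_hint` (midpoint of background and
#'   foreground).
#' @export
render_image <- function(culture, line_width = 3, noise_sd = 0,
                         background = 0, foreground = 200, seed = NULL) {
  stopifnot(inherits(culture, "astro_culture"), line_width >= 1)
  w <- culture$params$field_size[1]
  h <- culture$params$field_size[2]
  nr <- as.integer(round(h)); nc <- as.integer(round(w))
  rad <- floor(line_width / 2)

  labels <- matrix(0L, nr, nc)
  multi <- 65535L
  skels <- culture_to_skeletons(culture)
  for (cs in skels) {
    polys <- if (length(cs$polylines)) cs$polylines else
      list(as.matrix(cs$nodes[cs$soma, c("row", "col")]))
    px <- do.call(rbind, lapply(polys, rasterize_polyline))
    px <- px[!duplicated(px[, 1] * 2147483 + px[, 2]), , drop = FALSE]
    if (any(px[, 1] < rad | px[, 1] > nr - 1L - rad |
            px[, 2] < rad | px[, 2] > nc - 1L - rad))
      stop("culture extends outside the field at this line width")
    if (rad > 0) {
      offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
      px <- cbind(rep(px[, 1], nrow(offs)) + rep(offs$dr, each = nrow(px)),
                  rep(px[, 2], nrow(offs)) + rep(offs$dc, each = nrow(px)))
      px <- px[!duplicated(px[, 1] * 2147483 + px[, 2]), , drop = FALSE]
    }
    lin <- px[, 2] * nr + px[, 1] + 1L  # 0-based (row, col) -> R linear index
    old <- labels[lin]
    id <- as.integer(cs$cell_id)
    labels[lin] <- ifelse(old == 0L | old == id, id, multi)
  }

  img <- matrix(background, nr, nc)
  img[labels != 0L] <- foreground
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    img[img < 0] <- 0
  }
  list(image = img, labels = labels,
       threshold_hint = (background + foreground) / 2)
}

#' Write a grayscale or label image as 16-bit TIFF
#'
#' @param image numeric or integer matrix with values in `[0, 65535]`.
#' @param path output file.
#' @export
write_image_tiff <- function(image, path) {
  m <- pmin(pmax(image, 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a TIFF written by [write_image_tiff()] back to the 0..65535 scale
#'
#' @param path TIFF file.
#' @return numeric matrix.
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}
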