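#' Synthetic activity phantoms
#'
#' Procedurally generated 2D tracer-distribution phantoms for testing
#' emission-tomography reconstruction. `make_brain_phantom()` emulates the
#' classic digital brain phantom: an elliptical head with a gray-matter
#' cortex ring, a white-matter interior at lower uptake (gray:white roughly
#' 4:1, typical of FDG PET), and three hot "tumor" discs of distinct
#' diameters — the smallest probes the effective resolution of a
#' reconstruction. `make_abdomen_phantom()` emulates an abdominal
#' radioisotope distribution with three labelled soft-tissue regions of
#' differing uptake. `make_disc_phantom()` is a uniform centred disc used as
#' an analytic fixture.
#'
#' All generators are pure functions of `(size, seed)`: repeated calls are
#' bit-identical. The default phantoms are piecewise-constant and fully
#' deterministic; `seed` is accepted for configuration uniformity across the
#' pipeline and reserved for stochastic texture variants. Images are
#' returned on the `[0, 1]` display scale with air (outside the body
#' outline) exactly 0.
#'
#' @param size Grid side length in pixels (square grid), or a length-2
#'   vector `(rows, cols)`. Must be at least 32 so the three tumors fit
#'   without overlap.
#' @param seed Integer seed (determinism contract; see Details).
#' @param pixel_size_mm Physical pixel size in mm.
#' @return An [activity_image()]. The brain phantom carries attributes
#'   `levels` (named intensity levels) and `tumor_centers` (matrix of
#'   row/col/radius, in pixels). The abdomen phantom carries attribute
#'   `rois`: a named list of logical masks partitioning the nonzero support.
#' @examples
#' ph <- make_brain_phantom(96)
#' range(ph)
#' attr(ph, "tumor_centers")
#' @export
make_brain_phantom <- function(size = c(192, 192), seed = 0, pixel_size_mm = 3) {
  shape <- phantom_shape(size)
  nr <- shape[1]; nc <- shape[2]
  if (min(shape) < 32) {
    stopf("grid %dx%d too small to place three non-overlapping tumors (need >= 32)", nr, nc)
  }
  g <- pixel_grid(nr, nc)

  # geometry as fractions of the grid so any size >= 32 scales consistently
  head_a <- 0.375 * nc; head_b <- 0.455 * nr    # outer head ellipse semi-axes
  white_a <- 0.25 * nc; white_b <- 0.315 * nr   # white-matter core
  head <- ellipse_mask(g, 0, 0, head_a, head_b)
  white <- ellipse_mask(g, 0, 0, white_a, white_b)

  # pre-normalization uptake: air 0, white 0.25, gray (cortex ring) 1.0,
  # tumors 1.2-1.5; rescaled below so the display range is [0, 1]
  x <- matrix(0, nr, nc)
  x[head] <- 1.0
  x[white] <- 0.25

  tum <- tumor_layout(nr, nc)
  vals <- c(1.5, 1.35, 1.2)
  for (k in seq_len(nrow(tum))) {
    m <- disc_mask(g, tum[k, "row"], tum[k, "col"], tum[k, "radius"])
    x[m] <- vals[k]
  }
  x <- x / max(x)

  out <- activity_image(x, pixel_size_mm = pixel_size_mm)
  attr(out, "levels") <- c(air = 0, white = 0.25, gray = 1, tumor = 1.5) / 1.5
  attr(out, "tumor_centers") <- tum
  out
}

# fixed interior tumor positions (fractions of the grid), diameters spanning
# ~3-12 px at the reference 192-pixel size so the smallest disc probes
# resolution; radii scale linearly with grid size, floored at 1 px
tumor_layout <- function(nr, nc) {
  frac <- cbind(
    row = c(0.375, 0.570, 0.600),
    col = c(0.500, 0.365, 0.640),
    radius = c(6, 3, 1.5) / 192
  )
  tum <- cbind(
    row = frac[, "row"] * nr - (nr + 1) / 2,
    col = frac[, "col"] * nc - (nc + 1) / 2,
    radius = pmax(frac[, "radius"] * min(nr, nc), 1)
  )
  # centers are offsets from grid center (pixel units)
  d <- sqrt(outer(tum[, "row"], tum[, "row"], "-")^2 +
    outer(tum[, "col"], tum[, "col"], "-")^2)
  sep <- d + diag(Inf, nrow(tum))
  rr <- outer(tum[, "radius"], tum[, "radius"], "+")
  if (any(sep <= rr)) {
    stopf("grid too small: tumor discs would overlap")
  }
  tum
}

#' @rdname make_brain_phantom
#' @export
make_abdomen_phantom <- function(size = c(192, 192), seed = 0, pixel_size_mm = 3) {
  shape <- phantom_shape(size)
  nr <- shape[1]; nc <- shape[2]
  if (min(shape) < 32) stopf("grid %dx%d too small for the abdomen layout (need >= 32)", nr, nc)
  g <- pixel_grid(nr, nc)

  body <- ellipse_mask(g, 0.02 * nr, 0, 0.44 * nc, 0.36 * nr)
  stomach <- ellipse_mask(g, -0.10 * nr, -0.12 * nc, 0.13 * nc, 0.10 * nr)
  liver <- ellipse_mask(g, -0.08 * nr, 0.20 * nc, 0.14 * nc, 0.16 * nr)
  stomach <- stomach & body
  liver <- liver & body & !stomach

  x <- matrix(0, nr, nc)
  x[body] <- 0.3
  x[liver] <- 0.65
  x[stomach] <- 1.0

  out <- activity_image(x, pixel_size_mm = pixel_size_mm)
  attr(out, "rois") <- list(
    soft_tissue = body & !stomach & !liver,
    stomach = stomach,
    liver = liver
  )
  out
}

#' @rdname make_brain_phantom
#' @param radius_px Disc radius in pixels.
#' @param value Activity inside the disc (nonnegative).
#' @export
make_disc_phantom <- function(size = c(64, 64), radius_px = 10, value = 1,
                              pixel_size_mm = 3) {
  shape <- phantom_shape(size)
  nr <- shape[1]; nc <- shape[2]
  if (!is_scalar(value) || value < 0) stopf("disc `value` must be nonnegative")
  if (!is_scalar(radius_px) || radius_px < 0) stopf("`radius_px` must be nonnegative")
  if (2 * radius_px > min(shape)) stopf("disc radius %g does not fit in a %dx%d grid", radius_px, nr, nc)
  g <- pixel_grid(nr, nc)
  x <- matrix(0, nr, nc)
  x[disc_mask(g, 0, 0, radius_px)] <- value
  activity_image(x, pixel_size_mm = pixel_size_mm)
}

phantom_shape <- function(size) {
  if (length(size) == 1L) size <- c(size, size)
  if (length(size) != 2L || any(size < 1) || any(size != round(size))) {
    stopf("`size` must be one or two positive integers")
  }
  as.integer(size)
}

# row/col coordinates of pixel centers, offset from the grid center
pixel_grid <- function(nr, nc) {
  list(
    row = matrix(seq_len(nr) - (nr + 1) / 2, nr, nc),
    col = matrix(rep(seq_len(nc) - (nc + 1) / 2, each = nr), nr, nc)
  )
}

ellipse_mask <- function(g, row0, col0, a_col, b_row) {
  ((g$col - col0) / a_col)^2 + ((g$row - row0) / b_row)^2 <= 1
}

disc_mask <- function(g, row0, col0, radius) {
  (g$col - col0)^2 + (g$row - row0)^2 <= radius^2
}
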