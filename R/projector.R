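#' Parallel-beam acquisition geometry
#'
#' Describes the discrete sampling of the Radon domain: `n_angles`
#' projection angles uniformly spanning \eqn{[0, 180)} degrees (half-open)
#' and `n_bins` radial detector bins per angle, over an `image_shape` grid.
#' The sinogram therefore has \eqn{J = n_{angles} \times n_{bins}} elements
#' and the image \eqn{I = n_x \times n_y} pixels. A PET ring records
#' coincidence pairs, but rebinned parallel-beam sinograms are the standard
#' equivalent representation and are what this package models.
#'
#' @param n_angles Number of projection angles over \eqn{[0, 180)} degrees.
#' @param n_bins Number of radial bins per angle.
#' @param image_shape Length-1 or length-2 integer: image grid (rows, cols).
#' @param pixel_size_mm Image pixel size (mm).
#' @param bin_size_mm Radial bin width (mm); defaults to the pixel size.
#' @return An object of class `ect_geometry`.
#' @examples
#' ect_geometry(n_angles = 120, n_bins = 192, image_shape = 192)
#' @export
ect_geometry <- function(n_angles = 120, n_bins = 192, image_shape = c(192, 192),
                         pixel_size_mm = 3, bin_size_mm = pixel_size_mm) {
  if (!is_count(n_angles) || n_angles < 1) stopf("`n_angles` must be a positive integer")
  if (!is_count(n_bins) || n_bins < 1) stopf("`n_bins` must be a positive integer")
  shape <- phantom_shape(image_shape)
  if (!is_scalar(pixel_size_mm) || pixel_size_mm <= 0) stopf("`pixel_size_mm` must be positive")
  if (!is_scalar(bin_size_mm) || bin_size_mm <= 0) stopf("`bin_size_mm` must be positive")
  geom <- structure(
    list(
      n_angles = as.integer(n_angles),
      n_bins = as.integer(n_bins),
      image_shape = shape,
      pixel_size_mm = as.numeric(pixel_size_mm),
      bin_size_mm = as.numeric(bin_size_mm),
      angles_rad = (seq_len(n_angles) - 1) * pi / n_angles
    ),
    class = "ect_geometry"
  )
  # reject geometries whose closest ray passes outside the image entirely
  half_diag <- sqrt(sum((shape * pixel_size_mm)^2)) / 2
  if (min(abs(bin_centers_mm(geom))) > half_diag) {
    stopf("no detector bin's ray intersects the image: bins miss the grid entirely")
  }
  geom
}

bin_centers_mm <- function(geometry) {
  (seq_len(geometry$n_bins) - (geometry$n_bins + 1) / 2) * geometry$bin_size_mm
}

#' @export
print.ect_geometry <- function(x, ...) {
  cat(sprintf(
    "<ect_geometry> %d angles x %d bins (%.3g mm), image %dx%d (%.3g mm/px)\n",
    x$n_angles, x$n_bins, x$bin_size_mm,
    x$image_shape[1], x$image_shape[2], x$pixel_size_mm
  ))
  invisible(x)
}

#' Discrete system model (projection operator)
#'
#' The system matrix holds entries \eqn{p(i,j)}: the contribution of image
#' pixel \eqn{i} to sinogram bin \eqn{j}, here the exact intersection length
#' (mm) of bin \eqn{j}'s central ray with pixel \eqn{i}, computed by Siddon
#' ray tracing (one ray per bin center per angle). Forward projection is the
#' sparse matrix product \eqn{\hat y(j) = \sum_i x(i) p(i,j)}; back
#' projection is its exact adjoint. The sensitivity image
#' \eqn{s(i) = \sum_j p(i,j)} normalises the MLEM update.
#'
#' Pixels outside the inscribed circle of the grid are excluded from the
#' reconstruction `support` mask (some angles never see them, so their
#' sensitivity is unreliable); they are frozen at zero throughout
#' reconstruction. `bin_support` flags sinogram bins whose ray meets the
#' support at all — bins outside it can never receive signal from a
#' supported image.
#'
#' @param geometry An [ect_geometry()].
#' @return A `system_model`: list with elements `geometry`, `matrix` (a
#'   `dgCMatrix` of dim J x I, J indexed angle-fastest), `sensitivity`
#'   (matrix, image-shaped), `support` (logical matrix), `bin_support`
#'   (logical, length J).
#' @examples
#' m <- build_system_model(ect_geometry(12, 16, image_shape = 16))
#' range(m$sensitivity[m$support])
#' @export
build_system_model <- function(geometry) {
  stopifnot(inherits(geometry, "ect_geometry"))
  A <- siddon_matrix(geometry)
  model_from_matrix(A, geometry)
}

#' @rdname build_system_model
#' @param A A J x I matrix (dense or sparse) of nonnegative weights, J
#'   indexed angle-fastest (`j = angle + (bin-1) * n_angles`), I
#'   column-major over the image grid. Lets tests and custom acquisition
#'   models supply an explicit operator.
#' @param support Optional logical image-shaped matrix; defaults to
#'   `sensitivity > 0`.
#' @export
system_model <- function(A, geometry, support = NULL) {
  stopifnot(inherits(geometry, "ect_geometry"))
  A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  J <- geometry$n_angles * geometry$n_bins
  I <- prod(geometry$image_shape)
  if (!all(dim(A) == c(J, I))) stopf("system matrix must be %d x %d", J, I)
  if (any(A@x < 0)) stopf("system-matrix entries must be nonnegative")
  model_from_matrix(A, geometry, support)
}

model_from_matrix <- function(A, geometry, support = NULL) {
  shape <- geometry$image_shape
  sens <- matrix(Matrix::colSums(A), shape[1], shape[2])
  if (is.null(support)) {
    support <- inscribed_circle_mask(shape) & sens > 0
  } else {
    stopifnot(is.logical(support), all(dim(support) == shape))
    support <- support & sens > 0
  }
  if (!any(support)) stopf("empty reconstruction support: no pixel has positive sensitivity")
  bin_support <- as.vector(A %*% as.numeric(support)) > 0
  structure(
    list(
      geometry = geometry, matrix = A, sensitivity = sens,
      support = support, bin_support = bin_support
    ),
    class = "system_model"
  )
}

inscribed_circle_mask <- function(shape) {
  g <- pixel_grid(shape[1], shape[2])
  r <- min(shape) / 2
  g$row^2 + g$col^2 <= r^2
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf(
    "<system_model> %d bins x %d pixels, %d nonzeros, support %d px\n",
    nrow(x$matrix), ncol(x$matrix), length(x$matrix@x), sum(x$support)
  ))
  invisible(x)
}

# Siddon's algorithm: exact ray-grid intersection lengths, one ray per bin
# center. Image is centered at the origin; x1 runs along columns, x2 along
# rows; angle 0 projects along the x2 (row) axis so the detector coordinate
# is x1. Returns a J x I dgCMatrix with J indexed angle-fastest.
siddon_matrix <- function(geometry) {
  nr <- geometry$image_shape[1]; nc <- geometry$image_shape[2]
  px <- geometry$pixel_size_mm
  s <- bin_centers_mm(geometry)
  # grid plane coordinates (mm)
  planes1 <- ((0:nc) - nc / 2) * px  # x1 (column) boundaries
  planes2 <- ((0:nr) - nr / 2) * px  # x2 (row) boundaries
  n_ang <- geometry$n_angles
  eps <- 1e-12

  ii <- vector("list", n_ang * geometry$n_bins)
  jj <- vector("list", n_ang * geometry$n_bins)
  xx <- vector("list", n_ang * geometry$n_bins)
  k <- 0L
  for (a in seq_len(n_ang)) {
    th <- geometry$angles_rad[a]
    u <- c(-sin(th), cos(th))   # ray direction (x1, x2)
    v <- c(cos(th), sin(th))    # detector axis
    for (b in seq_len(geometry$n_bins)) {
      k <- k + 1L
      p0 <- s[b] * v
      # entry/exit parameters from the two slab intersections
      tlo <- -Inf; thi <- Inf; t1 <- numeric(0); t2 <- numeric(0)
      if (abs(u[1]) > eps) {
        t1 <- (planes1 - p0[1]) / u[1]
        tlo <- max(tlo, min(t1[1], t1[nc + 1]))
        thi <- min(thi, max(t1[1], t1[nc + 1]))
      } else if (p0[1] <= planes1[1] || p0[1] >= planes1[nc + 1]) next
      if (abs(u[2]) > eps) {
        t2 <- (planes2 - p0[2]) / u[2]
        tlo <- max(tlo, min(t2[1], t2[nr + 1]))
        thi <- min(thi, max(t2[1], t2[nr + 1]))
      } else if (p0[2] <= planes2[1] || p0[2] >= planes2[nr + 1]) next
      if (thi - tlo <= eps) next
      tt <- c(t1, t2)
      tt <- tt[tt > tlo & tt < thi]
      tt <- sort(unique(c(tlo, tt, thi)))
      dl <- diff(tt)
      keep <- dl > eps
      if (!any(keep)) next
      tm <- (tt[-1] + tt[-length(tt)])[keep] / 2
      dl <- dl[keep]
      col <- pmin(pmax(floor((p0[1] + tm * u[1]) / px + nc / 2), 0), nc - 1)
      row <- pmin(pmax(floor((p0[2] + tm * u[2]) / px + nr / 2), 0), nr - 1)
      ii[[k]] <- rep.int(a + (b - 1L) * n_ang, length(dl))
      jj[[k]] <- row + col * nr + 1
      xx[[k]] <- dl
    }
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_ang * geometry$n_bins, nr * nc)
  )
}

#' Forward and back projection
#'
#' `forward_project()` computes the expected sinogram
#' \eqn{\hat y(j) = \sum_i x(i)\, p(i,j)} of an activity image;
#' `back_project()` applies the adjoint, \eqn{\sum_j y(j)\, p(i,j)} per
#' pixel. Back-projecting an all-ones sinogram yields the sensitivity image.
#'
#' @param model A [build_system_model()] result.
#' @param image An [activity_image()] (or bare matrix) matching the model's
#'   image shape; must be nonnegative.
#' @return `forward_project()`: a [sinogram()] of expected counts.
#'   `back_project()`: an image-shaped numeric matrix.
#' @examples
#' geom <- ect_geometry(8, 16, image_shape = 16)
#' m <- build_system_model(geom)
#' y <- forward_project(m, make_disc_phantom(16, radius_px = 5))
#' bp <- back_project(m, y)
#' @export
forward_project <- function(model, image) {
  stopifnot(inherits(model, "system_model"))
  x <- unclass_matrix(image)
  shape <- model$geometry$image_shape
  if (!all(dim(x) == shape)) {
    stopf("image is %dx%d but the model expects %dx%d", nrow(x), ncol(x), shape[1], shape[2])
  }
  if (any(x < 0)) stopf("activity image must be nonnegative")
  y <- as.vector(model$matrix %*% as.vector(x))
  sinogram(matrix(y, model$geometry$n_angles, model$geometry$n_bins), model$geometry)
}

#' @rdname forward_project
#' @param sino A [sinogram()] (or bare `n_angles x n_bins` matrix).
#' @export
back_project <- function(model, sino) {
  stopifnot(inherits(model, "system_model"))
  y <- unclass_matrix(sino)
  g <- model$geometry
  if (!all(dim(y) == c(g$n_angles, g$n_bins))) {
    stopf("sinogram is %dx%d but the model expects %dx%d", nrow(y), ncol(y), g$n_angles, g$n_bins)
  }
  matrix(as.vector(Matrix::crossprod(model$matrix, as.vector(y))),
    g$image_shape[1], g$image_shape[2])
}

#' Sinograms
#'
#' A sinogram stores (expected or measured) counts per projection angle and
#' radial bin as an `n_angles x n_bins` matrix of class `sinogram` with the
#' acquisition geometry attached. Measured sinograms are integer-valued
#' Poisson draws; expected sinograms are nonnegative reals.
#'
#' @param counts Numeric `n_angles x n_bins` matrix, nonnegative.
#' @param geometry The [ect_geometry()] that produced it.
#' @return A `sinogram` object.
#' @export
sinogram <- function(counts, geometry) {
  stopifnot(inherits(geometry, "ect_geometry"))
  if (!is.matrix(counts) || !is.numeric(counts)) stopf("`counts` must be a numeric matrix")
  if (!all(dim(counts) == c(geometry$n_angles, geometry$n_bins))) {
    stopf("counts must be %d x %d", geometry$n_angles, geometry$n_bins)
  }
  if (anyNA(counts) || any(counts < 0)) stopf("sinogram counts must be nonnegative")
  structure(counts,
    geometry = geometry,
    class = c("sinogram", "matrix", "array")
  )
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf(
    "<sinogram> %d angles x %d bins, total counts %.6g\n",
    nrow(x), ncol(x), sum(x)
  ))
  invisible(x)
}
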