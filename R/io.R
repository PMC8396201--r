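#' Read and write activity images
#'
#' Format is chosen by extension. `.csv` stores exact values (plain numeric
#' grid, no header) with a JSON sidecar (`<path>.json`) holding the pixel
#' size — the lossless interchange format. `.tif`/`.tiff` stores a 16-bit
#' image linearly scaled by the maximum value (quantisation error at most
#' `max/65535`); `.png` an 8-bit display rendering. For the quantised
#' formats the sidecar also records the scale so reading recovers
#' approximate activities.
#'
#' @param image An [activity_image()] (or matrix).
#' @param path Output path; extension selects the format.
#' @return `write_image()` returns `path` invisibly; `read_image()` an
#'   [activity_image()].
#' @export
write_image <- function(image, path) {
  x <- unclass_matrix(image)
  meta <- list(pixel_size_mm = pixel_size(image), shape = dim(x))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write_matrix_csv(x, path)
  } else if (ext %in% c("tif", "tiff", "png")) {
    scale <- max(x, 1e-300)
    meta$scale <- scale
    if (ext == "png") {
      png::writePNG(x / scale, path)
    } else {
      tiff::writeTIFF(x / scale, path, bits.per.sample = 16L)
    }
  } else {
    stopf("unsupported image format '.%s' (use csv, png, tif/tiff)", ext)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size_mm Pixel size override when no sidecar is present.
#' @export
read_image <- function(path, pixel_size_mm = NULL) {
  if (!file.exists(path)) stopf("no such image file: %s", path)
  meta <- read_sidecar(path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else if (ext == "png") {
    drop_channels(png::readPNG(path)) * (meta$scale %||% 1)
  } else if (ext %in% c("tif", "tiff")) {
    drop_channels(tiff::readTIFF(path)) * (meta$scale %||% 1)
  } else {
    stopf("unsupported image format '.%s'", ext)
  }
  dimnames(x) <- NULL
  ps <- pixel_size_mm %||% meta$pixel_size_mm %||% 3
  if (!is.null(meta$shape) && !all(dim(x) == unlist(meta$shape))) {
    stopf("image %s does not match the shape recorded in its sidecar", path)
  }
  activity_image(matrix(as.numeric(x), nrow(x), ncol(x)), pixel_size_mm = ps)
}

drop_channels <- function(x) if (length(dim(x)) == 3L) x[, , 1] else x

# 17 significant digits round-trip IEEE doubles exactly through text
write_matrix_csv <- function(x, path) {
  txt <- matrix(formatC(x, digits = 17, format = "g"), nrow(x), ncol(x))
  utils::write.table(txt, path, sep = ",", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
}

#' Read and write sinograms
#'
#' Counts go to a plain CSV grid (angles in rows, radial bins in columns)
#' and the acquisition geometry to a JSON sidecar, so the pair round-trips
#' losslessly and stays human-readable.
#'
#' @param sino A [sinogram()].
#' @param path Output `.csv` path.
#' @return `write_sinogram()` returns `path` invisibly; `read_sinogram()` a
#'   [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  write_matrix_csv(unclass_matrix(sino), path)
  jsonlite::write_json(geometry_to_list(attr(sino, "geometry")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stopf("no such sinogram file: %s", path)
  meta <- read_sidecar(path)
  if (is.null(meta$n_angles)) stopf("sinogram %s is missing its geometry sidecar", path)
  geom <- geometry_from_list(meta)
  x <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(x) <- NULL
  sinogram(matrix(as.numeric(x), nrow(x), ncol(x)), geom)
}

geometry_to_list <- function(geom) {
  geom[c("n_angles", "n_bins", "image_shape", "pixel_size_mm", "bin_size_mm")]
}

geometry_from_list <- function(lst) {
  ect_geometry(
    n_angles = lst$n_angles, n_bins = lst$n_bins,
    image_shape = unlist(lst$image_shape),
    pixel_size_mm = lst$pixel_size_mm, bin_size_mm = lst$bin_size_mm
  )
}
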