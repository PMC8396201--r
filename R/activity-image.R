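#' Activity images
#'
#' An activity image is the unknown of the emission-tomography inverse
#' problem: a nonnegative 2D grid of tracer concentration (arbitrary units)
#' with a physical pixel size in millimetres. It is stored as a plain numeric
#' matrix of class `activity_image` carrying a `pixel_size_mm` attribute, so
#' all matrix arithmetic works directly on it.
#'
#' @param values Numeric matrix of nonnegative activities.
#' @param pixel_size_mm Edge length of a pixel in mm (default 3, the
#'   resolution used throughout the reference simulation protocol).
#' @return An `activity_image`: a numeric matrix with attribute
#'   `pixel_size_mm`.
#' @examples
#' img <- activity_image(matrix(1, 4, 4), pixel_size_mm = 3)
#' pixel_size(img)
#' @export
activity_image <- function(values, pixel_size_mm = 3) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stopf("activity values must be finite")
  }
  if (any(values < 0)) stopf("activity values must be nonnegative")
  if (!is_scalar(pixel_size_mm) || pixel_size_mm <= 0) {
    stopf("`pixel_size_mm` must be a positive scalar")
  }
  structure(values,
    pixel_size_mm = as.numeric(pixel_size_mm),
    class = c("activity_image", "matrix", "array")
  )
}

#' @rdname activity_image
#' @param x Object to coerce or query.
#' @export
as_activity_image <- function(x, pixel_size_mm = NULL) {
  if (inherits(x, "activity_image") && is.null(pixel_size_mm)) return(x)
  ps <- pixel_size_mm %||% attr(x, "pixel_size_mm") %||% 3
  activity_image(unclass_matrix(x), pixel_size_mm = ps)
}

#' @rdname activity_image
#' @export
pixel_size <- function(x) attr(x, "pixel_size_mm") %||% 3

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip class/attributes down to a bare matrix
unclass_matrix <- function(x) {
  y <- as.matrix(x)
  matrix(as.numeric(y), nrow(y), ncol(y))
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf(
    "<activity_image> %d x %d pixels, %.3g mm/pixel, range [%.4g, %.4g]\n",
    nrow(x), ncol(x), pixel_size(x), min(x), max(x)
  ))
  invisible(x)
}
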