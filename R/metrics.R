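#' Reconstruction quality metrics
#'
#' `relative_norm_error()` is the L2 error relative to the ground truth,
#' \deqn{df = \frac{\lVert x - \hat x \rVert_2}{\lVert x \rVert_2},}
#' zero iff the images are identical. `snr()` is the signal-to-noise ratio
#' \deqn{SNR = \frac{\sum \hat x^2}{\sum (x - \hat x)^2},}
#' returned as the raw ratio or, with `in_decibels = TRUE`, as
#' \eqn{10 \log_{10}} of it; identical images give `Inf` (zero error).
#' Both share the same error denominator, so
#' \eqn{SNR \cdot \sum(x - \hat x)^2 = \sum \hat x^2} holds identically.
#'
#' `df` is scale-covariant — `df(c*x, c*xhat) = df(x, xhat)` — but neither
#' metric is invariant to rescaling *one* image. Emission reconstruction
#' recovers activity only up to the simulator's count normalisation, so
#' `normalize = TRUE` divides each image by its own total before comparing.
#'
#' @param truth Ground-truth image (matrix or [activity_image()]), not
#'   identically zero.
#' @param estimate Reconstructed image, same shape.
#' @param normalize Normalise each image to unit sum before comparison.
#' @return A scalar.
#' @examples
#' relative_norm_error(matrix(c(3, 4), 1), matrix(c(3, 0), 1))  # 0.8
#' snr(matrix(1, 1, 4), matrix(c(1, 1, 1, 0), 1))               # 3
#' @export
relative_norm_error <- function(truth, estimate, normalize = FALSE) {
  cmp <- metric_pair(truth, estimate, normalize)
  sqrt(sum((cmp$x - cmp$xhat)^2)) / sqrt(sum(cmp$x^2))
}

#' @rdname relative_norm_error
#' @param in_decibels Return \eqn{10 \log_{10}(SNR)}.
#' @export
snr <- function(truth, estimate, in_decibels = FALSE, normalize = FALSE) {
  cmp <- metric_pair(truth, estimate, normalize)
  err <- sum((cmp$x - cmp$xhat)^2)
  ratio <- if (err == 0) Inf else sum(cmp$xhat^2) / err
  if (in_decibels) 10 * log10(ratio) else ratio
}

metric_pair <- function(truth, estimate, normalize) {
  x <- unclass_matrix(truth)
  xhat <- unclass_matrix(estimate)
  if (!all(dim(x) == dim(xhat))) stopf("truth and estimate shapes differ")
  if (all(x == 0)) stopf("ground truth is identically zero")
  if (normalize) {
    x <- x / sum(x)
    s <- sum(xhat)
    if (s > 0) xhat <- xhat / s
  }
  list(x = x, xhat = xhat)
}

#' Horizontal line profile through an image
#'
#' Extracts one image row as a 1D profile with a physical x-axis, the
#' standard way of inspecting edge sharpness and region bias in
#' reconstructed slices.
#'
#' @param image An [activity_image()] (or matrix; `pixel_size_mm` then
#'   defaults to 3).
#' @param row Row index (1-based).
#' @return A tibble with columns `col`, `x_mm` (distance from the image
#'   center line), and `value`.
#' @export
line_profile <- function(image, row) {
  x <- unclass_matrix(image)
  if (!is_count(row) || row < 1 || row > nrow(x)) {
    stopf("`row` must be in 1..%d", nrow(x))
  }
  ps <- pixel_size(image)
  nc <- ncol(x)
  tibble::tibble(
    col = seq_len(nc),
    x_mm = (seq_len(nc) - (nc + 1) / 2) * ps,
    value = x[row, ]
  )
}

#' Rectangular region-of-interest crop
#'
#' @param image An [activity_image()] or matrix.
#' @param rows,cols Length-2 integer ranges `(first, last)`, inclusive.
#' @return The cropped image with the same pixel size.
#' @export
roi_crop <- function(image, rows, cols) {
  x <- unclass_matrix(image)
  check_range <- function(r, n, what) {
    if (length(r) != 2L || any(r != round(r)) || r[1] < 1 || r[2] > n || r[1] > r[2]) {
      stopf("`%s` must be an increasing integer range within 1..%d", what, n)
    }
  }
  check_range(rows, nrow(x), "rows")
  check_range(cols, ncol(x), "cols")
  activity_image(x[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
    pixel_size_mm = pixel_size(image))
}

#' Tidy per-iteration metrics of a reconstruction trace
#'
#' @param x A `recon_trace` from [mlem()] or [f_mlem()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per iteration (0-based) and
#'   columns `iteration`, `loglik`, `df`, `snr_ratio`, `snr_db`,
#'   `clipped_pixels`. `glance()`: a one-row summary tibble.
#' @importFrom generics tidy
#' @method tidy recon_trace
#' @export
tidy.recon_trace <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    iteration = x$iteration,
    loglik = x$loglik,
    df = x$df,
    snr_ratio = x$snr_ratio,
    snr_db = x$snr_db,
    clipped_pixels = x$clipped
  )
}

#' @rdname tidy.recon_trace
#' @importFrom generics glance
#' @method glance recon_trace
#' @export
glance.recon_trace <- function(x, ...) {
  last <- length(x$iteration)
  tibble::tibble(
    algorithm = x$algorithm,
    n_iter = x$n_iter,
    final_loglik = x$loglik[last],
    final_df = x$df[last],
    final_snr_db = x$snr_db[last],
    total_clipped_pixels = sum(x$clipped, na.rm = TRUE)
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Plot reconstruction-quality curves
#'
#' Draws the chosen per-iteration metric for one or several reconstruction
#' traces (e.g. MLEM vs f-MLEM on the same sinogram).
#'
#' @param object A `recon_trace`.
#' @param metric One of `"snr_db"`, `"snr_ratio"`, `"df"`, `"loglik"`.
#' @param ... Further `recon_trace` objects to overlay.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot recon_trace
#' @export
autoplot.recon_trace <- function(object, metric = c("snr_db", "snr_ratio", "df", "loglik"),
                                 ...) {
  metric <- match.arg(metric)
  traces <- c(list(object), Filter(function(o) inherits(o, "recon_trace"), list(...)))
  dat <- do.call(rbind, lapply(traces, tidy))
  lab <- c(
    snr_db = "SNR (dB)", snr_ratio = "SNR (ratio)",
    df = "relative norm error", loglik = "Poisson log-likelihood"
  )[[metric]]
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$iteration, y = .data[[metric]], colour = .data$algorithm)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = lab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
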