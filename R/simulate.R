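#' Noise configuration for sinogram simulation
#'
#' @param total_true_counts Expected total true events over the whole
#'   sinogram (default 5e5, the reference protocol's count level).
#' @param background_fraction Uniform scatter/randoms background, expressed
#'   as a fraction of the true counts (default 0.30); the background
#'   expectation `background_fraction * total_true_counts` is spread evenly
#'   over all bins.
#' @param seed Integer seed making the Poisson draw reproducible.
#' @return A `noise_config` list.
#' @export
noise_config <- function(total_true_counts = 5e5, background_fraction = 0.30,
                         seed = 1) {
  if (!is_scalar(total_true_counts) || total_true_counts <= 0) {
    stopf("`total_true_counts` must be positive")
  }
  if (!is_scalar(background_fraction) || background_fraction < 0 ||
    background_fraction >= 1) {
    stopf("`background_fraction` must lie in [0, 1)")
  }
  if (!is_scalar(seed) || seed != round(seed)) stopf("`seed` must be an integer")
  structure(
    list(
      total_true_counts = total_true_counts,
      background_fraction = background_fraction,
      seed = as.integer(seed)
    ),
    class = "noise_config"
  )
}

#' Simulate a noisy measured sinogram
#'
#' Follows the standard emission simulation protocol: forward-project the
#' phantom, rescale the expected sinogram so its total equals
#' `total_true_counts`, add a spatially uniform background of
#' `background_fraction * total_true_counts` expected events (modelling
#' random and scattered coincidences), then draw independent Poisson counts
#' per bin. Because the trues are renormalised, the phantom's global scale
#' is irrelevant: `simulate_sinogram` on `x` and on `2*x` with the same
#' configuration yield identical sinograms.
#'
#' @param image Nonnegative [activity_image()] (not identically zero).
#' @param model A [build_system_model()] result.
#' @param cfg A [noise_config()].
#' @return An integer-valued measured [sinogram()]; attribute `expected`
#'   holds the Poisson mean per bin (trues + background).
#' @examples
#' geom <- ect_geometry(12, 16, image_shape = 16)
#' m <- build_system_model(geom)
#' sino <- simulate_sinogram(make_disc_phantom(16, radius_px = 5), m,
#'   noise_config(1e4, 0.3, seed = 7))
#' sum(sino)
#' @export
simulate_sinogram <- function(image, model, cfg = noise_config()) {
  stopifnot(inherits(cfg, "noise_config"))
  yhat <- unclass_matrix(forward_project(model, image))
  tot <- sum(yhat)
  if (tot <= 0) stopf("cannot simulate from an all-zero image (nothing to normalise)")
  lambda <- yhat * (cfg$total_true_counts / tot) +
    cfg$background_fraction * cfg$total_true_counts / length(yhat)
  counts <- local_seed_eval(cfg$seed, stats::rpois(length(lambda), as.vector(lambda)))
  out <- sinogram(matrix(as.numeric(counts), nrow(yhat), ncol(yhat)), model$geometry)
  attr(out, "expected") <- matrix(lambda, nrow(yhat), ncol(yhat))
  out
}

#' Poisson log-likelihood of a measured sinogram
#'
#' The counts in each bin are modelled as independent Poisson variables
#' with mean given by the expected sinogram. The log-likelihood is
#' \deqn{l = \sum_j \left[-\hat y(j) + n(j) \log \hat y(j)\right]
#'   \;-\; \sum_j \log n(j)!}
#' where the final data-only term is constant in the image and omitted by
#' default (set `full = TRUE` to include it via `lgamma`). Bins with zero
#' expectation contribute \eqn{-\hat y = 0} when their measured count is
#' also zero; a positive count on a zero-expectation bin has likelihood
#' zero, so the function returns `-Inf` with a warning (model mismatch).
#'
#' @param measured Measured counts ([sinogram()] or matrix), nonnegative.
#' @param expected Expected counts, same shape, nonnegative.
#' @param full Include the \eqn{-\sum_j \log n(j)!} constant.
#' @return Scalar log-likelihood.
#' @examples
#' poisson_loglik(matrix(1, 2, 2), matrix(1, 2, 2))  # -J = -4
#' @export
poisson_loglik <- function(measured, expected, full = FALSE) {
  n <- unclass_matrix(measured)
  y <- unclass_matrix(expected)
  if (!all(dim(n) == dim(y))) stopf("measured and expected sinograms differ in shape")
  if (any(n < 0) || any(y < 0)) stopf("counts and expectations must be nonnegative")
  bad <- y == 0 & n > 0
  if (any(bad)) {
    warning(sprintf(
      "%d bin(s) have positive counts but zero expectation; log-likelihood is -Inf",
      sum(bad)
    ), call. = FALSE)
    return(-Inf)
  }
  pos <- n > 0
  ll <- -sum(y) + sum(n[pos] * log(y[pos]))
  if (full) ll <- ll - sum(lgamma(n + 1))
  ll
}
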