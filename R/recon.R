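#' MLEM configuration
#'
#' @param n_iter Number of outer iterations (>= 0; 0 returns the initial
#'   estimate only).
#' @param x0 Initial estimate: `"uniform"` (default; a constant positive
#'   image on the support, scaled so total modelled counts match the
#'   measured total) or an image-shaped numeric matrix, strictly positive
#'   on the support.
#' @param epsilon Guard for the projected-counts denominator; bins with
#'   expected counts below it contribute nothing to the update (default
#'   1e-12).
#' @param rel_tol Optional early-stopping threshold on the relative image
#'   change between outer iterations; `NULL` (default) disables stopping,
#'   matching fixed-iteration practice.
#' @return An `mlem_config` list.
#' @export
mlem_config <- function(n_iter = 100, x0 = "uniform", epsilon = 1e-12,
                        rel_tol = NULL) {
  if (!is_count(n_iter)) stopf("`n_iter` must be a nonnegative integer")
  if (!is_scalar(epsilon) || epsilon <= 0) stopf("`epsilon` must be positive")
  if (!is.null(rel_tol) && (!is_scalar(rel_tol) || rel_tol <= 0)) {
    stopf("`rel_tol` must be positive or NULL")
  }
  if (!(identical(x0, "uniform") || (is.matrix(x0) && is.numeric(x0)))) {
    stopf("`x0` must be \"uniform\" or a numeric matrix")
  }
  structure(
    list(n_iter = as.integer(n_iter), x0 = x0, epsilon = epsilon, rel_tol = rel_tol),
    class = "mlem_config"
  )
}

#' One multiplicative MLEM update
#'
#' The maximum-likelihood expectation-maximization fixed-point update for
#' the Poisson emission model:
#' \deqn{x'(i) = \frac{x(i)}{s(i)} \sum_j p(i,j)\,
#'   \frac{n(j)}{\sum_{i'} x(i') p(i',j)}}
#' with sensitivity \eqn{s(i) = \sum_j p(i,j)}. The update preserves
#' nonnegativity, leaves consistent data fixed
#' (\eqn{n = \hat y(x) \Rightarrow x' = x}), and conserves total modelled
#' counts exactly: \eqn{\sum_i s(i) x'(i) = \sum_j n(j)} whenever every bin
#' with counts has expected counts above `epsilon`. Bins whose expected
#' counts fall below `epsilon` contribute zero to the back-projected ratio;
#' if such a bin nonetheless holds counts the model cannot explain it
#' (typically uniform background on rays missing the support) and the
#' number of such bins is attached as attribute `n_unmodelled_bins`.
#' Pixels outside the model's support mask stay frozen at zero.
#'
#' @param x Current estimate (image-shaped matrix, nonnegative, positive on
#'   the support).
#' @param measured Measured [sinogram()].
#' @param model A [build_system_model()] result.
#' @param epsilon Denominator guard.
#' @return Updated image-shaped matrix.
#' @export
mlem_update <- function(x, measured, model, epsilon = 1e-12) {
  stopifnot(inherits(model, "system_model"))
  x <- unclass_matrix(x)
  n <- unclass_matrix(measured)
  g <- model$geometry
  if (!all(dim(x) == g$image_shape)) stopf("estimate shape does not match the model")
  if (!all(dim(n) == c(g$n_angles, g$n_bins))) stopf("sinogram shape does not match the model")
  if (any(x < 0) || any(n < 0)) stopf("estimate and counts must be nonnegative")
  supp <- as.vector(model$support)
  sv <- as.vector(model$sensitivity)
  if (any(sv[supp] <= 0)) stopf("support mask includes pixels with zero sensitivity")

  xv <- as.vector(x)
  yhat <- as.vector(model$matrix %*% xv)
  nv <- as.vector(n)
  ratio <- numeric(length(yhat))
  ok <- yhat >= epsilon
  ratio[ok] <- nv[ok] / yhat[ok]
  bp <- as.vector(Matrix::crossprod(model$matrix, ratio))
  out <- numeric(length(xv))
  out[supp] <- xv[supp] * bp[supp] / sv[supp]
  res <- matrix(out, g$image_shape[1], g$image_shape[2])
  attr(res, "n_unmodelled_bins") <- sum(!ok & nv > 0)
  res
}

#' Iterative MLEM and filtered-MLEM (f-MLEM) reconstruction
#'
#' `mlem()` runs the plain multiplicative update ([mlem_update()]) for
#' `cfg$n_iter` iterations. `f_mlem()` interleaves an edge-preserving
#' Beltrami filtering pass after each MLEM update: at outer iteration
#' \eqn{n} it applies \eqn{K(n)} explicit flow steps ([beltrami_step()])
#' with time step `h_t`, where the schedule \eqn{K(n)} starts large and
#' decreases — early iterates are noisy and benefit from strong smoothing,
#' while later iterates have converged structure that should no longer be
#' diffused. Negative pixels produced by filtering (overshoot near sharp
#' boundaries) are clipped to zero and counted; pixels outside the support
#' mask are reset to zero after filtering.
#'
#' Both return a `recon_trace` recording, for iterations `0..n_iter`, the
#' Poisson log-likelihood over the model-covered bins (bins whose rays meet
#' the support; uncovered bins have expected counts identically zero for
#' every estimate and are excluded) and, when `truth` is supplied, the
#' relative norm error `df` and the signal-to-noise ratio (raw and dB).
#' Trace metrics compare unit-sum-normalised images by default
#' (`normalize = TRUE`), since emission reconstruction recovers activity
#' only up to the simulator's count normalisation.
#'
#' @param measured Measured [sinogram()].
#' @param model A [build_system_model()] result.
#' @param cfg An [mlem_config()].
#' @param truth Optional ground-truth [activity_image()] for per-iteration
#'   error metrics.
#' @param save_every Keep every `save_every`-th estimate in the trace (the
#'   initial and final estimates are always kept).
#' @param normalize Normalise truth and estimate to unit sum before
#'   computing `df`/SNR trace metrics.
#' @return A `recon_trace`; see [tidy.recon_trace()].
#' @examples
#' geom <- ect_geometry(24, 32, image_shape = 32)
#' m <- build_system_model(geom)
#' truth <- make_disc_phantom(32, radius_px = 10)
#' sino <- simulate_sinogram(truth, m, noise_config(2e4, 0.3, seed = 3))
#' tr <- mlem(sino, m, mlem_config(n_iter = 10), truth = truth)
#' tail(tidy(tr), 3)
#' @export
mlem <- function(measured, model, cfg = mlem_config(), truth = NULL,
                 save_every = 1, normalize = TRUE) {
  run_recon(measured, model, cfg,
    schedule = NULL, truth = truth,
    save_every = save_every, normalize = normalize, algorithm = "mlem"
  )
}

#' @rdname mlem
#' @param sched An [fmlem_schedule()] giving the initial filter depth `K0`,
#'   its decay over outer iterations, and the flow time step `h_t`.
#' @export
f_mlem <- function(measured, model, cfg = mlem_config(),
                   sched = fmlem_schedule(), truth = NULL,
                   save_every = 1, normalize = TRUE) {
  stopifnot(inherits(sched, "fmlem_schedule"))
  run_recon(measured, model, cfg,
    schedule = sched, truth = truth,
    save_every = save_every, normalize = normalize, algorithm = "f_mlem"
  )
}

#' Decreasing filter schedule for f-MLEM
#'
#' Maps the outer MLEM iteration \eqn{n = 1..N} to the number of inner
#' Beltrami filter steps \eqn{K(n)}. The default rule decays linearly from
#' `K0` to zero, \eqn{K(n) = \max(0, \mathrm{round}(K_0 (1 - (n-1)/N))},
#' reflecting the inverse relationship between MLEM progress and the
#' smoothing still needed. Any non-increasing rule may be supplied via
#' `decay`, a function of `(n, n_iter)`; the schedule is validated to be
#' non-increasing with \eqn{K(1) = K_0} when the reconstruction runs.
#'
#' @param K0 Initial number of Beltrami steps (default 10).
#' @param h_t Flow time step (default 0.1; see [beltrami_step()]).
#' @param decay `"linear"` or a function `(n, n_iter) -> K`.
#' @param stop_filter_after Outer iteration after which filtering is
#'   switched off entirely (default `Inf`: filter every iteration).
#' @param variant Beltrami denominator variant, see [beltrami_step()].
#' @return An `fmlem_schedule`.
#' @export
fmlem_schedule <- function(K0 = 10, h_t = 0.1, decay = "linear",
                           stop_filter_after = Inf,
                           variant = c("eq9", "sqrtg")) {
  if (!is_count(K0)) stopf("`K0` must be a nonnegative integer")
  if (!is_scalar(h_t) || h_t <= 0) stopf("`h_t` must be positive")
  variant <- match.arg(variant)
  decay_fn <- if (identical(decay, "linear")) {
    function(n, n_iter) max(0, round(K0 * (1 - (n - 1) / max(n_iter, 1))))
  } else if (is.function(decay)) {
    decay
  } else {
    stopf("`decay` must be \"linear\" or a function(n, n_iter)")
  }
  structure(
    list(K0 = as.integer(K0), h_t = h_t, decay = decay_fn,
      stop_filter_after = stop_filter_after, variant = variant),
    class = "fmlem_schedule"
  )
}

schedule_K <- function(sched, n_iter) {
  if (n_iter == 0) return(integer(0))
  K <- vapply(seq_len(n_iter), function(n) as.numeric(sched$decay(n, n_iter)), numeric(1))
  if (any(K < 0) || any(K != round(K))) stopf("schedule K(n) must be nonnegative integers")
  if (any(diff(K) > 0)) {
    stopf("filter schedule K(n) must be non-increasing in the outer iteration")
  }
  if (K[1] != sched$K0) stopf("schedule must start at K(1) = K0")
  K[seq_len(n_iter) > sched$stop_filter_after] <- 0
  as.integer(K)
}

run_recon <- function(measured, model, cfg, schedule, truth, save_every,
                      normalize, algorithm) {
  stopifnot(inherits(model, "system_model"), inherits(cfg, "mlem_config"))
  n <- unclass_matrix(measured)
  g <- model$geometry
  if (!all(dim(n) == c(g$n_angles, g$n_bins))) stopf("sinogram shape does not match the model")
  if (!is_count(save_every) || save_every < 1) stopf("`save_every` must be a positive integer")
  if (!is.null(truth)) {
    truth_m <- unclass_matrix(truth)
    if (!all(dim(truth_m) == g$image_shape)) stopf("`truth` shape does not match the model")
  }

  x <- init_estimate(cfg, model, n)
  N <- cfg$n_iter
  Ks <- if (is.null(schedule)) integer(N) else schedule_K(schedule, N)

  loglik <- df <- snr_ratio <- snr_db <- clipped <- rep(NA_real_, N + 1)
  estimates <- list()
  covered <- model$bin_support
  record <- function(slot, x) {
    yh <- as.vector(model$matrix %*% as.vector(x))
    loglik[slot] <<- poisson_loglik(as.vector(n)[covered], yh[covered])
    if (!is.null(truth)) {
      df[slot] <<- relative_norm_error(truth_m, x, normalize = normalize)
      snr_ratio[slot] <<- snr(truth_m, x, normalize = normalize)
      snr_db[slot] <<- 10 * log10(snr_ratio[slot])
    }
  }
  keep <- function(iter) iter == 0 || iter == N || iter %% save_every == 0

  record(1, x)
  clipped[1] <- 0
  if (keep(0)) estimates[[as.character(0)]] <- x
  for (it in seq_len(N)) {
    x_prev <- x
    x <- mlem_update(x, n, model, cfg$epsilon)
    nclip <- 0
    if (!is.null(schedule) && Ks[it] > 0) {
      x <- beltrami_filter(x,
        params = beltrami_params(h_t = schedule$h_t, K = Ks[it]),
        variant = schedule$variant
      )
      neg <- x < 0
      nclip <- sum(neg)
      x[neg] <- 0
      x[!model$support] <- 0
    }
    clipped[it + 1] <- nclip
    record(it + 1, x)
    if (keep(it)) estimates[[as.character(it)]] <- x
    if (!is.null(cfg$rel_tol)) {
      rel <- sum(abs(x - x_prev)) / max(sum(abs(x_prev)), .Machine$double.eps)
      if (rel < cfg$rel_tol) {
        loglik <- loglik[seq_len(it + 1)]; df <- df[seq_len(it + 1)]
        snr_ratio <- snr_ratio[seq_len(it + 1)]; snr_db <- snr_db[seq_len(it + 1)]
        clipped <- clipped[seq_len(it + 1)]
        N <- it
        break
      }
    }
  }
  if (!keep(N)) estimates[[as.character(N)]] <- x

  structure(
    list(
      algorithm = algorithm, n_iter = N, iteration = 0:N,
      loglik = loglik, df = df, snr_ratio = snr_ratio, snr_db = snr_db,
      clipped = clipped, estimates = estimates, final = x,
      K_schedule = Ks, geometry = g, normalize = normalize,
      has_truth = !is.null(truth)
    ),
    class = "recon_trace"
  )
}

init_estimate <- function(cfg, model, n) {
  supp <- model$support
  if (identical(cfg$x0, "uniform")) {
    # scale-matched uniform start: total modelled counts equal measured total
    x <- matrix(0, nrow(supp), ncol(supp))
    x[supp] <- sum(n) / sum(model$sensitivity[supp])
    x
  } else {
    x0 <- unclass_matrix(cfg$x0)
    if (!all(dim(x0) == dim(supp))) stopf("`x0` shape does not match the model")
    if (any(x0[supp] <= 0)) stopf("`x0` must be strictly positive on the support mask")
    x0[!supp] <- 0
    x0
  }
}

#' @export
print.recon_trace <- function(x, ...) {
  cat(sprintf("<recon_trace> %s, %d iterations\n", x$algorithm, x$n_iter))
  cat(sprintf("  final log-likelihood: %.6g\n", x$loglik[length(x$loglik)]))
  if (x$has_truth) {
    cat(sprintf(
      "  final df: %.4g, final SNR: %.4g (%.2f dB)\n",
      x$df[length(x$df)], x$snr_ratio[length(x$snr_ratio)],
      x$snr_db[length(x$snr_db)]
    ))
  }
  invisible(x)
}
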