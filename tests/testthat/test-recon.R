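# 2-pixel / 2-bin system with p(i,j) = [[1, 0.5], [0.25, 1]]: the update is
# hand-computable. With n = (2, 3), x = (1, 1):
#   yhat = (1.25, 1.5), s = (1.5, 1.25)
#   x1' = (1/1.5) * (1*2/1.25 + 0.5*3/1.5) = 26/15
#   x2' = (1/1.25) * (0.25*2/1.25 + 1*3/1.5) = 48/25
toy_model <- function() {
  geom <- ect_geometry(2, 1, image_shape = c(2, 1))
  A <- rbind(c(1, 0.25), c(0.5, 1)) # A[j, i] = p(i, j)
  system_model(A, geom, support = matrix(TRUE, 2, 1))
}

test_that("one MLEM update matches the hand-computed toy system", {
  m <- toy_model()
  x1 <- mlem_update(matrix(1, 2, 1), matrix(c(2, 3), 2, 1), m)
  expect_equal(as.vector(x1), c(26 / 15, 48 / 25), tolerance = 1e-12)
  # count conservation on the same step
  expect_equal(sum(m$sensitivity * x1), 5, tolerance = 1e-12)
})

test_that("consistent data is a fixed point of the update", {
  p <- small_problem(size = 16, n_angles = 12, radius = 5)
  x_true <- matrix(0, 16, 16)
  x_true[p$model$support] <- 1
  y <- unclass(forward_project(p$model, x_true))
  x1 <- mlem_update(x_true, y, p$model)
  expect_lt(max(abs(x1 - x_true)), 1e-10 * max(x_true))
})

test_that("every update conserves total modelled counts", {
  p <- small_problem(size = 16, n_angles = 12)
  set.seed(2)
  for (rep in 1:3) {
    x <- matrix(0, 16, 16)
    x[p$model$support] <- runif(sum(p$model$support), 0.1, 2)
    n <- matrix(rpois(12 * 16, 20), 12, 16)
    n[!matrix(p$model$bin_support, 12, 16)] <- 0 # counts only on covered bins
    x1 <- mlem_update(x, n, p$model)
    expect_equal(sum(p$model$sensitivity * x1), sum(n), tolerance = 1e-8)
  }
})

test_that("MLEM matches a dense explicit-loop reference over 5 iterations", {
  geom <- ect_geometry(10, 8, image_shape = 8, pixel_size_mm = 2.5)
  A <- dense_chord_matrix(geom)
  model <- system_model(A, geom, support = matrix(TRUE, 8, 8))
  truth <- make_disc_phantom(8, radius_px = 3, pixel_size_mm = 2.5)
  sino <- simulate_sinogram(truth, model, noise_config(5e3, 0.2, seed = 4))

  supp <- as.vector(model$support)
  x0 <- matrix(0, 8, 8)
  x0[model$support] <- 1
  trace <- mlem(sino, model, mlem_config(n_iter = 5, x0 = x0))
  ref <- mlem_dense_reference(A, unclass(sino), x0, supp, n_iter = 5)
  for (it in 1:5) {
    est <- trace$estimates[[as.character(it)]]
    expect_lt(max(abs(as.vector(est) - ref[[it]])), 1e-10)
  }
})

test_that("the Poisson log-likelihood is non-decreasing along MLEM iterations", {
  p <- small_problem(size = 32, n_angles = 24, counts = 2e4, seed = 11)
  trace <- mlem(p$sino, p$model, mlem_config(n_iter = 60), truth = p$truth)
  expect_true(all(diff(trace$loglik) > -1e-9))
  # and every estimate stays nonnegative
  expect_true(all(vapply(trace$estimates, function(e) all(e >= 0), logical(1))))
})

test_that("n_iter = 0 returns the initial estimate only", {
  p <- small_problem(size = 16, n_angles = 12)
  trace <- mlem(p$sino, p$model, mlem_config(n_iter = 0))
  expect_equal(length(trace$loglik), 1)
  expect_equal(trace$iteration, 0)
  expect_named(trace$estimates, "0")
  # scale-matched uniform start: modelled counts equal measured counts
  expect_equal(sum(p$model$sensitivity * trace$final), sum(p$sino),
    tolerance = 1e-10)
})

test_that("f-MLEM with an all-zero filter schedule reproduces MLEM bitwise", {
  p <- small_problem(size = 16, n_angles = 12)
  cfg <- mlem_config(n_iter = 10)
  tm <- mlem(p$sino, p$model, cfg, truth = p$truth)
  tf <- f_mlem(p$sino, p$model, cfg, sched = fmlem_schedule(K0 = 0), truth = p$truth)
  expect_identical(tf$final, tm$final)
  expect_identical(tf$loglik, tm$loglik)
})

test_that("an increasing filter schedule is rejected", {
  p <- small_problem(size = 16, n_angles = 12)
  bad <- fmlem_schedule(K0 = 2, decay = function(n, N) n)
  expect_error(
    f_mlem(p$sino, p$model, mlem_config(n_iter = 5), sched = bad),
    "non-increasing|K0"
  )
})

test_that("the default schedule decays linearly from K0 to zero", {
  sched <- fmlem_schedule(K0 = 10)
  K <- vapply(1:100, function(n) sched$decay(n, 100), numeric(1))
  expect_equal(K[1], 10)
  expect_true(all(diff(K) <= 0))
  expect_equal(K[100], 0)
  # stop_filter_after switches the filter off beyond the given iteration
  p <- small_problem(size = 16, n_angles = 12)
  tr <- f_mlem(p$sino, p$model, mlem_config(n_iter = 8),
    sched = fmlem_schedule(K0 = 4, stop_filter_after = 3))
  expect_equal(tr$K_schedule[4:8], rep(0L, 5))
})

test_that("filtering-induced activity drift is bounded and decays with K", {
  # each MLEM update restores total modelled counts exactly, so any drift
  # in a given iteration comes from that iteration's Beltrami pass alone;
  # it scales with the filter depth K(n) and so decays along the schedule
  p <- small_problem(size = 32, n_angles = 24, counts = 2e4, seed = 11)
  tr <- f_mlem(p$sino, p$model, mlem_config(n_iter = 30),
    sched = fmlem_schedule(K0 = 10, h_t = 0.1), truth = p$truth)
  total <- sum(unclass(p$sino))
  drift <- vapply(c(1, 5, 10, 20, 30), function(it) {
    est <- tr$estimates[[as.character(it)]]
    abs(sum(p$model$sensitivity * est) - total) / total
  }, numeric(1))
  # regression bounds measured on this fixture: < 4% at full depth K = 10,
  # under 1% once the schedule has decayed past K = 7
  expect_lt(max(drift), 0.04)
  expect_true(all(drift[-1] < 0.015))
  expect_lt(drift[5], 0.01)
  expect_true(all(diff(drift) < 0))
  expect_true(all(vapply(tr$estimates, function(e) all(e >= 0), logical(1))))
})

test_that("early stopping on relative change truncates the trace", {
  p <- small_problem(size = 16, n_angles = 12)
  tr <- mlem(p$sino, p$model, mlem_config(n_iter = 200, rel_tol = 1e-3))
  expect_lt(tr$n_iter, 200)
  expect_equal(length(tr$loglik), tr$n_iter + 1)
})

test_that("initial-estimate policies are validated", {
  p <- small_problem(size = 16, n_angles = 12)
  bad <- matrix(0, 16, 16) # zero on the support
  expect_error(mlem(p$sino, p$model, mlem_config(n_iter = 1, x0 = bad)),
    "strictly positive")
  expect_error(mlem(p$sino, p$model, mlem_config(n_iter = 1, x0 = matrix(1, 4, 4))),
    "shape")
  expect_error(mlem_config(n_iter = -1), "nonnegative")
  expect_error(mlem_config(epsilon = 0), "positive")
})
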