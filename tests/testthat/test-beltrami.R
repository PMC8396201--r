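test_that("central differences are exact on polynomial images", {
  nr <- 6; nc <- 7
  ramp <- matrix(rep(seq_len(nc), each = nr), nr, nc) # x(i,j) = j
  d <- spatial_derivatives(ramp)
  int_r <- 2:(nr - 1); int_c <- 2:(nc - 1)
  expect_equal(d$d_x1[int_r, int_c], matrix(1, nr - 2, nc - 2))
  expect_equal(d$d_x1x1[int_r, int_c], matrix(0, nr - 2, nc - 2))

  quad <- matrix(rep(seq_len(nc)^2, each = nr), nr, nc) # x = j^2
  expect_equal(spatial_derivatives(quad)$d_x1x1[int_r, int_c],
    matrix(2, nr - 2, nc - 2))

  bil <- outer(seq_len(nr), seq_len(nc)) # x = i*j
  db <- spatial_derivatives(bil)
  expect_equal(db$d_x1x2[int_r, int_c], matrix(1, nr - 2, nc - 2))
  # x2 runs along rows
  expect_equal(spatial_derivatives(t(ramp))$d_x2[int_c, int_r],
    matrix(1, nc - 2, nr - 2))

  # constant image: all five derivative fields vanish everywhere
  dc <- spatial_derivatives(matrix(3.7, 5, 5))
  for (f in dc) expect_equal(f, matrix(0, 5, 5))

  expect_error(spatial_derivatives(matrix(1, 2, 5)), "3x3")
})

test_that("the vectorised flow step matches the literal per-pixel oracle", {
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_equal(beltrami_step(imp, h_t = 0.1),
    beltrami_step_reference(imp, 0.1), tolerance = 1e-12)

  set.seed(13)
  x <- matrix(runif(12 * 9, 0, 2), 12, 9)
  for (v in c("eq9", "sqrtg")) {
    expect_equal(beltrami_step(x, h_t = 0.07, variant = v),
      beltrami_step_reference(x, 0.07, variant = v), tolerance = 1e-12)
  }
})

test_that("constant images are fixed points and h_t = 0 is the identity", {
  const <- matrix(2.5, 6, 6)
  expect_equal(beltrami_step(const, h_t = 0.2), const)
  expect_equal(beltrami_filter(const, beltrami_params(h_t = 0.1, K = 25)), const)
  x <- step_edge_fixture()
  expect_equal(beltrami_step(x, h_t = 0), x)
})

test_that("filtering composes steps and K = 0 is the identity", {
  x <- step_edge_fixture()
  expect_identical(beltrami_filter(x, beltrami_params(h_t = 0.1, K = 0)), x)
  three <- beltrami_step(beltrami_step(beltrami_step(x, 0.1), 0.1), 0.1)
  expect_equal(beltrami_filter(x, beltrami_params(h_t = 0.1, K = 3)), three,
    tolerance = 1e-14)
})

test_that("discrete surface area is non-increasing along the flow at h_t <= 0.1", {
  for (x in list(step_edge_fixture(), unclass(make_brain_phantom(48)))) {
    area <- surface_area(x)
    for (k in 1:20) {
      x <- beltrami_step(x, h_t = 0.1)
      a <- surface_area(x)
      expect_lte(a, area + 1e-12)
      area <- a
    }
  }
})

test_that("the flow degenerates to the heat equation for small gradients", {
  set.seed(5)
  x <- matrix(runif(100, 0, 5e-4), 10, 10) # max |grad| <= 1e-3
  b <- beltrami_step(x, h_t = 0.1)
  h <- heat_step(x, 0.1)
  expect_lt(max(abs(b - h)), 1e-5 * max(abs(h - x)))
})

test_that("filtering is covariant under grayscale shifts", {
  x <- step_edge_fixture()
  p <- beltrami_params(h_t = 0.1, K = 5)
  expect_equal(beltrami_filter(x + 3.2, p), beltrami_filter(x, p) + 3.2,
    tolerance = 1e-12)
})

test_that("the flow preserves a step edge better than linear diffusion", {
  nr <- 16; nc <- 32
  x <- matrix(rep(c(0, 1), each = nr * nc / 2), nr, nc)
  xb <- x; xh <- x
  for (k in 1:10) {
    xb <- beltrami_step(xb, h_t = 0.1)
    xh <- heat_step(xh, 0.1)
  }
  gb <- max(abs(spatial_derivatives(xb)$d_x1))
  gh <- max(abs(spatial_derivatives(xh)$d_x1))
  expect_gt(gb, gh)
})

test_that("filtering a noisy step edge denoises flat regions without moving the edge", {
  x <- step_edge_fixture() # 16 x 32, edge between columns 16 and 17
  xf <- beltrami_filter(x, beltrami_params(h_t = 0.1, K = 10))
  left <- 1:12; right <- 21:32
  expect_lt(var(as.vector(xf[, left])), var(as.vector(x[, left])))
  expect_lt(var(as.vector(xf[, right])), var(as.vector(x[, right])))
  # frozen regression values for the two flat-region variances
  expect_equal(var(as.vector(xf[, left])), 0.000237636, tolerance = 1e-5)
  expect_equal(var(as.vector(xf[, right])), 0.0002686014, tolerance = 1e-5)
  # the gradient peak stays on the pixel pair straddling the edge: central
  # differences straddle a half-pixel edge, so columns 16 and 17 tie up to noise
  peak_in <- which.max(colMeans(abs(spatial_derivatives(x)$d_x1)))
  peak_out <- which.max(colMeans(abs(spatial_derivatives(xf)$d_x1)))
  expect_true(peak_in %in% c(16L, 17L))
  expect_true(peak_out %in% c(16L, 17L))
})

test_that("parameter validation enforces stability and integrality", {
  expect_warning(beltrami_params(h_t = 0.3, K = 1), "stability")
  expect_error(beltrami_params(h_t = -0.1, K = 1), "positive")
  expect_error(beltrami_params(h_t = 0.1, K = -2), "nonnegative")
  expect_error(beltrami_step(matrix(1, 2, 2), 0.1), "3x3")
})
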