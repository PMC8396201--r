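# Independent reference implementations used as oracles. These use scalar
# loops, dense algebra and line-box clipping on purpose: they share no code
# with the package's vectorised/sparse paths.

# Chord length of the line p0 + t*u through the axis-aligned box [lo, hi]
# (Liang-Barsky clipping).
chord_length <- function(p0, u, lo, hi) {
  tmin <- -Inf
  tmax <- Inf
  for (ax in 1:2) {
    if (abs(u[ax]) > 1e-14) {
      ta <- (lo[ax] - p0[ax]) / u[ax]
      tb <- (hi[ax] - p0[ax]) / u[ax]
      tmin <- max(tmin, min(ta, tb))
      tmax <- min(tmax, max(ta, tb))
    } else if (p0[ax] <= lo[ax] || p0[ax] >= hi[ax]) {
      return(0)
    }
  }
  max(0, tmax - tmin)
}

# Dense system matrix built by clipping every ray against every pixel box.
dense_chord_matrix <- function(geometry) {
  nr <- geometry$image_shape[1]
  nc <- geometry$image_shape[2]
  px <- geometry$pixel_size_mm
  s <- (seq_len(geometry$n_bins) - (geometry$n_bins + 1) / 2) * geometry$bin_size_mm
  J <- geometry$n_angles * geometry$n_bins
  A <- matrix(0, J, nr * nc)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles_rad[a]
    u <- c(-sin(th), cos(th))
    v <- c(cos(th), sin(th))
    for (b in seq_len(geometry$n_bins)) {
      j <- a + (b - 1) * geometry$n_angles
      p0 <- s[b] * v
      for (col in seq_len(nc)) {
        for (row in seq_len(nr)) {
          lo <- c((col - 1 - nc / 2) * px, (row - 1 - nr / 2) * px)
          hi <- lo + px
          len <- chord_length(p0, u, lo, hi)
          if (len > 0) A[j, row + (col - 1) * nr] <- len
        }
      }
    }
  }
  A
}

# Textbook MLEM with explicit loops on a dense matrix. `supp` is a logical
# vector over pixels; pixels outside it stay 0.
mlem_dense_reference <- function(A, n, x0, supp, n_iter, eps = 1e-12) {
  A <- as.matrix(A)
  x <- as.vector(x0)
  n <- as.vector(n)
  s <- numeric(ncol(A))
  for (i in seq_len(ncol(A))) s[i] <- sum(A[, i])
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    yhat <- numeric(nrow(A))
    for (j in seq_len(nrow(A))) yhat[j] <- sum(A[j, ] * x)
    xnew <- numeric(length(x))
    for (i in seq_len(ncol(A))) {
      if (!supp[i]) next
      acc <- 0
      for (j in seq_len(nrow(A))) {
        if (yhat[j] >= eps) acc <- acc + A[j, i] * n[j] / yhat[j]
      }
      xnew[i] <- x[i] / s[i] * acc
    }
    x <- xnew
    out[[it]] <- x
  }
  out
}

# Literal per-pixel evaluation of one explicit Beltrami flow step with
# replicate padding.
beltrami_step_reference <- function(x, ht, variant = "eq9") {
  nr <- nrow(x)
  nc <- ncol(x)
  xp <- function(i, j) x[min(max(i, 1), nr), min(max(j, 1), nc)]
  out <- x
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d1 <- (xp(i, j + 1) - xp(i, j - 1)) / 2
      d2 <- (xp(i + 1, j) - xp(i - 1, j)) / 2
      d11 <- xp(i, j + 1) - 2 * x[i, j] + xp(i, j - 1)
      d22 <- xp(i + 1, j) - 2 * x[i, j] + xp(i - 1, j)
      d12 <- (xp(i + 1, j + 1) - xp(i + 1, j - 1) -
        xp(i - 1, j + 1) + xp(i - 1, j - 1)) / 4
      num <- d11 * (1 + d2^2) + d22 * (1 + d1^2) - 2 * d1 * d2 * d12
      den <- (1 + d1^2 + d2^2)^(if (variant == "eq9") 2 else 1.5)
      out[i, j] <- x[i, j] + ht * num / den
    }
  }
  out
}

# One explicit heat-equation step x + ht * Laplacian(x), replicate padding.
heat_step <- function(x, ht) {
  nr <- nrow(x)
  nc <- ncol(x)
  p <- x[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  ri <- seq_len(nr) + 1L
  ci <- seq_len(nc) + 1L
  lap <- p[ri, ci + 1L] + p[ri, ci - 1L] + p[ri + 1L, ci] + p[ri - 1L, ci] -
    4 * p[ri, ci]
  x + ht * lap
}

# 4-connected component count by flood fill (for tumor counting).
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (!mask[i0, j0] || lab[i0, j0] > 0L) next
      n <- n + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- n
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- n
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  n
}

# Small shared fixtures -------------------------------------------------

small_problem <- function(size = 32, n_angles = 24, counts = 2e4, seed = 11,
                          background = 0.3, radius = size / 3) {
  geom <- ect_geometry(n_angles, size, image_shape = size, pixel_size_mm = 3)
  model <- build_system_model(geom)
  truth <- make_disc_phantom(size, radius_px = radius)
  sino <- simulate_sinogram(truth, model, noise_config(counts, background, seed))
  list(geom = geom, model = model, truth = truth, sino = sino)
}

# Noisy step-edge image: left half 0, right half 1, seeded Gaussian noise.
step_edge_fixture <- function(nr = 16, nc = 32, sd = 0.08, seed = 42) {
  x <- matrix(rep(c(0, 1), each = nr * nc / 2), nr, nc)
  set.seed(seed)
  x + matrix(rnorm(nr * nc, sd = sd), nr, nc)
}
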