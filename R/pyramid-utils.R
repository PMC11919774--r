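# Low-level raster helpers shared by the saliency pipeline.
# Matrices are indexed [row, col] with row 1 at the top of the image.

# Separable 5-tap binomial blur ([1 4 6 4 1]/16) with replicated edges.
# Implemented by shift-and-add so a 1280x1024 frame stays cheap.
blur_binomial <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  nr <- nrow(m); nc <- ncol(m)
  # pad 2 rows/cols by edge replication
  ri <- c(1, 1, seq_len(nr), nr, nr)
  ci <- c(1, 1, seq_len(nc), nc, nc)
  p <- m[ri, ci, drop = FALSE]
  # vertical pass
  v <- k[1] * p[1:nr, ] + k[2] * p[2:(nr + 1), ] + k[3] * p[3:(nr + 2), ] +
    k[4] * p[4:(nr + 3), ] + k[5] * p[5:(nr + 4), ]
  # horizontal pass
  k[1] * v[, 1:nc] + k[2] * v[, 2:(nc + 1)] + k[3] * v[, 3:(nc + 2)] +
    k[4] * v[, 4:(nc + 3)] + k[5] * v[, 5:(nc + 4)]
}

# One pyramid step: binomial blur evaluated only at the retained (every
# other) samples — identical to blur-then-decimate, at ~1/3 the work.
pyr_down <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq(1, nr, by = 2)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  v <- k[1] * m[cl(ri - 2, nr), , drop = FALSE] +
    k[2] * m[cl(ri - 1, nr), , drop = FALSE] +
    k[3] * m[ri, , drop = FALSE] +
    k[4] * m[cl(ri + 1, nr), , drop = FALSE] +
    k[5] * m[cl(ri + 2, nr), , drop = FALSE]
  ci <- seq(1, nc, by = 2)
  k[1] * v[, cl(ci - 2, nc), drop = FALSE] +
    k[2] * v[, cl(ci - 1, nc), drop = FALSE] +
    k[3] * v[, ci, drop = FALSE] +
    k[4] * v[, cl(ci + 1, nc), drop = FALSE] +
    k[5] * v[, cl(ci + 2, nc), drop = FALSE]
}

# Gaussian pyramid as a list; element 1 is the input (level 0).
gaussian_pyramid <- function(m, n_levels = 9) {
  out <- vector("list", n_levels)
  out[[1]] <- m
  for (k in 2:n_levels) {
    prev <- out[[k - 1]]
    if (min(dim(prev)) < 2) stop("image too small for requested pyramid depth")
    out[[k]] <- pyr_down(prev)
  }
  out
}

# Bilinear resample of a matrix to nr x nc (used to upsample surround
# levels and to resize non-native-resolution input images).
resize_bilinear <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  # sample at cell centres of the target grid mapped into source coords
  sr <- (seq_len(nr) - 0.5) * nrow(m) / nr + 0.5
  sc <- (seq_len(nc) - 0.5) * ncol(m) / nc + 0.5
  r0 <- pmin(pmax(floor(sr), 1), nrow(m)); r1 <- pmin(r0 + 1, nrow(m))
  c0 <- pmin(pmax(floor(sc), 1), ncol(m)); c1 <- pmin(c0 + 1, ncol(m))
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

# Block-mean downsample by integer factors (exact; used for the
# across-scale sum onto the 80x64 grid).
block_mean <- function(m, fr, fc) {
  if (fr == 1 && fc == 1) return(m)
  nr <- nrow(m) %/% fr; nc <- ncol(m) %/% fc
  m <- m[seq_len(nr * fr), seq_len(nc * fc), drop = FALSE]
  # average rows within blocks, then columns
  dim(m) <- c(fr, nr, nc * fc)
  m <- colMeans(m)
  m <- t(m); dim(m) <- c(fc, nc, nr)
  t(colMeans(m))
}

# 2-D convolution ("same" size, replicated boundary) via EBImage.
# Inputs smaller than the kernel are edge-padded first (coarse pyramid
# levels can be tinier than the kernel).
conv2_same <- function(m, k) {
  pr <- max(0, nrow(k) - nrow(m))
  pc <- max(0, ncol(k) - ncol(m))
  if (pr == 0 && pc == 0) return(EBImage::filter2(m, k, boundary = "replicate"))
  ri <- pmin(pmax(seq_len(nrow(m) + pr) - ceiling(pr / 2), 1), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + pc) - ceiling(pc / 2), 1), ncol(m))
  big <- EBImage::filter2(m[ri, ci, drop = FALSE], k, boundary = "replicate")
  big[ceiling(pr / 2) + seq_len(nrow(m)), ceiling(pc / 2) + seq_len(ncol(m)),
      drop = FALSE]
}

# Quadrature pair of Gabor kernels for a given preferred bar orientation
# (degrees; 0 = horizontal bar, 90 = vertical bar). The carrier runs
# perpendicular to the bar. The even kernel is mean-corrected so constant
# input gives exactly zero response.
gabor_pair <- function(theta_deg, wavelength = 6, sigma = 3, size = 13) {
  stopifnot(size %% 2 == 1)
  half <- (size - 1) / 2
  x <- matrix(rep(-half:half, each = size), size, size)      # column offset
  y <- matrix(rep(-half:half, times = size), size, size)     # row offset
  th <- theta_deg * pi / 180
  # carrier axis perpendicular to the bar orientation
  u <- x * cos(th + pi / 2) + y * sin(th + pi / 2)
  v <- -x * sin(th + pi / 2) + y * cos(th + pi / 2)
  env <- exp(-(u^2 + v^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * u / wavelength)
  odd <- env * sin(2 * pi * u / wavelength)
  even <- even - mean(even)
  list(even = even, odd = odd)
}

# Gabor energy map: quadrature magnitude of the two phases.
gabor_energy <- function(m, pair) {
  e <- conv2_same(m, pair$even)
  o <- conv2_same(m, pair$odd)
  sqrt(e^2 + o^2)
}
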