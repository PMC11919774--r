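# Shared fixtures. Expensive objects (stimulus set, saliency maps) are
# memoized so the suite computes them once.

.fixture_env <- new.env(parent = emptyenv())

fix_geometry <- function() screen_geometry()

# small display for cheap saliency unit tests (maps come out 40 x 32)
small_geometry <- function() screen_geometry(640, 512, 19, 70, grid = c(40, 32))

uniform_map <- function(geometry = fix_geometry()) {
  saliency_map(matrix(1 / (geometry$n_row * geometry$n_col),
                      geometry$n_row, geometry$n_col), "full", "uniform")
}

point_map <- function(row = 30, col = 40, geometry = fix_geometry()) {
  m <- matrix(0, geometry$n_row, geometry$n_col)
  m[row, col] <- 1
  saliency_map(m, "full", "point")
}

# synthetic multi-peak density map (not via the saliency pipeline):
# random Gaussian bumps on a floor, density-normalized
make_density_map <- function(seed = 1, n_peaks = 6,
                             geometry = fix_geometry()) {
  salgaze:::with_seed(seed, {
    nr <- geometry$n_row; nc <- geometry$n_col
    m <- matrix(0.2 / (nr * nc), nr, nc)
    rows <- matrix(rep(seq_len(nr), nc), nr)
    cols <- matrix(rep(seq_len(nc), each = nr), nr)
    for (i in seq_len(n_peaks)) {
      r0 <- runif(1, 5, nr - 5); c0 <- runif(1, 5, nc - 5)
      s <- runif(1, 2, 6); a <- runif(1, 0.5, 2)
      m <- m + a * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * s^2))
    }
    saliency_map(to_density(m), "full", sprintf("synthpeaks_%d", seed))
  })
}

cached_stimuli <- function() {
  if (is.null(.fixture_env$stimuli))
    .fixture_env$stimuli <- generate_stimulus_set(0)
  .fixture_env$stimuli
}

cached_maps <- function() {
  if (is.null(.fixture_env$maps))
    .fixture_env$maps <- compute_set_maps(filter_images(cached_stimuli()))
  .fixture_env$maps
}

# closed-form two-sample Hedges g, the textbook oracle
hedges_g_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  d <- (mean(x2) - mean(x1)) / sp
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
  list(g = g, se = se)
}

# match programmed regular saccades to detected ones by onset proximity
match_saccades <- function(truth, detected, tol_ms = 15) {
  treg <- truth[truth$class == "regular", , drop = FALSE]
  det <- detected[detected$class == "regular", , drop = FALSE]
  recall_hits <- vapply(treg$onset, function(o)
    any(abs(det$onset - o) <= tol_ms), TRUE)
  prec_hits <- if (nrow(det)) vapply(det$onset, function(o)
    any(abs(treg$onset - o) <= tol_ms), TRUE) else logical(0)
  err <- vapply(which(recall_hits), function(i) {
    j <- which.min(abs(det$onset - treg$onset[i]))
    sqrt((det$x_end[j] - treg$x_end[i])^2 + (det$y_end[j] - treg$y_end[i])^2)
  }, 0)
  list(n_true = nrow(treg), n_det = nrow(det),
       recall = mean(recall_hits),
       precision = if (length(prec_hits)) mean(prec_hits) else NA_real_,
       endpoint_err = err)
}
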