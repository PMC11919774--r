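# Channel-level properties are checked on a reduced display (640 x 512,
# maps 40 x 32) to keep the pyramid cheap; the full 80 x 64 contract is
# exercised in the acceptance suite.

test_that("to_density normalizes, preserves order, and is scale invariant", {
  set.seed(1)
  m <- matrix(rexp(64 * 80), 64, 80)
  d <- to_density(m)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(order(d), order(m))
  expect_equal(to_density(7 * m), d, tolerance = 1e-12)
  # uniform map: every cell 1/5120
  u <- to_density(matrix(1, 64, 80))
  expect_equal(unique(as.vector(u)), 1 / 5120)
  # all-zero map falls back to the uniform density
  z <- to_density(matrix(0, 64, 80))
  expect_equal(unique(as.vector(z)), 1 / 5120)
  expect_error(to_density(matrix(c(-1, 1), 2, 2)), "non-negative")
})

test_that("normalization operator promotes lone peaks, suppresses many", {
  one <- matrix(0, 20, 20); one[10, 10] <- 3
  n1 <- normalize_iter(one)
  expect_equal(max(n1), 1)            # multiplier (1 - 0)^2 = 1
  many <- matrix(0, 20, 20)
  many[cbind(c(4, 4, 10, 10, 16, 16), c(4, 16, 4, 16, 10, 6))] <- 5
  n2 <- normalize_iter(many)
  expect_lt(max(n2), 1e-12)           # m_bar = 1 -> multiplier 0
  z <- matrix(0, 5, 5)
  expect_identical(normalize_iter(z), z)
})

test_that("center-surround is non-negative, zero on constants, and local", {
  img <- array(0.5, c(512, 640, 3))
  pyr <- build_pyramids(img)
  for (cl in c(2, 3)) for (s in c(5, 6)) {
    cs <- center_surround(pyr, "intensity", cl, s)
    expect_equal(max(abs(cs)), 0)
  }
  # single bright square on black: intensity contrast peaks there
  img2 <- array(0, c(512, 640, 3))
  img2[255:258, 319:322, ] <- 1
  pyr2 <- build_pyramids(img2)
  cs <- center_surround(pyr2, "intensity", 2, 5)
  pk <- which(cs == max(cs), arr.ind = TRUE)[1, ]
  expect_true(all(cs >= 0))
  # level-2 coordinates: pixel /4
  expect_lt(abs(pk[1] - 256 / 4), 3)
  expect_lt(abs(pk[2] - 320 / 4), 3)
})

test_that("achromatic input has exactly zero opponency at every level", {
  set.seed(2)
  g <- matrix(runif(512 * 640), 512, 640)
  img <- array(rep(g, 3), c(512, 640, 3))
  pyr <- build_pyramids(img)
  for (k in seq_along(pyr$rg)) {
    expect_equal(max(abs(pyr$rg[[k]])), 0)
    expect_equal(max(abs(pyr$by[[k]])), 0)
  }
  expect_equal(max(conspicuity(pyr, "color")), 0)
})

test_that("constant image yields the uniform density in all channels", {
  img <- array(0.5, c(512, 640, 3))
  maps <- compute_saliency(img, geometry = small_geometry())
  for (ch in names(maps)) {
    expect_equal(dim(maps[[ch]]$values), c(32, 40))
    expect_equal(unique(as.vector(maps[[ch]]$values)), 1 / (32 * 40))
  }
})

test_that("a vertical grating drives the 90-degree channel hardest", {
  g <- matrix(0.5 + 0.5 * sin(2 * pi * seq_len(640) / 16), 512, 640,
              byrow = TRUE)
  pyr <- build_pyramids(array(rep(g, 3), c(512, 640, 3)))
  e <- vapply(pyr$orientation, function(lv) sum(lv[[3]]), 0)
  expect_gt(e[["theta_90"]], 10 * e[["theta_0"]])
  expect_gt(e[["theta_90"]], max(e[["theta_45"]], e[["theta_135"]]))
})

test_that("a red patch on uniform gray peaks the color conspicuity there", {
  img <- array(0.5, c(512, 640, 3))
  img[140:180, 440:480, 1] <- 0.9
  img[140:180, 440:480, 2:3] <- 0.25
  maps <- compute_saliency(img, channels = "color",
                           geometry = small_geometry())
  v <- maps$color$values
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  # patch centre at pixel (160, 460) -> cell (10, 29) on the 32 x 40 grid
  expect_lt(abs(pk[1] - 160 / 16), 2)
  expect_lt(abs(pk[2] - 460 / 16), 2)
})

test_that("equal conspicuities pass through the full-map combination", {
  set.seed(3)
  c0 <- matrix(rexp(32 * 40), 32, 40)
  full <- combine_full(c0, c0, c0, "x")
  expect_equal(full$values, to_density(normalize_iter(c0)), tolerance = 1e-12)
  # zero color/orientation: full is proportional to N(luminance)
  z <- matrix(0, 32, 40)
  full2 <- combine_full(z, c0, z, "x")
  expect_equal(full2$values, to_density(normalize_iter(c0)), tolerance = 1e-12)
  expect_equal(sum(full$values), 1, tolerance = 1e-9)
  expect_error(combine_full(c0, c0, matrix(0, 2, 2)))
})

test_that("emitted maps satisfy the density contract on a real image", {
  ss <- generate_stimulus_set(9, n_per_category = 1,
                              geometry = small_geometry())
  maps <- compute_saliency(ss$images[["items_01"]], image_id = "items_01",
                           geometry = small_geometry())
  for (ch in c("full", "color", "luminance", "orientation")) {
    expect_s3_class(maps[[ch]], "saliency_map")
    expect_true(all(maps[[ch]]$values >= 0))
    expect_equal(sum(maps[[ch]]$values), 1, tolerance = 1e-9)
  }
  expect_error(build_pyramids(array(0.5, c(32, 32, 3))), "too small")
})
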