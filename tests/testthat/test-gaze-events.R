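make_trial_df <- function(x, y = NULL, pupil = NULL) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  if (is.null(pupil)) pupil <- rep(1000, n)
  tr <- data.frame(time_ms = 0:(n - 1), x_deg = x, y_deg = y, pupil = pupil)
  class(tr) <- c("gaze_trial", "data.frame")
  tr
}

test_that("smoothing filter has unit DC gain and -3 dB at 30 Hz", {
  # constant input passes unchanged (DC gain exactly 1)
  tr <- make_trial_df(rep(3, 2000))
  sm <- smooth_trace(tr)
  expect_equal(sm$x, rep(3, 2000), tolerance = 1e-9)
  # sinusoid attenuation measured on the filtered trace (steady state)
  atten <- function(f_hz) {
    t <- 0:3999
    tr <- make_trial_df(sin(2 * pi * f_hz * t / 1000))
    sm <- smooth_trace(tr)
    core <- 500:3500
    max(abs(sm$x[core])) / 1
  }
  expect_equal(atten(30), 10^(-3 / 20), tolerance = 0.02)
  expect_lt(20 * log10(atten(100)), -10)
  # linearity to numerical precision
  t <- 0:999
  a <- sin(2 * pi * 7 * t / 1000); b <- cos(2 * pi * 19 * t / 1000)
  sab <- smooth_trace(make_trial_df(a + 2 * b))$x
  sa <- smooth_trace(make_trial_df(a))$x
  sb <- smooth_trace(make_trial_df(b))$x
  expect_equal(sab, sa + 2 * sb, tolerance = 1e-9)
  # non-1 kHz input is rejected
  bad <- make_trial_df(rep(0, 10)); bad$time_ms <- seq(0, 18, by = 2)
  expect_error(smooth_trace(bad), "1 kHz")
})

test_that("two-point central difference recovers known derivatives", {
  n <- 1000; t_s <- (0:(n - 1)) / 1000
  # linear ramp 1 deg/s
  tr <- differentiate(data.frame(time_ms = 0:(n - 1), x = t_s, y = 0 * t_s,
                                 valid = TRUE))
  expect_equal(tr$vx[5:(n - 5)], rep(1, n - 9), tolerance = 1e-9)
  # constant position: zero velocity and acceleration
  tr0 <- differentiate(data.frame(time_ms = 0:(n - 1), x = rep(2, n),
                                  y = rep(-1, n), valid = TRUE))
  expect_equal(max(abs(tr0$speed)), 0)
  expect_equal(max(abs(tr0$accel)), 0)
  # parabola 0.5 * a * t^2 gives constant acceleration a (interior)
  a <- 4
  trp <- differentiate(data.frame(time_ms = 0:(n - 1), x = 0.5 * a * t_s^2,
                                  y = 0 * t_s, valid = TRUE))
  expect_equal(trp$accel[5:(n - 5)], rep(a, n - 9), tolerance = 1e-6)
  expect_error(differentiate(data.frame(time_ms = 0:1, x = c(0, 1),
                                        y = c(0, 0), valid = TRUE)),
               "too short")
})

test_that("noise-free programmed trials are segmented exactly", {
  u <- uniform_map()
  for (s in 1:5) {
    tr <- generate_trial(u, bias = 0, n_saccades = 10, n_micro = 0,
                         n_blinks = 0, jitter_sd = 0, seed = s)
    ev <- detect_events(tr)
    m <- match_saccades(attr(tr, "truth"), ev$saccades)
    expect_equal(m$n_det, 10L)
    expect_equal(m$recall, 1)
    expect_true(all(m$endpoint_err < 0.25))
  }
})

test_that("a pupil-zero gap becomes exactly one padded blink", {
  x <- rep(1.5, 3000); pupil <- rep(800, 3000)
  pupil[1001:1200] <- 0
  x[1001:1200] <- NA
  tr <- make_trial_df(x, pupil = pupil)
  ev <- detect_events(tr)
  expect_equal(nrow(ev$blinks), 1L)
  expect_lte(ev$blinks$onset, 1000)
  expect_gte(ev$blinks$offset, 1199)
  # padding is bounded by the configured margin
  expect_gte(ev$blinks$onset, 1000 - 25)
  expect_lte(ev$blinks$offset, 1199 + 25)
  # blink samples never enter fixations
  expect_false(any(ev$fixations$onset <= 1100 & ev$fixations$offset >= 1100))
})

test_that("constant-position trial is one long fixation; all-blink trial is empty", {
  tr <- make_trial_df(rep(0.7, 2000))
  ev <- detect_events(tr)
  expect_equal(nrow(ev$saccades), 0L)
  expect_equal(nrow(ev$fixations), 1L)
  expect_equal(ev$fixations$onset, 0)
  expect_equal(ev$fixations$offset, 1999)
  allb <- make_trial_df(rep(NA_real_, 500), pupil = rep(0, 500))
  evb <- detect_events(allb)
  expect_equal(nrow(evb$saccades), 0L)
  expect_equal(nrow(evb$fixations), 0L)
  expect_equal(nrow(evb$blinks), 1L)
})

test_that("events never overlap within a trial", {
  u <- uniform_map()
  tr <- generate_trial(u, bias = 0.5, n_saccades = 15, n_micro = 2,
                       n_blinks = 2, jitter_sd = 0.05, seed = 11)
  ev <- detect_events(tr)
  spans <- rbind(
    if (nrow(ev$blinks)) cbind(ev$blinks$onset, ev$blinks$offset),
    cbind(ev$saccades$onset, ev$saccades$offset),
    cbind(ev$fixations$onset, ev$fixations$offset))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
})

test_that("the regular/micro boundary is strict at one degree", {
  ev <- list(saccades = data.frame(
    onset = c(0, 100, 200), offset = c(30, 130, 230),
    x_start = c(0, 0, 0), y_start = c(0, 0, 0),
    x_end = c(1.5, 0.5, 1.0), y_end = c(0, 0, 0),
    amplitude = c(1.5, 0.5, 1.0)),
    blinks = data.frame(), fixations = data.frame())
  class(ev) <- "event_list"
  out <- classify_saccades(ev)
  expect_equal(out$saccades$class, c("regular", "micro", "micro"))
})

test_that("detection recovers programmed saccades under fixational jitter", {
  u <- uniform_map()
  recs <- c(); precs <- c()
  for (s in 1:15) {
    tr <- generate_trial(u, bias = 0.3, n_saccades = 18, n_micro = 2,
                         jitter_sd = 0.05, seed = 100 + s)
    m <- match_saccades(attr(tr, "truth"), detect_events(tr)$saccades)
    recs <- c(recs, m$recall); precs <- c(precs, m$precision)
  }
  expect_gte(mean(recs), 0.95)
  expect_gte(mean(precs), 0.95)
})
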