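#' Event detection in 1 kHz gaze recordings
#'
#' Raw traces are smoothed with a zero-phase FIR low-pass filter whose
#' half-amplitude (-3 dB) point sits at 30 Hz, velocity and acceleration
#' are derived with a two-point (central) difference, and the trace is
#' segmented into blinks (pupil = 0, padded), saccades (speed-threshold
#' detection with hysteresis) and fixations. Saccades with amplitude
#' greater than one degree are classed "regular", the rest "micro".
#'
#' @name gaze_events
NULL

#' Detection parameters
#'
#' The recording literature rarely prints detector thresholds; these are
#' standard velocity-based values and are all configurable.
#'
#' @param vel_onset speed threshold starting a saccade (deg/s).
#' @param vel_offset hysteresis threshold ending a saccade (deg/s).
#' @param min_sacc_ms minimum above-threshold duration for a saccade.
#' @param min_fix_ms minimum fixation duration.
#' @param blink_pad_ms padding added around pupil-zero gaps.
#' @param fir_order FIR filter order (taps = order + 1).
#' @param cutoff_hz frequency (Hz) at which the filter gain is -3 dB.
#' @param micro_max_deg regular/micro amplitude boundary (strict >).
#' @return list of parameters.
#' @export
event_params <- function(vel_onset = 30, vel_offset = 10, min_sacc_ms = 8,
                         min_fix_ms = 50, blink_pad_ms = 25, fir_order = 50,
                         cutoff_hz = 30, micro_max_deg = 1) {
  as.list(environment())
}

.salgaze_env <- new.env(parent = emptyenv())

# Windowed-sinc FIR low-pass whose single-pass gain at `cutoff_hz` is
# exactly -3 dB (1/sqrt(2)); the corner is solved numerically. DC gain is
# normalized to exactly 1. Cached per (order, cutoff, fs).
fir_lowpass <- function(order = 50, cutoff_hz = 30, fs = 1000) {
  key <- sprintf("fir_%d_%g_%g", order, cutoff_hz, fs)
  if (!is.null(.salgaze_env[[key]])) return(.salgaze_env[[key]])
  gain_at <- function(w, f) {
    h <- signal::fir1(order, w)
    h <- h / sum(h)
    Mod(sum(h * exp(-2i * pi * f * (0:order) / fs)))
  }
  target <- 10^(-3 / 20)
  w <- stats::uniroot(function(w) gain_at(w, cutoff_hz) - target,
                      c(cutoff_hz / fs, 0.5))$root
  h <- signal::fir1(order, w)
  h <- h / sum(h)
  .salgaze_env[[key]] <- h
  h
}

# zero-phase application of a symmetric odd-length FIR kernel: centred
# convolution with edge replication, same length out.
apply_fir <- function(x, h) {
  half <- (length(h) - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, h, sides = 2))[(half + 1):(half + length(x))]
}

#' Smooth a gaze trial
#'
#' Linearly interpolates invalid samples (blinks), applies the zero-phase
#' FIR low-pass to x and y, and keeps a validity mask. Requires an exact
#' 1 ms sampling interval.
#'
#' @param trial a `gaze_trial` (columns `time_ms`, `x_deg`, `y_deg`, `pupil`).
#' @param params [event_params()].
#' @return `filtered_trace`: data.frame with `time_ms`, `x`, `y`, `valid`.
#' @export
smooth_trace <- function(trial, params = event_params()) {
  if (any(diff(trial$time_ms) != 1))
    stop("smooth_trace() requires a 1 kHz (1 ms interval) recording")
  valid <- trial$pupil > 0 & is.finite(trial$x_deg) & is.finite(trial$y_deg)
  if (!any(valid)) {
    out <- data.frame(time_ms = trial$time_ms, x = NA_real_, y = NA_real_,
                      valid = FALSE)
    class(out) <- c("filtered_trace", "data.frame")
    return(out)
  }
  interp <- function(v) {
    if (all(valid)) return(v)
    stats::approx(trial$time_ms[valid], v[valid], xout = trial$time_ms,
                  rule = 2)$y
  }
  h <- fir_lowpass(params$fir_order, params$cutoff_hz)
  out <- data.frame(time_ms = trial$time_ms,
                    x = apply_fir(interp(trial$x_deg), h),
                    y = apply_fir(interp(trial$y_deg), h),
                    valid = valid)
  class(out) <- c("filtered_trace", "data.frame")
  out
}

#' Add velocity and acceleration to a filtered trace
#'
#' Two-point central difference: `v[t] = (p[t+1] - p[t-1]) / (2 dt)`;
#' acceleration is the same operator applied to the velocity components.
#' A forward difference is available for comparison.
#'
#' @param trace a `filtered_trace` from [smooth_trace()].
#' @param method "central" (default) or "forward".
#' @return the trace with `vx`, `vy`, `speed`, `accel` columns (deg/s,
#'   deg/s^2).
#' @export
differentiate <- function(trace, method = c("central", "forward")) {
  method <- match.arg(method)
  n <- nrow(trace)
  if (n < 3) stop("trace too short to differentiate")
  dt <- 1e-3
  dd <- function(p) {
    if (method == "central") {
      v <- c(NA, (p[3:n] - p[1:(n - 2)]) / (2 * dt), NA)
      v[1] <- v[2]; v[n] <- v[n - 1]
    } else {
      v <- c((p[2:n] - p[1:(n - 1)]) / dt, NA)
      v[n] <- v[n - 1]
    }
    v
  }
  trace$vx <- dd(trace$x)
  trace$vy <- dd(trace$y)
  trace$speed <- sqrt(trace$vx^2 + trace$vy^2)
  ax <- dd(trace$vx); ay <- dd(trace$vy)
  trace$accel <- sqrt(ax^2 + ay^2)
  trace
}

# maximal runs of TRUE as (start, end) sample indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Segment a trace into blinks, saccades and fixations
#'
#' Blinks are maximal pupil-zero/invalid runs padded by
#' `blink_pad_ms`. Saccades are runs with speed above `vel_onset` for at
#' least `min_sacc_ms`, extended in both directions until speed falls below
#' `vel_offset`; runs touching a blink are discarded. Fixations are the
#' remaining valid epochs of at least `min_fix_ms`. Every sample belongs to
#' at most one event; short leftover gaps stay unclassified.
#'
#' @param trace differentiated trace (see [differentiate()]).
#' @param params [event_params()].
#' @return an `event_list`: list with data.frames `blinks`
#'   (`onset`, `offset` in ms), `saccades` (`onset`, `offset`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `amplitude`, `class`) and `fixations`
#'   (`onset`, `offset`, `x`, `y`).
#' @export
segment_events <- function(trace, params = event_params()) {
  n <- nrow(trace)
  t0 <- trace$time_ms[1]
  pad <- params$blink_pad_ms

  in_blink <- rep(FALSE, n)
  if (any(!trace$valid)) {
    br0 <- true_runs(!trace$valid)
    for (r in seq_len(nrow(br0))) {
      in_blink[max(1, br0[r, 1] - pad):min(n, br0[r, 2] + pad)] <- TRUE
    }
  }
  blinks <- if (any(in_blink)) {
    br <- true_runs(in_blink)
    data.frame(onset = trace$time_ms[br[, 1]], offset = trace$time_ms[br[, 2]])
  } else data.frame(onset = integer(0), offset = integer(0))

  speed <- trace$speed
  cand <- speed > params$vel_onset & !in_blink
  sacc_mask <- rep(FALSE, n)
  if (any(cand)) {
    runs <- true_runs(cand)
    runs <- runs[runs[, 2] - runs[, 1] + 1 >= params$min_sacc_ms, ,
                 drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, 1]; b <- runs[r, 2]
      while (a > 1 && speed[a - 1] >= params$vel_offset && !in_blink[a - 1])
        a <- a - 1
      while (b < n && speed[b + 1] >= params$vel_offset && !in_blink[b + 1])
        b <- b + 1
      sacc_mask[a:b] <- TRUE
    }
  }
  saccades <- if (any(sacc_mask)) {
    sr <- true_runs(sacc_mask)
    data.frame(
      onset = trace$time_ms[sr[, 1]], offset = trace$time_ms[sr[, 2]],
      x_start = trace$x[sr[, 1]], y_start = trace$y[sr[, 1]],
      x_end = trace$x[sr[, 2]], y_end = trace$y[sr[, 2]])
  } else data.frame(onset = integer(0), offset = integer(0),
                    x_start = numeric(0), y_start = numeric(0),
                    x_end = numeric(0), y_end = numeric(0))
  saccades$amplitude <- sqrt((saccades$x_end - saccades$x_start)^2 +
                               (saccades$y_end - saccades$y_start)^2)

  fix_ok <- trace$valid & !in_blink & !sacc_mask
  fixations <- if (any(fix_ok)) {
    fr <- true_runs(fix_ok)
    fr <- fr[fr[, 2] - fr[, 1] + 1 >= params$min_fix_ms, , drop = FALSE]
    if (nrow(fr)) {
      data.frame(
        onset = trace$time_ms[fr[, 1]], offset = trace$time_ms[fr[, 2]],
        x = vapply(seq_len(nrow(fr)), function(i)
          stats::median(trace$x[fr[i, 1]:fr[i, 2]]), 0),
        y = vapply(seq_len(nrow(fr)), function(i)
          stats::median(trace$y[fr[i, 1]:fr[i, 2]]), 0))
    } else data.frame(onset = integer(0), offset = integer(0),
                      x = numeric(0), y = numeric(0))
  } else data.frame(onset = integer(0), offset = integer(0),
                    x = numeric(0), y = numeric(0))

  ev <- list(blinks = blinks, saccades = saccades, fixations = fixations)
  class(ev) <- "event_list"
  classify_saccades(ev, params)
}

#' Classify saccades as regular or micro
#'
#' Regular if and only if amplitude is strictly greater than
#' `micro_max_deg` (one degree by default); an amplitude of exactly one
#' degree is a microsaccade.
#'
#' @param events an `event_list`.
#' @param params [event_params()].
#' @return the `event_list` with a `class` column on `saccades`.
#' @export
classify_saccades <- function(events, params = event_params()) {
  s <- events$saccades
  s$class <- ifelse(s$amplitude > params$micro_max_deg, "regular", "micro")
  if (nrow(s) == 0) s$class <- character(0)
  events$saccades <- s
  events
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("event_list: %d blinks, %d saccades (%d regular), %d fixations\n",
              nrow(x$blinks), nrow(x$saccades),
              sum(x$saccades$class == "regular"), nrow(x$fixations)))
  invisible(x)
}

#' Detect events in a raw gaze trial
#'
#' Convenience wrapper: [smooth_trace()], [differentiate()],
#' [segment_events()].
#'
#' @inheritParams smooth_trace
#' @return an `event_list`.
#' @export
detect_events <- function(trial, params = event_params()) {
  tr <- smooth_trace(trial, params)
  if (!any(tr$valid)) {
    ev <- list(blinks = data.frame(onset = trial$time_ms[1],
                                   offset = trial$time_ms[nrow(trial)]),
               saccades = data.frame(onset = integer(0), offset = integer(0),
                                     x_start = numeric(0), y_start = numeric(0),
                                     x_end = numeric(0), y_end = numeric(0),
                                     amplitude = numeric(0),
                                     class = character(0)),
               fixations = data.frame(onset = integer(0), offset = integer(0),
                                      x = numeric(0), y = numeric(0)))
    class(ev) <- "event_list"
    return(ev)
  }
  segment_events(differentiate(tr), params)
}
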