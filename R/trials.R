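#' Synthetic gaze trials
#'
#' A synthetic trial is one 8 s, 1 kHz monocular trace: fixation epochs
#' connected by short saccadic position ramps, slow fixational jitter
#' (an Ornstein-Uhlenbeck drift process), and optional blink gaps during
#' which the pupil signal is zero and position is invalid. Each regular
#' saccade endpoint is drawn from a mixture: with probability `bias` from
#' the image's saliency density (a categorical draw over the 80 x 64 cells
#' followed by uniform within-cell jitter), otherwise uniformly over the
#' screen. `bias` is therefore the ground-truth "salience-following"
#' parameter that the downstream salience score estimates.
#'
#' @name trials
NULL

#' Sample saccade endpoints from the saliency/uniform mixture
#'
#' @param map a `saliency_map` (density-normalized).
#' @param bias mixture weight on the saliency density, in \[0, 1\].
#' @param n number of endpoints.
#' @param geometry display geometry.
#' @return data.frame with `x_deg`, `y_deg`, `row`, `col`, `from_map`.
#' @export
sample_endpoints <- function(map, bias, n, geometry = screen_geometry()) {
  stopifnot(inherits(map, "saliency_map"))
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]")
  if (abs(sum(map$values) - 1) > 1e-9) stop("map is not density-normalized")
  n_cells <- length(map$values)
  from_map <- stats::runif(n) < bias
  idx <- integer(n)
  if (any(from_map))
    idx[from_map] <- sample.int(n_cells, sum(from_map), replace = TRUE,
                                prob = as.vector(map$values))
  if (any(!from_map))
    idx[!from_map] <- sample.int(n_cells, sum(!from_map), replace = TRUE)
  row <- ((idx - 1) %% nrow(map$values)) + 1L
  col <- ((idx - 1) %/% nrow(map$values)) + 1L
  pos <- cell_to_deg(row, col, geometry, jitter = TRUE)
  data.frame(x_deg = pos$x_deg, y_deg = pos$y_deg,
             row = row, col = col, from_map = from_map)
}

# Ornstein-Uhlenbeck fixational drift: stationary SD `sd_deg`, time
# constant `tau_ms`. Slow by construction, so it does not masquerade as
# saccadic velocity the way per-sample white noise would.
ou_jitter <- function(n, sd_deg, tau_ms = 100) {
  if (sd_deg <= 0) return(numeric(n))
  rho <- exp(-1 / tau_ms)
  e <- stats::rnorm(n, 0, sd_deg * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd_deg)))
}

#' Generate one synthetic gaze trial
#'
#' Builds an 8000-sample trace of fixations connected by cosine-profile
#' saccade ramps. Regular saccades (default 18) jump to mixture-sampled
#' endpoints; a few microsaccades (amplitude < 1 degree) and blink gaps can
#' be added. Endpoints closer than `min_amp_deg` to the current fixation are
#' redrawn (up to 20 times, then accepted) so that programmed regular
#' saccades are unambiguous ground truth.
#'
#' @param map `saliency_map` the gaze is biased toward.
#' @param bias mixture weight on the map density, in \[0, 1\].
#' @param n_saccades number of regular (programmed) saccades.
#' @param n_micro number of microsaccades.
#' @param n_blinks number of blink gaps; NA draws 0-2 at random.
#' @param duration_ms trial length (1 kHz sampling).
#' @param jitter_sd fixational drift SD in degrees.
#' @param sacc_dur_ms,micro_dur_ms ramp durations.
#' @param min_amp_deg minimum programmed regular-saccade amplitude.
#' @param image_id,subject_id identifiers carried on the trial.
#' @param geometry display geometry.
#' @param seed optional seed (private stream).
#' @return a `gaze_trial`: data.frame with `time_ms`, `x_deg`, `y_deg`,
#'   `pupil`; attributes `image_id`, `subject_id` and `truth` (programmed
#'   event table with onset/offset ms, endpoints and class).
#' @export
generate_trial <- function(map, bias, n_saccades = 18, n_micro = 2,
                           n_blinks = NA, duration_ms = 8000,
                           jitter_sd = 0.05, sacc_dur_ms = 30,
                           micro_dur_ms = 15, min_amp_deg = 1.2,
                           image_id = map$image_id,
                           subject_id = NA_character_,
                           geometry = screen_geometry(), seed = NULL) {
  run <- function() {
    n_ev <- n_saccades + n_micro
    is_micro <- rep(FALSE, n_ev)
    if (n_micro > 0) is_micro[sample.int(n_ev, n_micro)] <- TRUE
    ev_dur <- ifelse(is_micro, micro_dur_ms, sacc_dur_ms)
    fix_total <- duration_ms - sum(ev_dur)
    if (fix_total < 80 * (n_ev + 1))
      stop("too many saccades for the trial duration")
    prop <- stats::rgamma(n_ev + 1, shape = 4)
    fix_dur <- 80 + floor(prop / sum(prop) * (fix_total - 80 * (n_ev + 1)))
    fix_dur[n_ev + 1] <- fix_dur[n_ev + 1] + (fix_total - sum(fix_dur))

    # fixation positions: start at centre, then mixture endpoints
    pos <- matrix(0, n_ev + 1, 2)
    truth <- NULL
    for (i in seq_len(n_ev)) {
      cur <- pos[i, ]
      if (is_micro[i]) {
        amp <- stats::runif(1, 0.2, 0.7)
        ang <- stats::runif(1, 0, 2 * pi)
        nxt <- cur + amp * c(cos(ang), sin(ang))
      } else {
        for (try in 1:20) {
          ep <- sample_endpoints(map, bias, 1, geometry)
          nxt <- c(ep$x_deg, ep$y_deg)
          if (sqrt(sum((nxt - cur)^2)) >= min_amp_deg) break
        }
      }
      pos[i + 1, ] <- nxt
    }

    # assemble the trace
    n <- duration_ms
    x <- numeric(n); y <- numeric(n)
    t0 <- 0
    truth <- data.frame(onset = integer(n_ev), offset = integer(n_ev),
                        x_end = numeric(n_ev), y_end = numeric(n_ev),
                        amplitude = numeric(n_ev),
                        class = character(n_ev))
    for (i in seq_len(n_ev + 1)) {
      f_idx <- (t0 + 1):(t0 + fix_dur[i])
      x[f_idx] <- pos[i, 1]; y[f_idx] <- pos[i, 2]
      t0 <- t0 + fix_dur[i]
      if (i <= n_ev) {
        d <- ev_dur[i]
        ramp <- (1 - cos(pi * seq_len(d) / d)) / 2
        s_idx <- (t0 + 1):(t0 + d)
        x[s_idx] <- pos[i, 1] + (pos[i + 1, 1] - pos[i, 1]) * ramp
        y[s_idx] <- pos[i, 2] + (pos[i + 1, 2] - pos[i, 2]) * ramp
        amp <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
        truth[i, ] <- list(t0, t0 + d - 1L, pos[i + 1, 1], pos[i + 1, 2],
                           amp, if (amp > 1) "regular" else "micro")
        t0 <- t0 + d
      }
    }
    x <- x + ou_jitter(n, jitter_sd)
    y <- y + ou_jitter(n, jitter_sd)

    pupil <- 1000 + as.numeric(ou_jitter(n, 20, 500))
    nb <- if (is.na(n_blinks)) sample(0:2, 1, prob = c(0.5, 0.35, 0.15))
    else n_blinks
    blink_tab <- NULL
    if (nb > 0) {
      # place blinks inside long fixation epochs, away from saccades
      fix_starts <- cumsum(c(0, fix_dur[-(n_ev + 1)] + ev_dur))
      ok <- which(fix_dur >= 450)
      ok <- ok[seq_len(min(nb, length(ok)))]
      for (i in ok) {
        bdur <- round(stats::runif(1, 100, 300))
        b0 <- fix_starts[i] + 60
        idx <- (b0 + 1):(b0 + bdur)
        pupil[idx] <- 0
        x[idx] <- NA_real_; y[idx] <- NA_real_
        blink_tab <- rbind(blink_tab, data.frame(onset = b0, offset = b0 + bdur - 1L))
      }
    }

    trial <- data.frame(time_ms = 0:(n - 1), x_deg = x, y_deg = y,
                        pupil = pupil)
    attr(trial, "image_id") <- image_id
    attr(trial, "subject_id") <- subject_id
    attr(trial, "truth") <- truth
    attr(trial, "blinks") <- blink_tab
    class(trial) <- c("gaze_trial", "data.frame")
    trial
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
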