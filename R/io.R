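#' Reading and writing gaze data, maps and images
#'
#' Plain-text interchange: per-trial CSVs (with identifiers in commented
#' header lines), an EyeLink-ASC-like sample dialect, saliency maps as
#' whitespace-delimited grids, and PNG export of stimuli and map heatmaps.
#'
#' @name salgaze_io
NULL

#' Write / read a gaze trial as CSV
#'
#' Columns `time_ms`, `x_deg`, `y_deg`, `pupil`; `image_id` and
#' `subject_id` are stored in `#`-commented header lines.
#'
#' @param trial a `gaze_trial`.
#' @param path file path.
#' @return `write_trial_csv`: the path, invisibly. `read_trial_csv`: a
#'   `gaze_trial`.
#' @export
write_trial_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# image_id=%s", attr(trial, "image_id")),
               sprintf("# subject_id=%s", attr(trial, "subject_id"))), con)
  utils::write.csv(as.data.frame(trial)[, c("time_ms", "x_deg", "y_deg",
                                            "pupil")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m)) sub(sprintf("^# %s=", key), "", m[1]) else NA_character_
  }
  tr <- utils::read.csv(path, comment.char = "#")
  attr(tr, "image_id") <- meta("image_id")
  attr(tr, "subject_id") <- meta("subject_id")
  class(tr) <- c("gaze_trial", "data.frame")
  tr
}

#' Read an EyeLink-ASC-like sample file
#'
#' Tab- or whitespace-separated lines `timestamp x y pupil`; lines whose
#' first token is not numeric (MSG, SFIX, EFIX, ...) are ignored; missing
#' samples marked `.` become NA with pupil 0.
#'
#' @param path file path.
#' @param units "deg" if x/y are already degrees, "px" to convert screen
#'   pixels to degrees via `geometry`.
#' @param geometry display geometry (used when `units = "px"`).
#' @return a `gaze_trial` data.frame.
#' @export
read_asc_samples <- function(path, units = c("deg", "px"),
                             geometry = screen_geometry()) {
  units <- match.arg(units)
  lines <- readLines(path)
  tok <- strsplit(trimws(lines), "[ \t]+")
  keep <- vapply(tok, function(t)
    length(t) >= 4 && !is.na(suppressWarnings(as.numeric(t[1]))), TRUE)
  tok <- tok[keep]
  num <- function(i) suppressWarnings(as.numeric(vapply(tok, `[`, "", i)))
  t_ms <- num(1); x <- num(2); y <- num(3); pupil <- num(4)
  pupil[is.na(pupil)] <- 0
  pupil[is.na(x) | is.na(y)] <- 0
  t_ms <- t_ms - t_ms[1]
  if (units == "px") {
    d <- px_to_deg(x, y, geometry)
    x <- d$x_deg; y <- d$y_deg
  }
  tr <- data.frame(time_ms = t_ms, x_deg = x, y_deg = y, pupil = pupil)
  class(tr) <- c("gaze_trial", "data.frame")
  tr
}

#' Write / read a saliency map as a plain-text grid
#'
#' @param map a `saliency_map`.
#' @param path file path; channel and image id go into a commented header.
#' @return `write_map`: the path, invisibly; `read_map`: a `saliency_map`.
#' @export
write_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel=%s image_id=%s", map$channel, map$image_id),
             con)
  utils::write.table(format(map$values, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  hdr <- readLines(path, n = 1)
  ch <- sub(".*channel=([a-z]+).*", "\\1", hdr)
  id <- sub(".*image_id=(\\S+).*", "\\1", hdr)
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  saliency_map(to_density(m), ch, id)
}

#' Write an image array or a map heatmap as PNG
#'
#' @param image `h x w x 3` array in \[0, 1\].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' @rdname write_image_png
#' @param map a `saliency_map`; rendered as a normalized grayscale heatmap.
#' @export
write_map_png <- function(map, path) {
  v <- map$values / max(map$values)
  png::writePNG(v, path)
  invisible(path)
}

#' Write the events of a trial as CSV (one row per event)
#'
#' @param events an `event_list`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  b <- events$blinks; s <- events$saccades; f <- events$fixations
  pad <- function(df, type) {
    if (nrow(df) == 0) return(NULL)
    base <- data.frame(type = type, onset = df$onset, offset = df$offset,
                       x_end = NA_real_, y_end = NA_real_,
                       amplitude = NA_real_, class = NA_character_)
    if (type == "saccade") {
      base$x_end <- df$x_end; base$y_end <- df$y_end
      base$amplitude <- df$amplitude; base$class <- df$class
    }
    if (type == "fixation") {
      base$x_end <- df$x; base$y_end <- df$y
    }
    base
  }
  out <- rbind(pad(b, "blink"), pad(s, "saccade"), pad(f, "fixation"))
  out <- out[order(out$onset), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
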