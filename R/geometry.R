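#' Screen geometry for degree/pixel/grid-cell conversions
#'
#' Describes the display used in the recording setup: pixel resolution,
#' physical size (via the panel diagonal, assuming square pixels), viewing
#' distance, and the resolution of the saliency grid laid over the screen.
#' All gaze coordinates in this package are degrees of visual angle relative
#' to the screen centre, x positive rightward and y positive upward; the
#' saliency grid is indexed (row, col) from the top-left of the screen.
#'
#' Degrees are converted to pixels with a single pixel pitch evaluated at the
#' screen centre (small-angle conversion), which is how gaze studies with a
#' central fixation treat a flat panel at this distance.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param diag_inch panel diagonal in inches.
#' @param distance_cm eye-to-screen distance in cm.
#' @param grid saliency grid size as c(columns, rows).
#' @return An object of class `screen_geometry`.
#' @examples
#' geo <- screen_geometry()
#' geo$px_per_deg
#' @export
screen_geometry <- function(width_px = 1280, height_px = 1024,
                            diag_inch = 19, distance_cm = 70,
                            grid = c(80, 64)) {
  stopifnot(width_px > 0, height_px > 0, diag_inch > 0, distance_cm > 0,
            length(grid) == 2, all(grid > 0))
  pitch_cm <- diag_inch * 2.54 / sqrt(width_px^2 + height_px^2)
  px_per_deg <- distance_cm * tan(pi / 180) / pitch_cm
  g <- list(
    width_px = width_px, height_px = height_px,
    distance_cm = distance_cm, pitch_cm = pitch_cm,
    px_per_deg = px_per_deg,
    n_col = as.integer(grid[1]), n_row = as.integer(grid[2]),
    cell_w_px = width_px / grid[1], cell_h_px = height_px / grid[2]
  )
  class(g) <- "screen_geometry"
  g
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen: %d x %d px, %.1f cm viewing distance, %.2f px/deg\n",
              x$width_px, x$height_px, x$distance_cm, x$px_per_deg))
  cat(sprintf("saliency grid: %d x %d cells (%.2f x %.2f deg per cell)\n",
              x$n_col, x$n_row,
              x$cell_w_px / x$px_per_deg, x$cell_h_px / x$px_per_deg))
  invisible(x)
}

#' Convert gaze degrees to screen pixel coordinates
#'
#' Pixel coordinates run from 0 at the left/top edge; a position is
#' on-screen when `0 <= px < width` and `0 <= py < height`.
#'
#' @param x_deg,y_deg gaze position in degrees (y positive upward).
#' @param geometry a [screen_geometry()].
#' @return data.frame with columns `px`, `py`.
#' @export
deg_to_px <- function(x_deg, y_deg, geometry = screen_geometry()) {
  data.frame(
    px = geometry$width_px / 2 + x_deg * geometry$px_per_deg,
    py = geometry$height_px / 2 - y_deg * geometry$px_per_deg
  )
}

#' Convert screen pixel coordinates to degrees
#' @param px,py pixel coordinates (0 at left/top).
#' @inheritParams deg_to_px
#' @return data.frame with columns `x_deg`, `y_deg`.
#' @export
px_to_deg <- function(px, py, geometry = screen_geometry()) {
  data.frame(
    x_deg = (px - geometry$width_px / 2) / geometry$px_per_deg,
    y_deg = (geometry$height_px / 2 - py) / geometry$px_per_deg
  )
}

#' Map gaze degrees to saliency-grid cells
#'
#' @inheritParams deg_to_px
#' @return data.frame with 1-based `row`, `col`; NA for off-screen positions.
#' @export
deg_to_cell <- function(x_deg, y_deg, geometry = screen_geometry()) {
  p <- deg_to_px(x_deg, y_deg, geometry)
  on <- p$px >= 0 & p$px < geometry$width_px &
    p$py >= 0 & p$py < geometry$height_px
  col <- ifelse(on, floor(p$px / geometry$cell_w_px) + 1L, NA_integer_)
  row <- ifelse(on, floor(p$py / geometry$cell_h_px) + 1L, NA_integer_)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Map saliency-grid cells to degrees
#'
#' Returns the cell centre by default; with `jitter = TRUE` a position
#' uniformly distributed within the cell (used when sampling saccade
#' endpoints from a cell-resolution density).
#'
#' @param row,col 1-based grid indices.
#' @param jitter logical; uniform within-cell jitter instead of the centre.
#' @inheritParams deg_to_px
#' @return data.frame with `x_deg`, `y_deg`.
#' @export
cell_to_deg <- function(row, col, geometry = screen_geometry(),
                        jitter = FALSE) {
  stopifnot(all(row >= 1 & row <= geometry$n_row),
            all(col >= 1 & col <= geometry$n_col))
  ox <- if (jitter) stats::runif(length(col)) else rep(0.5, length(col))
  oy <- if (jitter) stats::runif(length(row)) else rep(0.5, length(row))
  px <- (col - 1 + ox) * geometry$cell_w_px
  py <- (row - 1 + oy) * geometry$cell_h_px
  px_to_deg(px, py, geometry)
}
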