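#' Synthetic stimulus sets
#'
#' Procedural stand-ins for the five stimulus categories used in
#' free-viewing sessions: buildings, everyday items, foods, fractal
#' patterns, and grayscale noise. Four images per category, 20 in total.
#' Images are `height x width x 3` arrays in \[0, 1\] at the display
#' resolution; every noise-category image is exactly achromatic
#' (identical R, G and B planes), which is why that category is later
#' excluded from color-contrast analyses.
#'
#' @name stimuli
NULL

STIM_CATEGORIES <- c("buildings", "items", "foods", "fractals", "noise")

# Evaluate code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

new_canvas <- function(h, w, col = c(0.5, 0.5, 0.5)) {
  array(rep(col, each = h * w), c(h, w, 3))
}

fill_rect <- function(img, r0, r1, c0, c1, col) {
  r0 <- max(1, round(r0)); r1 <- min(dim(img)[1], round(r1))
  c0 <- max(1, round(c0)); c1 <- min(dim(img)[2], round(c1))
  if (r0 > r1 || c0 > c1) return(img)
  for (k in 1:3) img[r0:r1, c0:c1, k] <- col[k]
  img
}

fill_disk <- function(img, rc, cc, radius, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- max(1, floor(rc - radius)); r1 <- min(h, ceiling(rc + radius))
  c0 <- max(1, floor(cc - radius)); c1 <- min(w, ceiling(cc + radius))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc2 <- c0:c1
  mask <- outer((rr - rc)^2, (cc2 - cc)^2, "+") <= radius^2
  for (k in 1:3) {
    sub <- img[rr, cc2, k]
    sub[mask] <- col[k]
    img[rr, cc2, k] <- sub
  }
  img
}

# oriented dark bar centred at (rc, cc); theta in degrees, 0 = horizontal
fill_bar <- function(img, rc, cc, length_px, width_px, theta_deg, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- ceiling(length_px / 2) + 2
  r0 <- max(1, rc - half); r1 <- min(h, rc + half)
  c0 <- max(1, cc - half); c1 <- min(w, cc + half)
  rr <- r0:r1; cc2 <- c0:c1
  th <- theta_deg * pi / 180
  # coordinates along (u) and across (v) the bar axis
  dx <- matrix(rep(cc2 - cc, each = length(rr)), length(rr))
  dy <- matrix(rep(rr - rc, times = length(cc2)), length(rr))
  u <- dx * cos(th) - dy * sin(th)
  v <- dx * sin(th) + dy * cos(th)
  mask <- abs(u) <= length_px / 2 & abs(v) <= width_px / 2
  for (k in 1:3) {
    sub <- img[rr, cc2, k]
    sub[mask] <- col[k]
    img[rr, cc2, k] <- sub
  }
  img
}

# multi-octave value noise in [0, 1]
fractal_noise <- function(h, w, octaves = 6, gain = 0.55, base = 5) {
  acc <- matrix(0, h, w)
  amp <- 1
  for (k in seq_len(octaves)) {
    gh <- base * 2^(k - 1); gw <- round(gh * w / h)
    acc <- acc + amp * resize_bilinear(matrix(stats::rnorm(gh * gw), gh, gw), h, w)
    amp <- amp * gain
  }
  acc <- acc - min(acc)
  acc / max(acc)
}

gen_building_image <- function(h, w) {
  sky_top <- c(0.55, 0.7, 0.95); sky_bot <- c(0.8, 0.85, 0.95)
  t <- seq(0, 1, length.out = h)
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- sky_top[k] + (sky_bot[k] - sky_top[k]) * t
  img <- fill_rect(img, h * 0.85, h, 1, w, c(0.35, 0.32, 0.3))
  n_b <- sample(8:14, 1)
  xs <- sort(stats::runif(n_b, 0, w * 0.95))
  for (i in seq_len(n_b)) {
    bw <- stats::runif(1, 0.05, 0.14) * w
    top <- stats::runif(1, 0.15, 0.55) * h
    shade <- stats::runif(1, 0.25, 0.6)
    tint <- shade * c(1, stats::runif(1, 0.9, 1), stats::runif(1, 0.85, 1))
    img <- fill_rect(img, top, h * 0.87, xs[i], xs[i] + bw, tint)
    # window lattice: dark panes drawn in one batched assignment, a random
    # subset re-lit individually
    wr <- seq(round(top) + 8, round(h * 0.83) - 6, by = 14)
    wc <- seq(round(xs[i]) + 5, round(xs[i] + bw) - 7, by = 11)
    if (length(wr) && length(wc)) {
      ri <- unlist(lapply(wr, function(r) r:(r + 5)))
      ci <- unlist(lapply(wc, function(cw) cw:(cw + 4)))
      ri <- ri[ri >= 1 & ri <= h]; ci <- ci[ci >= 1 & ci <= w]
      dark <- c(0.1, 0.12, 0.2)
      for (k in 1:3) img[ri, ci, k] <- dark[k]
      lit <- expand.grid(r = wr, c = wc)
      lit <- lit[stats::runif(nrow(lit)) < 0.3, , drop = FALSE]
      for (j in seq_len(nrow(lit)))
        img <- fill_rect(img, lit$r[j], lit$r[j] + 5, lit$c[j], lit$c[j] + 4,
                         c(0.95, 0.9, 0.6))
    }
  }
  img
}

gen_item_image <- function(h, w) {
  bg <- stats::runif(1, 0.75, 0.9)
  img <- new_canvas(h, w, c(bg, bg, bg))
  n_i <- sample(10:18, 1)
  for (i in seq_len(n_i)) {
    col <- stats::runif(3, 0.05, 0.95)
    rc <- stats::runif(1, 0.08, 0.92) * h; cc <- stats::runif(1, 0.08, 0.92) * w
    sz <- stats::runif(1, 25, 80)
    if (stats::runif(1) < 0.5) {
      img <- fill_disk(img, rc, cc, sz, col)
    } else {
      img <- fill_rect(img, rc - sz, rc + sz, cc - sz * stats::runif(1, 0.4, 1.6),
                       cc + sz * stats::runif(1, 0.4, 1.6), col)
    }
  }
  img
}

gen_food_image <- function(h, w) {
  img <- new_canvas(h, w, c(0.45, 0.3, 0.2))        # table
  pc <- c(h / 2 + stats::runif(1, -60, 60), w / 2 + stats::runif(1, -80, 80))
  pr <- stats::runif(1, 0.3, 0.4) * h
  img <- fill_disk(img, pc[1], pc[2], pr, c(0.92, 0.92, 0.9))   # plate
  warm <- rbind(c(0.8, 0.15, 0.1), c(0.9, 0.55, 0.1), c(0.95, 0.8, 0.2),
                c(0.5, 0.3, 0.1), c(0.3, 0.6, 0.2), c(0.85, 0.4, 0.35))
  n_f <- sample(6:12, 1)
  for (i in seq_len(n_f)) {
    ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, pr * 0.6)
    col <- warm[sample(nrow(warm), 1), ] * stats::runif(1, 0.8, 1.1)
    img <- fill_disk(img, pc[1] + rad * sin(ang), pc[2] + rad * cos(ang),
                     stats::runif(1, 20, 60), clamp01(col))
  }
  img
}

gen_fractal_image <- function(h, w) {
  f <- fractal_noise(h, w)
  ph <- stats::runif(3, 0, 2 * pi); fr <- stats::runif(3, 1.5, 4)
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- 0.5 + 0.5 * sin(2 * pi * fr[k] * f + ph[k])
  img
}

gen_noise_image <- function(h, w) {
  g <- fractal_noise(h, w, octaves = 4, base = 16)
  array(rep(g, 3), c(h, w, 3))   # identical planes: zero color contrast
}

#' Generate a synthetic stimulus set
#'
#' @param seed integer seed; the full set is reproducible byte-for-byte.
#' @param n_per_category images per category (default 4, giving 20 images).
#' @param geometry display geometry fixing the image resolution.
#' @return object of class `stimulus_set`: list with `images` (named list of
#'   arrays), and `info` (data.frame with `image_id`, `category`).
#' @export
generate_stimulus_set <- function(seed = 0, n_per_category = 4,
                                  geometry = screen_geometry()) {
  h <- geometry$height_px; w <- geometry$width_px
  # procedural content is drawn on a half-resolution canvas and upsampled
  # (2x pixel replication); the saliency pyramid low-passes far below
  # this scale, and it keeps generation cheap
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
  up <- function(img) {
    ri <- rep(seq_len(h2), each = 2)[seq_len(h)]
    ci <- rep(seq_len(w2), each = 2)[seq_len(w)]
    array(c(img[ri, ci, 1], img[ri, ci, 2], img[ri, ci, 3]), c(h, w, 3))
  }
  gens <- list(buildings = gen_building_image, items = gen_item_image,
               foods = gen_food_image, fractals = gen_fractal_image,
               noise = gen_noise_image)
  with_seed(seed, {
    images <- list(); info <- NULL
    for (cat in STIM_CATEGORIES) {
      for (i in seq_len(n_per_category)) {
        id <- sprintf("%s_%02d", cat, i)
        images[[id]] <- up(clamp01(gens[[cat]](h2, w2)))
        info <- rbind(info, data.frame(image_id = id, category = cat))
      }
    }
    structure(list(images = images, info = info), class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set: %d images (%s)\n", nrow(x$info),
              paste(sprintf("%s: %d", names(table(x$info$category)),
                            table(x$info$category)), collapse = ", ")))
  invisible(x)
}

#' Generate a visual-search oddball array
#'
#' A grid of homogeneous items with one deviant, used to check that the
#' single-channel saliency maps localize feature pop-out. For
#' `type = "color"` the distractors are achromatic gray squares and the
#' oddball a saturated colored square; for `type = "orientation"` the
#' distractors are vertical bars and the oddball a 45-degree bar. The
#' oddball lattice position is drawn uniformly at random (away from the
#' outermost ring of the lattice so pyramid border effects do not enter).
#'
#' @param type "color" or "orientation".
#' @param seed integer seed.
#' @param geometry display geometry.
#' @return list with `image`, `odd_px` (c(px, py) of the oddball centre) and
#'   `odd_cell` (c(row, col) on the saliency grid).
#' @export
make_oddball_image <- function(type = c("color", "orientation"), seed = 0,
                               geometry = screen_geometry()) {
  type <- match.arg(type)
  h <- geometry$height_px; w <- geometry$width_px
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)   # drawn half-res, upsampled 2x
  with_seed(seed, {
    img <- new_canvas(h2, w2, c(0.5, 0.5, 0.5))
    sp <- 48
    cols <- seq(sp, w2 - sp / 2, by = sp)
    rows <- seq(sp, h2 - sp / 2, by = sp)
    odd_i <- sample(2:(length(rows) - 1), 1)
    odd_j <- sample(2:(length(cols) - 1), 1)
    odd_px <- c(NA_real_, NA_real_)
    for (i in seq_along(rows)) for (j in seq_along(cols)) {
      rc <- rows[i] + stats::runif(1, -4, 4)
      cc <- cols[j] + stats::runif(1, -4, 4)
      is_odd <- (i == odd_i && j == odd_j)
      if (is_odd) odd_px <- 2 * c(cc, rc)
      if (type == "color") {
        col <- if (is_odd) c(0.85, 0.1, 0.1) else c(0.35, 0.35, 0.35)
        img <- fill_rect(img, rc - 8, rc + 8, cc - 8, cc + 8, col)
      } else {
        theta <- if (is_odd) 45 else 90
        img <- fill_bar(img, rc, cc, 22, 5, theta, c(0.08, 0.08, 0.08))
      }
    }
    ri <- rep(seq_len(h2), each = 2)[seq_len(h)]
    ci <- rep(seq_len(w2), each = 2)[seq_len(w)]
    img <- array(c(img[ri, ci, 1], img[ri, ci, 2], img[ri, ci, 3]),
                 c(h, w, 3))
    cell <- deg_to_cell(px_to_deg(odd_px[1], odd_px[2], geometry)$x_deg,
                        px_to_deg(odd_px[1], odd_px[2], geometry)$y_deg,
                        geometry)
    list(image = img, odd_px = odd_px,
         odd_cell = c(row = cell$row, col = cell$col))
  })
}
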