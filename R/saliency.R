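#' Itti-Koch saliency maps as 80x64 density grids
#'
#' The saliency model follows the classic Itti-Koch architecture for static
#' images: a 9-level Gaussian pyramid of low-level features (intensity,
#' red-green and blue-yellow opponency, and Gabor orientation energy at 0,
#' 45, 90 and 135 degrees), center-surround contrasts between pyramid
#' levels c in \{2,3,4\} and s = c + \{3,4\}, Itti's peak-promotion
#' normalization N(.), across-scale summation into per-channel conspicuity
#' maps at pyramid level 4 (80 x 64 cells for a 1280 x 1024 input), and an
#' equal-weight combination of the three channels into the "full" map.
#' Every emitted map is normalized to a probability density (cells sum
#' to one) so that map values can be read directly as densities at saccade
#' endpoints.
#'
#' @name saliency
NULL

SAL_CHANNELS <- c("full", "color", "luminance", "orientation")

#' Construct a saliency map object
#'
#' @param values numeric matrix, `n_row x n_col` (default 64 x 80),
#'   non-negative; will be validated, not modified.
#' @param channel one of "full", "color", "luminance", "orientation".
#' @param image_id identifier of the image the map belongs to.
#' @param normalized if TRUE, require the cells to sum to 1 (1e-9).
#' @return object of class `saliency_map` (list with `values`, `channel`,
#'   `image_id`).
#' @export
saliency_map <- function(values, channel = "full", image_id = NA_character_,
                         normalized = TRUE) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  channel <- match.arg(channel, SAL_CHANNELS)
  if (any(values < 0)) stop("saliency map values must be non-negative")
  if (normalized && abs(sum(values) - 1) > 1e-9)
    stop("saliency map is not density-normalized (sum != 1)")
  structure(list(values = values, channel = channel, image_id = image_id),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map [%s] %d x %d cells, image %s, sum = %.6f\n",
              x$channel, ncol(x$values), nrow(x$values),
              x$image_id, sum(x$values)))
  invisible(x)
}

#' Normalize a non-negative map to a spatial probability density
#'
#' Rescales so the cells sum to one, preserving the ordering of cells.
#' An all-zero map carries no spatial information and falls back to the
#' uniform density (1 / n_cells per cell).
#'
#' @param values non-negative numeric matrix.
#' @return matrix of the same shape summing to 1.
#' @export
to_density <- function(values) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (any(values < 0)) stop("to_density() requires a non-negative map")
  s <- sum(values)
  if (s <= 0) return(matrix(1 / length(values), nrow(values), ncol(values)))
  values / s
}

#' Itti's map normalization operator N(.)
#'
#' Rescales a non-negative map to \[0, 1\] and multiplies by
#' `(1 - m_bar)^2`, where `m_bar` is the mean of the local maxima other
#' than (one instance of) the global maximum. A map with a single dominant
#' peak is promoted (multiplier near 1); a map with many similar peaks is
#' suppressed toward zero. Local maxima are cells that are >= all 8
#' neighbours and exceed `peak_thresh` after rescaling; the threshold keeps
#' flat near-zero background plateaus from counting as peaks. An all-zero
#' map is returned unchanged.
#'
#' @param values non-negative matrix.
#' @param peak_thresh minimum rescaled value for a cell to count as a peak.
#' @return normalized matrix.
#' @export
normalize_iter <- function(values, peak_thresh = 0.05) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("normalize_iter() requires a non-negative map")
  mx <- max(values)
  # numerically-zero maps (e.g. residual convolution noise on featureless
  # input) carry no signal and must not be rescaled to O(1)
  if (mx <= 1e-12) return(values * 0)
  m <- values / mx
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
    is_max <- is_max & (m >= nb)
  }
  peaks <- m[is_max & m > peak_thresh]
  if (length(peaks) <= 1) {
    m_bar <- 0
  } else {
    # drop one instance of the global maximum
    peaks <- peaks[-which.max(peaks)]
    m_bar <- mean(peaks)
  }
  m * (1 - m_bar)^2
}

# ---- feature extraction ---------------------------------------------------

#' Build the feature pyramids for one image
#'
#' Computes 9-level Gaussian pyramids of intensity `I = (R+G+B)/3`, signed
#' red-green and blue-yellow opponency (hue channels normalized by intensity
#' and zeroed where `I` is below 1/10 of its maximum), and Gabor orientation
#' energy of the intensity pyramid at 4 orientations. Grayscale input
#' (single plane, or R=G=B) is accepted: its opponency pyramids are
#' identically zero.
#'
#' @param image numeric array `h x w x 3` (values in \[0, 1\]) or an
#'   `h x w` matrix for grayscale; `h, w >= 64`.
#' @param params saliency parameters, see [saliency_params()].
#' @return object of class `feature_pyramid`: list with `intensity`, `rg`,
#'   `by` (each a list of matrices) and `orientation` (list per angle of
#'   lists of matrices, levels `params$cs_levels` only), plus `dims`.
#' @export
build_pyramids <- function(image, params = saliency_params()) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  if (min(dim(image)[1:2]) < 64)
    stop("image too small: need at least 64 x 64 pixels")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  inten <- (r + g + b) / 3
  thr <- max(inten) / 10
  scale <- ifelse(inten > thr & thr > 0, inten, Inf)   # Inf => zero after division
  rn <- r / scale; gn <- g / scale; bn <- b / scale
  R <- pmax(rn - (gn + bn) / 2, 0)
  G <- pmax(gn - (rn + bn) / 2, 0)
  B <- pmax(bn - (rn + gn) / 2, 0)
  Y <- pmax((rn + gn) / 2 - abs(rn - gn) / 2 - bn, 0)
  n_lev <- params$n_levels
  pyr_i <- gaussian_pyramid(inten, n_lev)
  pyr_rg <- gaussian_pyramid(R - G, n_lev)
  pyr_by <- gaussian_pyramid(B - Y, n_lev)
  need <- sort(unique(c(params$centers, outer(params$centers, params$deltas, "+"))))
  pairs <- lapply(params$orientations, gabor_pair,
                  wavelength = params$gabor_wavelength,
                  sigma = params$gabor_sigma, size = params$gabor_size)
  pyr_or <- lapply(pairs, function(pr) {
    out <- vector("list", n_lev)
    for (k in need) out[[k + 1]] <- gabor_energy(pyr_i[[k + 1]], pr)
    out
  })
  names(pyr_or) <- paste0("theta_", params$orientations)
  structure(list(intensity = pyr_i, rg = pyr_rg, by = pyr_by,
                 orientation = pyr_or, dims = dim(inten), params = params),
            class = "feature_pyramid")
}

#' Center-surround contrast between two pyramid levels
#'
#' `|center - surround|` evaluated at the resolution of the center level,
#' with the surround level upsampled bilinearly.
#'
#' @param pyramid a `feature_pyramid`.
#' @param channel "intensity", "rg", "by", or "theta_0"/"theta_45"/
#'   "theta_90"/"theta_135".
#' @param c_level,s_level 0-based pyramid levels; `s_level > c_level`.
#' @return non-negative matrix at the center level's resolution.
#' @export
center_surround <- function(pyramid, channel, c_level, s_level) {
  stopifnot(inherits(pyramid, "feature_pyramid"), s_level > c_level)
  lv <- if (startsWith(channel, "theta")) pyramid$orientation[[channel]]
  else pyramid[[channel]]
  if (is.null(lv)) stop("unknown channel: ", channel)
  if (s_level + 1 > length(lv) || is.null(lv[[s_level + 1]]))
    stop("surround level ", s_level, " not available in pyramid")
  ctr <- lv[[c_level + 1]]
  sur <- resize_bilinear(lv[[s_level + 1]], nrow(ctr), ncol(ctr))
  abs(ctr - sur)
}

#' Per-channel conspicuity map
#'
#' Sums N()-normalized center-surround maps over all (c, s) scale pairs at
#' the output level (level 4: 80 x 64 for a 1280 x 1024 input). The color
#' channel sums red-green and blue-yellow contributions; the orientation
#' channel normalizes each orientation's across-scale sum before adding.
#'
#' @param pyramid a `feature_pyramid`.
#' @param channel "luminance", "color" or "orientation".
#' @inheritParams build_pyramids
#' @return non-negative matrix (`n_row x n_col` of the output level).
#' @export
conspicuity <- function(pyramid, channel = c("luminance", "color", "orientation"),
                        params = pyramid$params) {
  channel <- match.arg(channel)
  feats <- switch(channel,
                  luminance = "intensity",
                  color = c("rg", "by"),
                  orientation = names(pyramid$orientation))
  out_level <- params$out_level
  acc_feat <- function(f) {
    acc <- NULL
    for (cl in params$centers) for (dl in params$deltas) {
      m <- center_surround(pyramid, f, cl, cl + dl)
      # resample to the common output scale, then apply N(): normalizing
      # at the common resolution keeps the operator scale-consistent
      # across (c, s) pairs
      m <- block_mean(m, 2^(out_level - cl), 2^(out_level - cl))
      m <- normalize_iter(m, params$peak_thresh)
      acc <- if (is.null(acc)) m else acc + m
    }
    acc
  }
  maps <- lapply(feats, acc_feat)
  if (channel == "orientation")
    maps <- lapply(maps, normalize_iter, peak_thresh = params$peak_thresh)
  Reduce(`+`, maps)
}

#' Combine channel conspicuities into the full saliency map
#'
#' `full = (N(color) + N(luminance) + N(orientation)) / 3`, then
#' density-normalized.
#'
#' @param color,luminance,orientation conspicuity matrices of equal shape.
#' @param image_id image identifier carried onto the map.
#' @return a `saliency_map` with channel "full".
#' @export
combine_full <- function(color, luminance, orientation,
                         image_id = NA_character_) {
  stopifnot(all(dim(color) == dim(luminance)),
            all(dim(color) == dim(orientation)))
  full <- (normalize_iter(color) + normalize_iter(luminance) +
             normalize_iter(orientation)) / 3
  saliency_map(to_density(full), "full", image_id)
}

#' Saliency model parameters
#'
#' @param n_levels pyramid depth (level 0 = input resolution).
#' @param centers 0-based center levels for center-surround pairs.
#' @param deltas level offsets of the surround relative to the center.
#' @param out_level level at which conspicuity maps are emitted
#'   (4 gives 80 x 64 for a 1280 x 1024 input).
#' @param orientations Gabor bar orientations in degrees.
#' @param gabor_wavelength,gabor_sigma,gabor_size Gabor kernel parameters
#'   (pixels at each pyramid level).
#' @param peak_thresh see [normalize_iter()].
#' @return list of parameters.
#' @export
saliency_params <- function(n_levels = 9, centers = c(2, 3, 4),
                            deltas = c(3, 4), out_level = 4,
                            orientations = c(0, 45, 90, 135),
                            gabor_wavelength = 6, gabor_sigma = 3,
                            gabor_size = 13, peak_thresh = 0.05) {
  stopifnot(max(centers) + max(deltas) <= n_levels - 1,
            out_level >= max(centers))
  as.list(environment())
}

#' Compute saliency maps for an image
#'
#' Runs the full model: images that are not at the display resolution
#' (1024 x 1280) are first resized to it, so the emitted grid is always
#' 80 columns x 64 rows. Returns density-normalized maps for the requested
#' channels; the "full" map is the equal-weight combination of the three
#' feature channels.
#'
#' @param image `h x w x 3` array in \[0, 1\] (or grayscale matrix).
#' @param channels subset of "full", "color", "luminance", "orientation".
#' @param image_id identifier attached to the maps.
#' @param geometry display geometry (fixes the target resolution).
#' @inheritParams build_pyramids
#' @return named list of `saliency_map` objects.
#' @export
compute_saliency <- function(image, channels = SAL_CHANNELS,
                             image_id = NA_character_,
                             geometry = screen_geometry(),
                             params = saliency_params()) {
  channels <- match.arg(channels, SAL_CHANNELS, several.ok = TRUE)
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  tgt <- c(geometry$height_px, geometry$width_px)
  if (!all(dim(image)[1:2] == tgt)) {
    image <- array(
      c(resize_bilinear(image[, , 1], tgt[1], tgt[2]),
        resize_bilinear(image[, , 2], tgt[1], tgt[2]),
        resize_bilinear(image[, , 3], tgt[1], tgt[2])),
      c(tgt, 3))
  }
  need_feat <- unique(unlist(lapply(channels, function(ch)
    if (ch == "full") c("color", "luminance", "orientation") else ch)))
  pyr <- build_pyramids(image, params)
  consp <- lapply(stats::setNames(need_feat, need_feat),
                  function(ch) conspicuity(pyr, ch, params))
  out <- list()
  for (ch in channels) {
    out[[ch]] <- if (ch == "full") {
      combine_full(consp$color, consp$luminance, consp$orientation, image_id)
    } else {
      saliency_map(to_density(consp[[ch]]), ch, image_id)
    }
  }
  out
}
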