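#' Salience scores at saccade endpoints
#'
#' The per-subject "salience score" for a map channel is computed in two
#' fixed stages: within each analysis image, the mean map density at the
#' endpoints of the subject's regular saccades; then the unweighted mean of
#' those per-image values across images. Noise-category images carry no
#' color contrast and are excluded from the analysis set (16 of 20 images
#' by default). On a uniform map every lookup is exactly `1/n_cells`
#' (1/5120 on the 80 x 64 grid), which fixes the chance baseline of the
#' score.
#'
#' @name scoring
NULL

#' Look up map density at gaze positions
#'
#' Nearest-cell lookup (maps are density histograms over cells, so no
#' interpolation); off-screen positions return NA.
#'
#' @param map a density-normalized `saliency_map`.
#' @param x_deg,y_deg gaze positions in degrees.
#' @param geometry display geometry.
#' @return numeric vector of densities (NA where off-screen).
#' @export
lookup_salience <- function(map, x_deg, y_deg, geometry = screen_geometry()) {
  stopifnot(inherits(map, "saliency_map"))
  if (abs(sum(map$values) - 1) > 1e-9)
    stop("lookup_salience() requires a density-normalized map")
  cells <- deg_to_cell(x_deg, y_deg, geometry)
  out <- rep(NA_real_, length(x_deg))
  ok <- !is.na(cells$row)
  out[ok] <- map$values[cbind(cells$row[ok], cells$col[ok])]
  out
}

#' Mean salience at a trial's saccade endpoints
#'
#' @param map `saliency_map` of the image shown in the trial.
#' @param events `event_list` for the trial.
#' @param include_micro include microsaccade endpoints (default: regular
#'   saccades only).
#' @param geometry display geometry.
#' @return mean density over usable endpoints, or NA if there are none.
#' @export
score_image <- function(map, events, include_micro = FALSE,
                        geometry = screen_geometry()) {
  s <- events$saccades
  if (!include_micro) s <- s[s$class == "regular", , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  v <- lookup_salience(map, s$x_end, s$y_end, geometry)
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Select the analysis images
#'
#' Drops the noise category (zero color contrast) from a stimulus set.
#'
#' @param stimulus_set a `stimulus_set`.
#' @param exclude categories to exclude.
#' @return the stimulus set restricted to the remaining images.
#' @export
filter_images <- function(stimulus_set, exclude = "noise") {
  keep <- !(stimulus_set$info$category %in% exclude)
  out <- list(images = stimulus_set$images[stimulus_set$info$image_id[keep]],
              info = stimulus_set$info[keep, , drop = FALSE])
  rownames(out$info) <- NULL
  class(out) <- "stimulus_set"
  out
}

#' Per-subject salience scores across analysis images
#'
#' @param per_image_scores named list (by channel) of numeric vectors of
#'   per-image mean densities (NAs mark unusable images).
#' @param n_saccades_total total usable endpoints (bookkeeping).
#' @return one-row data.frame `score_<channel>`, `n_images_used`,
#'   `n_saccades_total`, or NULL (with a warning) if no image was usable.
#' @export
subject_score <- function(per_image_scores, n_saccades_total = NA_integer_) {
  used <- !is.na(per_image_scores[[1]])
  if (!any(used)) {
    warning("subject has no usable analysis image; excluded")
    return(NULL)
  }
  out <- data.frame(n_images_used = sum(used),
                    n_saccades_total = n_saccades_total)
  for (ch in names(per_image_scores))
    out[[paste0("score_", ch)]] <- mean(per_image_scores[[ch]], na.rm = TRUE)
  out[, c(paste0("score_", names(per_image_scores)),
          "n_images_used", "n_saccades_total")]
}

#' Compute saliency maps for every image of a stimulus set
#'
#' @param stimulus_set a `stimulus_set` (typically after [filter_images()]).
#' @param channels channels to compute.
#' @param geometry display geometry.
#' @param params saliency parameters.
#' @return named list (by image id) of named lists of `saliency_map`s.
#' @export
compute_set_maps <- function(stimulus_set, channels = SAL_CHANNELS,
                             geometry = screen_geometry(),
                             params = saliency_params()) {
  out <- lapply(stimulus_set$info$image_id, function(id)
    compute_saliency(stimulus_set$images[[id]], channels, image_id = id,
                     geometry = geometry, params = params))
  names(out) <- stimulus_set$info$image_id
  out
}

#' Score one subject's trials against per-image maps
#'
#' Runs event detection on each trial and averages endpoint densities:
#' per-image first, then across images.
#'
#' @param trials list of `gaze_trial`s (attribute `image_id` links each to
#'   its map).
#' @param maps per-image channel maps as from [compute_set_maps()]; trials
#'   whose image has no map entry (e.g. noise category) are skipped.
#' @param include_micro include microsaccade endpoints.
#' @param geometry display geometry.
#' @param event_params detector settings.
#' @return one-row data.frame as from [subject_score()], or NULL.
#' @export
score_subject <- function(trials, maps, include_micro = FALSE,
                          geometry = screen_geometry(),
                          event_params = salgaze::event_params()) {
  channels <- names(maps[[1]])
  per_img <- stats::setNames(
    rep(list(rep(NA_real_, length(maps))), length(channels)), channels)
  n_end <- 0
  img_ids <- names(maps)
  for (trial in trials) {
    id <- attr(trial, "image_id")
    j <- match(id, img_ids)
    if (is.na(j)) next
    ev <- detect_events(trial, event_params)
    s <- ev$saccades
    if (!include_micro) s <- s[s$class == "regular", , drop = FALSE]
    n_end <- n_end + nrow(s)
    for (ch in channels)
      per_img[[ch]][j] <- score_image(maps[[id]][[ch]], ev, include_micro,
                                      geometry)
  }
  subject_score(per_img, n_saccades_total = n_end)
}

#' Generate trials and score a whole cohort through the full pipeline
#'
#' For each subject, generates `length(maps)` trials (one per analysis
#' image, in subject-specific random order) whose endpoints follow the
#' subject's ground-truth bias, then detects events and scores them. This
#' is the end-to-end route; for statistics-scale cohorts prefer
#' [simulate_scores()].
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param maps per-image channel maps (must include "full").
#' @param n_saccades,n_micro programmed saccades per trial.
#' @param jitter_sd fixational drift SD (degrees).
#' @param geometry display geometry.
#' @param event_params detector settings.
#' @param seed seed for the trial stream.
#' @return data.frame: cohort columns joined with per-subject scores.
#' @export
score_cohort <- function(cohort, maps, n_saccades = 18, n_micro = 2,
                         jitter_sd = 0.05, geometry = screen_geometry(),
                         event_params = salgaze::event_params(), seed = 1) {
  with_seed(seed, {
    rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      order_ids <- sample(names(maps))
      trials <- lapply(order_ids, function(id)
        generate_trial(maps[[id]][["full"]], bias = cohort$bias[i],
                       n_saccades = n_saccades, n_micro = n_micro,
                       jitter_sd = jitter_sd, image_id = id,
                       subject_id = cohort$subject_id[i],
                       geometry = geometry))
      sc <- score_subject(trials, maps, geometry = geometry,
                          event_params = event_params)
      if (!is.null(sc)) rows[[i]] <- cbind(cohort[i, ], sc)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
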