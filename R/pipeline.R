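#' End-to-end pipeline with a YAML-serializable configuration
#'
#' One configuration object drives the full chain: stimulus generation,
#' saliency maps, cohort generation, trial synthesis, event detection,
#' scoring, and the multi-site statistics. Every numeric choice that the
#' analysis depends on (geometry, detector thresholds, saliency parameters,
#' generator design) lives in the config with a documented default, and a
#' serialized copy is written into each run directory.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' The `cohort` section sizes the demo run (kept small so a full run with
#' trace-level synthesis completes in minutes); statistics-scale studies
#' use [simulate_scores()] with designs built from [calibrate_bias()].
#'
#' @param seed master seed for the run.
#' @return nested list (class `salgaze_config`).
#' @export
default_config <- function(seed = 1) {
  cfg <- list(
    seed = seed,
    geometry = list(width_px = 1280, height_px = 1024, diag_inch = 19,
                    distance_cm = 70),
    saliency = list(n_levels = 9, centers = c(2, 3, 4), deltas = c(3, 4),
                    out_level = 4, orientations = c(0, 45, 90, 135),
                    gabor_wavelength = 6, gabor_sigma = 3, gabor_size = 13,
                    peak_thresh = 0.05),
    events = list(vel_onset = 30, vel_offset = 10, min_sacc_ms = 8,
                  min_fix_ms = 50, blink_pad_ms = 25, fir_order = 50,
                  cutoff_hz = 30, micro_max_deg = 1),
    generator = list(n_per_category = 4, n_saccades = 18, n_micro = 2,
                     jitter_sd = 0.05, bias_sd = 0.08, pi_hc = 0.3),
    cohort = list(design = "two_group", n_sites = 2, n_per_group = 6,
                  d_target = 0.8, route = "traces"),
    scoring = list(include_micro = FALSE),
    stats = list(ref_age = 35.75, min_per_group = 5,
                 channels = c("full", "color", "luminance", "orientation"))
  )
  class(cfg) <- c("salgaze_config", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks presence and basic sanity of every required field; errors name
#' the offending field.
#'
#' @param config a config list (e.g. from [default_config()] or
#'   [read_config()]).
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  need <- list(
    seed = NULL,
    geometry = c("width_px", "height_px", "diag_inch", "distance_cm"),
    saliency = c("n_levels", "centers", "deltas", "out_level"),
    events = c("vel_onset", "vel_offset", "min_sacc_ms", "min_fix_ms",
               "blink_pad_ms", "fir_order", "cutoff_hz", "micro_max_deg"),
    generator = c("n_saccades", "n_micro", "jitter_sd", "bias_sd", "pi_hc"),
    cohort = c("design", "route"),
    scoring = "include_micro",
    stats = c("ref_age", "channels")
  )
  for (sec in names(need)) {
    if (is.null(config[[sec]]))
      stop("config is missing the '", sec, "' section")
    for (f in need[[sec]]) {
      if (is.null(config[[sec]][[f]]))
        stop("config is missing field '", sec, ".", f, "'")
    }
  }
  if (config$generator$pi_hc < 0 || config$generator$pi_hc > 1)
    stop("config field 'generator.pi_hc' must be in [0, 1]")
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config`: a validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("salgaze_config", "list")
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_geometry <- function(config) {
  g <- config$geometry
  screen_geometry(g$width_px, g$height_px, g$diag_inch, g$distance_cm)
}

config_sal_params <- function(config) {
  s <- config$saliency
  saliency_params(n_levels = s$n_levels, centers = s$centers,
                  deltas = s$deltas, out_level = s$out_level,
                  orientations = s$orientations,
                  gabor_wavelength = s$gabor_wavelength,
                  gabor_sigma = s$gabor_sigma, gabor_size = s$gabor_size,
                  peak_thresh = s$peak_thresh)
}

config_event_params <- function(config) {
  e <- config$events
  event_params(vel_onset = e$vel_onset, vel_offset = e$vel_offset,
               min_sacc_ms = e$min_sacc_ms, min_fix_ms = e$min_fix_ms,
               blink_pad_ms = e$blink_pad_ms, fir_order = e$fir_order,
               cutoff_hz = e$cutoff_hz, micro_max_deg = e$micro_max_deg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Generates stimuli, computes saliency maps for the analysis images,
#' generates a cohort with known salience-following bias, synthesizes and
#' scores gaze trials (or samples endpoints directly when
#' `cohort.route = "endpoints"`), runs per-site effect sizes plus the
#' fixed-effects meta-analysis for each channel (and the cross-disorder GLM
#' when more than two groups are present), and writes everything into
#' `out_dir` together with the serialized config and a checksum manifest.
#'
#' @param config a validated configuration.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the output directory, invisibly; side effects: `config.yaml`,
#'   `scores.csv`, `effect_sizes.csv`, `meta.csv`, `forest_<channel>.csv`,
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  geometry <- config_geometry(config)
  sal_par <- config_sal_params(config)
  ev_par <- config_event_params(config)

  say("stage: stimuli")
  stimuli <- run_stage("stimuli", generate_stimulus_set(
    config$seed, config$generator$n_per_category, geometry))
  analysis <- run_stage("stimuli", filter_images(stimuli))

  say("stage: saliency (", nrow(analysis$info), " images)")
  maps <- run_stage("saliency", compute_set_maps(
    analysis, config$stats$channels, geometry, sal_par))

  say("stage: cohort")
  cohort <- run_stage("cohort", {
    calib <- calibrate_bias(lapply(maps, `[[`, "full"),
                            n_endpoints = config$generator$n_saccades,
                            bias_sd = config$generator$bias_sd)
    design <- switch(config$cohort$design,
                     two_group = design_two_group(
                       calib, n_sites = config$cohort$n_sites,
                       n_per_group = config$cohort$n_per_group,
                       d_target = config$cohort$d_target,
                       pi_hc = config$generator$pi_hc,
                       bias_sd = config$generator$bias_sd,
                       seed = config$seed),
                     cross_disorder = design_cross_disorder(
                       calib, pi_hc = config$generator$pi_hc,
                       bias_sd = config$generator$bias_sd,
                       seed = config$seed),
                     stop("unknown cohort design: ", config$cohort$design))
    generate_cohort(design)
  })

  say("stage: scoring (", nrow(cohort), " subjects, route = ",
      config$cohort$route, ")")
  scores <- run_stage("scoring", switch(
    config$cohort$route,
    traces = score_cohort(cohort, maps,
                          n_saccades = config$generator$n_saccades,
                          n_micro = config$generator$n_micro,
                          jitter_sd = config$generator$jitter_sd,
                          geometry = geometry, event_params = ev_par,
                          seed = config$seed + 1),
    endpoints = simulate_scores(cohort, maps,
                                n_endpoints = config$generator$n_saccades,
                                seed = config$seed + 1),
    stop("unknown scoring route: ", config$cohort$route)))

  say("stage: stats")
  stats_files <- run_stage("stats", {
    files <- character(0)
    es_all <- NULL; meta_rows <- NULL
    min_pg <- config$stats$min_per_group %||% 5
    groups <- intersect(c("HC", "SZ"), as.character(unique(scores$diagnosis)))
    for (ch in config$stats$channels) {
      es <- site_effect_sizes(scores, ch, groups = groups,
                              min_per_group = min_pg)
      meta <- fixed_effects_meta(es)
      es_all <- rbind(es_all, es)
      meta_rows <- rbind(meta_rows, data.frame(
        channel = ch, d = meta$d, se = meta$se, z = meta$z, p = meta$p,
        ci_lower = meta$ci[1], ci_upper = meta$ci[2],
        n_sites = nrow(es)))
      fpath <- file.path(out_dir, sprintf("forest_%s.csv", ch))
      utils::write.csv(forest_table(meta), fpath, row.names = FALSE)
      files <- c(files, fpath)
    }
    p1 <- file.path(out_dir, "effect_sizes.csv")
    p2 <- file.path(out_dir, "meta.csv")
    utils::write.csv(es_all, p1, row.names = FALSE)
    utils::write.csv(meta_rows, p2, row.names = FALSE)
    files <- c(files, p1, p2)
    if (length(unique(scores$diagnosis)) > 2) {
      glm_rows <- do.call(rbind, lapply(config$stats$channels, function(ch) {
        g <- cross_disorder_glm(scores, ch, ref_age = config$stats$ref_age)
        cbind(channel = ch, g$emmeans, p_diagnosis = g$p_diagnosis)
      }))
      p3 <- file.path(out_dir, "glm_emmeans.csv")
      utils::write.csv(glm_rows, p3, row.names = FALSE)
      files <- c(files, p3)
    }
    files
  })

  scores_path <- file.path(out_dir, "scores.csv")
  utils::write.csv(scores, scores_path, row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)

  out_files <- c(scores_path, stats_files, cfg_path)
  manifest <- list(
    package = "salgaze",
    version = as.character(utils::packageVersion("salgaze")),
    seed = config$seed,
    files = lapply(stats::setNames(out_files, basename(out_files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", out_dir)
  invisible(out_dir)
}
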