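#' Synthetic cohorts with group- and site-structured salience bias
#'
#' A cohort design specifies, per site and diagnostic group, how many
#' subjects to draw and with what demographics, plus the group-level
#' salience-following bias. Each subject's bias `pi` is Beta-distributed
#' around the group mean (shifted by a per-site offset and small age/sex
#' effects); `pi` is the ground truth that the pipeline's salience score
#' estimates, so group differences in `pi` translate into recoverable
#' effect sizes.
#'
#' @name cohort
NULL

DIAGNOSES <- c("HC", "SZ", "BD", "MDD", "ASD")

#' Multi-site demographic table emulating a published mega-analysis cohort
#'
#' Per-site sex counts and age summaries for 5 diagnostic groups across 7
#' sites (550 HC, 238 SZ, 41 BD, 50 MDD, 133 ASD; 1012 in total), shipped
#' as a plain-text fixture.
#'
#' @return data.frame with `site`, `diagnosis`, `n_male`, `n_female`,
#'   `age_mean`, `age_sd`.
#' @export
cohort_table1 <- function() {
  path <- system.file("extdata", "cohort_table1.csv", package = "salgaze")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$diagnosis <- factor(tab$diagnosis, levels = DIAGNOSES)
  tab
}

#' Construct a cohort design
#'
#' @param groups data.frame with columns `site`, `diagnosis`, `n_male`,
#'   `n_female`, `age_mean`, `age_sd`.
#' @param bias named vector of group-mean salience bias `pi` (one entry per
#'   diagnosis present in `groups`), each in \[0, 1\].
#' @param bias_sd between-subject SD of `pi` within a group (Beta scale).
#' @param site_bias named per-site additive offset on `pi`; defaults to
#'   small offsets in \[-0.02, 0.02\] spread over the sites.
#' @param age_coef,sex_coef additive effects of (age - 40) years and male
#'   sex on `pi`.
#' @param seed integer seed fixing the whole generated stream.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups, bias, bias_sd = 0.08, site_bias = NULL,
                          age_coef = -0.0008, sex_coef = 0.01, seed = 1) {
  need <- c("site", "diagnosis", "n_male", "n_female", "age_mean", "age_sd")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (nrow(groups) == 0 || sum(groups$n_male + groups$n_female) == 0)
    stop("empty cohort design")
  dx <- unique(as.character(groups$diagnosis))
  if (!all(dx %in% names(bias)))
    stop("bias must name every diagnosis in the design")
  if (any(bias < 0 | bias > 1)) stop("group bias must be in [0, 1]")
  sites <- unique(groups$site)
  if (is.null(site_bias)) {
    site_bias <- stats::setNames(
      seq(-0.02, 0.02, length.out = max(length(sites), 2))[seq_along(sites)],
      sites)
  }
  structure(list(groups = groups, bias = bias, bias_sd = bias_sd,
                 site_bias = site_bias, age_coef = age_coef,
                 sex_coef = sex_coef, seed = seed),
            class = "cohort_design")
}

rbeta_ms <- function(n, mean, sd) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  v <- min(sd^2, mean * (1 - mean) * 0.9)
  nu <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

#' Generate a cohort table from a design
#'
#' Draws per-subject demographics and the ground-truth salience bias.
#' Symptom-scale scores (PANSS-like totals for SZ, HAMD-like for MDD) and
#' medication doses are drawn independently of the bias by default, giving
#' a null for correlation screens.
#'
#' @param design a [cohort_design()].
#' @return data.frame with one row per subject: `subject_id`, `site`,
#'   `diagnosis`, `age`, `sex`, `bias`, `scale_score`, `med_dose`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    rows <- vector("list", nrow(design$groups))
    for (i in seq_len(nrow(design$groups))) {
      g <- design$groups[i, ]
      n <- g$n_male + g$n_female
      if (n == 0) next
      sex <- sample(rep(c("M", "F"), c(g$n_male, g$n_female)))
      age_sd <- if (is.na(g$age_sd)) 0 else g$age_sd
      age <- pmax(stats::rnorm(n, g$age_mean, age_sd), 6)
      dxc <- as.character(g$diagnosis)
      mu <- design$bias[[dxc]] + design$site_bias[[g$site]]
      pi0 <- rbeta_ms(n, mu, design$bias_sd)
      pi <- pmin(pmax(pi0 + design$age_coef * (age - 40) +
                        design$sex_coef * (sex == "M"), 0.01), 0.99)
      scale_score <- rep(NA_real_, n)
      med_dose <- rep(NA_real_, n)
      if (dxc == "SZ") {
        scale_score <- round(pmin(pmax(stats::rnorm(n, 75, 15), 30), 210))
        med_dose <- round(stats::rlnorm(n, log(400), 0.5))
      } else if (dxc == "MDD") {
        scale_score <- round(pmin(pmax(stats::rnorm(n, 18, 6), 0), 52))
        med_dose <- round(stats::rlnorm(n, log(150), 0.5))
      } else if (dxc == "BD") {
        med_dose <- round(stats::rlnorm(n, log(600), 0.4))
      }
      rows[[i]] <- data.frame(
        site = g$site, diagnosis = dxc, age = round(age, 1), sex = sex,
        bias = pi, scale_score = scale_score, med_dose = med_dose)
    }
    out <- do.call(rbind, rows)
    out <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(out))), out)
    out$diagnosis <- factor(out$diagnosis, levels = DIAGNOSES)
    out$sex <- factor(out$sex, levels = c("F", "M"))
    rownames(out) <- NULL
    out
  })
}

#' Analytic calibration of the bias-to-score mapping
#'
#' For endpoints drawn from the mixture `pi * map + (1 - pi) * uniform`,
#' the expected density at an endpoint is linear in `pi`:
#' `E[score | pi] = a + b * pi` with `a = 1/n_cells` and
#' `b = mean_i(sum(p_i^2)) - 1/n_cells`. The within-group score SD combines
#' the between-subject Beta spread of `pi` with the endpoint-sampling noise
#' (computed from the exact second moments of each map). `delta_pi(d)`
#' inverts this to the group-mean bias shift that produces a true
#' standardized difference `d`.
#'
#' @param maps list of full-channel `saliency_map`s for the analysis images.
#' @param n_endpoints regular-saccade endpoints per image per subject.
#' @param bias_sd between-subject SD of `pi`.
#' @return list with `a`, `b`, `sigma_score(pi)` and `delta_pi(d, pi_ref)`.
#' @export
calibrate_bias <- function(maps, n_endpoints = 18, bias_sd = 0.08) {
  vals <- lapply(maps, function(m) {
    if (inherits(m, "saliency_map")) m$values else m
  })
  n_cells <- length(vals[[1]])
  u <- 1 / n_cells
  s2 <- vapply(vals, function(p) sum(p^2), 0)
  s3 <- vapply(vals, function(p) sum(p^3), 0)
  m <- length(vals)
  a <- u
  b <- mean(s2) - u
  v_noise <- function(pi) {
    vi <- pi * s3 + (1 - pi) * s2 / n_cells - (pi * s2 + (1 - pi) * u)^2
    sum(vi / n_endpoints) / m^2
  }
  sigma_score <- function(pi) sqrt(b^2 * bias_sd^2 + v_noise(pi))
  delta_pi <- function(d, pi_ref = 0.3) {
    dl <- d * sigma_score(pi_ref) / b
    d * sigma_score(min(pi_ref + dl / 2, 0.95)) / b
  }
  list(a = a, b = b, sigma_score = sigma_score, delta_pi = delta_pi)
}

#' Fast endpoint-level simulation of subject salience scores
#'
#' Draws each subject's saccade endpoints directly from the
#' saliency/uniform mixture and averages map densities at those endpoints,
#' reproducing the statistical structure of the full
#' trace-generation/event-detection/scoring route at a fraction of the
#' cost. Used for statistics-scale simulations (effect-size recovery,
#' cross-disorder ordering); the full route is validated separately.
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param maps per-image saliency maps: a named list (by image id), each
#'   element a named list of `saliency_map`s with at least the "full"
#'   channel (endpoints are drawn from the full-map mixture; scores are
#'   computed for every channel present).
#' @param n_endpoints endpoints per image per subject.
#' @param seed optional seed (private stream).
#' @return data.frame: cohort columns plus `score_<channel>`,
#'   `n_images_used`, `n_saccades_total`.
#' @export
simulate_scores <- function(cohort, maps, n_endpoints = 18, seed = NULL) {
  run <- function() {
    channels <- names(maps[[1]])
    n_s <- nrow(cohort)
    k <- n_endpoints
    n_cells <- length(maps[[1]][[1]]$values)
    acc <- matrix(0, n_s, length(channels),
                  dimnames = list(NULL, channels))
    for (img in names(maps)) {
      p_full <- as.vector(maps[[img]][["full"]]$values)
      if (is.null(p_full)) stop("maps must include the 'full' channel")
      m_from <- stats::rbinom(n_s, k, cohort$bias)
      cells_map <- sample.int(n_cells, sum(m_from), replace = TRUE,
                              prob = p_full)
      cells_unf <- sample.int(n_cells, n_s * k - sum(m_from), replace = TRUE)
      subj <- c(rep(seq_len(n_s), m_from), rep(seq_len(n_s), k - m_from))
      ord <- order(subj)
      cells <- c(cells_map, cells_unf)[ord]
      for (ch in channels) {
        v <- as.vector(maps[[img]][[ch]]$values)[cells]
        dim(v) <- c(k, n_s)
        acc[, ch] <- acc[, ch] + colMeans(v)
      }
    }
    acc <- acc / length(maps)
    out <- cohort
    for (ch in channels) out[[paste0("score_", ch)]] <- acc[, ch]
    out$n_images_used <- length(maps)
    out$n_saccades_total <- k * length(maps)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Two-group multi-site design calibrated to a target effect size
#'
#' Builds an HC-vs-SZ design with `n_sites` sites and `n_per_group`
#' subjects per group per site, with the SZ group-mean bias placed so the
#' true covariate-adjusted standardized difference equals `d_target`
#' (via [calibrate_bias()]).
#'
#' @param calib result of [calibrate_bias()] for the analysis maps.
#' @param n_sites,n_per_group design size.
#' @param d_target true standardized HC-vs-SZ difference.
#' @param pi_hc HC group-mean bias.
#' @param bias_sd between-subject bias SD.
#' @param seed design seed.
#' @return a [cohort_design()].
#' @export
design_two_group <- function(calib, n_sites = 3, n_per_group = 100,
                             d_target = 0.8, pi_hc = 0.3, bias_sd = 0.08,
                             seed = 1) {
  pi_sz <- pi_hc + calib$delta_pi(d_target, pi_hc)
  if (pi_sz > 0.98) stop("target effect size not reachable with pi in [0,1]")
  sites <- sprintf("SITE%d", seq_len(n_sites))
  groups <- expand.grid(site = sites, diagnosis = c("HC", "SZ"),
                        stringsAsFactors = FALSE)
  groups$n_male <- ceiling(n_per_group / 2)
  groups$n_female <- n_per_group - groups$n_male
  groups$age_mean <- 36
  groups$age_sd <- 12
  cohort_design(groups, bias = c(HC = pi_hc, SZ = pi_sz), bias_sd = bias_sd,
                site_bias = stats::setNames(rep(0, n_sites), sites),
                seed = seed)
}

#' Cross-disorder design at published-cohort scale
#'
#' Uses the packaged demographic table ([cohort_table1()]) for sample
#' sizes, ages and sexes, and places the five group-mean biases so the
#' ground-truth ordering of standardized shifts is
#' SZ > BD > MDD > ASD > HC. The default shifts (in within-group SD units)
#' are sized so the ordering is statistically recoverable at these group
#' sizes (smallest group n = 41).
#'
#' @param calib result of [calibrate_bias()].
#' @param shifts named vector of true standardized shifts relative to HC.
#' @param pi_hc HC group-mean bias.
#' @param bias_sd between-subject bias SD.
#' @param seed design seed.
#' @return a [cohort_design()].
#' @export
design_cross_disorder <- function(calib,
                                  shifts = c(HC = 0, ASD = 0.35, MDD = 0.95,
                                             BD = 1.55, SZ = 2.15),
                                  pi_hc = 0.25, bias_sd = 0.08, seed = 1) {
  bias <- pi_hc + vapply(shifts, calib$delta_pi, 0, pi_ref = pi_hc)
  if (any(bias > 0.98)) stop("shifts not reachable with pi in [0,1]")
  cohort_design(cohort_table1(), bias = bias, bias_sd = bias_sd, seed = seed)
}
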