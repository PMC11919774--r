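#' Multi-site effect sizes, meta-analysis and cross-disorder GLMs
#'
#' The statistical pipeline mirrors multi-site gaze mega-analyses: within
#' each site, the patient-vs-control difference in a salience score is
#' expressed as an unbiased standardized mean difference (Hedges-corrected
#' d) from a linear regression controlling for age and sex; site estimates
#' are pooled with an inverse-variance fixed-effects model; cross-disorder
#' comparisons use a general linear model controlling for age, sex and
#' site, with Bonferroni-corrected pairwise contrasts of estimated marginal
#' means evaluated at a fixed reference age.
#'
#' @name salience_stats
NULL

#' Covariate-adjusted unbiased d within one site
#'
#' Fits `score ~ group + covariates` by least squares on the subjects of
#' one site and standardizes the group coefficient by the residual SD.
#' Hedges' small-sample correction `J = 1 - 3 / (4 df - 1)` is applied
#' (df = residual degrees of freedom), and the standard error uses the
#' usual d-variance formula `(n1 + n2) / (n1 n2) + d^2 / (2 df)`.
#' A covariate that is constant (or collinear) within the site is dropped
#' with a warning. Positive d means the patient group scores higher.
#'
#' @param scores subject-level table with the score column, `diagnosis`,
#'   `site` and the covariates.
#' @param site site to analyse (NULL = use all rows as one site).
#' @param channel score channel ("full", "color", "luminance",
#'   "orientation"), i.e. column `score_<channel>`.
#' @param groups length-2 character: reference group then patient group.
#' @param covariates covariate column names (default age and sex).
#' @param standardize "residual" (regression residual SD) or "pooled"
#'   (raw pooled within-group SD).
#' @return one-row data.frame: `site`, `channel`, `d`, `se`, `n_ref`,
#'   `n_pat`, `df`.
#' @export
unbiased_d <- function(scores, site = NULL, channel = "full",
                       groups = c("HC", "SZ"),
                       covariates = c("age", "sex"),
                       standardize = c("residual", "pooled")) {
  standardize <- match.arg(standardize)
  col <- paste0("score_", channel)
  stopifnot(col %in% names(scores))
  dat <- if (is.null(site)) scores else scores[scores$site == site, ]
  dat <- dat[dat$diagnosis %in% groups, ]
  dat$group <- factor(as.character(dat$diagnosis), levels = groups)
  n1 <- sum(dat$group == groups[1]); n2 <- sum(dat$group == groups[2])
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 subjects per group (site ", site, ")")
  keep <- character(0)
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v[!is.na(v)])) > 1) keep <- c(keep, cv)
    else warning("covariate '", cv, "' constant in site ", site, "; dropped")
  }
  fml <- stats::reformulate(c("group", keep), response = col)
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- keep[vapply(keep, function(cv)
      any(is.na(cf[startsWith(names(cf), cv)])), TRUE)]
    warning("rank-deficient design in site ", site, "; dropping: ",
            paste(bad, collapse = ", "))
    keep <- setdiff(keep, bad)
    fit <- stats::lm(stats::reformulate(c("group", keep), response = col),
                     data = dat)
  }
  beta <- stats::coef(fit)[[paste0("group", groups[2])]]
  df <- fit$df.residual
  sd_use <- if (standardize == "residual") {
    sqrt(sum(stats::residuals(fit)^2) / df)
  } else {
    r1 <- dat[[col]][dat$group == groups[1]]
    r2 <- dat[[col]][dat$group == groups[2]]
    sqrt(((n1 - 1) * stats::var(r1) + (n2 - 1) * stats::var(r2)) /
           (n1 + n2 - 2))
  }
  J <- 1 - 3 / (4 * df - 1)
  d <- J * beta / sd_use
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * df))
  data.frame(site = if (is.null(site)) NA_character_ else site,
             channel = channel, d = d, se = se,
             n_ref = n1, n_pat = n2, df = df)
}

#' Per-site effect sizes for one channel
#'
#' Applies [unbiased_d()] to every site with at least `min_per_group`
#' subjects in both groups.
#'
#' @inheritParams unbiased_d
#' @param min_per_group minimum subjects per group for a site to enter.
#' @return data.frame of `EffectSizeRecord` rows.
#' @export
site_effect_sizes <- function(scores, channel = "full",
                              groups = c("HC", "SZ"),
                              covariates = c("age", "sex"),
                              min_per_group = 5) {
  counts <- table(scores$site, as.character(scores$diagnosis))
  ok <- rownames(counts)[counts[, groups[1]] >= min_per_group &
                           counts[, groups[2]] >= min_per_group]
  if (length(ok) == 0) stop("no site meets the per-group minimum")
  do.call(rbind, lapply(ok, function(s)
    unbiased_d(scores, s, channel, groups, covariates)))
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-site standardized differences with weights `1/se^2`:
#' `d_pooled = sum(w d) / sum(w)`, `se_pooled = sum(w)^(-1/2)`,
#' `z = d_pooled / se_pooled`, two-sided normal p.
#'
#' @param records data.frame with columns `d` and `se` (e.g. from
#'   [site_effect_sizes()]).
#' @return object of class `meta_result`: list with `d`, `se`, `z`, `p`,
#'   `ci` (95%), `records` (with a `weight` column, proportions summing
#'   to 1) and `channel`.
#' @export
fixed_effects_meta <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (any(records$se <= 0)) stop("all standard errors must be positive")
  w <- 1 / records$se^2
  d <- sum(w * records$d) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- d / se
  p <- 2 * stats::pnorm(-abs(z))
  records$weight <- w / sum(w)
  out <- list(d = d, se = se, z = z, p = p,
              ci = c(lower = d - 1.96 * se, upper = d + 1.96 * se),
              records = records,
              channel = if ("channel" %in% names(records))
                records$channel[1] else NA_character_)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects meta [%s]: d = %.3f +/- %.3f (95%% CI %.3f, %.3f), z = %.2f, p = %.3g, k = %d sites\n",
              x$channel, x$d, x$se, x$ci[1], x$ci[2], x$z, x$p,
              nrow(x$records)))
  invisible(x)
}

#' Forest-plot table for a meta-analysis
#'
#' @param meta a `meta_result`.
#' @return data.frame with per-site rows and a pooled row: `site`, `d`,
#'   `ci_lower`, `ci_upper` (d +/- 1.96 se), `weight_pct`.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  r <- meta$records
  out <- data.frame(
    site = c(as.character(r$site), "pooled"),
    d = c(r$d, meta$d),
    se = c(r$se, meta$se),
    weight_pct = c(100 * r$weight, 100))
  out$ci_lower <- out$d - 1.96 * out$se
  out$ci_upper <- out$d + 1.96 * out$se
  out
}

#' Cross-disorder general linear model with marginal means
#'
#' Fits `score ~ diagnosis + age + sex + site` by least squares, tests the
#' diagnosis main effect with an F-test, and computes estimated marginal
#' means per diagnosis at a fixed reference age (35.75 years by default),
#' averaging sex and site over their observed frequencies. All pairwise
#' group contrasts are Bonferroni-adjusted
#' (`p_adj = min(1, p_raw * n_contrasts)`).
#'
#' @param scores subject-level score table.
#' @param channel score channel.
#' @param ref_age age at which marginal means are evaluated.
#' @param covariates adjustment terms besides diagnosis.
#' @return object of class `glm_result`: list with `channel`,
#'   `p_diagnosis`, `emmeans` (data.frame `diagnosis`, `emmean`, `se`,
#'   `ci_lower`, `ci_upper`), `pairwise` (data.frame `contrast`,
#'   `estimate`, `se`, `p_raw`, `p_adj`), `fit`.
#' @export
cross_disorder_glm <- function(scores, channel = "full", ref_age = 35.75,
                               covariates = c("age", "sex", "site")) {
  col <- paste0("score_", channel)
  stopifnot(col %in% names(scores))
  dat <- scores
  dat$diagnosis <- droplevels(factor(dat$diagnosis,
                                     levels = intersect(DIAGNOSES,
                                                        unique(as.character(dat$diagnosis)))))
  if (nlevels(dat$diagnosis) < 2) stop("need at least 2 diagnostic groups")
  dat$site <- factor(dat$site)
  keep <- character(0)
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v[!is.na(v)])) > 1) keep <- c(keep, cv)
    else warning("covariate '", cv, "' constant; dropped")
  }
  fit <- stats::lm(stats::reformulate(c("diagnosis", keep), response = col),
                   data = dat)
  fit0 <- stats::lm(stats::reformulate(if (length(keep)) keep else "1",
                                       response = col), data = dat)
  p_dx <- stats::anova(fit0, fit)[2, "Pr(>F)"]

  at <- if ("age" %in% keep) list(age = ref_age) else list()
  emm <- emmeans::emmeans(fit, "diagnosis", at = at, weights = "proportional")
  es <- as.data.frame(emm)
  emm_tab <- data.frame(diagnosis = es$diagnosis, emmean = es$emmean,
                        se = es$SE, ci_lower = es$lower.CL,
                        ci_upper = es$upper.CL)
  pr_raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  pr_adj <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                            adjust = "bonferroni"))
  pairwise <- data.frame(contrast = pr_raw$contrast,
                         estimate = pr_raw$estimate, se = pr_raw$SE,
                         p_raw = pr_raw$p.value, p_adj = pr_adj$p.value)
  out <- list(channel = channel, p_diagnosis = p_dx, emmeans = emm_tab,
              pairwise = pairwise, fit = fit, ref_age = ref_age)
  class(out) <- "glm_result"
  out
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("cross-disorder GLM [%s]: diagnosis F-test p = %.3g\n",
              x$channel, x$p_diagnosis))
  cat(sprintf("marginal means at age %.2f:\n", x$ref_age))
  print(x$emmeans, row.names = FALSE)
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * n)`; thin wrapper kept for explicitness in reports.
#'
#' @param p raw p-values.
#' @param n number of tests (default: length of `p`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, n = length(p)) pmin(1, p * n)

#' Correlation screen between salience scores and clinical variables
#'
#' Pearson correlations for every (channel, clinical variable) pair within
#' a diagnostic group, Bonferroni-corrected over the whole screen.
#'
#' @param scores subject-level score table.
#' @param clinical_cols clinical column names (e.g. `scale_score`,
#'   `med_dose`).
#' @param channels score channels to screen.
#' @param diagnosis restrict to one group (NULL = all rows).
#' @param method "pearson" (default) or "spearman".
#' @return data.frame: `channel`, `variable`, `n`, `r`, `p_raw`, `p_adj`.
#' @export
correlation_screen <- function(scores, clinical_cols,
                               channels = c("full", "color", "luminance",
                                            "orientation"),
                               diagnosis = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dat <- if (is.null(diagnosis)) scores
  else scores[scores$diagnosis == diagnosis, ]
  rows <- list()
  for (ch in channels) for (cl in clinical_cols) {
    x <- dat[[paste0("score_", ch)]]; y <- dat[[cl]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      warning("fewer than 3 paired values for ", ch, " vs ", cl)
      rows[[length(rows) + 1]] <- data.frame(channel = ch, variable = cl,
                                             n = sum(ok), r = NA_real_,
                                             p_raw = NA_real_)
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero variance in ", ch, " vs ", cl)
      rows[[length(rows) + 1]] <- data.frame(channel = ch, variable = cl,
                                             n = sum(ok), r = NA_real_,
                                             p_raw = NA_real_)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    rows[[length(rows) + 1]] <- data.frame(channel = ch, variable = cl,
                                           n = sum(ok),
                                           r = unname(ct$estimate),
                                           p_raw = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, sum(!is.na(out$p_raw)))
  out
}
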