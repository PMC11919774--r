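scores_frame <- function(x1, x2, site = "A") {
  data.frame(site = site,
             diagnosis = rep(c("HC", "SZ"), c(length(x1), length(x2))),
             age = 0, sex = "F", score_full = c(x1, x2))
}

test_that("covariate-free unbiased d equals closed-form Hedges g", {
  set.seed(101)
  for (r in 1:10) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x1 <- rnorm(n1); x2 <- rnorm(n2, 0.4)
    res <- unbiased_d(scores_frame(x1, x2), site = "A", channel = "full",
                      covariates = character(0))
    orc <- hedges_g_oracle(x1, x2)
    expect_equal(res$d, orc$g, tolerance = 1e-10)
    expect_equal(res$se, orc$se, tolerance = 1e-10)
  }
})

test_that("Hedges small-sample factor matches its closed form at df = 38", {
  # two groups of 20, no covariates: df = 38, J = 1 - 3/151
  set.seed(5)
  x1 <- rnorm(20); x2 <- rnorm(20) + 1
  res <- unbiased_d(scores_frame(x1, x2), "A", covariates = character(0))
  sp <- sqrt((19 * var(x1) + 19 * var(x2)) / 38)
  d_raw <- (mean(x2) - mean(x1)) / sp
  expect_equal(res$d / d_raw, 1 - 3 / 151, tolerance = 1e-12)
})

test_that("a pure one-SD shift is estimated near d = 1 at large n", {
  set.seed(7)
  x1 <- rnorm(4000); x2 <- rnorm(4000) + 1
  res <- unbiased_d(scores_frame(x1, x2), "A", covariates = character(0))
  expect_equal(res$d, 1, tolerance = 0.06)
})

test_that("null simulation keeps |d| small and covariates are adjusted", {
  # sd(d) under the null at n = 50/50 is ~sqrt(4/100) = 0.2
  set.seed(11)
  ds <- replicate(60, {
    x1 <- rnorm(50); x2 <- rnorm(50)
    unbiased_d(scores_frame(x1, x2), "A", covariates = character(0))$d
  })
  expect_lt(abs(mean(ds)), 0.08)
  expect_gt(mean(abs(ds) < 0.4), 0.9)
  # an age effect common to both groups must not inflate d
  set.seed(12)
  age <- c(rnorm(300, 30, 8), rnorm(300, 50, 8))  # confounded with group
  sc <- scores_frame(rnorm(300), rnorm(300))
  sc$age <- age
  sc$score_full <- sc$score_full + 0.1 * age      # strong age effect only
  adj <- unbiased_d(sc, "A", covariates = "age")
  raw <- unbiased_d(sc, "A", covariates = character(0))
  expect_lt(abs(adj$d), 0.35)
  expect_gt(abs(raw$d), 1)
  # constant covariate is dropped with a warning, not an error
  sc3 <- scores_frame(rnorm(20), rnorm(20))
  sc3$age <- rnorm(40, 40, 10)     # age varies; only sex is constant
  expect_warning(unbiased_d(sc3, "A", covariates = c("age", "sex")),
                 "'sex' constant")
})

test_that("fixed-effects pooling matches the inverse-variance closed form", {
  one <- data.frame(d = 0.7, se = 0.1)
  m1 <- fixed_effects_meta(one)
  expect_equal(m1$d, 0.7)
  expect_equal(m1$se, 0.1)
  two <- data.frame(d = c(0.5, 0.5), se = c(0.1, 0.1))
  m2 <- fixed_effects_meta(two)
  expect_equal(m2$d, 0.5)
  expect_equal(m2$se, 0.1 / sqrt(2))
  worked <- data.frame(d = c(0.2, 0.8), se = c(0.1, 0.2))
  m3 <- fixed_effects_meta(worked)
  expect_equal(m3$d, 0.32, tolerance = 1e-12)
  expect_equal(m3$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_error(fixed_effects_meta(data.frame(d = 1, se = 0)), "positive")
  # pooling K identical records: d unchanged, se shrinks by sqrt(K)
  k5 <- data.frame(d = rep(0.4, 5), se = rep(0.12, 5))
  m5 <- fixed_effects_meta(k5)
  expect_equal(m5$d, 0.4)
  expect_equal(m5$se, 0.12 / sqrt(5))
})

test_that("fixed-effects pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(21)
  rec <- data.frame(d = rnorm(6, 0.5, 0.3), se = runif(6, 0.05, 0.3))
  mine <- fixed_effects_meta(rec)
  ref <- metafor::rma(yi = rec$d, sei = rec$se, method = "FE")
  expect_equal(mine$d, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$se, ref$se, tolerance = 1e-10)
  expect_equal(mine$p, ref$pval, tolerance = 1e-10)
})

test_that("forest table carries normal CIs and weights summing to 100", {
  rec <- data.frame(site = c("A", "B"), channel = "full",
                    d = c(0.78, 0.5), se = c(0.08, 0.3))
  meta <- fixed_effects_meta(rec)
  ft <- forest_table(meta)
  a <- ft[ft$site == "A", ]
  expect_equal(a$ci_lower, 0.78 - 1.96 * 0.08, tolerance = 1e-12)
  expect_equal(a$ci_upper, 0.78 + 1.96 * 0.08, tolerance = 1e-12)
  expect_equal(sum(ft$weight_pct[ft$site != "pooled"]), 100, tolerance = 1e-9)
  single <- forest_table(fixed_effects_meta(rec[1, ]))
  expect_equal(single$weight_pct, c(100, 100))
})

test_that("Bonferroni arithmetic is exact and capped at one", {
  expect_equal(bonferroni(0.004, 10), 0.04)
  expect_equal(bonferroni(0.01, 8), 0.08)
  expect_equal(bonferroni(0.3, 10), 1)
  expect_equal(bonferroni(c(0.004, 0.2), 10), c(0.04, 1))
})

test_that("correlation screen: exact identity, nulls, degenerate input", {
  set.seed(31)
  sc <- data.frame(diagnosis = "SZ", score_full = rnorm(30))
  sc$scale_score <- sc$score_full           # y = x exactly
  out <- correlation_screen(sc, "scale_score", channels = "full")
  expect_equal(out$r, 1, tolerance = 1e-12)
  # null rejection rate near alpha over many replicates
  set.seed(32)
  hits <- 0; total <- 0
  for (r in 1:100) {
    sc <- data.frame(diagnosis = "SZ",
                     score_full = rnorm(40), score_color = rnorm(40),
                     score_luminance = rnorm(40),
                     score_orientation = rnorm(40),
                     scale_score = rnorm(40))
    out <- correlation_screen(sc, "scale_score")
    hits <- hits + sum(out$p_raw < 0.05); total <- total + nrow(out)
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
  # zero-variance column: missing r with warning
  sc$scale_score <- 5
  expect_warning(outz <- correlation_screen(sc, "scale_score",
                                            channels = "full"),
                 "variance")
  expect_true(is.na(outz$r))
  # adjusted p = min(1, raw * number of tests)
  set.seed(33)
  sc2 <- data.frame(diagnosis = "SZ", score_full = rnorm(25),
                    score_color = rnorm(25), scale_score = rnorm(25),
                    med_dose = rnorm(25))
  out2 <- correlation_screen(sc2, c("scale_score", "med_dose"),
                             channels = c("full", "color"))
  expect_equal(out2$p_adj, pmin(1, out2$p_raw * 4))
})

test_that("single-site GLM contrast agrees with unbiased d in sign and size", {
  maps <- list(im = list(full = make_density_map(14)))
  tab <- data.frame(site = "A", diagnosis = c("HC", "SZ"),
                    n_male = 150, n_female = 150, age_mean = 36, age_sd = 10)
  cal <- calibrate_bias(list(make_density_map(14)), 60, 0.06)
  des <- cohort_design(tab, bias = c(HC = 0.3,
                                     SZ = 0.3 + cal$delta_pi(0.8, 0.3)),
                       bias_sd = 0.06,
                       site_bias = c(A = 0), seed = 41)
  coh <- generate_cohort(des)
  sc <- simulate_scores(coh, maps, n_endpoints = 60, seed = 42)
  d_rec <- unbiased_d(sc, "A", "full")
  g <- cross_disorder_glm(sc, "full", covariates = c("age", "sex"))
  ctr <- g$pairwise[g$pairwise$contrast == "HC - SZ", ]
  d_glm <- -ctr$estimate / summary(g$fit)$sigma
  expect_gt(d_rec$d * d_glm, 0)                       # same sign
  expect_equal(d_glm, d_rec$d, tolerance = 0.05)      # within 5%
})

test_that("cross-disorder GLM orders marginal means by the true bias", {
  maps <- lapply(c(a = 14, b = 15), function(s)
    list(full = make_density_map(s)))
  cal <- calibrate_bias(lapply(maps, `[[`, "full"), 40, 0.06)
  tab <- expand.grid(site = c("A", "B"),
                     diagnosis = c("HC", "SZ", "BD", "MDD", "ASD"),
                     stringsAsFactors = FALSE)
  tab$n_male <- 60; tab$n_female <- 60; tab$age_mean <- 36; tab$age_sd <- 10
  shifts <- c(HC = 0, ASD = 0.5, MDD = 1.0, BD = 1.5, SZ = 2.0)
  bias <- 0.25 + vapply(shifts, cal$delta_pi, 0, pi_ref = 0.25)
  des <- cohort_design(tab, bias = bias, bias_sd = 0.06, seed = 43)
  coh <- generate_cohort(des)
  sc <- simulate_scores(coh, maps, n_endpoints = 40, seed = 44)
  g <- cross_disorder_glm(sc, "full")
  em <- setNames(g$emmeans$emmean, as.character(g$emmeans$diagnosis))
  expect_true(em["SZ"] > em["BD"] && em["BD"] > em["MDD"] &&
                em["MDD"] > em["ASD"] && em["ASD"] > em["HC"])
  expect_lt(g$p_diagnosis, 1e-6)
  expect_equal(nrow(g$pairwise), 10L)
  expect_equal(g$pairwise$p_adj, pmin(1, g$pairwise$p_raw * 10))
})

test_that("null GLM p-values are approximately uniform", {
  set.seed(51)
  ps <- replicate(60, {
    sc <- data.frame(site = rep(c("A", "B"), each = 60),
                     diagnosis = sample(rep(c("HC", "SZ", "BD"), 40)),
                     age = rnorm(120, 40, 10),
                     sex = sample(c("M", "F"), 120, TRUE),
                     score_full = rnorm(120))
    cross_disorder_glm(sc, "full")$p_diagnosis
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
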