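test_that("mixture endpoint sampling honours its degenerate limits", {
  geo <- fix_geometry()
  pm <- point_map(30, 40)
  set.seed(1)
  ep <- sample_endpoints(pm, bias = 1, n = 500, geometry = geo)
  expect_true(all(ep$row == 30L & ep$col == 40L))
  cc <- deg_to_cell(ep$x_deg, ep$y_deg, geo)
  expect_true(all(cc$row == 30L & cc$col == 40L))
  expect_error(sample_endpoints(pm, bias = 1.2, n = 10), "\\[0, 1\\]")
  raw <- point_map(1, 1); raw$values[1, 1] <- 2  # de-normalize
  expect_error(sample_endpoints(raw, 0.5, 10), "normalized")
})

test_that("with zero bias endpoints are uniform over the screen", {
  geo <- fix_geometry()
  set.seed(2)
  ep <- sample_endpoints(uniform_map(), bias = 0, n = 10000, geometry = geo)
  # chi-square GOF on an 8 x 10 super-cell partition (125 expected/bin)
  bins <- table(factor((ep$row - 1) %/% 8, levels = 0:7),
                factor((ep$col - 1) %/% 8, levels = 0:9))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("trial construction respects programmed structure", {
  u <- uniform_map()
  # zero saccades: a single 8 s fixation epoch
  tr <- generate_trial(u, 0.5, n_saccades = 0, n_micro = 0, n_blinks = 0,
                       jitter_sd = 0, seed = 1)
  expect_equal(nrow(tr), 8000L)
  expect_equal(length(unique(tr$x_deg)), 1L)
  # determinism: same seed, identical trace
  t1 <- generate_trial(u, 0.5, seed = 9)
  t2 <- generate_trial(u, 0.5, seed = 9)
  expect_identical(t1$x_deg, t2$x_deg)
  expect_identical(attr(t1, "truth"), attr(t2, "truth"))
  # sampling interval is exactly 1 ms and pupil is non-negative
  expect_true(all(diff(t1$time_ms) == 1))
  expect_true(all(t1$pupil >= 0))
  # programmed regular saccades exceed one degree
  tru <- attr(t1, "truth")
  expect_true(all(tru$amplitude[tru$class == "regular"] > 1))
})

test_that("expected salience score increases strictly with the bias", {
  map <- make_density_map(4)
  pis <- seq(0, 1, length.out = 10)
  set.seed(5)
  mean_scores <- vapply(pis, function(p) {
    ep <- sample_endpoints(map, p, 1000)
    mean(map$values[cbind(ep$row, ep$col)])
  }, 0)
  rho <- stats::cor(pis, mean_scores, method = "spearman")
  expect_gt(rho, 0.99)
  # and the analytic calibration predicts the endpoint mean to first order
  cal <- calibrate_bias(list(map), n_endpoints = 1000, bias_sd = 0)
  expect_equal(mean_scores[1], cal$a, tolerance = 0.3)
  expect_equal(unname(mean_scores[10]), cal$a + cal$b, tolerance = 0.2)
})

test_that("cohort generation reproduces the design counts deterministically", {
  tab <- cohort_table1()
  des <- cohort_design(tab, bias = c(HC = 0.3, SZ = 0.4, BD = 0.37,
                                     MDD = 0.34, ASD = 0.32), seed = 3)
  coh <- generate_cohort(des)
  cnt <- table(coh$diagnosis)
  expect_equal(unname(cnt[c("HC", "SZ", "BD", "MDD", "ASD")]),
               c(550L, 238L, 41L, 50L, 133L), ignore_attr = TRUE)
  expect_equal(nrow(coh), 1012L)
  expect_identical(coh, generate_cohort(des))
  expect_true(all(coh$bias >= 0 & coh$bias <= 1))
  # per-site sex counts match the table
  m_by_site <- tapply(coh$sex == "M", list(coh$site, coh$diagnosis), sum)
  expect_equal(m_by_site["OSK", "HC"], 126L, ignore_attr = TRUE)
  expect_equal(m_by_site["NARA", "ASD"], 41L, ignore_attr = TRUE)
  expect_error(cohort_design(tab[0, ], bias = c(HC = 0.3)), "empty")
})

test_that("equal group biases give null group differences", {
  tab <- data.frame(site = rep(c("A", "B"), each = 2),
                    diagnosis = rep(c("HC", "SZ"), 2),
                    n_male = 100, n_female = 100,
                    age_mean = 36, age_sd = 10)
  des <- cohort_design(tab, bias = c(HC = 0.35, SZ = 0.35), seed = 21)
  coh <- generate_cohort(des)
  maps <- list(img1 = list(full = make_density_map(6)))
  sc <- simulate_scores(coh, maps, n_endpoints = 50, seed = 22)
  es <- site_effect_sizes(sc, "full")
  expect_true(all(abs(es$d) < 0.3))
  meta <- fixed_effects_meta(es)
  expect_lt(abs(meta$d), 0.2)
})

test_that("endpoint-level scores agree with the full trace route", {
  # small cohort through both routes; means must agree within sampling error
  maps <- lapply(c(a = 8, b = 9, c = 10, d = 12), function(s)
    list(full = make_density_map(s)))
  tab <- data.frame(site = "A", diagnosis = c("HC", "SZ"),
                    n_male = 6, n_female = 6, age_mean = 35, age_sd = 8)
  des <- cohort_design(tab, bias = c(HC = 0.2, SZ = 0.8), bias_sd = 0.02,
                       seed = 31)
  coh <- generate_cohort(des)
  fast <- simulate_scores(coh, maps, n_endpoints = 30, seed = 32)
  slow <- score_cohort(coh, maps, n_saccades = 30, n_micro = 0, seed = 33)
  for (g in c("HC", "SZ")) {
    mf <- mean(fast$score_full[fast$diagnosis == g])
    ms <- mean(slow$score_full[slow$diagnosis == g])
    expect_equal(ms, mf, tolerance = 0.2)   # relative
  }
  # both routes place SZ well above HC
  expect_gt(mean(slow$score_full[slow$diagnosis == "SZ"]),
            mean(slow$score_full[slow$diagnosis == "HC"]))
})
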