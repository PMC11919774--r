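# salgaze

Does gaze during free viewing follow bottom-up visual salience — and does
it do so more strongly in some clinical groups than in others? **salgaze**
is an R package implementing the complete measurement and analysis chain
used to answer that question in multi-site eye-tracking studies of
psychiatric disorders (healthy controls vs. schizophrenia, bipolar
disorder, major depressive disorder, autism spectrum disorder):

1. **Saliency maps** — the classic Itti–Koch model for static images:
   Gaussian feature pyramids (intensity, red–green / blue–yellow
   opponency, 4-orientation Gabor energy), center–surround contrasts at
   scale pairs (c, s) with c ∈ {2,3,4}, s = c + {3,4}, the peak-promotion
   normalization N(·), and an equal-weight combination of the three
   channels. Each map is emitted as an 80 × 64 probability density over
   the 1280 × 1024 display (cells sum to 1).
2. **Event detection** — 1 kHz gaze traces are smoothed with a zero-phase
   FIR low-pass (−3 dB at 30 Hz), differentiated with a two-point central
   difference, and segmented into blinks, saccades (velocity threshold
   with hysteresis) and fixations; saccades with amplitude > 1° are
   "regular", the rest "micro".
3. **Salience score** — per subject and map channel: the mean map density
   at regular-saccade endpoints within each image, averaged over the 16
   analysis images (the 4 zero-color-contrast noise images are excluded).
   Chance level on a uniform map is exactly 1/5120.
4. **Statistics** — per-site unbiased d (Hedges-corrected standardized
   difference from a regression controlling age and sex), fixed-effects
   inverse-variance meta-analysis (d̄ = Σwᵢdᵢ/Σwᵢ, w = 1/se², se =
   (Σw)^(−1/2)), cross-disorder GLM (`score ~ diagnosis + age + sex +
   site`) with estimated marginal means at age 35.75 and all 10 pairwise
   contrasts Bonferroni-adjusted, plus Bonferroni-corrected correlation
   screens against symptom scales and medication dose.
5. **Synthetic data** — because clinical recordings of this kind are not
   redistributable, the package generates the whole study: procedural
   stimuli in 5 categories (4 images each), 8 s / 1 kHz trials whose
   saccade endpoints follow the mixture π·saliency + (1−π)·uniform,
   blinks, fixational drift, and multi-site cohorts with group-structured
   bias π calibrated analytically to target effect sizes.

The audience is researchers analysing free-viewing eye-tracking data who
want a tested, fully reproducible reference implementation of this
pipeline, from pixels to forest plot.

## Worked example

Generate a synthetic study, score it, and pool per-site effect sizes:

```r
library(salgaze)

stimuli  <- generate_stimulus_set(seed = 1)          # 20 images, 5 categories
analysis <- filter_images(stimuli)                   # drop noise -> 16 images
maps     <- compute_set_maps(analysis)               # 4 channels x 16 maps

# place the SZ group bias so the true covariate-adjusted d is 0.8
cal    <- calibrate_bias(lapply(maps, `[[`, "full"), n_endpoints = 18)
design <- design_two_group(cal, n_sites = 3, n_per_group = 60,
                           d_target = 0.8, seed = 1)
cohort <- generate_cohort(design)
scores <- simulate_scores(cohort, maps, n_endpoints = 18, seed = 2)

es   <- site_effect_sizes(scores, channel = "full")
meta <- fixed_effects_meta(es)
print(meta)
#> fixed-effects meta [full]: d = 0.695 +/- 0.109 (95% CI 0.481, 0.909),
#>   z = 6.37, p = 1.86e-10, k = 3 sites
print(forest_table(meta), digits = 3)
#>     site     d    se weight_pct ci_lower ci_upper
#> 1  SITE1 0.697 0.188       33.6   0.3279    1.066
#> 2  SITE2 0.388 0.184       35.0   0.0271    0.750
#> 3  SITE3 1.037 0.195       31.4   0.6548    1.419
#> 4 pooled 0.695 0.109      100.0   0.4815    0.909
```

The pooled estimate (0.695 ± 0.109) recovers the programmed ground-truth
d = 0.8 within its confidence interval; per-site spread (0.39–1.04) is
what three sites of 60 + 60 subjects produce. The event-detection and
scoring stages work trial by trial:

```r
tr <- generate_trial(maps[[1]]$full, bias = 0.6, seed = 3)  # 8 s at 1 kHz
ev <- detect_events(tr)
print(ev)
#> event_list: 0 blinks, 20 saccades (18 regular), 21 fixations
score_image(maps[[1]]$full, ev)
#> [1] 0.0001918      # vs. chance 1/5120 = 0.0001953
```

A bias of 0.6 on one image yields a score just below chance here — single
images are noisy; the subject-level score averages 16 of them. For a
five-group cohort at published-study scale (550/238/41/50/133 subjects
across 7 sites), see `design_cross_disorder()` and
`cross_disorder_glm()`, and the vignette
`vignettes/gaze-salience-methods.Rmd` for the model, generator
calibration, and every tunable parameter. An end-to-end run (stimuli →
maps → cohort → traces → events → scores → statistics, with a YAML config
and checksum manifest) is one call:

```r
run_pipeline(default_config(seed = 1), out_dir = "demo_run")
```

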