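---
title: "Measuring salience-guided gaze: models, generators and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring salience-guided gaze: models, generators and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salgaze)
```

## What the package measures

During free viewing of a static image, some of where people look is driven
bottom-up by low-level image features. **salgaze** quantifies this per
subject as a *salience score*: the mean value of a saliency density map at
the endpoints of the subject's regular saccades, first within each image,
then averaged across the analysis images. Because maps are normalized to
probability densities over an 80 x 64 grid, the score has a fixed chance
level — a subject whose saccade endpoints ignore the image entirely scores
exactly `1/5120` on any uniform map, and on real maps a higher score means
gaze follows bottom-up salience more closely. Group differences in the
score, expressed as covariate-adjusted standardized differences and pooled
across recording sites, are the quantity of scientific interest, e.g. when
comparing psychiatric diagnostic groups (healthy controls and people with
schizophrenia, bipolar disorder, major depressive disorder, or autism
spectrum disorder) recorded at several institutes.

Clinical gaze recordings of this kind are not redistributable, so the
package pairs the measurement pipeline with a synthetic-data generator
whose ground truth is known by construction. Every stage is testable
end-to-end without any external data.

## The saliency model

Maps come from the classic Itti–Koch architecture for static images:

1. **Feature pyramids.** A 9-level Gaussian pyramid (5-tap binomial blur,
   factor-2 decimation) of: intensity $I=(r+g+b)/3$; red–green and
   blue–yellow opponency (hue channels normalized by intensity and zeroed
   where $I$ is below a tenth of its maximum, then rectified broadly
   tuned components $R,G,B,Y$ combined to signed $RG = R-G$ and
   $BY = B-Y$); and Gabor orientation energy of the intensity pyramid at
   0°, 45°, 90° and 135° (one quadrature pair per level, wavelength 6 px,
   $\sigma = 3$ px, 13 x 13 kernels; the even kernel is mean-corrected so
   featureless input responds exactly zero).
2. **Center–surround contrast.** $|c - s|$ between center levels
   $c \in \{2,3,4\}$ and surround levels $s = c + \{3,4\}$, the surround
   upsampled bilinearly — six scale pairs per feature.
3. **Normalization $N(\cdot)$.** Each contrast map is rescaled to $[0,1]$
   and multiplied by $(1-\bar m)^2$, where $\bar m$ is the mean of the
   local maxima other than the global maximum. A map with one dominant
   peak is promoted; a map with many similar peaks is suppressed. We use
   the single-pass peak-promotion form rather than iterative
   difference-of-Gaussians normalization. Local maxima must exceed 0.05
   after rescaling (so flat near-zero background does not count), and maps
   whose maximum is numerically zero are left at zero rather than
   rescaled.
4. **Conspicuity and combination.** Contrast maps are block-averaged onto
   the level-4 grid (80 x 64 for a 1280 x 1024 input), normalized, and
   summed per channel (color sums the RG and BY streams; orientation
   normalizes each angle's across-scale sum before adding). The full map
   is the equal-weight combination
   $(N(C) + N(I) + N(O))/3$. Every emitted map is density-normalized.

Design choices where the architecture is genuinely open, and why:

* **Classic Itti–Koch, not graph-based saliency.** The graph-based
  toolbox's random-walk activation is a different model; the classic
  algorithm with its published defaults (levels, scale pairs, four
  orientations) is the reproducible reference point. Absolute map values
  therefore need not match any particular toolbox — all claims are about
  the pipeline's behavior, with map contracts (shape, non-negativity,
  unit sum) and pop-out localization as the checkable properties.
* **Simple color opponency.** Center–surround on signed $RG$ and $BY$
  pyramids uses $|RG_c - RG_s|$ rather than the chromatic double-opponent
  form $|(R-G)_c + (G-R)_s|$; both are zero for achromatic input, and the
  simple form is the common choice in reimplementations.
* **Normalization at the common grid.** $N(\cdot)$ is applied after
  resampling each contrast map to the output grid, keeping the operator's
  peak statistics comparable across scale pairs (and making its cost
  independent of the pyramid level).
* **Output grid from the pyramid.** 80 x 64 is pyramid level 4 of the
  1280 x 1024 display; images at other resolutions are resized to the
  display first, so the grid is invariant.
* **All-zero maps become uniform densities.** A featureless channel (e.g.
  color on a grayscale image) carries no information; the uniform density
  is the only order-preserving choice with unit sum.

On generated oddball arrays (one colored square among gray ones, one
45° bar among vertical bars) the corresponding single-channel map's argmax
falls within the oddball item's extent in well over 95% of random
placements — the package's acceptance property for the model.

## Geometry

The display is modelled as a 19-inch 5:4 panel (1280 x 1024 px) at 70 cm.
With square pixels this gives a pitch of 0.0295 cm and 41.5 px/deg at the
screen centre; a single small-angle pixel pitch converts degrees to pixels
everywhere (at the screen corner the flat-screen error is a few percent,
well under one grid cell of 0.39°). Grid cells are 16 x 16 px. Gaze
coordinates are degrees from the screen centre, x rightward, y upward;
grid indices count from the top-left.

## Event detection

Recordings are monocular 1 kHz traces of position (degrees) and pupil
area. Processing:

* **Smoothing.** A zero-phase windowed-sinc FIR low-pass (order 50,
  Hamming window) applied by centred convolution. The corner is solved
  numerically so the single-pass gain at 30 Hz is exactly −3 dB; DC gain
  is normalized to exactly 1. Samples invalid during blinks are linearly
  interpolated before filtering and tracked in a validity mask.
* **Differentiation.** Two-point central differences
  ($v_t = (p_{t+1}-p_{t-1})/2\Delta t$), applied again for acceleration.
  A forward difference is available via `differentiate(method =
  "forward")`.
* **Segmentation.** Blinks are maximal pupil-zero runs padded by 25 ms.
  Saccades start where speed exceeds 30 deg/s for at least 8 ms and extend
  until speed falls below 10 deg/s (hysteresis); fixations are remaining
  valid epochs of at least 50 ms. The thresholds are standard
  velocity-based values — recording methods papers in this area typically
  do not print theirs — and all of them are exposed in `event_params()`
  and the pipeline config.
* **Classification.** Saccades with amplitude strictly greater than 1°
  are *regular*; the rest are *micro*. Only regular-saccade endpoints
  enter the salience score by default (`include_micro` switches this),
  since the analysis convention defines the regular class immediately
  before scoring.

On synthetic trials with realistic fixational jitter (SD 0.05°), detection
recovers programmed regular saccades with recall and precision above 0.95
and mean endpoint error under 0.25° (about two-thirds of a grid cell).

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes:

* **Stimuli.** 20 procedural images, four per category — building
  skylines, scattered colored items, food on a plate, multi-octave
  fractal textures, and grayscale noise. Noise images have exactly
  identical R, G, B planes, which is why that category (4 images) is
  excluded from analysis, leaving 16.
* **Trials.** 8 s at 1 kHz. Fixation epochs (gamma-distributed durations,
  minimum 80 ms) alternate with cosine-profile saccade ramps (30 ms
  regular, 15 ms micro; 18 regular + 2 micro per trial by default).
  Each regular endpoint is drawn from the mixture
  $\pi \cdot \text{map density} + (1-\pi) \cdot \text{uniform}$: a
  categorical draw over the 80 x 64 cells followed by uniform within-cell
  jitter. $\pi$ is the subject's ground-truth salience-following bias.
  Kinematics are deliberately minimal — the detector needs detectable
  events, not main-sequence realism. Endpoints closer than 1.2° to the
  current fixation are redrawn (up to 20 times) so programmed regular
  saccades are unambiguous; with degenerate maps (a point mass) the draw
  is eventually accepted as-is.
* **Jitter and blinks.** Fixational drift is an Ornstein–Uhlenbeck
  process (position SD 0.05°, time constant 100 ms). Per-sample white
  noise would imply velocities far above anything a tracker records and
  would make velocity-threshold detection meaningless, so slow drift is
  the realistic choice. Blinks are 100–300 ms pupil-zero gaps with
  invalid positions, placed inside long fixations. Trials start at image
  onset; the pre-trial fixation spot period (whose duration distribution
  is never printed for such protocols) is not simulated.
* **Cohorts.** A design table fixes per-site, per-group sample sizes,
  age distributions and sex counts; the packaged `cohort_table1()`
  mirrors a published 7-site, 1012-subject demographic structure
  (550 HC, 238 SZ, 41 BD, 50 MDD, 133 ASD). Subject biases are
  Beta-distributed around group means (SD 0.08) with small per-site
  offsets and mild age/sex effects, and symptom-scale/medication columns
  are drawn independently of bias so correlation screens have a true null.

### Calibration: from bias to effect size

For endpoints drawn from the mixture, the expected density at an endpoint
is linear in $\pi$:
$E[\text{score}\,|\,\pi] = a + b\pi$ with $a = 1/5120$ and
$b = \overline{\sum_i p_i^2} - 1/5120$ over the analysis maps. The
within-group score variance combines the Beta spread of $\pi$ with
endpoint-sampling noise, both computable exactly from the maps' second
and third moments (`calibrate_bias()`). Inverting this mapping places
group-mean biases so that a *target* standardized difference is the
ground truth:

* the two-group (HC vs SZ) design is calibrated to a true adjusted
  d of 0.8, making the pooled fixed-effects estimate a recoverable
  quantity (50-replicate simulations recover it within ±0.15 with 95% CI
  coverage in the nominal band);
* the cross-disorder design orders the five groups
  SZ > BD > MDD > ASD > HC with standardized shifts 2.15 / 1.55 / 0.95 /
  0.35 / 0. These gaps are sized by a power computation so that the
  ordering of GLM marginal means is recoverable in ≥95% of runs at the
  packaged sample sizes (the smallest group has n = 41; each adjacent
  gap is ≥2.8 standard errors of its mean difference). They are
  deliberately larger than the modest clinical effects such studies
  report — the generator's job is to make the *ordering* a testable
  ground truth at these n, not to mimic clinical effect magnitudes.

### Two simulation routes

`score_cohort()` runs the full route — synthesize 1 kHz traces, detect
events, look up densities. `simulate_scores()` draws endpoints directly
from the mixture and skips trace synthesis and detection; the two routes
agree in expectation (checked by test), and the fast route is used for
statistics-scale simulations (hundreds of subjects, dozens of
replicates), which keeps the full test suite and the demo pipeline within
a few minutes on one core. Problem sizes used by the shipped tests: 50
replicates of 3 sites x 200 subjects for effect-size recovery; 50 runs of
the 1012-subject cross-disorder design for the ordering property; 100
trials for detector recovery; 100 oddball placements for pop-out.

What the generator does *not* emulate: photographic image statistics,
main-sequence saccade kinematics, smooth pursuit, head movement, drift in
calibration, or any dependence of symptom scales on gaze. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes
— not that clinical effects of a given size exist in real data.

## Statistics

* **Per-site effect size.** `unbiased_d()` fits
  `score ~ group + age + sex` within a site and standardizes the group
  coefficient by the residual SD (the covariate-adjusted analogue of
  Cohen's d; a `standardize = "pooled"` option uses the raw pooled SD
  instead). Hedges' correction $J = 1 - 3/(4\,df - 1)$ removes
  small-sample bias, and $se^2 = \frac{n_1+n_2}{n_1 n_2} +
  \frac{d^2}{2\,df}$ with the regression's residual df. Covariates that
  are constant within a site (e.g. a single-sex group) are dropped with a
  warning. Sites need a minimum of 5 subjects per group (configurable) to
  contribute.
* **Pooling.** Fixed-effects inverse-variance meta-analysis:
  $\bar d = \sum w_i d_i / \sum w_i$, $w_i = 1/se_i^2$,
  $se = (\sum w_i)^{-1/2}$, two-sided normal p. Forest tables report
  $d \pm 1.96\,se$ and percentage weights. Random-effects pooling and
  heterogeneity statistics are out of scope.
* **Cross-disorder GLM.** `score ~ diagnosis + age + sex + site` by least
  squares; F-test for the diagnosis main effect; estimated marginal means
  per group at age 35.75 years with sex and site averaged over their
  observed frequencies (proportional weights — the convention of
  SPSS-style EMMEANS output, which such studies report); all 10 pairwise
  contrasts Bonferroni-adjusted ($p_{adj} = \min(1, 10\,p)$).
* **Correlation screens.** Pearson by default (Spearman available) between
  channel scores and clinical variables, Bonferroni-corrected over the
  screen; zero-variance inputs yield missing values with a warning.

Numerical notes: the covariate-free special case of `unbiased_d()` equals
textbook Hedges g to 1e-10 (tested against a closed-form oracle); the
pooling step is tested against both the closed form and an independent
meta-analysis package; under the null, sd(d) at n = 50 + 50 is
$\approx\sqrt{4/100} = 0.2$, so individual-site estimates of ±0.3 are
unremarkable.

## Known limitations

* Map values are implementation-specific: only densities, orderings and
  derived statistics are comparable across implementations, not raw map
  numbers.
* The degree-to-pixel conversion uses a single central pixel pitch; at
  the display corners the flat-panel deviation approaches ~4% of
  eccentricity.
* The detector has no pursuit class; slow drifts of more than 30 deg/s
  would be misread as saccades (none are generated).
* Endpoint-level simulation bypasses detector imperfections; its
  agreement with the full route is demonstrated at small scale only.
* With a point-mass saliency map and full bias, consecutive endpoints
  collapse onto one cell and programmed "regular" saccades can shrink
  below the 1° class boundary; this degenerate regime is exercised in
  tests but is not a sensible study condition.
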