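---
title: "Parcellation-based analysis of fixation selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellation-based analysis of fixation selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenefix)
```

# The scientific problem

When people inspect photographs of real-world scenes, where they fixate is
driven jointly by a strong bias toward the image centre, by low-level image
salience, and by the objects present in the scene. scenefix implements a
parcellation-based analysis of this selection process for a two-group
(young / older adult) scene-viewing corpus: scenes are divided a priori into
regions — either the cells of a regular grid or annotated object bounding
boxes — and each region contributes, per trial, a binary outcome ("was this
region fixated?") together with region-level predictors. Those observation
matrices are analysed with binomial logit mixed models; complementary
analyses model log fixation times on objects, normalized within-object
landing positions (the preferred viewing location, PVL), and memory-test
performance via signal detection theory.

# Reference frame and region predictors

All coordinates are 0-based pixels, origin top-left, x rightward, y
downward. A box with corner $(x_{\min}, y_{\min})$ and size $w \times h$
covers the inclusive pixel range $[x_{\min}, x_{\min}+w-1] \times
[y_{\min}, y_{\min}+h-1]$ and its centre is the midpoint of that range; the
scene centre is $((W-1)/2, (H-1)/2)$. Grid cells are half-open in continuous
coordinates, so every fixation belongs to exactly one cell, with the
right/bottom image edge assigned to the last cell. The centre convention
(the paper-level alternative $W/2$ differs by 0.5 px) is immaterial at the
scale of the predictors but is fixed here once to make all boundary cases
deterministic.

Three region predictors enter the models:

* **central bias** — the anisotropic distance
  $\sqrt{\Delta x^2 + (0.45\,\Delta y)^2}$ from region centre to scene
  centre in pixels. The 0.45 down-weighting of the vertical component
  reflects the wider horizontal spread of scene-viewing fixations; it is
  applied to raw pixel distances *before* standardization. The formula
  itself (rather than, say, scaling after the square root) is our reading of
  "vertical distances scaled by 0.45".
* **size** — the natural log of the bounding-box area in px² (object
  analyses only; grid cells share one size).
* **salience** — the mean value of the scene's salience map inside the
  region's inclusive bounds. Maps are treated as probability surfaces:
  every map is normalized to unit integral, so a scene's mean salience is
  $1/(W \cdot H)$ and region means are directly comparable across scenes.

Predictors are z-transformed (sample SD, $n-1$) over the rows of each
analysis' observation matrix, pooling both age groups. Pooled
standardization keeps the age-interaction coefficients interpretable as
differences on a common scale; per-analysis standardization (grid vs object)
follows from each analysis having its own observation rows.

# Observation matrices and exclusion rules

Fixation reports carry ordered fixations per (subject, scene) trial. The
initial, central fixation of each trial is excluded from all analyses. The
last fixation of a trial is included in position analyses (the participant
chose its location) but excluded from duration analyses (its duration was
cut off by stimulus offset).

The **grid matrix** has one row per analysed trial and grid cell, minus, per
trial, the cell containing that trial's very first fixation; a cell is
fixated if any non-initial fixation falls in it. With 76 subjects, 150
scenes, 10 missing trials and an 8×6 grid this yields exactly
$11{,}390 \times 47 = 535{,}330$ rows, which the test suite checks.

The **object matrix** has one row per subject × annotated object (rows of
missing trials dropped); a fixation inside several overlapping boxes credits
each object, and each object's outcome is coded independently. Cases where
the initial central fixation coincided with a subject's first fixation on an
object are counted and excluded from the fixation-time and landing-position
tables (interpreted per-case, not per-object); in the binary matrix the
initial fixation can never set the outcome, but later visits can.

**Fixation times** segment each trial into object visits. The first visit is
the first maximal run of consecutive in-box fixations entered from outside;
first-fixation duration is the duration of the run's first fixation and
first-pass gaze duration the sum over the run (immediate refixations
included). Visits containing the trial's last fixation are dropped from the
time analyses. Fixation times are modelled on the natural-log scale (an
intercept of 5.45 corresponds to about 233 ms).

# Preferred viewing location

For each qualifying first-pass entry fixation, the landing position is
normalized per axis by the object's extent and signed relative to the launch
site: $u_a = (\text{landing}_a - \text{centre}_a)/\text{extent}_a$ and $n_a =
\mathrm{sign}(\text{centre}_a - \text{launch}_a)\, u_a$ (sign(0) taken as
+1). Negative values are undershoots of the object centre. The two axes are
treated independently rather than projecting onto the saccade vector:
launch, landing and object centre are generally not collinear, so any 2D
projection would be arbitrary — mirroring the design choice of the emulated
analysis. With the inclusive-range centre, inside landings satisfy $|n_a| <
0.5$, with the box edges mapping to ±0.5 in the limit. Smoothed 2D landing
histograms are computed on a fixed 51×51 lattice over $[-0.5, 0.5]^2$ with a
Gaussian product kernel and normal-reference bandwidths.

# Mixed-model estimation core

The binomial logit GLMMs and Gaussian LMMs are fitted by an estimation core
implemented in this package on sparse Matrix algebra, so that the analysis
is self-contained and its objective function can be validated directly
against independent oracles.

* **GLMM (Laplace).** With spherical random effects $u$, relative
  covariance factor $\Lambda_\theta$ and $U = Z\Lambda_\theta$, the inner
  PIRLS loop minimizes the penalized deviance $d(y,\mu) + \|u\|^2$ with
  step-halving; the Laplace deviance adds $\log\det(U^\top W U + I)$ at the
  conditional mode. The outer optimization runs over a log-Cholesky
  parametrization of $\Lambda_\theta$ (diagonal on the log scale, free
  off-diagonals), which enforces positive semi-definite covariance blocks.
  Fixed effects are profiled inside PIRLS during the covariance search —
  which ignores the log-determinant's (weak) dependence on $\beta$ — and an
  optional Newton polish of $\beta$ on the exact Laplace objective at the
  optimized $\theta$ follows (`refine = TRUE`, using the conditional
  information as the Hessian), removing that discrepancy. Starting values are fixed and
  documented (null fixed effects, unit random-effect SDs), so fits are
  reproducible. Wald SEs come from the fixed-effects block of the inverse
  observed information conditional on $\theta$, and $p$-values from the
  normal approximation — the reporting convention of the emulated analysis.
* **LMM (REML).** For a given $\theta$ the fixed effects and residual
  variance have closed-form profiles, leaving a profiled REML criterion that
  is minimized by Nelder-Mead, then polished by BFGS and a short Newton
  refinement with numerical derivatives. The polish exists so that variance
  components agree with closed-form estimators (e.g. balanced one-way ANOVA)
  to ~1e-9 rather than optimizer-tolerance precision. LMM coefficients are
  judged by the two-tailed $|t| > 1.96$ criterion; no $p$-values are
  reported for LMMs.
* **Degenerate structures.** With no random terms the same PIRLS/profile
  code paths reduce exactly to logistic regression / OLS, which the tests
  exploit as an oracle. Near-zero variance components are reported and
  flagged (`singular`), not treated as errors; `fit_lmm(reduce = TRUE)`
  removes random terms whose SD falls below `sd_tol` (default 1e-4) times
  the response SD, stepwise, re-fitting after each removal.
* **Convergence.** Inner loop: relative penalized-deviance change < 1e-10,
  at most 50 iterations. Outer: relative criterion change < 1e-8 (< 1e-13
  for REML before polishing), Nelder-Mead capped at 500 (GLMM) / 2000 (LMM)
  evaluations. Optimizer identity is irrelevant to the contract; only the
  converged objective value matters.

**Validation strategy.** The objective itself is checked against an
adaptive Gauss-Hermite (order 25) integration oracle on scalar
random-intercept fixtures. Because the Laplace approximation differs from
the exact likelihood by an amount that grows with the random-effect
dispersion (measured gaps on a 20-cluster × 20-observation fixture: ~6e-5 at
SD 0.05, ~9e-4 at SD 0.1, ~1e-2 at SD 0.2), the tight 1e-3 agreement is
asserted in the small-dispersion regime (SD ≤ 0.1), where implementation
errors — a wrong penalty, log-determinant or mode — would still appear as
order-one discrepancies. Estimates and SEs are additionally cross-checked
against an independent mixed-model fitter on small instances.

# The synthetic-data generator

No public corpus accompanies the analysis, so the generator emulates the
study conditions and doubles as the test fixture. Its defaults are the
study's: 42 young + 34 older subjects, 150 scenes of 800×600 px (25.78°
wide, hence 31.0 px/deg), ~6.9 annotated objects per scene (Poisson,
truncated at 2 so inter-object distances exist), 10 missing trials, ~21
fixations per 6-s trial, lognormal durations (meanlog 5.45, sdlog 0.35,
mean ≈ 248 ms), and generating logit coefficients equal to the study's
fitted object-model values (intercept −0.2278, age −0.208, central bias
−0.1795, size 1.028, salience 0.3823, with the corresponding interactions)
over subject/scene/object random intercepts (SDs 0.367/0.304/1.018, the
square roots of the reported variances).

Two generators exist on purpose:

* the **indicator-level** generator draws the binary outcomes directly from
  the logit-linear model — an exact match to the fitted model, used for
  estimator validation and parameter recovery;
* the **scanpath-level** generator produces ordered fixations: an initial
  centre fixation, then saccades that target objects with probability
  increasing in their generating logit (otherwise centre-biased background
  locations with a horizontally elongated spread), immediate refixations at
  rate 0.3, and within-object landings from a launch-relative 2D Gaussian
  with mean `pvl_mean_offset` (default (−0.0509, −0.0294), the study's
  fitted undershoots) and SD 0.15 per axis, truncated to the box.

The sequential target-selection rule is a pragmatic stand-in — the study
recorded real eye movements and describes no generative scanpath process —
so scanpath-level data follow the fitted fixation-probability model only
approximately, and nothing here is a claim about oculomotor behaviour.
Passing tests on synthetic data therefore show that the pipeline recovers
the structure it assumes, not that real data satisfy those assumptions:
real corpora bring overdispersion, spatial correlation between neighbouring
regions, and annotation noise that the generator deliberately omits (as do
velocity profiles, blinks and image content).

Salience maps are mixtures of 2D Gaussian blobs — most objects carry one
(SDs 0.5–1.5× the object half-extent), plus three background blobs — over a
uniform floor holding 10% of the mass, normalized to unit integral. This
yields an object-salience distribution with appreciable spread and scene
maxima that often, but not always, fall inside annotated boxes. Object boxes
are rejection-sampled (≤ 1000 tries) to stay inside the image, avoid the
vertical midline (as the annotation protocol required), and overlap by at
most 20% of the smaller box. A single global seed drives everything;
per-scene and per-subject substreams are derived by hashing, so regenerating
part of a corpus is stable.

Memory-test rates invert the study's printed group summaries through the
equal-variance SDT model: solving $d' = z_H - z_F$, $c = -(z_H + z_F)/2$
for (d′ = 1.54, c = 0.45) young and (1.33, 0.67) old gives hit/false-alarm
probabilities (0.626, 0.111) and (0.498, 0.091), from which hits and false
alarms are binomial over 15 signal and 15 noise trials per subject.

# Signal detection scoring

Hit and false-alarm rates use the log-linear correction, applied to all
subjects uniformly: $H = (\text{hits}+0.5)/(n_s+1)$, $F =
(\text{fa}+0.5)/(n_n+1)$, then $d' = \Phi^{-1}(H) - \Phi^{-1}(F)$ and $c =
-(\Phi^{-1}(H) + \Phi^{-1}(F))/2$. The correction keeps both rates strictly
inside (0,1), so perfect performance stays finite. Positive $c$ means a
conservative tendency to call present objects absent. Group comparisons use
Welch's unequal-variance $t$ with fractional degrees of freedom, matching
the reporting style of all group tests in the package.

# Problem sizes and study-design choices for validation

The validation suites run at desk scale, chosen as the package's own
simulation-design decisions:

* Parameter recovery uses 20 + 20 subjects × 60 scenes with a 4×3 grid (12
  regions per scene) and 200 replicates over one fixed scene set — stimuli
  are fixed in a real study; responses are resampled. Generating
  interaction coefficients are set to moderate magnitudes (0.3 and −0.2)
  rather than the study's near-zero printed interactions, because a
  relative-bias criterion is uninterpretable for coefficients near zero.
* The study-scale bookkeeping check (535,330 rows) generates short
  scanpaths (~4 fixations/trial): the row count depends only on which
  trials exist and on the per-trial excluded cell.
* PVL recovery uses 10 + 10 subjects × 40 scenes (~3,500 landings), enough
  to pin the generating undershoot to ±0.01. A small positive bias
  (~0.002) from truncating the landing Gaussian to the box is expected and
  stays well inside that band.
* Full paper-style random structures (correlated by-subject slopes, by-scene
  slopes for the grid model) are exercised in the analysis drivers; the
  recovery loops use random-intercept models matching the indicator
  generator, which is the structure under which coverage claims are made.

# Known limitations

* The Laplace approximation is least accurate for small clusters with large
  random-effect dispersion; no adaptive-quadrature *fitting* mode is
  provided (quadrature is used as a test oracle only).
* Wald SEs condition on the estimated covariance parameters, as in standard
  practice; with few grouping levels they can run slightly below the
  empirical sampling SD, and coverage of interval estimates is
  correspondingly near, not exactly at, the nominal level.
* The scanpath generator does not model saccade dynamics, scene semantics,
  or the memory questions' content; its object-selection rule is a fixture
  device. With the default targeting rate (0.6, chosen so that nearly all
  first-visit entries come from the landing-position model rather than from
  background fixations drifting into boxes) its marginal object-fixation
  probability runs higher (~0.6–0.75) than the emulated study's 0.44;
  fixation-probability recovery claims are made against the indicator-level
  generator, which matches the fitted model exactly.
* Salience maps are synthetic stand-ins for algorithmic salience maps; the
  salience *algorithm* itself is out of scope and maps are treated purely
  as an input format.
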