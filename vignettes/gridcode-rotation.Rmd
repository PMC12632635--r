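---
title: "Detecting grid-like codes that rotate with cognitive reference frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting grid-like codes that rotate with cognitive reference frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridshift)
```

## The scientific problem

Grid cells fire in a hexagonal lattice over space, and in fMRI this
six-fold symmetry appears as a 60°-periodic modulation of the BOLD signal by
the direction of travel,

$$ y(t) \propto \cos\!\big(6\,[\theta_t - \phi]\big), $$

where $\theta_t$ is the angle of travel on trial $t$ and $\phi$ is the *grid
orientation*, identified only modulo $360/k$ degrees ($k = 6$ for a
hexadirectional code). `gridshift` implements the full analysis chain for a
predictive-inference task in which all target locations rotate together at
unsignaled *state changes*: participants move a colored shield to block an
attack whose location is drawn from a Gaussian centered on a color-specific
target. Because the whole target configuration rotates by 90° between two
alternating states, the orientation of a directional code can distinguish
two hypotheses:

* a **spatial** code anchored to the screen: $\phi$ identical in both
  states, so a modulator built from one state's orientation predicts the
  other state's signal *positively*;
* a **cognitive** code anchored to the relative target configuration:
  $\phi$ rotates with the targets, and since
  $90 \equiv 30 \pmod{60}$, the two states' orientations are precisely
  antiphase — a cross-state predicted modulator correlates *negatively*.

Every stage runs on synthetic data with known ground truth, so each
estimator is validated by parameter recovery rather than by reference to any
real recording.

## The task generator

`build_session_schedule()` reproduces the three session designs: a training
session (8 state-blocks × 8 mini-blocks × 5 colors = 320 trials, rotations
alternating 0°/90°), a scanner session (8 × 6 mini-blocks over 4 runs, five
original colors plus two novel-color trials appended to each mini-block),
and a novel-rotations session (320 trials; block 1 at 0°, blocks 2–8 drawn
without replacement from the 23 rotations at 15°–345° in 15° steps). Each
mini-block presents every original color exactly once in pseudorandom order.

Two generator choices deserve comment:

* **Session-2 totals.** Two novel-color trials per mini-block over eight
  state-blocks gives 8 × 6 × 7 = 336 trials; the published total for this
  design (332) cannot be derived from the stated block structure, so the
  generator emits the structural 336 and records the published figure in
  `attr(schedule, "printed_trial_total")` rather than silently dropping
  trials at an arbitrary position.
* **Timing.** Trials run simulation (2–6 s uniform in 1 s steps) →
  response (3 s) → outcome (1 s) with a 1 s inter-trial gap and a 4 s
  run lead-in. The angle of travel $\theta$ is the direction from the
  shield's random start position to its final response position;
  zero-length movements get $\theta = 0$ and are flagged missed.

Simulated agents provide behavioral ground truth: `random` (chance
baseline), `persistent` (always answers at the previous state's target —
normalized error 1 after a change), and `transfer_learner`, which infers the
block rotation from the first post-change outcome and applies it to all
colors (zero-shot transfer; optional Gaussian angular response noise via
`noisy_learner`).

## Behavioral statistics

The normalized angular error is
$e = \theta_{curr}/(\theta_{alt} + \theta_{curr})$, built from minimal
angular distances about the arena center: 0 at the current-state target's
angle, 1 at the alternate-state target's angle, 0.5 equidistant. By a
reflection-symmetry argument a uniformly random responder has expected
normalized error exactly 0.5 for *any* target geometry; the test suite and
acceptance script verify 0.5 ± 0.01 over ≥ 10,000 trials.

Trials are labeled correct below 45° absolute angular error, missed below
10 px of movement (excluded from error regressions — there is no meaningful
response position), and *transfer* for positions 2–5 of the first
mini-block after a state change. `random_response_null()` simulates guessing
means per trial set (the analytic mean of a uniform absolute angular error
is 90°), `rank_order_guessing_null()` builds per-rank cohort nulls, and
`multi_timescale_regression()` implements the two-stage scheme — per-subject
OLS on trial/block or mini-block/block predictors (mean-centered before
forming interactions), then group one-sample t-tests with Cohen's
$d = \bar\beta / s_\beta$. Error measures are logit-transformed with
clipping at $\varepsilon = 10^{-3}$ (keeps 0 and 1 finite while leaving the
interior effectively untouched).

## The BOLD simulator

`simulate_bold()` plants a directional code with known parameters: per
trial, the simulation-period boxcar carries amplitude
$b + A\cos(k[\theta_t - \phi_{state}])$; under the cognitive regime
$\phi_{state} = (\phi + \mathrm{rotation}) \bmod (360/k)$, under the
spatial regime $\phi$ is constant. Boxcars are laid on a microtime grid
($dt = TR/16$), convolved with a canonical double-gamma HRF (delays 6/16 s,
undershoot ratio 6, 32 s support, peak-normalized), and read out at mid-TR.
Slow cosine drift (0.5/1/2 cycles per run), smooth nuisance series
(standardized random walks, returned as known regressors) and white
Gaussian noise complete the signal; an optional AR(1) toggle exists but the
default is white noise, which is sufficient for recovery testing. SNR is
`grid_amplitude / noise_sd`; the residual SD after regressing out the true
design matches `noise_sd` within 5%. Runs are simulated independently and
concatenated, and a volumetric mode places the signal in a designated
sphere of a small 3 mm grid for searchlight tests.

What the generator does *not* emulate: physiological noise spectra, motion,
spatial autocorrelation of the BOLD signal within the ROI, or
between-subject variability in HRF shape. Passing recovery tests therefore
demonstrates the estimators' correctness, not robustness to every real-data
artifact.

## GLM core and the hexagonal modulation test

`build_grid_design()` assembles the concatenated-run design: boxcars per
condition cell (correct/incorrect/missed × state, or × state × run),
quadrature modulators $\sin k\theta$, $\cos k\theta$ for correct and
incorrect cells (mean-centered within cell before convolution — standard
parametric-modulation practice that keeps modulators orthogonal to their
boxcar), response- and outcome-period boxcars, block-diagonal drift,
per-run intercepts and unconvolved nuisance columns. A centered sin/cos
pair needs at least three trials to be linearly independent; sparser cells
are flagged unidentifiable and skipped. `fit_glm()` is massively univariate
OLS with an informative error naming null-space columns.

`hexagonal_f_test()` tests the joint null on the correct-trial quadrature
betas of both states (four columns at $k$ = 6) and maps F to Z through the
p-value route, $Z = \Phi^{-1}(1 - p_F)$, computed with log-space tail
probabilities and capped at $|Z| = 37$ — numerically equivalent to the
classical asymptotic F→Z transform at double precision. Only correct-trial
modulators enter the F-test; incorrect-trial modulators are nuisance.

## Grid orientation and cross-validation

$\hat\phi = \mathrm{atan2}(\hat\beta_{sin}, \hat\beta_{cos})/k$, reduced to
$[0, 360/k)$; the two-argument arctangent preserves the quadrant that the
ratio form loses. Orientations are averaged on unit vectors at $k\phi$
(naive averaging is wrong across the wrap). At SNR 1 with 240 trials the
orientation is recovered within 3°.

* `between_state_crossval()` fits $\phi$ per state, then fits one GLM in
  which each state's modulator is $\cos(k[\theta_t - \phi_{other}])$ — the
  state-Y modulator carries the state-X prediction and vice versa, both
  fitted simultaneously (a `simultaneous = FALSE` switch fits one direction
  per model). The mean of the two coefficients is positive for a spatial
  code and negative for a cognitive code under a 90° rotation at $k = 6$.
* `within_state_crossval()` fits quadrature pairs per state × run, takes
  the leave-one-run-out circular mean orientation, and scores the predicted
  modulator on the held-out run — positive coefficients indicate a stable
  orientation. With a noiseless stable signal the held-out coefficient
  equals the planted amplitude.
* `fold_symmetry_scan()` repeats either test at $k \in \{4,5,6,7,8\}$
  (90°/72°/60°/51.4°/45° periodicities); a genuine six-fold code is
  significant only at $k = 6$.

`trialwise_phase_consistency()` adapts the cross-validation logic to single
trials: the ROI series is residualized against a baseline model
(condition-level simulation boxcars, the response-period movement
regressor, outcome, drift and nuisance — removing the mean trial-locked
response while leaving per-trial amplitude deviations), and each trial's
HRF-convolved signed regressor ($\cos(k[\theta_t - \phi_{alt}])$ on the
trial boxcar) is correlated with the residual over
$[\mathrm{onset}, \mathrm{onset} + \mathrm{duration} + 8\,\mathrm{s}]$
(both demeaned in-window; 8 s covers the hemodynamic lag). Coefficients are
Fisher-transformed. Because correlation discards scale, the cosine weight
contributes its sign — in-phase signals give positive $z$, antiphase
negative. `trialwise_dynamics()` then runs the per-subject regressions of
$z$ on logit error (with and without the mini-blocks-since-change
covariate) and on trial/mini-block indices, with group t-tests.

One residualization detail was genuinely open: "trial regressors" could
mean per-trial boxcars or the across-trial mean response. Per-trial
boxcars would absorb exactly the amplitude deviations the correlation is
meant to detect, so the baseline model uses condition-level boxcars; the
recovery tests (planted in-phase → $z > 0$, antiphase → $z < 0$, noise →
$z \approx 0$) confirm the choice.

## Representational similarity analysis

`single_trial_maps()` estimates one GLM per trial (the trial's simulation
regressor, one pooled all-other-simulations regressor, outcome, response,
drift and nuisance) and keeps the trial regressor's t-map — the
least-squares-single style of beta-series estimation, which is stable when
neighboring trials overlap. Missed trials are excluded. The neural RDM is
$1 - r$ (Pearson) over voxels, in $[0, 2]$ with a zero diagonal.

`build_hypothesis_rdms()` constructs the model RDMs: state-specific and
state-invariant mean-target-position distances, shield identity, and a
transfer-trial indicator, plus covariates (run, state-block, state,
within-state identity, response-angle change since the last same-color
trial, CIELAB ΔE color distance — CIE76, the simplest standard — movement,
start/end position distances, and within-run lag indicators at lags 1–16;
temporal autocorrelation does not cross run boundaries).
`rdm_regression()` z-scores the vectorized strict lower triangles and fits
OLS with an intercept, making coefficients invariant to affine rescaling of
any model RDM; near-collinear predictors (|r| > 0.99) are rejected by name.

`searchlight_rsa()` moves a 9 mm sphere (123 voxels in the interior of a
3 mm grid) over every in-mask voxel and assigns each voxel the mean
coefficient over all spheres containing it; spheres with fewer than 10
in-mask voxels are skipped and logged. `second_level()` provides per-voxel
one-sample t-tests and covariate-slope t-tests (covariate centered;
restrict with `mask` to voxels with a group effect, the standard usage).

## Cluster-extent permutation correction

`permutation_cluster_correct()` thresholds the group t-map at two-tailed
p < 0.001 (positive and negative tails separately, since effects are
signed), labels clusters with face (6-neighbor) connectivity —
the conservative default — and builds the null by flipping the sign of a
random half (exactly ⌊N/2⌋, or independent coins via `flip = "coin"`) of
the subjects' maps, recording the maximum cluster extent over both tails.
A cluster survives when its corrected p,
$(1 + \#\{\mathrm{null\ maxima} \ge \mathrm{extent}\})/(n_{perm}+1)$, is at
most 0.05; the reported threshold $k$ is the smallest surviving extent.
This is the exact tie-aware version of "the 95th percentile of the null
maxima": with small volumes the null extent distribution is coarsely
discrete, and an interpolated percentile combined with a ≥ rule inflates
the family-wise error well above nominal, while the exact rule keeps it at
or below 5%. On simulated cohorts of spatially smoothed Gaussian null maps
(12³ voxels, 3-voxel FWHM — the smoothness of a typically preprocessed
group map; cluster statistics are only meaningful on smooth fields) the
empirical family-wise error over 200 datasets × 500 permutations is ≈ 3–5%.

## Numerical choices and problem sizes

* Angles: degrees everywhere; orientations live in $[0, 360/k)$ with
  values within $10^{-9}$ of the period wrapped to 0.
* Convolution: microtime oversampling 16, mid-TR sampling; HRF support 32 s.
* $|Z|$ capped at 37; F→Z computed in log space.
* Correlations clipped to $\pm(1 - 10^{-12})$ before the Fisher transform.
* Determinism: every stochastic stage takes an integer seed; a master seed
  derives labeled child seeds (`run_experiment()` records them all in its
  JSON manifest, sufficient to reproduce any single stage).

The validation suite runs at desk scale, chosen so the full suite completes
in under two minutes: simulated subjects use 240-trial sessions (8 × 6 × 5
over 4 runs, ≈ 1100 scans at TR 2 s) with a single-voxel or small-grid ROI;
regime-sign calibration uses 100 seeds per regime; fold specificity uses a
16-subject cohort; the family-wise error calibration uses 200 datasets of
12 subjects at 12³ voxels with 500 permutations. These sizes give
Monte-Carlo error comfortably below each test's tolerance.

## Known limitations

* The simulator's noise is temporally white (AR(1) optional) and spatially
  independent; claims about robustness to structured fMRI noise are out of
  scope.
* Voxel-wise grid-orientation maps and cross-participant orientation
  alignment are not provided; orientation estimation is ROI-level.
* The between-state test is defined for exactly two states; the
  novel-rotations session is analyzed behaviorally only.
* Session-2 novel-color placement follows the structural reading (two per
  mini-block, appended after the originals); if the published 332-trial
  layout ever becomes precise, the generator's `novel_plan` hook accepts a
  custom assignment.

## A worked example

```{r example, eval = FALSE}
library(gridshift)

cfg  <- task_config()
sched <- build_session_schedule(1, cfg, seed = 1)
beh  <- simulate_agent(sched, "transfer_learner", cfg, seed = 2)
mean(beh$normalized_error[beh$transfer])        # rapid zero-shot transfer

sim  <- bold_sim_config(regime = "cognitive", grid_phi = 10,
                        grid_amplitude = 1, noise_sd = 1)
sched2 <- gridshift:::make_schedule(rep(c(0, 90), 4), 6, cfg,
                                    seed = 3, n_runs = 4)
beh2 <- simulate_agent(sched2, "transfer_learner", cfg, seed = 4)
bold <- simulate_bold(beh2, sim, seed = 5)

fit <- grid_glm(bold)                            # per-state orientations
fit
between_state_crossval(bold)                     # negative: cognitive code
within_state_crossval(bold)                      # positive: stable code
fold_symmetry_scan(bold)                         # effect only at k = 6
```
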