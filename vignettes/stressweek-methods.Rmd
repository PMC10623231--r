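---
title: "Simulating and analysing prolonged real-life stress: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing prolonged real-life stress: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stressweek)
```

## The study design this package emulates

`stressweek` implements the complete analysis path for a two-arm naturalistic
stress design: every participant is observed for one week culminating in a
high-stakes examination (the *stress week*) and one ordinary *control week*,
answering six ecological momentary assessment (EMA) surveys a day on a
7-point Likert scale (four stress-appraisal scales, positive and negative
affect), while a wrist biosensor continuously records electrodermal activity
(EDA, 4 Hz), device-processed heart rate (1 Hz), skin temperature (4 Hz) and
3-axis acceleration (32 Hz). Ten-minute windows immediately before each
answered survey summarize physiological arousal per *beep*.

Because no raw cohort of this kind is publicly deposited, the package's
first-class component is a synthetic cohort generator whose *true* effect
structure is configurable. The shipped configuration
(`inst/extdata/effects_default.yaml`, loaded by `default_effects()`) encodes
the published estimates this design is known for: higher event-related
(0.30 SD) and activity-related (0.51 SD) stress and negative affect
(0.12 SD), lower positive affect (-0.08 SD), fewer skin-conductance
responses (SCRs; -0.27 on the log scale) and lower maximum heart rate
(-0.10 SD) in the stress week, and a partial mediation of the
skin-conductance-magnitude decrease by positive affect (indirect -0.013,
direct -0.166, about 7.3% mediated). Every downstream stage can therefore
be validated by parameter recovery: simulate, analyse, and compare the
estimates with the configured truths.

## The generative model

### EMA scales and the variance budget

For each scale the per-beep latent state is

\[ z_{ij} = \beta_w W_{ij} + u_{0i} + u_{1i} W_{ij}
   + \textstyle\sum_s \beta_{s} \tilde d_{sij} + \varepsilon_{ij}, \]

with \(W\) the stress-week indicator, \((u_{0i}, u_{1i})\) per-participant
random intercepts and slopes, \(\tilde d_{sij}\) the *observed* standardized
within-beep deviation of stress scale \(s\) (for the affect scales, which
receive momentary stress input), and \(\varepsilon\) residual noise. Items
discretize \(4 + z + \eta_j\) onto 1..7 with equal-width thresholds
(\(\eta_j\) is item noise, SD 0.3); reversed items are emitted inverted.
This mapping is linear in expectation, so the scored, rescaled scale is an
unbiased (noisy) readout of \(z\): scoring adds the item noise plus the
rounding variance \(1/12\) per item.

Configured effects are standardized coefficients *on the scored outcome*.
The generator therefore solves a variance budget per scale: the residual SD
is chosen so that the total variance of the scored scale — fixed effects,
random effects, momentary input, item noise and rounding — equals one.
Week effects and momentary associations are then recovered by the mixed
models without attenuation, which is the property the acceptance checks
exercise. Momentary stress inputs use the *residual* part of the stress
deviation (week-driven variation removed), so the configured week effects
on affect remain marginal truths, and the momentary model conditions on
week type; for scales with zero week effect (social stress, the focal
momentary association) the two parameterizations coincide exactly.

Random-effect SDs are not printed in the sources this configuration
mirrors, so they are design parameters with two constraints. Intercept SDs
(0.3-0.5) give intraclass correlations near 0.2-0.25, typical of momentary
affect. Slope SDs control how much *individual-level* week signal each
outcome carries — exactly what individualized classifiers consume — and the
published classification regime (affect classifies beeps at about 33%
error, physiology 36%, both far below chance, with per-participant error
SDs of only 2-3 percentage points) pins down both their size and their
shape. Week slopes are therefore drawn as *two-point* (+/- SD) deviations —
individual week effects of near-constant magnitude and random direction —
rather than Gaussian: Gaussian magnitudes would spread individualized
errors far wider than the published 2-3 points and leave many participants
at chance. The shipped SDs (negative affect 0.55 against a 0.12 fixed
effect; magnitude 0.15; max-HR 0.08; stress scales 0.20-0.25) make affect
more individually separable than physiology with their union best, while
per-seed fixed-effect estimates stay within the published confidence
widths. The count channel carries *no* random slope: a +/- slope either
cancels the -0.27 fixed effect for half the cohort (a dead feature) or
overpowers the affect features, and both regimes make the model ordering
cohort-dependent; instead the resting rate (2.4 per window) gives every
participant the same moderate count separability. The positive-affect
slope is kept small (0.15) because it also bounds the Monte-Carlo noise of
the mediation path `a` and hence of the proportion mediated.

### Physiology

Per beep, the generator draws a Poisson SCR count with
\(\log \lambda = \log \lambda_0 + \delta W + u_{0i} + u_{1i} W\)
(\(\lambda_0 = 2.4\) per 10-minute window at rest, a typical wrist-EDA rate
at a 0.01 uS detection threshold), and a latent magnitude state combining the
direct week path, the positive-affect path (the mediation mechanism) and
participant effects, again normalized to unit variance. Event amplitudes are
`0.4 + 0.12 * m + jitter` microsiemens, scaled by a per-participant
dynamic-range multiplier (log-normal, SD 0.2). The continuous EDA stream is
a slowly drifting tonic level (spline through hourly knots) plus the event
train convolved with the Bateman kernel
\(h(t) = e^{-t/\tau_d} - e^{-t/\tau_r}\) (\(\tau_r = 0.75\) s,
\(\tau_d = 2\) s, unit peak), white noise, and motion artifacts: short
(<= 0.5 s) positive spikes co-timed with accelerometer bursts, giving the
despiking stage a known ground truth to remove.

Maximum heart rate needs one calibration step: the week effect is configured
in SD units of the *realized window maximum*, whose variance combines the
between-participant baseline SD, the within-day drift SD and the sampling
variability of the maximum of 600 noise samples (SD about 0.37 times the
sample noise SD; the Gumbel approximation for Gaussian maxima). The
generator converts the standardized coefficient to beats per minute with
that closed form.

Sensor noise floors are design choices: EDA white noise is 0.002 uS,
near the device's ~1 nS quantization. This matters for the SCR counter:
with a 0.01 uS prominence-and-amplitude criterion, detection needs roughly
a 5x margin over the effective phasic noise floor; realistic amplitudes
(0.25-0.8 uS) are then recovered essentially exactly, and false detections
are rare enough (< 0.1 per window) not to bias the count model's log-scale
week effect.

### Missingness

Beeps are answered within the 1-hour window with probability 0.85
(unanswered beeps are split between never-answered and answered-late, so
compliance filtering has both cases to reject). Given an answered beep, the
sensor window is usable with probability 0.905 — realized as flat
sub-threshold electrode contact, so it is the *quality rules* downstream
that exclude those windows, not a bookkeeping flag — giving the joint
~77% EMA+EPA availability the design reports. Two participants carry a dead
temperature sensor (constant 0 C); their temperature features are imputed
from the population mean and SD.

### What the generator does not emulate

Raw blood-volume pulse is not synthesized (the analysis path uses the
device-processed heart-rate channel, as the emulated studies do); interbeat
intervals are generated only as sparse coverage (~27% of each window) for
format completeness and are never consumed. EMA items are structural
stand-ins (correct scale structure, reversed items, discretization), not
psychometric replicas of any validated questionnaire. Diurnal physiology
(circadian HR/EDA rhythms), posture, and exercise-driven arousal are absent.
Passing recovery tests on this cohort therefore demonstrates the
correctness of the pipeline's estimators, not the field validity of wrist
EDA for stress detection.

## The analysis path

### EMA scoring

Reversed items are re-inverted (`v -> 8 - v`), items summed, and sums
rescaled to [0, 1] by the theoretical scale minimum and maximum (stable
under missingness, unlike sample-based rescaling). A scale with any missing
item is missing for that beep: with 3-5 item scales, prorating would bias
person means. Person-centering subtracts each participant's mean over
compliant beeps across both weeks. The median-split incongruence summary
aggregates event + social + activity stress per beep and splits at the
participant's own median, ties assigned "not stressed" (conservative for
stress detection).

### EDA processing

`clean_eda()` applies, in order: a quality floor (windows whose median skin
conductance is below 0.01 uS are discarded), despiking (samples deviating
more than 5 MADs from a 1.25 s rolling median are interpolated), transient
denoising (an excursion larger than 0.02 uS per sample that *returns to its
pre-jump level* within 2.5 s is an artifact and is interpolated away; a
genuine SCR at these time constants stays elevated much longer, and
mid-rise samples are protected by requiring onsets to start from locally
level signal), and a zero-phase order-4 elliptic low-pass (0.1 dB ripple,
40 dB attenuation). The cut-off is the midpoint of the configurable
0.8-1.1 Hz transition band, read in hertz on the 4 Hz stream: the
alternative normalized-frequency reading would place 1.1 above Nyquist.
Signals are detrended by their endpoint ramp before filtering so the
forward-backward pass sees no boundary step.

`decompose_eda()` deconvolves with the unit-peak Bateman kernel by
Wiener-regularized FFT division (regularization 0.025 of the peak spectral
magnitude — large enough to suppress the ~50x noise amplification near
Nyquist where the kernel spectrum vanishes, small enough that reconvolving
the driver reproduces clean signals to under 5% RMSE of the signal SD).
The endpoint ramp is removed first (a step against the zero padding would
deconvolve into a large edge impulse). The driver splits into a tonic part
(8 s running median — robust, so sparse SCR impulses do not leak into it)
and a phasic part (lightly smoothed over 1.25 s); `tonic + phasic`
reconstructs the input exactly by construction, and the reconstruction
property is tested through the driver. SCRs are local maxima of the phasic
component with both prominence and absolute amplitude at least 0.01 uS
(amplitude matters: prominence alone counts peak-to-trough noise wiggles),
excluding peaks within 2 s of the window edges (their events began outside
the window). Magnitude is the mean peak amplitude — a declared reading of
the ambiguous "magnitude"; the area under the non-negative phasic curve and
the mean tonic level complete the feature set. The full chain recovers
injected event counts exactly on clean windows and attenuates amplitudes by
about 6% (filter plus split smoothing), uniformly across conditions.

### Mixed models

Gaussian outcomes are z-scored on the full two-week sample (so week
coefficients are standardized betas); SCR counts use a Poisson log link
(week effect = log-mean difference). All models carry the declared
covariate sets (subject: sex, program, week order; day: day index, beep
number, sleep duration, previous-night alcohol; beep: hunger, caffeine,
exercise, sexual activity; physiology models add ambient temperature and
accelerometer movement — all generated with zero true effects, so they cost
degrees of freedom without biasing recovery). The random-effects ladder is
by-participant intercept + focal-predictor slope, falling back to
intercept-only when singular; fits use maximum likelihood without
derivative re-checks, and intervals are Wald. FDR correction is
Benjamini-Hochberg within declared model families.

### Mediation

`mediate()` uses the product-of-coefficients decomposition: `a` (week to
mediator) times `b` (mediator to outcome given week), with the direct path
the week coefficient given the mediator; total = indirect + direct, and the
proportion mediated is their ratio (flagged unstable when the total is
within 0.02 of zero). Point estimates come from random-intercept mixed
models. Confidence intervals come from 5000 cluster-bootstrap resamples:
participants are resampled with replacement (respecting repeated measures)
and both models are refit by ordinary least squares — refitting mixed
models thousands of times would cost hours for no change in the resampled
point estimates' center. Windows with zero detected SCRs are excluded from
magnitude models: a mean peak amplitude is undefined without peaks, and
scoring those windows 0 would fold the count effect into the magnitude
effect. Because the measured magnitude is a noisy linear readout of the
latent state, both `b` and the direct path shrink by the same outcome-side
factor, so the proportion mediated — the quantity of interest — is
preserved even though the absolute paths shrink somewhat.

### Classification

Random forests (500 trees, sqrt(p) features per split, the standard
`randomForest` implementation) classify each beep's week type from Model 1
(person-centered positive and negative affect), Model 2 (the ten
physiological features, unstandardized), or Model 3 (their union).
Leave-one-beep-out (LOBO) fits one forest per held-out beep within each
participant; leave-one-subject-out (LOSO) fits one forest per held-out
participant on everyone else's beeps. Every fold's forest is seeded from
the (participant, beep) pair, so results are exactly reproducible. Each
participant's error is compared with a bootstrap null that resamples
predicted labels i.i.d. from the observed predicted-class frequencies
(10,000 draws) — fast, and matching the error-distribution reading of a
bootstrap null; a slow label-permutation check is available through the
test suite's permuted-cohort runs. Paired two-tailed t tests compare models
against their null means and against each other, BH-corrected; zero-variance
differences are reported as exact with an explicit flag rather than an
infinite t statistic.

The constructed-heterogeneity configuration (`heterogeneous_effects()`)
flips the week-effect direction of a randomly chosen *half* of the cohort
and raises the random slopes to near the variance-budget ceiling (SCR base
rate 6 per window), with every slope sharing its participant's flip
direction. The two half-cohorts are then exact mirrors of each other in
feature space: no pattern — not even a joint multi-feature one — relates
features to week type across participants, while within any one
participant the week signal is strong and coherent. Individualized models
therefore reach very low error while group models sit at chance, the
regime that demonstrates, by construction, why individualized stress
detection outperforms population models. Two subtleties found the hard
way: the SCR-count slope stays at zero here, because symmetric +/- effects
on the *log* rate leave a convexity signature in the counts that a group
model can exploit; and if slope directions were drawn independently per
feature, the cohort would fall into feature-space "corner types" whose
uneven sampling at small n gives group models real signal. Even in this
regime a group model is not *exactly* at chance for every participant:
with raw (uncentered) physiological features it can occasionally ride a
held-out participant's baseline similarity to a like-signed neighbour, so
individual LOSO errors scatter around chance while every model's mean
LOSO error stays far above its LOBO counterpart — which is also the level
(model means, paired over participants) at which the individualized-vs-
group comparison is defined.

## Problem sizes and reproducibility

All randomness flows from one integer seed through hashed per-unit child
seeds (`derive_seed()`), so any participant-day or fold is reproducible in
isolation and byte-identical across reruns. Cohort-scale feature extraction
generates per-window sensor segments whose samples are identical to the
full-day streams (same seeds and draw order; the SCR convolution lookback
truncates at 30 s, a sub-microsiemens-per-million difference), avoiding
half-day 32 Hz vectors; `write_cohort()` materializes the full sessions
when the on-disk dialect is wanted. Sensor noise exists inside analysis
windows; between windows the streams carry the deterministic baseline (no
analysis ever reads there).

The recovery analyses in the test suite and acceptance script run the full
design — 83 participants, two 7-day arms, 6 beeps/day — averaged over 5
seeds for fixed-effect and mediation recovery. Classification checks use
smaller cohorts (14 participants for the default regime, 8 for the
constructed-heterogeneity one, with 300-tree forests), where the orderings
of interest are already stable: per-participant error SEs scale with
beeps, not cohort size, and the paired comparisons gain little beyond
~15 participants.
Recovery checks compare estimates to configured truths within twice the
Monte-Carlo standard error of the seed average, using the larger of the
empirical across-seed SE and the model-based SE (the empirical SD of five
draws is itself noisy).

## Known limitations

- The latent-to-Likert mapping attenuates regression slopes by the rounding
  covariance (~1.5%); week (mean-difference) effects are unaffected. This
  is visible as a slight conservative bias in momentary-association
  recovery.
- Absolute mediation paths shrink with outcome measurement noise (the
  proportion mediated does not); recovering the printed indirect and direct
  values exactly would require a noise-free magnitude readout no real
  pipeline has.
- The Poisson count model ignores the (rare) detection errors of the SCR
  counter; at the default noise floor these are below 1% of events.
- `fit_week_model()`'s ladder never tries correlated random slopes beyond
  the maximal two-term structure, and Wald intervals are first-order.
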