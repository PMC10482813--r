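---
title: "Discovering morphologies of intra-tidal PaO2 oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering morphologies of intra-tidal PaO2 oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fast intra-arterial oxygen sensors resolve oscillations of arterial oxygen
tension (PaO2) *within* each mechanical breath. The shape of these
oscillations is physiologically informative: a *ventilation-dependent*
oscillation rises through inspiration and falls through expiration (as
expected under cyclical alveolar recruitment/derecruitment), an *inverted*
(perfusion-dependent) oscillation does the opposite, and intermediate
morphologies show two peaks and two troughs per breath. `pao2morph`
implements a complete, reproducible pipeline for discovering such discrete
morphologies from raw PaO2 / airway-pressure recordings, together with a
synthetic cohort simulator that makes every stage testable against known
ground truth.

The pipeline is: alignment of the PaO2 signal with the phases of ventilation
→ breath segmentation → linear detrending → per-timepoint median aggregation
→ SD normalization → exclusion filtering → functional principal component
analysis (FPCA) → Monte-Carlo AIC-guided k-means clustering → progression
ordering → association statistics.

## The canonical breath grid

All breath-level computations use a fixed dense grid of **600 samples per
breath at 0.1 s spacing** (10 Hz sampling), i.e. a 60 s breath axis at the
nominal respiratory rate of 10/min with inspiratory:expiratory ratio 1:2
(20 s inspiration, 40 s expiration). `breath_grid()` encodes this convention;
for other respiratory rates the breath period is defined as 600/RR seconds so
the grid length never changes. Each condition contributes ten breaths
(a 10 × 600 matrix) and, after aggregation, one normalized 600-point breath.

## Signal model and the synthetic generator

`simulate_condition()` builds each recording as

* eleven steady pre-hold tidal breaths:
  `mean_pao2 + drift_slope * t + osc_amplitude * template(phase - offset)`
  plus cardiac ripple and white noise,
* a 20 s end-expiratory breath hold with linear PaO2 decline
  (default 2.5 mmHg/s) at zero-flow airway pressure, and
* ten post-restart breaths in which the *mean level* recovers exponentially
  (time constant 2.5 s) from the apnoea deficit, starting `true_offset`
  seconds after the ventilator restarts, while the oscillation ramps back in
  with a slower time constant. The decline must dominate the oscillation
  amplitude for the change point to exist for *every* morphology — for
  inverted shapes the end-expiratory PaO2 sits above the mean, so a shallow
  apnoea decline would otherwise land exactly on the post-restart target and
  erase the rise.

### The morphology template family

No generative model for the intermediate oscillation shapes is established,
so the template family is a design of this package. A template
(`breath_template()`) is the standardized mixture

```
raw(t) = (1 - 2*theta) * b(t)
       + (w + 0.55 * sin(pi*theta)) * sqrt(2) * cos(2nd harmonic + phase)
       + s1 * sqrt(2) * cos(3rd harmonic) + s2 * sqrt(2) * sin(3rd harmonic)
```

where `b(t)` is an asymmetric fundamental rising over inspiration and falling
over expiration with its peak exactly at the inspiration→expiration
transition. The progression coordinate `theta` runs from the
ventilation-dependent shape (`theta = 0`) to its exact pointwise negation
(`theta = 1`, when `w = s1 = s2 = 0`). The `sin(pi*theta)` transition bump on
the second harmonic keeps the mid-continuum shapes biphasic instead of
letting the waveform collapse to zero at `theta = 0.5`; as a consequence the
map `theta -> template` is uniformly continuous (adjacent values on a 0.05
grid differ by < 0.2 RMS for biphasic weights ≥ 0.15; at exactly `w = 0` the
mid-continuum step reaches ≈ 0.22, because the negation endpoints force a
long path through the transition bump).

The five archetypes (`morphology_archetypes()`) are fixed parameter points
along this continuum, ordered by progression rank:

| rank | theta | biphasic weight | harmonic phase | 3rd-harm. cos |
|------|-------|-----------------|----------------|---------------|
| 1    | 0.0   | 0.25            | 0              | 0             |
| 2    | 0.3   | 0.80            | -0.7           | 0.32          |
| 3    | 0.5   | 0.95            | 0              | -0.50         |
| 4    | 0.7   | 0.80            | +0.7           | 0.32          |
| 5    | 1.0   | 0.25            | 0              | 0             |

and each simulated condition jitters its archetype (SDs: theta 0.035, weight
0.07, phase 0.15, third-harmonic cos 0.12 / sin 0.33). This geometry was
calibrated once, before freezing, so that synthetic cohorts reproduce the
qualitative structure the method is designed to detect: five well-separated
clusters whose curves need five principal components to reach 95% of the
variance, with the first component carrying a bit over half of the variance
and tracking the progression monotonically. Three parameter dimensions alone
(`theta`, weight, phase) span at most three curve dimensions, which is why
the third-harmonic shape coefficients exist: the archetype-level alternation
of the cosine coefficient provides the fourth variance dimension and the
per-condition sine jitter the fifth.

What the generator deliberately does **not** emulate: haemoglobin-buffering
damping of low PaO2 signals (the trough filter exists precisely to exclude
that regime), mechanistic shunt/perfusion physiology (templates are
phenomenological), sensor drift nonlinearity, and breath-to-breath
variability of the ventilator period. Passing recovery tests therefore shows
the pipeline is correct and well-calibrated on signals with this structure,
not that five clusters exist in any particular animal cohort.

### The noise and SNR dial

The signal-to-noise criterion needs a concrete definition; this package uses

```
SNR = 10 log10( Var_t(median breath) / Var(residuals) )
```

with residuals = each detrended breath minus the median breath, pooled over
all breaths and timepoints (`estimate_snr_db()`, capped at +60 dB). The
generator is self-consistent with this definition: the requested `snr_db`
fixes the total non-respiratory variance, of which the cardiac ripple may
take at most 10% (its nominal amplitude is 5% of the oscillation amplitude)
and white noise the rest. Because the median of ten breaths absorbs a small
part of the noise, the realized estimate carries a bias well under 1 dB,
inside the ±1.5 dB calibration band the tests enforce over 10–40 dB. Cardiac
rates are drawn as non-integer values (110–146/min) so the ripple dephases
across breaths — on this grid any integer per-minute rate would be
breath-periodic and survive median aggregation.

## Preprocessing choices

**Alignment.** A line is fitted to the last 5 s of the breath-hold decline;
the change point is the first post-restart time at which PaO2 exceeds the
extrapolated line by more than 3 residual SDs for at least 5 consecutive
samples. Because threshold crossing necessarily lags the true onset by a few
samples, the reported offset is refined by intersecting the decline line with
a rise line fitted over the following 1.5 s (re-fitted once from the
intersection), the classical two-straight-lines construction; the same
construction over the maximum-gradient window is the fallback when no
discrete change point exists. Recoveries with rise slope below 1 mmHg/s are
declared unalignable (a flat, damped recovery still drifts above the
*declining* extrapolation, so a threshold crossing alone is not evidence of a
genuine PaO2 response), as are offsets outside the plausibility range
[0.2, 5] s. All parameters sit in `alignment_config()`.

**Segmentation.** Inspiration onsets are read off the airway-pressure trace;
the offset, rounded to the nearest sample, is applied retrospectively to the
tidal ventilation immediately before the breath hold, and the last ten
complete breaths are extracted.

**Detrending.** The drift line of the ten-breath segment is estimated from
the per-breath mean levels rather than a sample-wise OLS fit: for a periodic
waveform plus linear drift the breath-mean estimator recovers the drift
exactly, whereas sample-wise OLS aliases the waveform's asymmetry into a
spurious slope and redistributes it as step offsets between breaths, which
would contaminate the SNR residuals. (`detrend_linear()` on a plain vector is
the ordinary sample-wise OLS detrend.)

**Exclusion.** A condition is excluded iff trough < 100 mmHg (strict, on the
raw extracted segment, before detrending), SNR < 20 dB, or unalignable —
evaluated in that order, first failure recorded. Units are mmHg internally;
kPa inputs are converted at 7.50062 mmHg/kPa.

## FPCA

On a dense regular grid, FPCA is exactly weighted PCA: `fit_fpca()` takes the
SVD of the centred curve matrix with rectangle-rule quadrature weight
`dt = 0.1 s`. No smoothing is applied by default (median aggregation has
already denoised the breath; a `smoother` hook exists). Eigenfunctions are
unit-norm in L2(dt); their sign is fixed so the largest-magnitude element is
positive (eigenvectors are sign-ambiguous, and a deterministic convention
makes fits reproducible across runs and platforms). The covariance uses the
1/(n−1) normalization, so eigenvalues equal score variances; numerically zero
eigenvalues (below 1e−10 of the leading one) are dropped. The number of
retained components is the smallest K whose cumulative variance fraction
reaches 0.95.

## Clustering

Scores are clustered *unstandardized* (preserving the FPCA variance ranking)
with Hartigan–Wong k-means. Cluster-count selection follows the Monte-Carlo
AIC procedure: for each candidate k (1 … K_retained; zero clusters is
undefined for k-means, so the floor is 1), 10,000 single-start runs each
yield `AIC = WCSS + 2·m·k` (distortion plus two times the parameter count,
m = score dimensions); single starts are deliberate — the spread across
initializations is the thing being measured. The chosen k follows the tie
rule: every k whose mean AIC lies within one SD (of the minimizer's AIC
distribution) of the minimum is a candidate, and the largest candidate wins;
a strict-minimum rule is available. The final fit is the best of 100 starts.
Edge cases: `k = n` returns the zero-distortion singleton solution directly,
and failed initializations (possible with duplicated points) are re-drawn.

Clusters are then ordered into a progression by their mean PC1 score, with
the direction normalized against the ventilation-dependent reference
template: rank 1 is the cluster whose mean curve correlates best with the
shape that peaks at end-inspiration, rank K the inverted end.

## Statistics

The progression rank enters all models as a continuous variable. Per
covariate, association with cluster membership is tested by one-way ANOVA
(numeric) or Pearson chi-square without continuity correction (categorical);
no post-hoc pairwise tests and no multiple-testing adjustment are applied
across covariates (flagged in the output metadata). The exploratory
mixed-effects model (`fit_mixed_progression()`) regresses the progression on
PaO2/FiO2 ratio and pulse pressure variation with a random intercept per
animal, fitted by REML via `lme4`; fixed-effect p-values are Wald normal
approximations, singular fits are flagged rather than raised, and an optional
all-subsets maximum-likelihood AIC search (`select_fixed_effects()`) chooses
the fixed effects. `sensitivity_excluding_cluster()` re-runs the comparison
table with one cluster removed. `mechanical_power_pcv()` implements the
simplified pressure-control formula `0.098 · RR · VT · (ΔP + PEEP)` J/min.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; `run_config()` expands one
master seed into independent per-stage streams, so cohort simulation and
Monte-Carlo clustering never share a stream, and a rerun with the same
configuration is bit-identical. The validation suite exercises the pipeline
at the sizes the method targets: 84-condition factorial cohorts (7 animals ×
4 PEEP × 3 VT) for the exclusion-filter checks, 75-condition five-archetype
cohorts over 20 seeds (with the Monte-Carlo selection scaled to 1,000
iterations) for end-to-end recovery, 50 seeds for alignment-offset
calibration, and 1,000 replicates for the null calibration of the tests.
Exhaustive-enumeration and brute-force-PCA oracles back the k-means and FPCA
implementations on small instances.

## Known limitations

* The template family is phenomenological; intermediate shapes are harmonic
  mixtures, not outputs of a cardiopulmonary model.
* Only the canonical 600-point regular grid is supported (no sparse or
  irregular FPCA), and v1 assumes the nominal RR-10 grid throughout.
* The SNR definition, while self-consistent, is one of several reasonable
  choices; absolute dB values are not comparable to estimators that window or
  prewhiten differently.
* Low-PaO2 signals damped by haemoglobin O2 buffering are excluded, not
  corrected.
* With only a handful of animals the mixed-model variance components are
  noisy; the recovery tests check calibration bands, not point accuracy.
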