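---
title: "Models and methods behind chronobug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronobug}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical choices that a reader of the results should know about.

## Time, light schedules and Zeitgeber time

All analyses express time as Zeitgeber time (ZT): hours since lights-on
of the entraining light cycle, with ZT0 = lights-on. A `light_schedule`
is a piecewise light program — cyclic light:dark (LD) days, constant
darkness (DD) or light (LL), plus optional acute pulses. Two conventions
matter downstream:

* **Half-open intervals.** Every segment is `[start, end)` and a time bin
  belongs to the light state at its start, so a switch instant is never
  counted in both states.
* **ZT continuity across release.** When a constant block follows LD
  entrainment (`append_schedule()`), ZT keeps running on the 24-h dial of
  the prior cycle, so phases before and after release are comparable.

Monitor text files (tab-separated: index, date, time, status flag, one
count column per channel; 5-min bins) are read with hard validation:
non-monotone timestamps and gaps are errors that name the offending rows,
and rows whose status flag marks a reader error keep their grid position
with counts stored as missing. Missing bins are excluded from statistics
(the periodogram handles gaps natively); they are imputed as zero only
for plotting.

## The synthetic activity agent

The generator exists so that every analysis can be tested as a closed
loop against known truth. An agent's expected count per 5-min bin is

$$\lambda(t) = \max\{0,\; b\,(1 + m(t)) + A(t)\,\mathrm{bump}(c(t)) +
d_L I_{light}(t)\}$$

with counts drawn independently per bin from a Poisson law.

* `b` — baseline rate (counts/bin). Default 2, a realistic order for a
  moderately active bug in 5-min bins.
* **Clock drive.** `bump()` is a von Mises-shaped function
  $\exp(\kappa(\cos\theta - 1))$ normalized to unit peak, centred on
  `clock_peak_zt` with concentration `clock_width` (default κ = 2.5). A
  bump rather than a sinusoid confines diurnal activity to mid-day, as
  entrained insect activity typically is. The clock phase `c(t)` equals
  ZT while entrained and advances at period `tau_free` in constant
  conditions. Separate amplitudes apply while entrained
  (`clock_amplitude_ld`) and free-running (`clock_amplitude_const`),
  which is how a light-dependent genotype (diurnal in LD, arrhythmic in
  DD) is represented.
* **Masking.** A state `m(t)` jumps by `+mask_gain_dark` at every
  lights-off, by `-mask_gain_light` at every lights-on, and decays
  exponentially toward zero with time constant `mask_decay_hours`.
  Masking multiplies the baseline and the rate clamps at zero, so strong
  light suppression silences the agent rather than producing negative
  rates. With a decay constant of 1.5–2 h the post-switch transient has
  largely vanished (to $e^{-3} \approx 5\%$ of its jump) after 4.5–6 h,
  matching the several-hour transients masking-driven insects show after
  light steps. Because the transient is a superposition of decaying
  jumps, DD and LL differ only through the initial release transient for
  a masking-only agent.

Four genotype presets encode the behavioral archetypes the analyses must
distinguish — a diurnal clock-driven wild type (τ = 24.2 h, mild masking
g = 0.5); a clock-output null whose nocturnality is pure masking
(amplitude 0, g = 4, τ_m = 2 h; 75% of agents masked, 25% pure noise); a
light-driven genotype (entrained amplitude 6, constant-condition
amplitude 0); and a long-period variant (τ = 24.95 h, 45 min longer than
wild type). All preset values are simulator choices tuned to reproduce
the qualitative contrasts, not measurements. Per-animal seeds derive
from the cohort seed and animal index through a fixed affine map, so
cohorts are reproducible regardless of generation order.

The generator deliberately does **not** emulate: temperature effects,
social interaction between animals, aging or death during recordings,
non-Poisson overdispersion within bins, or gradual re-entrainment
dynamics. Passing closed-loop tests therefore demonstrates the analysis
chain's correctness under Poisson noise and the stated rate model — not
robustness to every pathology of real recordings.

## LD-cycle analyses

**Average-day profile.** The last `window_days` complete days (default 5,
or 10 for long recordings) are folded modulo 24 h; per-bin means are
smoothed with a circular Gaussian kernel, σ = 20 min, the conventional
smoothing for such profiles. The kernel is normalized on its truncated
support (±5σ), so smoothing conserves the profile sum to numerical
precision; circular convolution avoids edge bias at ZT0.

**Rhythmic-in-LD call.** An animal is rhythmic when every analyzed day
shows exactly one activity peak. Peaks are circular local maxima with
topographic prominence at least `prominence_frac` (default 0.25) of the
day's smoothed range and circular separation at least
`min_separation_hours` (default 4 h). Two smoothing scales are involved,
deliberately: profiles use the 20-min kernel, but the *single-day* traces
being peak-counted use a wider default (`day_sigma_minutes = 60`). One
day of Poisson counts is far noisier than a five-day average, and at
20 min the peak counter flags transient noise bumps (especially the small
lights-off masking blip) as second peaks on isolated days; 60 min
suppresses those while leaving genuinely bimodal patterns (peaks ≥ 4 h
apart) intact. An `averaged` mode that scores the multi-day profile
instead is available. All-zero days mark an animal `inactive`, which is
reported and excluded rather than silently classed.

**Onset and offset.** The threshold is the median of the smoothed 24-h
profile values. The onset scan starts at the profile's circular minimum
and finds the first upward threshold crossing; the offset scan starts at
the maximum and finds the first downward crossing — anchors that make
both unique on unimodal profiles. Crossings are linearly interpolated
between bins; when the profile leaves a plateau lying exactly at the
threshold, the crossing is placed at the first above-threshold bin
(step-edge rule), which reproduces the analytic answers for both square
and triangular profiles. A crossing must hold for `min_dwell_h`
(default 2 h) on its far side; without this, noise blips near the
threshold occasionally produce gross (many-hour) onset errors. The median
threshold is one reading of "reached the median value of the average
total activity"; half-of-total-activity is a plausible alternative the
package does not use, and the choice is documented here precisely because
the operational rule is a convention.

**Partitions and pulses.** Light/dark partitions average the last three
complete LD days (per-bin means within each light state); constant
conditions use the grand per-bin mean over ten days. Pulse responses
compare the pulse window with the same ZT window on the non-pulse days,
controlling for time of day rather than using the flanking hours of the
pulse day.

## Free-running analysis

The periodogram is the classical normalized Lomb-Scargle estimator: at
each test frequency, the power is the variance explained by the
least-squares sine+cosine fit to the mean-subtracted series, over twice
the total variance. The frequency grid spans periods 16–35 h (covering
the extreme mutant periods with margin) at `oversampling = 4` times the
natural resolution `1/T`. On the evenly sampled, gap-tolerant series the
estimator equals the direct least-squares fit exactly; the test suite
asserts this equivalence to 10⁻⁸.

**Significance.** Three threshold modes are provided. The closed form
$z = -\log(1 - (1-\alpha)^{1/M})$ with `M = grid size / oversampling`
treats frequencies as independent; on oversampled grids it is
anticonservative (measured ≈10% false alarms at α = 0.05), a known
property of maxima over fine grids. The default is therefore a
Monte-Carlo calibration: the null distribution of the maximum power is
simulated once per (time grid, frequency grid) configuration from white
noise and cached, giving false-alarm rates at the nominal α. A
permutation mode (shuffling the observed counts) is the slower exact
alternative.

**Classification and τ.** Significant components are counted by
iterative prewhitening: find the maximum; if significant, refine its
frequency by parabolic interpolation, regress out the fitted waveform at
the fundamental and its low harmonics, and re-test the residual.
Without prewhitening, spectral-leakage sidelobes of one strong rhythm
are misread as extra components and a cleanly rhythmic animal can be
called "complex"; removing harmonics as well prevents the second
harmonic of a non-sinusoidal waveform from leaking into the search
window's edge. Components closer than `merge_window_h = 0.5 h` merge
(grid artifacts must not create complexity). One component → `rhythmic`
with τ = its period; two or more → `complex`; none → `arrhythmic`.

## Rhythmicity and circular statistics

**JTK-style test.** For each candidate period (default {24 h}) and phase
lag (default step = the sampling interval), the data are compared with a
cosine reference ordering through Kendall's tie-corrected tau. The
per-combination one-sided p-value comes from the exact permutation null
— enumerated multiset-aware in compiled code — when the sample has at
most `exact_n_max = 10` observations, and from a seeded random
permutation null (default 10,000 draws) otherwise. The reported p is the
minimum over the grid, Bonferroni-multiplied by the number of
combinations and capped at 1. Reference orderings that are circular
shifts of each other share a permutation null, which is computed once
and cached. All-tied data return p = 1, tau = 0.

**Rayleigh and Watson's U².** The Rayleigh statistic is Z = n·ρ² with
the standard 1/n-series p-value approximation. The two-sample Watson's
U² uses the combined-ranking formulation with tie blocks evaluated once
at their midrank position; the default p-value is a seeded label
permutation (asymptotics are poor at the sample sizes typical of phase
comparisons), with the asymptotic series available for cross-checks. U²
is invariant under rotation of both samples and under swapping them.

**Grubbs' test** runs in iterative single-outlier mode against the
t-based critical value; zero-variance input returns no outliers. Routine
location tests (t, ANOVA, Kruskal-Wallis and friends) are delegated to
base R, not re-derived.

## qPCR quantification

Standard curves are least-squares lines of Cq on log₁₀ concentration;
E = 10^(−1/slope), with warnings outside sanity bounds (E > 2.2,
r² < 0.9). Relative expression uses the efficiency-corrected ratio
(target efficiency to the power of the target ΔCq over reference
efficiency to the power of the reference ΔCq, both against a calibrator
sample); the plain 2^−ΔΔCq form is an option. Technical replicates are
averaged before ratio formation (the alternative order differs only at
nonzero noise and is not exposed as a default). The ratio is invariant
to plate-wide Cq offsets when the calibrator sits on the same plate.

## Densitometry

ROIs are specified in micrometres and converted to pixels with half-open
rounding (floor of the start edge, ceiling of the end edge) — a
deterministic, testable convention; sub-pixel edges are not
interpolated. Corrected intensity is signal-ROI mean minus a nearby
background-ROI mean (conventionally 20 × 20 µm outside the stained
structures); negative corrected values are kept and flagged rather than
clamped so group statistics stay unbiased. Per-brain values average the
two hemispheres, with a flagged single-hemisphere fallback. Cell bodies
are measured under supplied masks; no automated segmentation is
attempted, mirroring manual delineation practice.

## Photoperiodic response and critical day length

A female is diapausing when she laid no eggs and dissection found
neither mature eggs nor vitellogenic oocytes. Response curves are
binomial proportions per photoperiod. The fitted model is the decreasing
logistic

$$p(L) = p_{min} + \frac{p_{max} - p_{min}}{1 + e^{s(L - L_{50})}}$$

estimated by maximum binomial likelihood (group sizes vary, so weighting
is automatic; a least-squares mode exists for cross-checks). Bounds
$p_{min} \in [0, 0.5]$, $p_{max} \in [0.5, 1]$, $s > 0$ keep the curve
identifiable and monotone on 11-point designs; optimization is
box-constrained quasi-Newton with a derivative-free fallback when line
searches stall on flat likelihoods. Starting values come from the
observed asymptotes and the interpolated 50% crossing.

The CDL is reported, by default, as the photoperiod where the *fitted
curve* crosses 50% diapause (`absolute_50`); the asymptote midpoint
`L₅₀` is the alternative (`midpoint`). The two diverge exactly for lines
that never reach complete diapause, where an absolute-50% crossing may
not exist (reported as missing) or fall outside the tested range
(flagged `extrapolated`). Uncertainty comes from a seeded nonparametric
bootstrap over individual females — binomial resampling within each
photoperiod, default B = 1000 — summarized as the bootstrap SD and a
basic (reverse-percentile) 95% interval, which calibrates better than
the raw percentile interval for this mildly skewed functional; a
delta-method SD from the likelihood Hessian is reported alongside.
Degenerate curves (all diapause or none) are flagged and given no CDL.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the statistical claims are
meaningful: 12-day constant-condition recordings at 5-min bins for τ
estimation; 16–32 animal cohorts for contrasts; 30 females × 11
photoperiods for CDL work; a few hundred replicates for error-rate and
coverage checks; permutation nulls of 1–2 thousand draws where an exact
null is infeasible. Every stochastic step takes an explicit seed, cohort
members derive their seeds reproducibly, and `run_experiment()` produces
byte-identical reports when re-run from the same config.

## Known limitations

* The Monte-Carlo significance calibration assumes the marginal noise is
  well approximated by white noise after mean subtraction; heavy
  overdispersion would need the permutation mode.
* Onset/offset are defined only for profiles with genuine structure; the
  median-crossing rule has no meaning for flat profiles and the package
  refuses them.
* The LD classifier's day-trace smoothing trades a small amount of
  sensitivity to narrow (< ~2 h) genuine secondary peaks for robustness
  to single-day noise; tune `day_sigma_minutes` down for high-count
  recordings.
* CDL estimates from curves that never cross 50% are extrapolations of a
  parametric form and are flagged as such; they inherit the model's
  assumptions.
* No multiple-testing correction is applied across genes or experiments;
  analyses are per-gene/per-cohort as in the underlying workflows.
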