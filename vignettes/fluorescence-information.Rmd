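---
title: "Measuring spatial information in spikes and fluorescence: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial information in spikes and fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorinfo)
```

## The problem

Spatial information metrics of the Skaggs family estimate, from a
neuron's spatial rate map, how much a single action potential (bits/AP)
or a second of activity (bits/s) tells an observer about an animal's
position.  With two-photon calcium imaging, what is recorded is not
spikes but a slow, asymmetric fluorescence impulse response to each
spike, plus noise.  Applying the spike-born metrics directly to dF/F
traces changes their meaning: the bits/s form inherits an unknown
dF/F-per-Hz scale factor, and the bits/AP form is biased by the
temporal smearing of the indicator.  `fluorinfo` quantifies these
effects with a fully simulated pipeline in which the ground-truth
information of every neuron is known exactly.

## Ground-truth rate maps

A neuron's normalized spatial profile $p(x) = \lambda/\bar\lambda(x)$ on
the unit-normalized track carries

$$I_{AP} = \int_0^1 p(x)\,\log_2 p(x)\,dx \quad \text{bits/AP},$$

with $p \log_2 p := 0$ at $p = 0$.  The per-second form is
$I_s = \bar\lambda\, I_{AP}$.  Profiles are exponentiated natural cubic
splines through five nodes (two anchored at the track ends), normalized
by a composite-trapezoid integral on a fixed 10,001-point grid.  The
same grid defines the ground-truth integral, so truth and construction
share one deterministic quadrature; the Monte-Carlo oracle in the test
suite confirms the quadrature to within sampling error.

**Hitting an information target.**  Rather than running a generic
simplex over all eight free node coordinates, `optimize_ratemap()`
draws a random spline $s(x)$ and solves a one-dimensional root-find on
a gain $\beta$ applied to the node log-rates.  For
$p_\beta \propto e^{\beta s}$ the information satisfies
$dI/d\beta = \beta\,\mathrm{Var}_{p_\beta}(s) \ge 0$, so $I(\beta)$ is
strictly increasing and any target in $[0, 6]$ bits/AP is bracketed and
solved to ~1e-10 bits/AP in a handful of profile evaluations, orders of
magnitude tighter than the 1.5e-7 mean-absolute-error budget the
framework demands.  Degenerate draws (nearly flat splines, nearly
coincident interior nodes) are rejected and redrawn, up to a retry
budget.  Evaluation is carried out in the log domain so that large
gains (sharp, high-information maps) never overflow.

**Target sampling.**  Half the draws target the per-AP domain
($I_{AP} \sim U[0,6]$, $\bar\lambda \sim U[0.1,30]$ Hz) and half the
per-second domain ($I_{AP} \sim U[0,6]$, $I_s \sim U[0,24]$ bits/s);
draws violating any of the three bounds are rejected and repeated.  The
50/50 domain split is a package choice: the published distribution of a
comparable library constrains but does not fix it.

Gaussian maps (`gaussian_ratemap()`) set
$\sigma = \exp\{\frac12(-1 - 2I\ln 2 - \ln 2\pi)\}$ in closed form.
Below ~0.3 bits/AP the bump is wide enough that truncation at the track
ends moves its raw integral by more than 1%; such maps carry a warning
flag rather than an error, since the profile is renormalized after
truncation.

## Synthetic behavior

The generator emulates head-fixed running on a 3-m virtual track with
an end-of-track reward and teleportation to the start after a 1.5-s
delay.  Within-lap speed follows an Ornstein--Uhlenbeck process (mean
22 cm/s, SD 4 cm/s, time constant 2 s, clipped at zero) with
Poisson-arriving pauses (2 per minute, exponential mean 2 s).  These
defaults were fixed once to jointly reproduce the session statistics
the simulations emulate: ~19 cm/s overall track velocity including
stops, and ~4 laps per minute (~120 laps in a 30-minute session).
Sessions for the library are drawn uniformly between 3 and 60 minutes.

The generator matches first-order statistics only.  It does not model
reward anticipation (deceleration into the reward zone), lap-to-lap
speed correlations, or licking-related stillness structure, so the
occupancy maps are more homogeneous than real ones; undersampling
biases at very low rates and lap counts are therefore, if anything,
slightly milder here than in real recordings.

Speed is computed as a centered finite difference with the samples
adjacent to teleports masked, so lap boundaries never contribute
±3 m/sample artifacts to run-period detection.

## Spikes and fluorescence

The conditional intensity function evaluates the profile at the
animal's position at 1 kHz and is rescaled so its session average
equals the neuron's mean rate exactly; per-millisecond counts are
Poisson, spikes sit at bin centers, and frames are half-open 1/30-s
intervals so frame binning conserves every spike.

The single-AP kernel is a peak-normalized double exponential
$g(t) \propto e^{-at} - e^{-bt}$ whose rate constants are fitted so the
kernel peaks at the rise time and decays to 50% a half-fall time later.
Its width is the half-amplitude cutoff period of the mean-normalized
kernel viewed as a low-pass filter,
$\omega^2 = (-a^2-b^2+\sqrt{a^4+14a^2b^2+b^4})/2$.  The conventional
"-3 dB" label would place the cutoff at half *power*
($|H|^2 = 1/2$); it is the half-*amplitude* convention that reproduces
the tabulated indicator widths (gCaMP6s 2.54 s, iGluSnfR-A184S 0.52 s),
so that is the convention implemented, and the discrepancy between the
label and the formula is noted here rather than resolved.

Convolution is performed exactly at the 1 kHz simulation rate as the
difference of two first-order recursive filters (one per exponential),
sampled at frame centers; this has no kernel-truncation error and
preserves the sub-frame rise dynamics of fast indicators.  A
frame-level convolution path (`at = "frames"`) exists for comparison.
White Gaussian noise (SD 0.15 dF/F) is added at the frame rate.  The
optional saturating summation nonlinearity
$x \mapsto \mathrm{sign}(x)\,6.264/(1 + e^{-3.251\log_{10}|x|})$ is
applied element-wise after synthesis.

## Estimators

All rate-map estimators work from 60-bin occupancy/activity maps (5-cm
bins).  Numerical conventions:

* Bins never visited are excluded and occupancy is renormalized over
  occupied bins.
* Fluorescence bin means that come out negative (possible with additive
  noise) are floored to zero and contribute nothing to the sums,
  preserving the $x\log x \to 0$ limit; the overall mean is recomputed
  from the floored map so the weighted-mean identity holds.
* The binned plug-in estimator uses 10 activity bins (equal-width or
  equal-count; quantile edges are right-closed with ties to the lower
  bin) against the 60 position bins, and reports bits per sample scaled
  by the 30 Hz frame rate to bits/s.  The k-nearest-neighbor (KSG,
  algorithm 2) estimator uses k = 5 with a seeded 1e-10-range jitter to
  break duplicates, and the same per-sample-to-per-second convention.
  That scaling convention is a package choice -- time samples are the
  natural unit of both estimators -- and absolute bits/s magnitudes
  from them should be read as convention-dependent.

**Which frames enter the maps.**  The ground truth is defined with the
intensity function normalized over the *entire* session, so the library
experiments estimate occupancy and activity from all frames by default;
this is the convention under which spike-based estimates recover the
truth with near-unit slope.  Restricting the maps to run periods
(`use_run_mask = TRUE`) decouples the run-period mean rate from the
session mean whenever the neuron's field overlaps the places where the
animal stands still, and correspondingly inflates the scatter of the
bits/s estimates; the run-period convention remains the right one for
real recordings, where no session-normalized ground truth exists, and
is what the place-field and decoding analyses use.

## Library experiments

`run_library()` draws targets, optimizes maps, synthesizes behavior,
spikes and fluorescence, and computes all estimators per neuron, with
per-neuron seeds derived from the master seed so any execution order
reproduces the same table.  Error summaries report native-unit and
percent errors (percent errors against the truth in the truth column's
units, with zero-truth rows excluded from percent statistics only), an
ordinary least-squares fit, a saturating-exponential fit
$y = A(1 - e^{-x/B})$, and a Gaussian-residual likelihood-ratio test
with one degree of freedom between the two.

The standard problem sizes are 1000 neurons for the main library and
500 traces for the kernel-height sweep -- large enough that the
headline statistics (fit slopes, mean percent errors) are stable to a
few percent, small enough to run on a laptop in minutes.  At these
sizes the expected behavior is: spike bits/s and bits/AP slopes a few
percent below unity (finite bins and finite sessions), fluorescence
bits/s rescaled by a scale factor near the kernel integral times its
height (~0.04 dF/F per Hz for GCaMP6f), fluorescence bits/AP biased a
few percent low overall with the bias concentrated above ~3 bits/AP,
and a height-sweep intercept at -100%: a zero-height kernel carries no
signal, and pure noise yields (after the zero-floor) an estimate near
zero, i.e. an error of -100%.

## Transients, place fields, decoding

Significant-transient detection classifies excursions beyond 2 sigma by
peak amplitude (0.5-sigma classes) and duration (frame classes) and
accepts a class when the cumulative ratio of negative-going to
positive-going events at or above it falls below the target false
positive rate (1e-4).  Negative excursions cannot be real transients,
so they estimate each class's false-positive rate; the class
granularity is a package choice, since the cited thresholding approach
does not fix it.  Traces too short or too quiet to populate the
negative-event histogram fall back, with a warning, to an analytic
Gaussian-null amplitude threshold at the same target false-positive
rate; all-zero traces return an empty mask.

Place fields are contiguous bins of the boxcar-smoothed significant-
transient map exceeding the per-bin 99th percentile of 1000 surrogate
maps, retained at 20--120 cm width.  Surrogates permute transient event
order and re-place each event at a uniformly random interval within the
run-period frames, preserving event count and durations; the precise
surrogate scheme in the literature is underspecified, and this choice
is the simplest that preserves both.

The Bayesian decoder works on 0.1-s windows of per-neuron significant-
frame counts, with per-neuron rate maps fitted on the first 80% of the
session and a small rate floor (1e-3 Hz) keeping log-likelihoods
finite; windows with no finite likelihood anywhere fall back to the
occupancy-prior argmax and are flagged.  Decoding error is the absolute
decoded-vs-true distance as a percentage of the track, without
wraparound.  On synthetic populations the qualitative orderings hold:
error decreases with population size, and higher-information quantiles
decode better — the package demonstrates these properties at synthetic
scale only and makes no claim about reproducing real-hippocampus
numbers, which would require the original imaging data.

## Known limitations

* The behavior generator reproduces first-order session statistics,
  not the full temporal structure of rodent running.
* Ground truth is Poisson by construction; bursting, refractoriness and
  neural hysteresis are out of scope.
* The fluorescence model is a linear kernel sum (plus an optional
  static nonlinearity); photobleaching, baseline drift and
  calcium-buffer dynamics are not modeled.
* Deconvolution-based spike inference is intentionally excluded; the
  estimators operate on raw dF/F.

## A minimal end-to-end example

```{r example, eval = FALSE}
map <- optimize_ratemap(2, mean_rate = 1, seed = 1)
trace <- synth_behavior(600, seed = 2)
cif <- build_cif(map, trace)
train <- generate_spikes(cif, seed = 3)
frames <- bin_to_frames(train)
dff <- synth_fluorescence(train, preset_kernel("gCaMP6f"), seed = 4)

maps_spk <- spatial_maps(frames, trace)
maps_flu <- spatial_maps(dff, trace)
smgm_bits_per_ap(maps_spk)   # close to the 2 bits/AP ground truth
smgm_bits_per_ap(maps_flu)   # slightly biased low by kernel smoothing
```
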