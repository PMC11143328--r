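---
title: "calciumRF: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{calciumRF: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciumRF)
```

calciumRF quantifies receptive-field plasticity of cerebellar Purkinje
cell dendrites from two-photon calcium imaging: how often and how strongly
a dendrite responds to a parallel-fibre or tactile stimulus, how those
responses change after a tetanisation protocol, and how the change is
distributed in space along the dendritic cross-section. This vignette is
the package's own account of the underlying models, the parameters that
matter, and the places where a design decision had to be made.

## The measurement model

The raw signal is a fluorescence time series per region of interest
(ROI), reduced to ΔF/F = (Fₜ − F₀)/F₀ with F₀ the 20th percentile of the
ROI's concatenated session trace. The percentile baseline assumes the
cell is inactive at least ~20% of the time; it is robust to events but
not to monotone drift (no bleaching correction is applied — a stated
non-goal). Percentiles use linear interpolation between order statistics
(R's default type 7), a convention `compute_dff()` documents because
"20th percentile" alone does not pin down a definition.

Before detection, traces are smoothed by a five-frame centred moving
mean. At the boundaries the window shrinks to the available frames, so
trace length is preserved without inventing data. Smoothing never
increases the global maximum (a tested invariant).

Calcium events are local maxima with height ≥ 0.09 ΔF/F **and**
topographic prominence ≥ 0.09 ΔF/F — about one SD of the pre-stimulus
baseline at the recording conditions this pipeline targets. Prominence is
computed by walking from the peak towards strictly higher ground (or the
trace end) on each side and taking the higher of the two saddle minima.
Plateau maxima are attributed to their earliest frame; trace endpoints
are never peaks. `detect_events()` is verified sample-for-sample against
an exhaustive brute-force scan in the test suite.

A trial is *responsive* when a detected peak lies in the half-open
response window [stim, stim + 200 ms). The 200 ms window covers the 70 ms
parallel-fibre test train (eight pulses at 100 Hz: `stim_train_span(8,
100)` = 0.07 s) and leaves time for the calcium response to build.
Half-open intervals are used everywhere, so a peak exactly at
stim + 200 ms is outside. Two amplitude conventions coexist, matching the
two experimental settings:

* `peak_amplitude` — the detected peak ΔF/F, averaged over responsive
  trials only (electrical PF and climbing-fibre analyses). When several
  peaks fall inside one window, the largest is taken: the evoked response
  dominates overlapping spontaneous activity, and taking the first peak
  instead lets a small spontaneous event shadow the response.
* `max_in_window` — the maximum ΔF/F inside the window regardless of
  detection, averaged over all trials (tactile and compartment analyses,
  where slow low-amplitude responses defeat the detection criteria).

Amplitudes of individual trials are averaged — never the peak of a
trial-averaged trace, which would confound amplitude with jitter.

Event amplitude is the ΔF/F value *at the peak sample*, with no local
baseline re-referencing. This choice (detection operates on ΔF/F
directly) has a measurable consequence: when spontaneous events are
frequent relative to the indicator decay, their overlapping tails form a
standing pedestal under every peak. At the default 1.1 Hz spontaneous
rate and 400 ms decay the pedestal is ≈ 0.6 ΔF/F, and because it adds to
both pre- and post-tetanus amplitudes it attenuates normalized
potentiation ratios toward 1 (by ~9% for a true gain of 1.5). The
parameter-recovery analyses therefore isolate measurement noise (evoked
events plus Gaussian noise); the attenuation under heavy spontaneous
background is a property of the amplitude convention, not an estimator
bug.

## The spontaneous null

Spontaneous activity is summarised by the shuffled-window probability:
200 ms windows drawn uniformly (with replacement) from −4.5 to −0.5 s
before the stimulus, scored by whether they contain a detected peak. For
Poisson events at rate λ the expected probability is 1 − exp(−0.2 λ);
at λ = 1.1 Hz that is 1 − exp(−0.22) ≈ 0.197, and the linear conversion
rate = P / 0.2 s maps the window probabilities 0.22 / 0.25 / 0.37 to
1.1 / 1.25 / 1.85 Hz.

Two resolution caveats, both visible in the tests: (i) the five-frame
moving mean at 31 Hz spans 161 ms and merges event pairs closer than
that, biasing the detected window probability a few points low — the
Poisson calibration is therefore run on unsmoothed traces with low noise;
(ii) the 0.09 threshold is ~4 SD of *smoothed* default noise but only
~1.8 SD of raw noise, so detection on unsmoothed data assumes noise SD
below ~0.03 ΔF/F. Users trade temporal resolution against noise rejection
when choosing whether to smooth before `shuffled_null()`.

## Plasticity quantification

Per-cell probability and amplitude are computed for the pre-, early
post- and late post-tetanus blocks and divided by the pre-tetanus values
(`normalize_to_baseline()`); cells with zero pre-tetanus responses are
excluded from normalized analyses and routed to the weak-responder
pathway (`weak_responder_filter()`, strict bound at 2 × 0.9 = 1.8 ΔF/F).

Stimulus-intensity dependence uses the Pearson correlation of the five
condition points (spontaneous + four ascending intensities) against
condition rank 0–4. Ranks, not physical intensities, keep current (µA)
and pressure (psi) designs comparable; Pearson r is invariant to affine
rescaling of the responses, so raw and normalised data give identical
labels. A cell is *dependent* when r > 0.5 with the correlation-test p
below the cutoff. The conventional 0.05 is the default; the permissive
0.5 that appears in the original classification rule is available as an
argument rather than silently "corrected" — with five points, p < 0.5
corresponds roughly to |r| > 0.35, so the r threshold dominates either
way.

## The spatial statistic

A linescan profile assigns each pixel along the dendritic cross-section
(15 µm spacing, the reslice output thickness of a Purkinje cell
cross-section) the trial-averaged maximum ΔF/F in the response window.
Pre and post profiles are normalised by the *pre-tetanus* maximum, so the
pre maximum is 1 by construction and potentiation can exceed 1.

The cumulative length CL(f) is the total dendritic length (pixel count ×
pixel spacing) at or above normalised level f — pixels are counted
irrespective of position, so a fragmented response and a contiguous one
of equal area are equivalent. Δlength(f) = CL_post(f) − CL_pre(f):
expansion of the responsive area is positive. (The opposite orientation
appears in one figure legend of the source literature; it is available
via `delta_length(sign = "pre_minus_post")`, with post − pre as the
default.) The level grid runs from 0 to the larger normalised maximum in
steps of 0.01.

Band summaries average Δlength over the hotspot band (levels strictly
above 0.9) and the off-hotspot band (0.3–0.67). A local-only cell shows
positive hotspot Δlength with an off-hotspot mean at zero; a global-only
cell shows positive off-hotspot Δlength; a control cell shows both near
zero. Cells responding across the whole cross-section cannot be split
into the two regions and are excluded when more than 90% of pixels exceed
the 0.9 level (`exclude_global_responders()`; the coverage cutoff is a
package choice, the source rule being qualitative).

One numerical caveat: at levels crossing a flat baseline, CL is
ill-conditioned — many pixels are tied at the baseline value and any
noise flips them across the level. Tolerances for "no spurious
expansion" are therefore stated for levels ≥ 0.3, the analysis range,
where at most the pixels within ~3 noise SD of the level can flip.

## Motion correction

Whole-frame rigid registration: each frame's integer (dy, dx) shift is
the argmax of its circular cross-correlation with a reference image
(means removed, FFT-accelerated). Sub-pixel interpolation and non-rigid
warps are out of scope. The reference defaults to the mean of a chosen
frame set (use the first trial's frames for a baseline-anchored
reference). Zero-variance frames carry no signal and are left unshifted
with an `NA` score. On noise-free fixtures the round trip through
`generate_movie()` is exact; at noise of 10% of the dynamic range shifts
are recovered within 1 pixel (both tested).

## The synthetic-session generator

The generator reproduces the *statistical* structure of the study's
sessions, and is itself first-class, tested code:

* Trials of 10 s at 31 Hz with the stimulus at 5 s (electrical PF
  protocol) or 20 s at 62 Hz with the stimulus at 10 s (tactile,
  `tactile_config()`); 12 trials per block (the upper end of the 10–12
  used in vivo).
* Spontaneous events: homogeneous Poisson at 1.1 Hz, amplitudes
  ~N(1.0, 0.3) truncated at 0.2 ΔF/F.
* Evoked events: at most one Bernoulli draw per trial (matching the
  per-trial responsive/non-responsive dichotomy), probability rising
  0.25 → 0.37 and amplitude rising linearly across the four intensities.
  The per-intensity amplitudes (1.0–1.45 ΔF/F PF, 0.9–1.2 tactile) are
  stand-ins consistent with the linear intensity dependence; no printed
  table fixes them.
* Kernel: unit-peak difference of exponentials, 50 ms rise / 400 ms
  decay (GCaMP6f-like; configurable — the source reports no kernel).
  Evoked latency 30 ms with 10 ms Gaussian jitter, also stand-ins
  flagged as configurable.
* Plasticity regimes as multiplicative gains (`regime_spec()`):
  wild-type-like `both` (hotspot 1.5, off-hotspot 1.3, probability 1.2),
  `local_only` (1.5 / 1.0 / 1.1), `global_only` (1.1 / 1.3 / 1.2),
  `control` (all 1). The dendritic-ROI amplitude gain of a session is the
  hotspot gain, since the ROI response is dominated by the hotspot. Both
  post-tetanus blocks use the same gains; the decay of potentiation
  between early and late blocks is not modelled.
* Linescan pairs: flat baseline (0.2) plus a Gaussian bump peaking at
  1.0; hotspot membership follows the same > 0.9 × max rule the analysis
  uses, so gain recovery is exact at zero noise.
* Reproducibility: each session draws from a stream keyed by
  (seed, session index); a fixed seed gives bit-identical output. When
  running many cells, stride per-cell seeds by ≥ 10 — the three session
  streams of one experiment occupy seed + 0/1/2.

What the generator does **not** emulate — and hence what passing
recovery tests do not show about real data: dendritic morphology and
optics (no point-spread function, no neuropil contamination), bleaching
and slow drift, motion during trials (motion is simulated only as whole-
frame shifts between frames), climbing-fibre events, inhomogeneous or
bursty spontaneous activity, and trial-to-trial evoked amplitude
variability beyond latency jitter and noise.

## Statistical battery

Standard tests are delegated to base R and car: `aov`/`lm` +
`TukeyHSD` (Tukey–Kramer for unbalanced groups), `kruskal.test`
(midrank tie correction), `cor.test`. Two-way ANOVA reports Type II sums
of squares by default — well defined for the unbalanced cell counts
typical of by-cell physiological data; Type I/III are selectable. The
repeated-measures variant uses the balanced within-subject error
partition and rejects unbalanced designs outright rather than silently
approximating them. The Dunn–Šidák post hoc (pairwise rank z tests with
Šidák adjustment `1 − (1 − p)^m`) is implemented in the package, as no
installed library provides it; its two-group case is verified against the
closed-form Wilcoxon rank-sum z. Identities tested: F = t² for two
groups, H = 0 on identical groups, invariance to group order and (for H)
to monotone transforms, and agreement of analytic p with a permutation
oracle on small fixtures.

## Problem sizes

The validation studies run at desk scale, chosen to give tight
Monte-Carlo bounds while remaining quick: 10,000 sampled windows and
10,000 trials for the Poisson calibrations, 1,000 random traces/profiles
for the oracle-equivalence sweeps, 50 synthetic cells per regime for the
gain-recovery and spatial-signature studies, and 64 × 64 images for
registration. The full suite runs in about a minute.

## Known limitations

* Integer-pixel registration only; real drift has sub-pixel components.
* The detection threshold pair (0.09/0.09) is a fixed default, not
  estimated per recording; recordings with different baseline noise need
  a rescaled threshold.
* The relation between the 0.09 detection threshold and the 0.9
  "inclusion criterion" used for responder classification is kept as two
  independent parameters.
* Linescan profiles are treated as given 1-D arrays; resampling an
  arbitrary polyline across a 2-D field of view at 15 µm spacing is
  supported only insofar as the profile is extracted per pixel row
  (`extract_profile()`); no dendrite reconstruction is attempted.
* Event amplitudes are peak-sample ΔF/F; under heavy spontaneous
  background this attenuates normalized plasticity ratios (see above).
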