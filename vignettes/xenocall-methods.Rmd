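---
title: "Methods: disc kinematics, sound coupling and call dyads in xenocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disc kinematics, sound coupling and call dyads in xenocall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Male clawed frogs (*Xenopus*) call underwater without moving air. Each sound
pulse is produced in the larynx when the paired arytenoid discs — held
together at rest by a capillary liquid bridge — are pulled apart by a
bipennate muscle contraction. Two quantitative analyses establish how this
works and what shapes the sound:

1. **Mechanism (ex vivo)**: track the discs in high-speed video, derive the
   gap-width kinematics, detect the sound onset of every evoked pulse, and
   relate pulse amplitude and timing to peak disc velocity and acceleration.
   Millipascal pulse amplitudes and millisecond onset scales, together with
   a velocity threshold and a linear amplitude–velocity relation, support
   mechanical excitation of laryngeal resonances and exclude cavitation
   (whose collapse transients are ~50–100 kPa and ~1 µs).
2. **Dyads (in vivo calls)**: each advertisement-call pulse carries two
   simultaneous dominant frequencies, DF1 < DF2. Their ratio DF2/DF1 is
   conserved within each *Xenopus* clade (~4:3 in clade A, ~5:4–6:5 in
   clade L, ~2:1 in clade M) even though the individual frequencies overlap
   across species.

No raw recordings are distributed with this package; a synthetic-data
module generates video, audio and paired experiments with closed-form
ground truth so that every stage of both pipelines is testable end to end.

## The synthetic-data generator

### Disc motion

Per stimulus the gap width follows a logistic opening
`w(t) = s_i · L · σ(k (t − t0))` and a slower logistic closure
(rate `k_c ≪ k`, delayed by `hold_s`), where `L = gap_max_um` and `k =
steepness`. The logistic was chosen because it is smooth, has analytic
derivatives, and needs only two parameters; published waveforms are shown
but not parameterised. Closed forms anchor the ground truth:

* peak opening velocity `v_peak = L k / 4`, at the midpoint `t0`;
* peak opening acceleration `a_peak = L k² / (6√3)`, at
  `t0 − 1.317/k`; peak deceleration mirrors it at `t0 + 1.317/k`.

Defaults are `L = 29.38 µm`, `k = 6847 s⁻¹`, reproducing the reported mean
regime `v_peak = 50.3 mm/s` and `a_peak = 13.5 g` (1 g = 9.82 m/s²). A
two-parameter logistic cannot simultaneously also reproduce the reported
0.57 ms acceleration-to-deceleration interval (it implies 0.385 ms) or the
72.6 µm mean maximum gap; we prioritised the velocity and acceleration
peaks because the coupling analysis regresses on them. Tests therefore
assert the analytic logistic relations, not that irreproducible
combination.

Facilitation at the weak laryngeal neuromuscular synapse is modelled as a
multiplicative ramp on the per-stimulus amplitude,
`s_i = 1 − exp(−i / facil_tau)` with lognormal jitter (10 % SD). With
`facil_tau = 1.2` the first stimulus emits nothing, the second barely
crosses the emission threshold but stays below the 0.01 Pa detection
threshold, and the first *detectable* pulse falls on stimulus 3 — the
behaviour reported for 40 Hz trains. Resting bead jitter is 0.05 µm SD,
a small value representing residual tremor of a pinned preparation.

### Sound pulses

A stimulus whose `v_peak` exceeds the velocity threshold (default
`210.5 / 5.2 = 40.5 mm/s`, the x-intercept of the published amplitude
regression) emits a damped two-tone pulse (defaults DF1 = 1879 Hz,
DF2 = 2154 Hz, decay 600 s⁻¹) preceded by a 1.5 ms broadband attack
(0.5–8 kHz noise burst at half the tonal peak), starting 0.51 ms after the
instant of peak velocity. The peak-to-peak amplitude follows
`min(5.2 · v_peak − 210.5, 180)` mPa. Amplitudes are calibrated on the
1–4 kHz band-passed waveform, since received levels are measured on the
filtered trace; this keeps the measured ptp within filter ripple (<2 %) of
its ground truth. Background noise is Gaussian (2 mPa SD), placing the
3×SD noise floor (~7 mPa) below the 0.01 Pa onset threshold, as in the
reported recordings. The microphone distance is a free configuration value
(default 23 mm, mid-range of the stated 22–24 mm placement); the package
does not attempt to reconcile it with the 44 mm reference distance quoted
for the maximum received level.

### Advertisement calls

A call is a biphasic train — fast trill then slow trill (defaults 60 and
30 pulses/s, 60 + 30 pulses) — of pulses, each a broadband attack followed
by a sustained two-tone dyad (default duration 8 ms, decay 250 s⁻¹).
Setting the second component's amplitude to zero emulates the single-band
outcome observed after puncturing the elastic-cartilage septa.

### What the generator does and does not emulate

It reproduces the *structure* of the study's data: subpixel disc motion
under facilitation, threshold-gated pulses whose amplitude is linear in
peak velocity with saturation, onset lags, dyadic spectra, trill timing.
It does not emulate optical artefacts (glare, defocus, rolling shutter),
reverberation in the recording chamber, non-Gaussian sensor noise, or
inter-individual variability of laryngeal anatomy. Passing tests therefore
show that the estimators are correct and well-conditioned at realistic
noise levels, not that they are robust to every artefact of real video or
audio.

## Tracking

Markers are tracked by normalized (zero-mean) cross-correlation of a
template patch against a search window around the previous position, with
the integer argmax refined per axis by a quadratic fit through the 3×3 peak
neighbourhood. The quadratic refinement was validated against an
independent oracle — the argmax of the cross-correlation evaluated on a
20×-refined shift grid via bilinear image interpolation — and agrees within
0.05 px, with ~0.002 px bias on noiseless Gaussian spots. The template may
be averaged over several rest frames to reduce template noise; the bead's
subpixel offset inside the template (thresholded darkness centroid) is
stored so positions are absolute rather than relative to the integer patch
centre. Frames whose peak score falls below 0.5 are flagged, linearly
interpolated, and reported with a warning — never silently.

Gap width is the summed displacement of the two markers from their rest
positions, projected perpendicular to the laryngeal midline (a
user-specified image axis; the rest baseline comes from a required
pre-stimulus interval). This follows the stated definition — summed
perpendicular displacement, zero at rest — rather than raw bead
separation.

## Differentiation and peak extraction

Velocity and acceleration come from central finite differences after
Savitzky–Golay smoothing (order 2); the velocity is smoothed again with the
same window before the second differentiation because double
differentiation of raw tracking jitter would otherwise dominate the
acceleration. The window is the analysis parameter that matters most:

* too short, and jitter-driven acceleration noise inflates per-window
  maxima (at 40 kfps a 0.05 µm jitter yields ~3 g of acceleration noise
  with a 5-frame window);
* too long, and the sharp logistic transient is attenuated.

A 13-frame window was calibrated on synthetic ground truth: it keeps both
the attenuation and the noise inflation of `a_peak` within a few percent at
both study regimes (k = 6847 s⁻¹ at 40 kfps and k = 2000 s⁻¹ at 10 kfps —
in both cases the frame interval is ≈ 1/(6k), so the same window in frames
suits both). The package default remains 5 frames, appropriate for gentler
motion; both pipelines in `analysis/` pass `smooth_window = 13` explicitly.

The mechanism experiments are sampled at 40,000 fps, inside the study's
10,000–44,000 fps imaging range: the default steepness violates the
resolvability precondition `frame_rate ≥ 20 k / 2π` (≈ 21,800 fps) at
10 kfps, so the camera's upper range is the appropriate setting for the
sharp default transient. Rendered-video tracking is validated at 10 kfps
with the gentler k = 2000 s⁻¹ motion.

Acceleration extrema are searched only where the opening velocity exceeds
20 % of its within-window peak: for a smooth opening both extrema lie well
inside that region (they occur where v = 2/3 · v_peak), while outside it
double-differentiated jitter produces spurious extrema.

## Acoustics

The sound trace is band-passed 1–4 kHz with a 3rd-order Butterworth filter
applied forward–backward (`filtfilt`, zero phase), the noise floor is 3×
the SD of a 67 ms pre-stimulus background, and the onset in each
half-open stimulus window is the first sample with |p| > 0.01 Pa. The fixed
threshold (rather than the noise floor) reflects that reverberant energy
need not dissipate between stimuli; the threshold is applied to the
*filtered* trace, which is defined in the same processing step as the
filter. Rectification (|p|) makes detection invariant to polarity, which
tests assert. Time-of-flight correction subtracts `distance / c` with
c = 343 m/s by default (microphone in air above the dish); the speed is
configurable for submerged sensors. Hydrophone and laser channels share
the same pipeline.

## Coupling

Kinematic and sound events are outer-joined on stimulus index; lags are
reported in ms. Pulse amplitude (mPa) is regressed by ordinary least
squares on peak velocity (mm/s) or peak acceleration (g) over sounded
events only, and the motion threshold is the regression x-intercept
(−intercept/slope), with the smallest sounded predictor value reported as a
secondary statistic. OLS is unweighted; no weighting scheme is stated for
the original analysis. Per-individual versus pooled regression is left to
the caller (the reported 28 ± 12 mm/s minimal velocity is consistent with
averaging per-individual x-intercepts); the package regresses whatever
event set it is given.

The cavitation diagnostic compares the maximum observed peak-to-peak
pressure against the 50–100 kPa collapse reference and the pulse duration
against the ~1 µs transient reference, flagging inconsistency at a 10³-fold
discrepancy per axis. With paper-scale inputs (≤180 mPa, ms pulses) both
axes fail by ≥10³, excluding cavitation.

## Dyads

Pulses are located on the smoothed magnitude envelope of the analytic
signal (FFT Hilbert transform); sub-threshold gaps shorter than 3 ms are
bridged so the beat minima of a two-tone pulse do not split it, and onsets
are refined on the unsmoothed envelope. The first 2 ms of each pulse (the
broadband attack) is excluded from analysis; the exclusion length is
configurable since no value is stated.

Spectra are Hann-windowed, zero-padded (4×) magnitude-squared FFTs; a
rectangular window is available for fully decayed transients, whose
Lorentzian shape the taper would otherwise distort. Dominant frequencies
are the two most prominent peaks (topographic prominence ≥ 6 dB, at least
15 dB above the median spectrum level, ≥ 100 Hz apart, and within 20 dB of
the strongest peak — the last criterion rejects window sidelobes in
near-noiseless spectra), refined by parabolic interpolation. One
qualifying peak yields a single-band measurement (the punctured-septa
outcome); three or more comparable peaks raise a harmonic-stack flag and
are not classified. Q is peak frequency over the −6 dB bandwidth, with
crossings linearly interpolated between bins; this follows the Methods
formula — the table caption's inverted wording (bandwidth divided by peak)
contradicts the printed Q values of 10–34 and is not used.

### Interval classification

The published rule assigns a musical interval when DF2/DF1 falls "within
0.02" of a small-integer ratio (2:1 Octave, 3:2 Perfect 5th, 4:3 Perfect
4th, 5:4 Major Third, 6:5 Minor Third). Read as an absolute band, the rule
contradicts the published table itself: *X. muelleri* (ratio 2.04) is
labelled Octave although |2.04 − 2| = 0.04. We therefore classify by
proportional deviation, `|ratio/candidate − 1| ≤ 0.02`, which reproduces
all 19 published ratio→interval pairs, including both Non-consonant
exceptions, and is uniform across the candidate range (an absolute band
would be 1.7 % of a minor third but only 1 % of an octave). Classification
is applied to the two-decimal rounded ratio, the published precision.
Ratios within tolerance of 1.0 are outside the candidate set and labelled
Non-consonant.

### Clade bands

The species table ships with a clade column (A/L/M) and an `in_band` flag.
The published clade means (A = 1.33, L = 1.23, M = 2.02) are reproduced
exactly only when, besides the harmonic-stack species (*X. allofraseri*)
and the two stated ratio exceptions (*X. wittei*, *X. laevis* South
Africa), *X. largeni* (1.49) is also excluded from the A band; its Perfect
5th dyad is an outlier under any assignment. The membership is plain,
editable data, not code.

Species summaries are means of per-male means (then SE over males), so
unbalanced call counts do not bias the species value.

## Numerical choices and degenerate inputs

* Quadratic peak refinement is clamped to ±0.5 bin/px and skipped when the
  curvature is non-negative.
* Stimulus windows are half-open `[onset_i, onset_{i+1})`; the last runs to
  the end of the recording.
* A kinematic window with < 0.5 µm of motion yields a zero event flagged
  `flat` rather than noise-driven peaks.
* A non-positive regression slope leaves the motion threshold undefined and
  flagged, never silently extrapolated.
* Segments shorter than 64 samples after attack exclusion are dropped;
  −6 dB points that are not bracketed leave Q as `NA` with a warning.
* WAV output defaults to float32 so millipascal pressures are stored
  verbatim; PCM16 output records its full-scale pressure in a sidecar.

## Problem sizes

The test-suite and analysis runs use: 3-stimulus rendered stacks of ~950
frames (48 × 98 px) at 10 kfps for tracking validation; 40-stimulus
trajectory + 30 kHz audio experiments at 40 kfps for mechanism recovery
(rendering 40 k frames is unnecessary for that purpose — tracking accuracy
is established separately); 200 event-level replicates for threshold
recovery; and 0.5 s single-pulse calls at 44.1 kHz for each of the 19
species dyads. These sizes give Monte-Carlo error comfortably below the
tolerances asserted.

## Known limitations

* The logistic gap profile cannot reproduce every reported kinematic
  moment simultaneously (see above); recovery tests target the generator's
  own ground truth, as the in vivo raw recordings are unpublished.
* Tracking assumes translation only — no rotation, scale change, or
  multi-target association; beads are rendered as Gaussians, whereas real
  carbon spheres are opaque with unspecified contrast profiles.
* Pulse segmentation assumes the trace is quiet for at least ~5 % of its
  duration when auto-thresholding.
* Dyad resolution within a single pulse is limited by the pulse length
  (Hann −6 dB width ≈ 2/T); closely spaced dyads (e.g. 275 Hz apart) need
  ≥ 15 ms of sustained pulse or multi-pulse averaging.
* The interval classifier is restricted to the five published candidate
  ratios; harmonic stacks are flagged, not classified.

## Workflow shape

The package exposes every computation as ordinary functions (this is what
the tests and the acceptance script call); the numbered scripts under
`analysis/` are thin narrative drivers that generate fixtures and write
the result tables under `results/`. They are the command-line surface of
the package: each stage reads files written by the previous one, so any
stage can be re-run or swapped against real recordings in the same
formats (multi-page TIFF, WAV, CSV, YAML).
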