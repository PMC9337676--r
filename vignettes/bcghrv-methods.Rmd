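---
title: "Chair-BCG heart-rate estimation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chair-BCG heart-rate estimation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `bcghrv`, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the problem was
genuinely open. It states no empirical result that the package's tests do
not themselves compute.

## 1. The measurement model

A sitter on a four-legged chair loads four strain-gage load cells. Each
cell is read through a Wheatstone bridge with 350 Ω arms and excitation
$E$:

$$e = \frac{R_1 R_3 - R_2 R_4}{(R_1+R_2)(R_3+R_4)}\,E .$$

A balanced bridge outputs exactly zero; a strained arm produces a small
differential voltage. The package treats the bridge as a *static
sensitivity* (force → ΔR → mV) rather than simulating circuit dynamics:
only the static equation is physically specified, and the load cell's
mechanical bandwidth far exceeds the cardiac band. The absolute
mV-per-unit-force calibration of real hardware is unknown, so the
simulator's `strain_gain` (default 0.176 per unit normalized force) is a
free parameter chosen so that clean per-channel, per-second peak-to-peak
amplitudes land inside the 35–85 mV quality-acceptance band — i.e. the
simulated sitter is, by construction, "properly seated".

Each heartbeat contributes a force along the head–foot axis described by
the aortic pressure-difference model

$$F_{BCG}(t) = A_D\,[P_1(t)-P_2(t)] - A_A\,[P_0(t)-P_1(t)],$$

with $A_A, A_D$ the mean cross-sectional areas of the ascending and
descending aorta and $P_0, P_1, P_2$ the pressures at the aortic inlet,
the ascending/descending boundary, and the descending outlet. The
pressures are modeled as delayed, attenuated copies of one raised-cosine
systolic pulse (width 0.30 s, 40 mmHg): $P_1 = 0.95\,P_0(t-0.02)$,
$P_2 = 0.90\,P_1(t-0.04)$. With the default areas
($A_A = 5.0$, $A_D = 3.5$ cm², physiologic proportions) the template
reproduces the characteristic sequence: I trough, dominant J peak,
K trough. The tests verify both the zero-cancellation property (equal
pressures ⇒ identically zero force) and the I-J-K ordering.

## 2. What the simulator emulates — and what it does not

`simulate_paired()` generates a four-channel BCG and a single-lead ECG
sharing ground-truth R-peak times:

* **Rhythm**: RR intervals are `mean_rr + rr_sd·ε + RSA(t)`, clipped to
  0.4–1.5 s. Cohort defaults draw `mean_rr` from 0.7–1.0 s (60–86 bpm,
  resting adults), `rr_sd` from 0.03–0.06 s and RSA amplitude 0.01–0.03 s
  at 0.25 Hz — values a physiologist would call unremarkable for young,
  healthy sitters. The default recording is 600 s (the ten-minute seated
  protocol); tests use shorter recordings and state so.
* **Mechanics**: a beat train places one force template per beat with the
  J peak at `R + 0.25 s`. The R-to-J latency of real recordings is
  visible but unquantified in the literature we model; 0.25 s is a
  mid-systolic choice, constant by default with optional per-beat
  Gaussian jitter (`jitter_sd`, default 0.01 s when enabled).
* **Nuisance** (`layout_noisy()`): per-channel Gaussian sensor noise
  (2 mV), a respiration sinusoid (8 mV at 0.25 Hz, scaled by the leg's
  weight share), slow drift (5 mV at 0.03 Hz), and Poisson motion bursts
  (2/min, 0.5 s of 50 mV noise). Mass distributes unevenly over the legs
  (default 0.30/0.28/0.22/0.20).

It does **not** emulate: beat-to-beat morphology changes (posture,
pathology), multiplicative respiratory modulation of beat amplitude,
inter-subject template differences, electrode artifacts in the ECG, or
arrhythmias. A green end-to-end test therefore establishes that the
pipeline recovers timing and HRV *when the beat shape is stable and the
noise is additive* — it does not certify performance on abnormal rhythms
or on sitters whose morphology drifts, which is exactly where real-world
validation on human recordings remains necessary.

## 3. Preprocessing

Segmentation is 1 s with 50 % overlap (`W = round(window·fs)` samples,
hop `H = round(W/2)`, trailing partial windows discarded). Amplitude QC
uses the **raw** (unfiltered) segment's peak-to-peak, compared as
`≥ 85 mV` (heavy noise) and `≤ 35 mV` (no contact): the thresholds'
"amplitude" is not further specified at the source, and peak-to-peak
captures both saturating artifacts and flat-line contact loss. QC comes
before filtering because the drift/respiration components it reacts to
would otherwise be partially removed. Excluded segments mask the samples
they alone cover; peak candidates falling there are dropped.

The band-pass is a Butterworth design (2nd-order prototype, i.e.
4th-order band-pass) applied forward–backward, so it is zero-phase —
non-negotiable when the deliverable is peak *timing*. Coefficients come
from the standard analog-prototype → band transform → bilinear mapping;
the contract (5 Hz gain ≥ 0.9, 0.25 Hz attenuated ≥ 20 dB, DC removed,
linearity) is asserted in the tests. Reflection padding is sized to
several periods of the low edge so start-up transients die inside the
padding.

## 4. Peak localization

Candidates are strict local maxima (plateaus resolve to their center)
passing a minimum-spacing rule of 0.3 s — the period of a 200 bpm
ceiling rate — and a minimum-height rule: the peak value must stand at
least 3 rolling inter-quartile ranges above the rolling median of the
band-passed signal (10-s windows). Expressing the threshold in
median/IQR units makes it invariant to per-channel gain (a leg bearing
less weight sees the same waveform, smaller) and robust to short
artifact bursts, which barely move either statistic. In the band-passed
signal genuine J peaks stand ≈ 7–17 IQR above baseline across the clean
and noisy presets, while the secondary post-K rebound oscillation stays
below ≈ 1 IQR, so the margin is wide on both sides. Two alternative
gates were evaluated and rejected: a permissive low threshold admits one
rebound candidate per beat, and because the network head is
translation-invariant (global average pooling) the position-dependent
targets of those windows are largely unlearnable — they dominate the
training loss and inject spurious predictions; a *prominence* gate
(height above the higher flanking minimum) fails for short RR intervals,
where the rebound sits between the deep K and I troughs and scores a
prominence far above its actual height. Minima are not used as
candidates: in this morphology the J wave is the only robust positive
landmark.

Each candidate yields a 3-s window, z-scored per window (removing
weight-distribution scale differences between channels), with regression
target the signed time to the nearest true R peak; windows overrunning
the recording are discarded. The CNN is
Conv(16, k=11) → ReLU → maxpool 4 → Conv(32, k=7) → ReLU → maxpool 4 →
Conv(32, k=5) → ReLU → global average → Dense 64 → ReLU → Dense 1, with
the output passed through `1.5·tanh` so predictions live in ±1.5 s (half
the window). The exact published architecture is not available; this
stand-in is small enough for minutes-scale CPU training and is documented
as such. The output layer is zero-initialized: the head then starts at
offset 0, far from tanh saturation, which keeps plain fixed-step SGD
(default step 0.05, minibatch 64, seeded shuffling) stable across seeds —
with a generic random head initialization the loss can saturate at the
tanh rails. Training stops when the epoch mean squared error falls below
`1e-4` *and* the epoch-to-epoch improvement is below `1e-4`, or at
`max_epochs` (default 500). "Error" is read as epoch mean training loss
and "margin" as the absolute loss difference between consecutive epochs.
Training windows are drawn from the channel with the most QC-accepted
segments of each training subject; after per-window z-scoring the other
channels contribute nearly duplicate windows at four times the cost.

At prediction time every candidate's window passes through the network;
the predicted event is `candidate time + offset`. Predictions closer than
0.3 s are deduplicated keeping the more prominent candidate's, so tracks
are strictly ascending with bounded density. The convolution, pooling and
gradient kernels are compiled (Rcpp/RcppArmadillo); an im2col expansion
turns each convolution into one BLAS matrix product, and training with a
fixed seed is bit-reproducible on a given BLAS build.

## 5. RR quality, channel selection, HRV

Intervals outside the **closed** band [0.5 s, 1.1 s] are flagged
`bad_short`/`bad_long`. The band brackets the normal resting 60–100 bpm
range with margin; clinical convention for such normal bands is
inclusive, so exact boundary values are accepted. The source text's
phrasing around which segments are "bad" is self-contradictory (it reads
as if values *inside* the thresholds were bad); following its own
rationale — deviations from normal conditions indicate poor signal — the
package flags intervals *outside* the band. Flags are computed on RR
intervals, not on the 1-s preprocessing segments: the thresholds are
RR-valued.

The channel with the fewest bad intervals represents the sitter; ties go
to the lowest channel index. Time-domain features (mean HR = 60/mean RR,
SDNN as sample SD, RMSSD, pNN50 at the 50 ms convention) use good
intervals only, and successive differences are taken only between
intervals adjacent in the original series — bad intervals break the
chain; nothing is interpolated, because no gap-filling procedure is
specified for this pipeline. Spectral LF (0.04–0.15 Hz) and HF
(0.15–0.4 Hz) powers come from the periodogram of the 4-Hz
cubic-spline-resampled tachogram of the longest contiguous good run, and
are reported only when that run has ≥ 64 intervals. The feature set
{mean HR, SDNN, RMSSD, pNN50, LF, HF, LF/HF} is fixed here; the source
never enumerates its features, and these are the standard short-term set.

## 6. Validation semantics

The recording is partitioned into 1-s epochs. Predictions and truths are
matched one-to-one within ±0.1 s by scanning truths in ascending order
and taking the earliest unused prediction in range; on a line this convex
greedy achieves the maximum possible number of matches, so it coincides
with exhaustive assignment enumeration (asserted against a brute-force
oracle in the tests). A "nearest-pair-first" greedy does not have this
property and was rejected. Epoch accounting: an epoch holding truth is TP
if all its truths are matched, else FN; a truth-free epoch is FP if it
holds an *unmatched* prediction, else TN. Counting matched predictions as
FPs would double-score a correct detection whose prediction lands just
across an epoch boundary from its truth. At resting rates a 1-s epoch
legitimately holds two beats; `warn_multi` surfaces this when wanted. TN
is not defined at the source for event detection; this accounting is the
package's documented interpretation.

Heart-rate error compares 60/mean(RR) between predicted and true series
over consecutive 10-s windows (no averaging window is specified at the
source; 10 s spans roughly 10–16 beats). By default flagged-bad intervals
are dropped first: validation is based on the pipeline's *output* RR
series, which is the flagged one.

Leave-one-subject-out cross-validation trains on all-but-one subject and
scores the held-out sitter over the span where full 3-s windows exist
(1.5 s is trimmed at each end; no prediction can exist there by
construction). The conventional baseline — an adaptive-threshold picker
(rolling mean + 1.5·SD over 2 s, same 0.3 s spacing) whose detected
J times serve directly as beat times — shares the preprocessing but
deliberately *not* the RR flagging or least-bad-channel selection: those
are part of the proposed method's contribution, and granting them to the
baseline makes the comparison degenerate (once flagging removes
spurious-beat intervals, J-to-J intervals equal R-to-R exactly because
the mechanical latency cancels). The baseline's channel is the one with
the most QC-accepted segments, and its bpm error is computed on its raw
RR series.

## 7. Numerical and degenerate-input choices

* Time is seconds from recording start; samples are 0-based; windows and
  epochs are half-open `[start, end)`.
* A beat lands at each cumulative-RR time starting at `t = 0`; `n`
  intervals yield `n+1` beats when the last still fits, and beats whose
  force template would overrun the recording are dropped from both signal
  and truth.
* Sub-window recordings segment to zero segments (not an error); empty
  candidate sets predict empty tracks; fewer than two events give an
  empty RR series; fewer than three good intervals is an error for HRV.
* Model serialization writes weights as `%.17g` strings inside JSON —
  plain JSON numbers do not round-trip IEEE doubles bit-exactly.
* All randomness flows through explicitly passed seeds, and every
  generator restores the caller's RNG state.

## 8. Timing precision versus the stopping rule

The stopping tolerance has a quantifiable downstream consequence worth
spelling out. Training halts once the epoch MSE (seconds²) drops below
10⁻⁴, i.e. at a per-beat timing RMSE of about 10 ms (two samples at
200 Hz); held-out residuals in the clean-cohort tests land at 7–10 ms.
RMSSD is built from successive differences of intervals — second
differences of event times — so independent per-beat noise σ inflates it
to roughly $\sqrt{\mathrm{RMSSD}^2 + 6\sigma^2}$: more than 5 % whenever
the true RMSSD is below ≈ 70 ms, which healthy resting adults at the
low-variability end of the simulated range genuinely produce. Mean heart
rate is immune (noise averages out) and SDNN is affected half as much.
Training past the tolerance (e.g. to MSE ≈ 2·10⁻⁵) shrinks σ to ≈ 3 ms
and brings all features within a few percent — the architecture is not
the limit; the stopping rule is. The package keeps the published
tolerance as its default and documents the trade-off instead of quietly
tightening it; the corresponding acceptance test is expected to flag
RMSSD/SDNN disagreement for the lowest-variability subjects.

## 9. Known limitations

* The CNN head's global average pooling limits localization sharpness;
  the candidate-prominence gate compensates by ensuring windows are
  J-centered. Morphologically diverse data would likely need a
  position-preserving head.
* The stated CNN architecture, optimizer and learning rate are this
  package's documented stand-ins for an unavailable original.
* Criterion-style comparisons between the CNN and the threshold baseline
  depend on the noise model; with stable morphology and additive noise
  the baseline's *detection* is rarely wrong, and the CNN's measured
  advantage comes from the spurious/missed detections the baseline's raw
  RR series inherits near bursts and drift.
* EDF export is not implemented; recordings use the delimited-text +
  JSON-sidecar format exclusively.
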