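---
title: "Methods: cardiorespiratory processing and resonance-frequency biofeedback in rftkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiorespiratory processing and resonance-frequency biofeedback in rftkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rftkit)
```

## Scope and model

`rftkit` implements the software side of a wearable cardiorespiratory
biofeedback system: digital cleaning of single-channel ECG, PPG and
nasal-thermistor respiration; beat and breath event detection; heart-rate
variability (HRV) and coherence metrics; stress classification; and the
three-step resonance-frequency training (RFT) protocol. The physiological
premise is respiratory sinus arrhythmia (RSA): heart rate oscillates with
breathing, and the oscillation amplitude is maximal at an individual
resonance frequency near 0.1 Hz (about 6 breaths/min, with essentially all
individuals falling between 4 and 7 breaths/min). Breathing at that
frequency produces large, sine-wave-like ("coherent") heart-rhythm
oscillations, which is the training target.

All internal times are seconds, intervals are milliseconds, sample
indexing is 0-based in time (`t0 + i/fs`) and windows are half-open —
the millisecond conventions match standard HRV measurement practice.
ECG amplitudes are in mV; PPG and respiration are in arbitrary units and
never converted.

## Preprocessing chain

Four stages, all zero-phase (no waveform lag, verified by
cross-correlation in the test suite), with reflection padding at edges:

* **60 Hz notch** — second-order IIR with quality factor Q = 30
  (bandwidth 2 Hz), applied forward–backward. The digital zero lies
  exactly on 60 Hz, so steady-state mains attenuation is essentially
  complete; the narrow bandwidth implies an edge transient of roughly
  0.5 s at each end of a record, which is why the tests measure
  attenuation on the record interior.
* **FIR band-pass** — windowed linear-phase design with the transition
  kept at or below 0.5 Hz at the low edge, applied with exact group-delay
  compensation via FFT convolution, and explicitly de-meaned. Channel
  defaults mirror the analog front end of wearable sensors of this class:
  ECG 0.5–40 Hz, PPG 0.1–20 Hz, respiration 0.1–10 Hz.
* **3M morphological filter** — stage 1 averages open–close and
  close–open with a small flat structuring element (SE) `B1`, removing
  impulses narrower than `B1` in either polarity; stage 2 estimates the
  baseline as `close(open(y1, B2), B3)` and subtracts it. Defaults:
  `B1 = 0.01·fs`, `B2 = 0.2·fs`, `B3 = 0.3·fs` samples, rounded odd.
  `B1` must sit well below the width of the R wave's tip: an opening
  removes any peak narrower than its SE, so an SE comparable to the QRS
  duration (e.g. 0.06 s) would clip the R wave by half or more. 0.01 s
  removes one-to-three-sample artifacts while changing QRS amplitudes by
  only a few percent; `B2`/`B3` are longer than a QRS complex but shorter
  than one beat, so the baseline estimate tracks drift, not beats.
* **DOM smoothing/normalisation** — a moving average followed by min–max
  normalisation to [0, 1] (constant input maps to 0.5). The name "DOM"
  (differential operation method) has no published definition beyond
  smoothing and normalisation; this implementation is our reading of it
  and is labelled interpretive here deliberately.

## Event detection

**R peaks** use the classic integrate-and-threshold scheme: 5–15 Hz
band-pass, differentiation, squaring, 150 ms moving-window integration.
Candidate local maxima are accepted when they exceed an adaptive
threshold `thr = 0.5·rpe`, with the running peak estimate updated per
beat as `rpe ← 0.125·peak + 0.875·rpe`; a 200 ms refractory period
applies, a candidate larger than the accepted beat within the refractory
window supersedes it, and a search-back at 1.66× the running mean RR
rescues missed beats at half threshold. Events are refined to the raw
signal maximum within ±50 ms. Every quantity is relative to the signal
scale, so detection is invariant to positive amplitude scaling. Pulse
peaks use the same machinery with a 0.5–8 Hz band and a ±100 ms
refinement window. Plateau ties break to the earliest sample.

**Respiration cycles**: 1 s moving-average smoothing, alternating
extrema with prominence at least 20% of the inter-quartile range and
cycles at least 1.5 s, then landmark refinement on a lightly smoothed
(0.1 s) version of the signal — without this refinement the 1 s average
biases the peak position of asymmetric breaths by several hundred
milliseconds. Rising segments are inspiration; real thermistor traces
whose output rises during exhalation should be inverted (`--invert-resp`
in the CLI).

**Interval construction** rejects intervals outside (200, 3000) ms;
an interval below 200 ms is read as a spurious extra beat and both
intervals sharing that beat are dropped; intervals deviating more than
30% from the running median of the surrounding 11 are dropped. The
ectopic/median rule is this package's addition — upstream descriptions of
such systems are typically silent on RR cleaning — and the dropped count
is always reported.

## HRV metrics

SDNN and rMSSD follow their textbook definitions (sample SD; root mean
square of successive differences). Spectra are computed by cubic-spline
resampling of the tachogram onto a 4 Hz grid, linear detrending, and a
Welch estimate with 120 s Hann segments at 50% overlap. The spectral
integral is checked against the variance of the resampled series
(Parseval); deviations beyond 10% raise a warning. Band powers are
trapezoidal integrals: total ≤ 0.4 Hz, LF 0.04–0.15 Hz, HF 0.15–0.4 Hz;
power below 0.04 Hz is included in the total but not reported separately.
Normalized units are `100·X/(LF + HF)` — the variant pinned by published
group tables in which LF and HF normalized values sum exactly to 100.
The coherence ratio takes the tallest peak in 0.04–0.26 Hz, integrates a
0.030 Hz window centred on it (`P`) and reports `P/(TP − P)`.

A 120 s record yields a single Welch segment, whose realized spectral
integral can deviate from the realized variance by more than 10% purely
through estimator variance; Parseval-based checks in the tests therefore
use 5-minute records (two to four averaged segments).

## Stress classification

SDNN (ms) bins: > 50 non-stressed, 35–50 normal, 20–35 high, < 20 very
high. LF/HF bins: > 2.0 hyper-sympathetic, 0.5–2.0 balanced, < 0.5
hyper-parasympathetic. The published bin edges overlap at 35, 50, 0.5
and 2.0; this package fixes boundary membership as closed on the middle
categories (35 and 50 belong to NORMAL, 0.5 and 2.0 to BALANCED).
The 22-item simplified Stress Response Index questionnaire is summed
(items 0–4 each) and a total *strictly greater than* 56 is flagged
severe; the cutoff is exposed as an argument.

## RFT protocol

Step 1 paces the subject over the 4–7 breaths/min grid in 0.5 steps and
computes each epoch's RSA gain as the mean per-breath peak-to-trough RR
range (breaths needing at least 3 beats, epochs at least 5 such breaths
and 2 minutes long). The resonant frequency is the grid argmax, ties
breaking toward the lowest frequency (slower breathing preferred on
equal evidence). An LF-peak-power alternative was considered and
rejected as the default because the per-breath RR range is what the
subject directly manipulates and it needs no spectral estimate on short
epochs. Step 2 classifies the pre-training metrics. Step 3 analyses the
training epoch and reports adherence: the fraction of breaths whose
instantaneous rate lies within 0.5 breaths/min of the pacing target.
Sweep epoch length defaults to 2 minutes per frequency.

## Synthetic generator

The generator is the package's validation substrate and defines its
study conditions:

* `synthRr` — instantaneous interval
  `RR(t) = mean_rr + gain(f_b)/2 · sin(2π f_b t)`, with beats placed by
  integrate-to-threshold (IPFM) on the instantaneous rate so that beat
  times and intervals stay mutually consistent; per-beat Gaussian noise
  is then added and the beat times rebuilt cumulatively, so the interval
  noise SD is exactly the requested value. The gain curve over breathing
  frequency is a unimodal Gaussian centred on the subject's resonance
  (default width 0.8 breaths/min, putting grid neighbours about 20%
  below the peak — identifiable by the sweep, but not trivially so).
* `synthEcg` — Gaussian-sum P-QRS-T templates (R amplitude 1 mV) at the
  requested beat times, plus declared noise: 60 Hz powerline, sinusoidal
  baseline wander, random single-sample impulses, and/or broadband noise
  at a requested SNR. Morphology is sufficient for detector validation,
  not clinical realism: no beat-to-beat shape variability, no muscle
  noise spectrum, no ectopy. Passing tests on this substrate demonstrate
  algorithmic correctness, not clinical-grade performance on ambulatory
  recordings.
* `synthResp` — piecewise raised-cosine cycles with a configurable
  inspiratory fraction and exact landmark truth.
* `makeCohort` — three groups emulating a baseline group (target SDNN
  56.4 ms, 12.2 breaths/min), a stressed group before training (27.8 ms,
  rapid shallow breathing at 19.3 breaths/min, low RSA) and the same
  group after training (55.3 ms); per-beat noise is solved from the
  target SDNN and the RSA contribution, subjects jitter by a 5% CV, and
  recordings are generated at the beat/interval level (300 s each) with
  full ECG rendering available by composing with `synthEcg`.

All generators are deterministic under a seed and return ground-truth
annotations.

## Numerical choices and degenerate inputs

Reflection padding everywhere at signal edges; FFT convolutions are
padded to 2-3-5-smooth lengths (mixed-radix FFTs degrade badly at
near-prime lengths). Constant signals: DOM maps to 0.5; a constant RR
series has zero total power and the coherence ratio refuses it
(tolerance 1e-10 ms²) — so a full metric panel on degenerate input fails
loudly rather than classifying noise. A paired t-test on identical
vectors returns t = 0, p = 1, but constant non-zero differences are a
zero-variance error. EDF storage is 16-bit, so round-trips are exact
only to half a least-significant bit of the stored physical range.

## Validation problem sizes

The test suite runs 60 s records for detector unit checks, 130 s epochs
for the 7 × 7 sweep-recovery grid, 300 s records for spectral and
Parseval properties, and one 30-minute, 512 Hz, SNR 10 dB record for the
headline detection-rate check; cohort checks use 5 subjects per group at
300 s. These sizes were chosen as the smallest at which each property is
stable across seeds.

## Known limitations

The DOM stage is interpretive (see above). The synthetic ECG's
template regularity makes detection easier than on real recordings; the
detection-rate figure should be read as a validation of the algorithm
chain on its declared substrate. Group statistics implement standard
one-way ANOVA with Bonferroni-corrected pairwise t-tests (equal
variances; a Welch variant is available via `t.test`'s default in user
code); published F statistics from repeated-measures designs with
inconsistent degrees of freedom are not reproduction targets. No
arrhythmia handling, multi-lead fusion, or nonlinear HRV indices.
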