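---
title: "Wearable gait event detection and between-algorithm agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wearable gait event detection and between-algorithm agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The problem

Temporal gait parameters — stride, stance, swing and step times — are
computed from two event types per foot and gait cycle: the initial contact
(IC, heel strike) and the final contact (FC, toe off).  Wearable inertial
measurement units (IMUs) allow these events to be detected outside the
laboratory, but different sensor placements observe very different signals:
a lower-back (L5) sensor sees the vertical acceleration of the trunk, a
shank sensor sees the sagittal-plane angular velocity of the shin.  Two
algorithm families dominate practice, and this package implements one of
each:

* **A1 (lower back)** — tilt-correct the tri-axial acceleration to the
  horizontal–vertical frame, low-pass filter (4th-order Butterworth, 20 Hz),
  integrate the vertical channel (cumulative trapezoid), differentiate it
  with a first-order-Gaussian (`gaus1`) continuous wavelet transform at
  scale 10; ICs are the local minima of that output, and a second wavelet
  differentiation yields FCs at the local maxima.
* **A2 (shank)** — decompose the sagittal angular velocity with a 10-level
  5th-order Coiflet (`coif5`) wavelet transform; suppress drift (deep
  smooth) and sensor noise (finest details); detect the per-cycle positive
  mid-swing peak `tms`; then search two band-limited approximations for the
  most negative peak in the windows `(tms + 0.25 s, tms + 2 s)` for the IC
  and `(tms − 2 s, tms − 0.05 s)` for the FC.

The scientific question the analysis layer answers is not "are the
detectors right" (no reference system is involved) but "how well do the two
placements/algorithms *agree*", per cohort — young adults (YA), older
adults (OA), people with Parkinson's disease (PD) — and per walking
environment (treadmill speed ramp, indoor repeated walks, outdoor walks).
Agreement is quantified per parameter and statistic by Pearson's r,
Spearman's rho, the single-measure absolute-agreement intraclass
correlation ICC(2,1) with a 95% CI and p value, a categorical label, the
absolute difference of method means (AD), Bland–Altman limits of agreement,
and pooled-scatter OLS regression.

## Why synthetic data, and what the generator emulates

The package ships a first-class synthetic gait generator instead of raw
recordings.  `make_gait_script()` draws a bilateral ground-truth IC/FC
schedule; `synthesize_lumbar_accel()` and `synthesize_shank_gyro()` turn a
schedule into sensor streams whose morphology carries the events at
analytically known positions.  Every downstream stage is therefore testable
against exact ground truth — including the failure modes (missed or extra
events) that drive the agreement analysis.

The timing model is deliberately minimal:

* Subject-level parameters are drawn once per subject around cohort
  presets: mean stride time (YA 1.096 s, OA 1.162 s, PD 1.168 s — the
  indoor lower-back estimates for each cohort), within-subject stride SD,
  stance fraction, and a constant step-asymmetry offset.  Between-subject
  SDs take the corresponding reported dispersions.
* Step times are independent truncated-normal draws (±3 SD, floor 0.2 s),
  left/right strictly interleaved; no stride-to-stride autocorrelation is
  modelled because only means and dispersions enter the analysis.
* The asymmetry offset is split ±a/2 between the sides so the mean stride
  time is unchanged.
* FCs sit at the cycle's stance fraction of the stride; per-cycle stance
  fractions are capped so swing time never falls below ~0.38 s.  Human
  swing time is comparatively speed-invariant (~0.35–0.45 s), and the cap
  keeps the fast end of the treadmill ramp physiologic rather than letting
  a constant stance *fraction* compress swing unrealistically.
* Environments are bout structures: a 7 × 1-minute treadmill ramp
  (2–8 km/h in 1 km/h steps, cadence following the heuristic stride time
  ∝ speed^(−1/2) referenced to 4 km/h), four 15-s indoor walks at
  normal/slow/fast/normal self-selected pace separated by 2-s event-free
  turn gaps, and two 40-s outdoor walks.

Waveform amplitudes are **not** reported quantities anywhere; they are set
to typical literature magnitudes (mid-swing shank peak ~400 deg/s for YA,
reduced to ~260 deg/s for PD to emulate a shuffling, low-amplitude swing;
contact notches tens of deg/s; lumbar impact transients a few m/s²) and are
exposed per cohort and per call.  Two placement choices deserve explicit
justification:

* **Lumbar morphology.**  Each IC contributes a positive-then-negative
  impact transient (anticipatory lobe, then a deceleration dip whose
  minimum is at the scripted IC; the lobe amplitude is chosen so the pair
  integrates to zero and the gravity baseline is preserved).  Each FC
  contributes an odd push-off transient whose *slope* peaks exactly at the
  scripted FC — the feature A1's second differentiation stage detects.
  Widths scale with the local step time.
* **Mid-swing anchor placement.**  The generator places the shank's
  positive peak at `FC + 0.28 × swing`, early in swing rather than at its
  temporal midpoint.  With realistic stance fractions (~0.60–0.63) a
  midpoint peak would leave only ~0.20 s between the anchor and the next
  IC, inside the IC search window's excluded first 0.25 s, and the shank
  algorithm could never find ICs.  Real shank signals place the angular
  velocity peak early enough for the published windows to work; the
  generator follows that reality.

What the generator does **not** emulate: multi-segment biomechanics,
freezing-of-gait episodes, turning signals (turn gaps are simply
event-free), soft-tissue artefact spectra, or sensor-axis misalignment
beyond a fixed tilt.  Passing tests therefore demonstrate the pipeline's
correctness and its qualitative behaviour under controlled degradation —
not clinical validity on real recordings.

## Numerical choices

* **Wavelets.**  The CWT uses the odd kernel ψ(u) = u·e^(−u²/2), i.e. a
  smoothed differentiator with positive orientation; `scale` is expressed
  in samples and pinned to the 100 Hz reference (`scale = 10 × fs/100`),
  because the published scale is in samples while the data mix 60–128 Hz.
  The shank decomposition is a maximal-overlap (undecimated) discrete
  wavelet transform implemented in the frequency domain; multiresolution
  detail transfers are real and non-negative, so band reconstructions are
  exactly zero-phase and never move event timing.  Signals are
  reflection-padded before the circular transform.  Band selections at
  100 Hz: denoised baseline = details 3–8, IC approximation `a1` =
  details 2–4 (sharp, favouring the brief IC notch), FC approximation
  `a2` = details 4–6 (smoother, favouring the broader FC notch); selections
  shift by `round(log2(fs/100))` levels at other rates.
* **Filtering.**  The Butterworth low-pass is applied forward–backward
  (zero phase).  The published description states the order but not the
  phase handling; a causal filter would delay every event by a
  cadence-dependent lag that the agreement analysis would then
  misattribute to the algorithms.
* **Extrema.**  Strict sign-change extrema, visited in order of decreasing
  magnitude; IC minima enforce a 0.25 s minimum separation (the shortest
  plausible step at the fastest protocol speed), while FC maxima are
  deduplicated by keeping only the dominant maximum inside each IC-to-IC
  interval — during short double-support phases the true toe-off maximum
  sits too close to the heel-strike recovery flank for a blanket
  separation rule.  A relative height gate (20% of the dominant extremum)
  suppresses shallow spurious extrema between steps, and events within one
  wavelet support (4 × scale samples) of either signal end are
  discarded.
* **Shank windows.**  Windows are truncated at the recording boundaries
  and at the neighbouring mid-swing anchors (no window may cross an
  anchor), with an additional safety margin (0.35 s on the IC side,
  0.15 s on the FC side) that keeps the neighbouring swing peak's own
  support out of the search.  The most negative *local minimum* wins; ties
  break toward the anchor; a window with no sample below a small
  scale-invariant floor yields a missing event and a dropped-cycle
  diagnostic.
* **Cycle building.**  Cycles are consecutive same-side IC pairs with
  exactly one FC strictly inside; zero or multiple FCs drop the cycle with
  a diagnostic count (the "extra FC" failure mode), as do IC gaps longer
  than 2.5 s (turns, bout boundaries).  The step reference is the
  contralateral IC inside the cycle, so stride = stance + swing holds
  exactly by construction and step < stride always.
* **Lumbar side assignment.**  A1's events carry no side.  When shank
  detections exist, each lumbar IC takes the side of the nearest shank IC;
  each lumbar FC takes the side *opposite* its closest preceding lumbar
  IC, because in a bilateral event stream the FC after an IC is the other
  foot's toe-off (end of double support).  In lumbar-only mode sides
  alternate from the first event — a documented fallback that cannot
  recover from a missed event.
* **ICC.**  The label "ICC(2,1)" (two-way random) and the phrase
  "two-factor mixed model" conflict in the source literature; the
  single-measure absolute-agreement point estimate coincides under both,
  so the package computes the two-way absolute-agreement single-measure
  form with the F-based McGraw–Wong confidence interval and the
  conventional `F = MSR/MSE` p value.  Identical columns return exactly 1;
  a zero-variance matrix is an error, not a perfect score.
* **Category bins** are closed as conventionally printed (≤0.30 none,
  0.31–0.50 fair, 0.51–0.70 moderate, 0.71–0.90 substantial, ≥0.91 very
  good); gap values such as 0.305 resolve downward.
* **Bland–Altman** uses the 1.96 multiplier; **variability** is the pooled
  per-cycle SD (the per-side alternative is an option); **asymmetry** is
  |mean L − mean R| (a per-cycle alternative is an option); p values are
  reported raw with no multiple-testing correction.

## Problem sizes

The default study design mirrors the reference layout: YA-treadmill 16,
YA-indoor 31, YA-outdoor 25, OA-indoor 20 and PD-indoor 36 subjects
(128 total), all at 100 Hz, simulated deterministically from a master seed
via counter-derived per-subject seeds.  A full five-cell run takes well
under a minute on one core.  Detector-accuracy checks use single
continuous 45–60 s walks (30–60 strides per side): bout-initial strides
have no preceding mid-swing anchor and are structurally undetectable by
A2, so multi-bout protocols bound A2's recall at (strides−1)/strides per
bout — a property of mid-swing-anchored algorithms, not a defect.  The
replicated-agreement experiment repeats the YA-indoor cell 50 times; the
jitter experiment adds controlled Gaussian timing noise to ground-truth
schedules and summarizes swing-time ICC per jitter level.

## Known limitations

* Resampling is linear interpolation without an anti-alias filter; the
  detectors low-pass their inputs, but aggressive downsampling of
  broadband signals would alias.
* The A1 pipeline at a fixed analysed frequency band loses final contacts
  at the fastest treadmill stages, where double support shrinks toward the
  smoothing width; the treadmill cell consequently shows larger
  between-method differences than the steady-walk cells.
* The exact detail-level recompositions behind the published shank
  approximations are not documented anywhere; the shipped `a1`/`a2` band
  selections are this package's calibrated choice and are fully
  configurable.
* Synthetic waveforms are sums of analytic transients; conclusions about
  real-data accuracy require validation against reference systems, which
  is out of scope here.

## A worked example

```{r example, eval = FALSE}
sub <- simulate_subject("YA", "indoor", fs = 100, seed = 42)
res <- analyze_subject(sub)
res$summary_a1
cell <- run_cell("YA", "indoor", n_subjects = 10, master_seed = 1)
cell$table[cell$table$statistic == "mean",
           c("parameter", "icc", "category", "ad")]
```

The `analysis/` directory contains the numbered drivers that reproduce the
full workflow: simulation, detection with ground-truth scoring, temporal
parameter tables, agreement tables, and pooled scatter / Bland–Altman
figures, all writing under `results/`.
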