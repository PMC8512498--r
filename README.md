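# imugait

Gait event detection from wearable inertial sensors, temporal gait
parameters, and between-algorithm agreement analysis.

## What this is for

Clinical and free-living gait analysis increasingly relies on body-worn
inertial measurement units (IMUs).  The two workhorse sensor placements —
the lower back (fifth lumbar vertebra, L5) and the shanks — observe
different signals and use different algorithms to find the two events that
define a gait cycle: the initial contact (IC, heel strike) and the final
contact (FC, toe off).  Researchers who swap placements or algorithms need
to know how much the derived temporal parameters change.  `imugait`
implements both detector families, the temporal parameter layer, and the
full between-algorithm agreement analysis, together with a synthetic gait
generator that provides ground-truth event schedules so the whole pipeline
is testable without access to raw recordings.

**A1 — lower back.**  Tilt-correct tri-axial acceleration to the
horizontal–vertical frame, Butterworth low-pass (4th order, 20 Hz),
integrate the vertical channel (`cumtrapz`), differentiate with a
first-order-Gaussian (`gaus1`) continuous wavelet transform at scale 10
(ICs = local minima), differentiate again (FCs = local maxima).

**A2 — shank.**  Decompose the sagittal angular velocity with a 10-level
`coif5` wavelet transform, remove drift and high-frequency artefacts, find
the per-cycle mid-swing peak `tms`, then take the most negative peak of a
sharp approximation in `(tms + 0.25 s, tms + 2 s)` as the IC and of a
smoother approximation in `(tms − 2 s, tms − 0.05 s)` as the FC.

**Parameters and agreement.**  Per cycle: stride, stance, swing and step
times (stride ≡ stance + swing).  Per subject: mean, variability (SD of
per-cycle values) and asymmetry (|left − right| of side means).  Per
cohort/environment cell: Pearson r, Spearman rho, single-measure
absolute-agreement intraclass correlation

    ICC(2,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)),  k = 2

with McGraw–Wong 95% CI and p value, a categorical label (≤0.30 none,
0.31–0.50 fair, 0.51–0.70 moderate, 0.71–0.90 substantial, ≥0.91 very
good), the absolute difference of method means AD = |A1 − A2|, and
Bland–Altman limits of agreement (mean difference ± 1.96 SD).

## Worked example

```r
library(imugait)

sub  <- simulate_subject("YA", "indoor", fs = 100, seed = 42)
res  <- analyze_subject(sub)          # run A1 and A2, summarize
cell <- run_cell("YA", "indoor", n_subjects = 12, master_seed = 1)
cell$table[cell$table$statistic == "mean",
           c("parameter", "a1_mean", "a2_mean", "icc", "category", "ad")]
```

```
  parameter a1_mean a2_mean   icc  category      ad
1    stride   1.087   1.096 0.998 very_good 0.00811
2    stance   0.669   0.671 0.942 very_good 0.00206
3     swing   0.419   0.425 0.677  moderate 0.00605
4      step   0.544   0.547 0.998 very_good 0.00391
```

Twelve synthetic young adults walked the indoor protocol; both algorithms
then measured their mean temporal parameters.  Stride and step times agree
almost perfectly (ICC ≥ 0.99, differences of a few milliseconds); swing
time — which needs *both* event types and inherits the timing error of
each — agrees least.  Variability and asymmetry rows of the same table
show much lower ICCs, the expected signature of event-timing jitter
accumulating in dispersion statistics.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `05_figures.R`): simulate the five default
cohort/environment cells (YA treadmill/indoor/outdoor, OA indoor, PD
indoor; 128 subjects), detect events and score them against ground truth,
tabulate per-subject temporal parameters, write one agreement table per
cell, and draw pooled scatter and Bland–Altman figures under `results/`.

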