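# gazeMEM

Entropy-based detection of eye-movement events in jumping-point gaze
recordings.

## What it does, and for whom

When a fixation target jumps between screen positions, each trial of
the recorded gaze signal contains a fixation at the old target
(saccadic latency), one rapid saccade, and fixation at the new
target.  Locating the saccadic period usually relies on velocity or
dispersion thresholds with no agreed values.  gazeMEM takes a
different route, aimed at eye-tracking researchers working with
high-rate (≈1000 Hz) recordings: it characterizes signal *regularity*
with approximate entropy and lets a classifier find the saccade from
the entropy pattern alone.

The core statistic is the classical ApEn estimator

    ApEn(m, r, N) = Φ_m(r) − Φ_{m+1}(r),
    Φ_m(r) = (N−m+1)⁻¹ Σ_i log C_i^m(r),

where `C_i^m(r)` is the fraction of `m`-length template vectors within
Chebyshev distance `r` of template `i` (self-matches included,
natural log, defaults `m = 2`, `r = 0.2·SD`).  Each trial's velocity
series (two-point differentiation of position, truncated to
`N_EMr = 2048` samples) is covered by a dyadic grid — 6 levels of
contiguous windows of 64·2^(l−1) samples, 32 cells of 64 samples up
to one cell of 2048 — and ApEn is computed per window.  The resulting
63-cell pyramid is the **Multilevel Entropy Map (MEM)**.  Windows
containing the smooth, deterministic saccade score markedly lower
entropy than fixational noise, at every scale that touches them.

Feature vectors combine a finest-level cell with its coarser
ancestors (e.g. `set128_256_512`: 16 elements per map, 3 features
each); a deterministic Euclidean knn under
leave-one-participant-session-out cross-validation then predicts
*which* segment of the trial an element came from.  Segments carrying
the saccade are recognized far above the rest — that asymmetry is the
event detector.  A seeded synthetic jumping-point simulator with
ground-truth saccade windows makes the whole pipeline testable
without human data.

## Worked example

```r
library(gazeMEM)
cfg <- synthConfig(nParticipants = 2, nSessions = 2, nPoints = 10, seed = 42)
cohort <- simulateCohort(cfg)
maps <- unlist(lapply(cohort, function(r)
  lapply(extractEMSeries(r$recording, 2048), buildMEM)), recursive = FALSE)
maps[[1]]
#> MultilevelEntropyMap [P01/S1/1]: 6 levels over 2048 samples
#>   L1 (w=  64, 32 cells): 0.49 0.44 0.40 0.58 0.41 0.38 0.41 0.28 ...
#>   L2 (w= 128, 16 cells): 0.75 0.63 0.70 0.67 0.67 0.75 0.65 0.71 ...
#>   L3 (w= 256,  8 cells): 0.71 1.05 1.01 0.95 1.04 0.99 0.99 1.02
#>   L4 (w= 512,  4 cells): 0.88 1.31 1.34 1.34
#>   L5 (w=1024,  2 cells): 1.13 1.60
#>   L6 (w=2048,  1 cells): 1.38
```

The first cells of levels 3–5 (samples 1–256/512/1024, which contain
this trial's saccade) sit well below their fixation-only neighbours —
that is the signature the classifier exploits.

```r
dataset <- buildFeatures(maps, "set128_256_512")
report <- runLOSO(dataset, kGrid = c(3, 31))
report
#> EvalReport set128_256_512: 16 classes, 4 folds, k = 3/31
#>   overall accuracy: k3=0.138 k31=0.180
#>   best segment:     k3=0-128 k31=0-128
round(report@perSegment[1:4, ], 3)
#>            k3   k31
#> 0-128   0.475 0.625
#> 128-256 0.300 0.525
#> 256-384 0.200 0.200
#> 384-512 0.175 0.325
```

Overall 16-class accuracy is modest, as expected — fixation segments
are mutually indistinguishable — but the per-segment view shows the
early, saccade-bearing segments classified several times better than
the rest (all later segments sit near chance, 1/16).  With a cohort
of realistic size the saccade-bearing segment `128-256` dominates the
column.

`compareSegments(maps, level = 2)` runs the accompanying one-way
ANOVA + Tukey HSD across segment positions, and
`renderMEM(maps[[1]], "map")` writes the colour-banded grid
(HTML/CSV/JSON).  A command-line front end covering
simulate/mem/classify lives at
`system.file("cli", "gazemem.R", package = "gazeMEM")`.

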