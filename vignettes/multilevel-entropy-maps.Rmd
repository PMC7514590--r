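---
title: "Multilevel Entropy Maps: method, choices and limits"
author: "gazeMEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel Entropy Maps: method, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeMEM)
```

## The problem

In a jumping-point experiment a fixation target jumps between screen
positions at a fixed interval, and the recorded gaze trace for each
trial contains three regimes: a saccadic-latency fixation at the old
target, one rapid saccade, and post-saccadic fixation at the new
target.  Event detection — deciding where the saccadic period lies —
is classically done with velocity or dispersion thresholds whose
values are notoriously arbitrary.  gazeMEM instead characterizes the
*regularity* of the velocity signal: a saccade is a large, smooth,
deterministic excursion, so windows containing it are far more regular
(lower approximate entropy) than windows of fixational noise.

## Approximate entropy

For a series $u(1),\dots,u(N)$, embedding dimension $m$ and tolerance
$r$, let $x(i) = [u(i),\dots,u(i+m-1)]$ and

$$C_i^m(r) = \frac{\#\{j : \max_k |u(i+k-1)-u(j+k-1)| \le r\}}{N-m+1},
\qquad
\Phi_m(r) = \frac{1}{N-m+1}\sum_i \log C_i^m(r),$$

with the estimator $\mathrm{ApEn}(m,r,N) = \Phi_m(r) -
\Phi_{m+1}(r)$.  Implementation choices, all fixed and tested:

* natural logarithm only;
* self-matches are counted, so $C_i^m \ge 1/(N-m+1)$, no $\log 0$
  arises, and the estimator is non-negative;
* at dimension $m+1$ both count and normalizer run over the $N-m$
  existing templates;
* a constant (zero-SD) window returns 0 with a degeneracy flag rather
  than an error: a constant signal is maximally regular, and silently
  erroring on flat gaze segments would make batch processing brittle.

Defaults are $m = 2$ and $r = 0.2 \times \mathrm{SD}$, the standard
operating point for short biomedical series.  The tolerance policy is
`per_segment` (each window uses its own SD) because the map computes
entropy *independently per segment*; a `global` policy (one SD for the
whole 2048-sample series) is provided since either reading of
"standard deviation of the entire time series" is defensible when the
series is segmented.  Because $r$ scales with the SD, the entropy is
invariant to offset and positive rescaling of the coordinate, so the
units of the gaze signal never matter.

## The dyadic map

Each trial's velocity series of $N_{EMr} = 2048$ samples (the largest
power of two inside a 3 s trial at 1000 Hz) is covered by 6 levels of
contiguous windows of $64 \cdot 2^{l-1}$ samples: 32 windows of 64
samples at level 1 up to one 2048-sample window at level 6 — 63 cells,
a time-scale pyramid in which every coarse window is the exact union
of its two children.  64 samples is close to the smallest length at
which ApEn is statistically usable, and gives the finest time
resolution the dyadic scheme allows.  The velocity itself is the
two-point *forward* difference scaled by the sampling rate — the
literal two-point rule, which keeps sample $i$'s velocity causally
aligned with the onset — and each series is anchored at the stimulus
onset, truncating the 3000-sample trial to its *first* 2048 samples,
because everything of interest (latency, saccade) happens early.

## Features and classification

A feature set named `set128_256_512` takes the 128-sample level as its
element grid (16 elements per map, class label = element index) and
attaches, per element, the entropy of the containing window at each
listed level: element $i$ of finest size $X$ uses segment
$\lceil iX/S \rceil$ at level size $S$.  Classification is plain
Euclidean knn — the features are entropies on a common scale, so no
normalization — under leave-one-participant-session-out
cross-validation: all maps of one session form the test fold, so a
session can never inform its own prediction.  Ties are resolved
deterministically (vote tie → smaller summed neighbour distance →
lower class label; equidistant neighbours at the cutoff prefer the
lower class label, then the earlier training row), which makes every
run bit-reproducible and permutation-invariant; the rule is a package
convention, chosen because leaving ties to randomness would make the
cross-validation results irreproducible.  Per-segment accuracy is the
mean over folds of within-fold per-class accuracy; with complete
sessions the folds are class-balanced and this equals pooled
per-class accuracy.

Segment-level inference (are early segments really different?) uses a
one-way ANOVA across segment positions followed by Tukey HSD at the
95% family-wise level, via `compareSegments()`.

## The synthetic generator

`simulateCohort()` emulates the jumping-point paradigm with known
ground truth, which is what makes end-to-end testing possible without
human recordings.  Per trial (3 s at 1000 Hz by default):

* saccadic latency uniform on 100–250 ms, plus a per-participant
  offset uniform on ±20 ms (latency idiosyncrasy between subjects);
* one saccade of uniform 30–80 ms duration whose velocity is a
  raised-cosine pulse scaled so its integral equals the target step —
  smooth, unimodal, compactly supported; no main-sequence model is
  fitted because only segment-level distinguishability matters here;
* target steps of 0.2–0.8 screen units, kept inside $[0,1]$;
* fixation as white position noise (SD $5\times10^{-4}$ screen units,
  the order of a good video/coil tracker's noise floor) plus a
  random-walk drift (per-sample SD $2\times10^{-5}$); optional
  microsaccade pulses, off by default.

What it does *not* emulate: post-saccadic oscillations, blinks,
tracker dropouts, main-sequence amplitude–velocity coupling, smooth
pursuit, and the spectral colour of real fixational noise.  Passing
tests on this generator therefore demonstrate that the pipeline's
mechanics recover a known saccadic period embedded in plausible noise
— not that the method attains any particular accuracy on human data.

One structural consequence of the simulator is worth knowing: with
latency 100–250 ms, the first *three* 128-sample segments can carry
saccade samples, and elements 1 and 2 share their coarser ancestors,
so both are highly identifiable and their accuracies are close; the
saccade-bearing segment (129–256, the modal location of the saccade
midpoint) is separated from element 1 only by its own-level cell.
The end-to-end test therefore uses 20 sessions of 29 trials — the
generator's default trial count — so that fold noise does not swamp
that margin.

## Numerical and degenerate-input conventions

* Map cells are validated finite and non-negative (to $10^{-8}$
  floating slack).
* Averaging maps uses the sample SD by default; degenerate cells
  contribute their stored 0 unless explicitly excluded — no silent
  exclusion rule is assumed.
* Colour bands for rendering are left-closed/right-open
  ($[0.4, 0.5)$ brown, etc.), values $\ge 1$ red.
* Gaze timestamps must be strictly increasing with median spacing
  within 10% of the declared rate; segmentation is sample-index based
  from the nearest sample at-or-after each onset.
* Recordings are serialized with 17 significant digits so round trips
  are exact.

## Worked example

```{r example, eval = FALSE}
cfg <- synthConfig(nParticipants = 2, nSessions = 2, nPoints = 10,
                   seed = 42)
cohort <- simulateCohort(cfg)
maps <- unlist(lapply(cohort, function(r)
  lapply(extractEMSeries(r$recording, 2048), buildMEM)),
  recursive = FALSE)
dataset <- buildFeatures(maps, "set128_256_512")
report <- runLOSO(dataset, kGrid = c(3, 31))
report
```

Problem sizes in the shipped tests are chosen to keep the suite quick
on one core: the oracle sweep uses series of 16–256 samples, and the
end-to-end cohort is 20 sessions × 29 trials (580 maps).

## Known limitations

* ApEn is biased at short $N$; cells at level 1 ($N = 64$) are below
  the usual 75-sample recommendation and should be compared only with
  like-sized cells — which is all the map ever does.
* The ANOVA step assumes approximate normality of per-segment entropy
  values; no nonparametric fallback is provided.
* Only the horizontal channel is analysed; vertical coordinates are
  carried through I/O but ignored by the pipeline.
* knn accuracy figures from the synthetic cohort are not comparable
  to figures obtained on human recordings.
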