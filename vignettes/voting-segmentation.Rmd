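---
title: "Plurality-vote segmentation and backward tracking of budding yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plurality-vote segmentation and backward tracking of budding yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastvote)
```

## The problem and the model

Time-lapse phase-contrast imaging of growing *Saccharomyces cerevisiae*
colonies is the workhorse of single-cell studies of the cell cycle, but any
quantitative trace is only as good as its segmentation and tracking.  The
difficulty compounds geometrically: with per-frame success probability $p$
over $n$ frames, a whole track survives with probability $p^n$
(`compoundingSuccess(0.99, 100)` is about 0.37), so per-frame accuracy has
to be extreme.

yeastvote implements a segmentation strategy that avoids committing to any
single "optimal" intensity threshold.  In phase contrast, yeast interiors
are dark and cell boundaries carry bright halos on a mid-gray background.
For one cell and one frame the algorithm:

1. crops a window around the cell's previous mask (the *seed*);
2. for every threshold $t = 1, \dots, 256$ forms the candidate mask
   $\{x : I(x) < t\}$ and partitions it with a watershed on the negated
   Euclidean distance transform (Meyer flooding; non-candidates excluded);
3. scores each watershed sub-region 1 ("cell") iff (i) more than 40% of
   its area overlaps the seed, (ii) less than a third of its area is
   non-candidate at this threshold, and (iii) it does not touch the window
   border — and 0 otherwise;
4. sums the accepted regions over all 256 passes into a *composite score*
   image with integer votes in $[0, 256]$.

The composite is then refined: the Euclidean distance to the nearest seed
pixel is subtracted (penalizing movement — yeast are effectively immobile
between frames), and the phase image scaled by `phasePenaltyWeight` is
subtracted (penalizing bright halos).  The result is cut with two
thresholds expressed as fractions of its 90th percentile $P$: pixels
already in the seed need only exceed `lowFraction * P`, while new pixels
must exceed `highFraction * P`.  This tolerates the natural backward-in-time
shrinkage of growing cells while still admitting genuinely new area at a
stricter bar.  If the putative mask grew by more than `growthFraction`, both
fractions are raised once by 0.2 and the cut is repeated (never more than
once).  Finally only the largest 8-connected component is kept, and the
termination rules fire if the mask is below `minArea`, above
`maxAreaFactor` times the largest seeded cell, or more than 50% larger than
its predecessor.

Tracking runs **backward** from a seeded final frame, cell by cell; each
accepted mask seeds the next (earlier) frame.  Backward propagation means
buds need no detection logic: a bud's track simply fails at the frame
before its birth, and that frame is recorded as its disappearance —
normally its birth.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lowFraction` | 0.3 | fraction of $P$ | permissive cut for seed pixels; the main experiment-to-experiment knob (sensible range 0.2–0.4) |
| `highFraction` | `low + 0.2` | fraction of $P$ | strict cut for new pixels |
| `growthFraction` | 0.075 | fraction | tolerated per-frame growth before the one-time bump |
| `minArea` | 10 | px | minimal cell size; also the bud-termination size |
| `maxAreaFactor` | 4/3 | — | area cap relative to the largest seeded cell |
| `windowPad` | 10 | px | padding of the seed bounding box |
| `phasePenaltyWeight` | 0.25 | votes per intensity unit | halo veto strength |

`phasePenaltyWeight` is chosen so that a maximal-brightness boundary pixel
(255) forfeits ~64 votes — enough to veto halos, which collect almost no
votes of their own, without touching dark interiors (a 40-gray interior
loses only 10 of its ~190 votes).

**Why `windowPad = 10`.** The dual threshold is anchored at the 90th
percentile of the window's penalized scores.  Only cell-interior pixels end
up with positive scores (background earns no votes — any region containing
it touches the border or fails the overlap test — and is further dragged
down by both penalties), so $P > 0$ requires the tracked object to occupy
at least ~10% of its window.  With padding $p$ and object radius $r$ this
means $\pi r^2 \gtrsim 0.1\,(2r + 2p)^2$.  At $p = 10$ the smallest
trackable object is roughly 100 px — comfortably below a visible bud —
whereas at $p = 20$ it would be ~380 px, larger than many buds at birth.
The window must therefore scale with the smallest object one wants to
track; 10 px of context is plenty for the movement penalty to act on.

**Percentile and tie conventions.** The percentile is computed over the
whole window, negatives included, with R's default (type 7) quantile.
Threshold comparisons use $\ge$ so the boundary case is deterministic.  The
watershed floods basins seeded at the regional-maxima plateaus of the
distance transform (numbered by the row-major position of each plateau's
first pixel) in order of decreasing depth, breaking ties first-in-first-out
with a fixed row-major push order — the classic Meyer discipline.  We
initially tried resolving equal-depth ties globally in favour of the
lower-numbered basin, but that lets one basin crawl around equal-distance
rings of its neighbours; FIFO confines the meeting line to the saddle (the
neck between touching cells), which is what the method needs.  All
remaining ties (equal component sizes in the connectivity filter, equal
smoothed intensities in the nucleus mask) resolve to the first candidate in
row-major order.

Thresholds run 1–256 inclusive: 256 passes, so a pixel dark enough to be
accepted at every pass scores 256.

## Feature extraction

Morphology per mask: area, centroid, major/minor axis lengths from the
second central moments (the ellipse-equivalent convention, $4\sqrt{\lambda}$
of the covariance eigenvalues), and circumference as the length of the
Moore-traced 8-connected contour with diagonal steps weighted $\sqrt2$.

Nuclear fluorescence per cell-frame: the window is smoothed with a 3×3 box
filter; the nucleus is the brightest 25% of cell pixels by *smoothed*
intensity (smoothing first makes the mask robust to single hot pixels); the
reported nuclear level is the mean raw intensity over that mask; and a 2D
elliptical Gaussian with constant offset is fitted by Levenberg–Marquardt
least squares on a 15×15 patch around the peak (initial guesses: amplitude
= peak − patch median, σ = 2 px, offset = patch median).  A failed fit is
flagged, never fatal.

Out-of-focus correction: a constant-brightness nuclear reference channel
(e.g. a histone–mCherry fusion) should never *decrease* — its per-area
intensity only rises during S phase — so, after a window-3 moving average,
any dip below the running pre-dip level is attributed to focus drift, and
the signal channel is multiplied by `reference / smoothed` (coefficient 1,
i.e. correction in direct proportion to the fractional decrease; the
coefficient is exposed).  The reference level tracks increases immediately,
so a monotone rising reference yields no correction, and all factors are
≥ 1.  Gating the correction on a simultaneous decrease of the signal
channel is available (`requireGfpDecrease`) but off by default.

## The synthetic colony generator

`generateColony()` renders what the algorithm assumes: elliptical dark
interiors (default 40) with 2-px halos (230) on background 150, Gaussian
pixel noise (SD 6), exponential area growth of 1% per frame (growth per
frame ≪ a cell diameter), per-frame centre jitter of 0.3 px (well below
1 px — the immobility assumption), buds appearing at a uniform random angle
on mature mothers with probability 0.01 per cell-frame and then riding
outward on the growing mother boundary, optional shmoo-like teardrop
protrusions, and two fluorescence channels: a Whi5-like nuclear Gaussian
that switches off after a geometric-length G1, and a constant nuclear
reference dimmed by 15–35% during randomly placed focus episodes.
Overlapping halos take the maximum intensity; contested interior pixels go
to the nearer cell centre, so truth masks are disjoint by construction.

Buds are born at 140 px (about 20% of a mature mother's area, i.e. a
clearly visible bud).  Objects much below ~100 px sit under the method's
resolution floor described above — their windows have no positive
percentile level — so a generator emitting, say, 12-px buds would produce
objects the percentile normalization provably cannot segment, regardless of
implementation quality.

What the generator does **not** emulate: optics (no point-spread function,
no shot noise), focus gradients in phase, cell wall texture, vacuoles and
other dark organelles, cell deaths, or colonies so dense that interiors
merge without halos.  Passing tests on synthetic movies therefore
demonstrate the algorithm's mechanics (voting, penalties, dual threshold,
termination, birth recording) under its own stated assumptions, not
performance on any particular microscope's data — on real movies the two
dual-threshold fractions are the knobs to adjust upon inspection.

## Numerical choices and degenerate inputs

* 16-bit phase input is mapped to 8 bits linearly between the movie-global
  0.1st and 99.9th intensity percentiles (clipped, rounded half-up):
  deterministic, robust to hot pixels, and movie-global so a threshold
  means the same thing in every frame.  Already-8-bit input passes through
  unchanged, making the conversion idempotent.
* An empty candidate mask watersheds to zero regions; an empty foreground
  at seeding warns instead of failing.
* A window whose score percentile is ≤ 0 (nothing cell-like near the seed)
  yields an empty mask, which the termination rules turn into a recorded
  disappearance — this is precisely the mechanism that stamps a bud's
  birth frame.
* Evaluation operationalizes "fraction of the area segmented correctly" as
  intersection-over-union (symmetric, punishes over- and under-segmentation
  alike); the one-sided truth-coverage reading is available behind a flag.
* The suite exercises the pipeline at deliberately modest sizes — 48×48
  oracle windows, a 20-founder/50-frame default colony on a 320×320 frame,
  50-nucleus fit-recovery batches — chosen so each property is measured on
  hundreds to thousands of cases while a full run stays interactive.

## Known limitations

* One cell at a time, no exclusion constraint between cells: two tracks can
  claim the same pixel (it is logged, and label export resolves to the
  lower id).  The thin bright halo between kissing cells is what actually
  separates them; movies without such boundaries will merge neighbours.
* Backward-only: no division detection or mother–daughter lineage
  assignment; a bud's record is its disappearance frame.
* Sudden large movements violate the distance penalty's assumption and are
  the expected failure mode (typically a growth-jump or size termination).
* Objects below ~100 px (at the default window padding) cannot be tracked;
  shrink `windowPad` further only if the movement penalty still has room to
  act.
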