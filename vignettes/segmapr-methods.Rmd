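---
title: "Methods: segmental mapping, profile registration and the threshold-survival model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmental mapping, profile registration and the threshold-survival model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmapr)
```

This vignette documents the scientific and numerical choices behind
`segmapr`: how events are mapped into a normalized segmental coordinate
system, how intensity profiles are registered to stripe landmarks, what the
threshold-survival model assumes, what the synthetic-embryo generator does
and does not emulate, and where the design was genuinely open.

## Coordinate conventions

Images are numeric arrays indexed `[row = y, col = x, channel]`, with x the
anterior–posterior (A/P) axis (anterior at low x) and y the dorsal–ventral
(D-V) axis. All pixel coordinates are **1-based**, following R's indexing;
positions are in pixel units unless noted. The survival model works in
dimensionless segment-width units instead, because it is not tied to any
image.

## Segmental event mapping

**Segmentation.** Landmark stripes are extracted by a single global
intensity threshold followed by 8-connected component labelling, with a
minimum-area filter against noise specks. This is a deterministic
replacement for interactive pixel classification; it is adequate whenever
the landmark channel is well separated from background, which is the case
for immunostained En stripes and for the generator's output. The threshold
is a parameter (conventionally half the stripe intensity), not an
estimate — the package deliberately avoids automatic threshold selection so
runs are reproducible and auditable.

**Skeletonization.** Each stripe is reduced to a single-pixel curve by
Zhang–Suen thinning. Two post-passes enforce the curve contract: a
unit-width cleanup removes staircase pixels whose skeletal neighbours
remain 8-connected without them (thinning can leave pixels with three
neighbours where no real branch exists), and spur pruning walks inward from
each endpoint and deletes side branches shorter than `prune_length_px`
(default 10 px) that terminate at a branch point. A curve that is already
single-pixel passes through unchanged, so the operation is idempotent, and
pruning never erodes the ends of a simple curve because it only deletes
walks that reach a branch pixel.

**Flanking-pair assignment.** Stripes are ordered by their median x; an
event whose x falls in `[median_i, median_{i+1})` is assigned segment *i*.
Ordering fails loudly when two stripes' medians are closer than 1 px, since
their A/P rank would be meaningless. Events anterior of the first or at and
beyond the last stripe median are flagged unmappable and never enter
histograms; an event lying exactly on a skeleton pixel is assigned position
0% of the segment posterior to it.

**Normalized position.** With d~ant~ and d~post~ the minimal Euclidean
distances from the event to any pixel of the anterior and posterior
flanking skeletons,

$$\mathrm{rel\_pos} = 100\cdot\frac{d_{ant}}{d_{ant}+d_{post}}\ \ [\%].$$

For straight parallel boundaries this equals the linear coordinate exactly;
for curved boundaries it remains well defined and bounded in [0, 100]. The
distances are computed exactly over the full event-by-pixel distance
matrix — no approximate spatial index — so the unit tests can compare them
against an explicit per-pixel scan at 10^-9^ tolerance. Distances are
planar Euclidean; whether a cartographic projection's geodesics would
differ is outside the package's scope, which begins at projected 2D images.

**Midline exclusion.** Apoptotic figures of the developing nervous system
are removed by excluding a central D-V band covering a fraction (default
0.20) of the linear dorsal-to-ventral extent. The band is centred on the
midpoint of the D-V range because a ventral-view projection places the
midline mid-image; callers with off-centre fields pass explicit
`dv_min_px`/`dv_max_px`. Both band edges are inclusive, and the generator
uses the identical rule, so exclusion can be compared against ground truth
exactly rather than up to boundary ties.

**Histograms.** Positions are binned into `n_bins` (default 10, matching
the granularity at which such histograms are conventionally drawn) half-open
bins on [0, 100], last bin closed. Per-embryo rows are kept as raw counts;
averaging across embryos defaults to per-embryo *fractions* so that embryos
with very different amounts of apoptosis contribute equally — whether to
normalize before averaging is genuinely open, so a raw-count mode is also
provided. With a single embryo the cross-embryo standard deviation is
undefined and reported as `NA`.

**Group comparison.** `compare_mean_intensity()` is the classical unpaired
two-sample Student t test with pooled variance (`t.test(var.equal = TRUE)`),
returning group means and standard deviations alongside t, df and the
two-sided p — the quantities typically plotted. It assumes approximate
normality of per-embryo means and similar group variances; with the small
group sizes typical here (3–10 embryos) it is a descriptive convention as
much as an inference.

## Profile registration

ROI traces are per-channel column means over the ROI rows. Landmark peaks
are local maxima of a lightly smoothed trace (centred moving average,
default 5 px — enough to suppress single-pixel noise without displacing
peaks of width ≥ stripe width), filtered by topographic prominence and a
minimum separation (most prominent kept first). Endpoints never count as
peaks, so monotone traces correctly fail with "cannot register". Linear
interpolation is used for resampling: the 50-intervals-per-segment
convention specifies sample positions, not an interpolation scheme, and
linear is the minimal assumption.

Registration is **half-open**: segment *s* between peaks p~s~ and p~s+1~ is
sampled at p~s~ + k/B·(p~s+1~−p~s~) for k = 0…B−1 (B = 50 by default), so
every peak lands exactly on the first bin of its segment, segments
concatenate without duplicated bin positions, and the trace outside
[first peak, last peak] is discarded. Registration is invariant to uniform
stretching of the x axis and commutes with averaging (both properties are
tested). SEM requires at least two samples; a batch run reports per-sample
registration failures and continues, failing only when fewer than two
samples register. Samples that register different segment counts are
truncated to the common leading segments before averaging.

## The threshold-survival model

The model formalizes one idea: segmental EGFR-ligand sources maintain
signaling above the level cells need to survive, and apoptosis appears
wherever signaling falls below it. Its ingredients:

- **Sources.** Each segment carries two sources flanking its boundaries — a
  Vein-like domain at 0.1 segment widths posterior to the anterior boundary
  and a rhomboid/Spitz-like domain 0.1 anterior to the posterior boundary.
  Relative amplitudes of the two ligand classes are unknown; defaults set
  them equal (amplitude 1), exposed as columns callers can edit.
- **Kernel.** S(x) = Σ~s~ A~s~·exp(−|x−x~s~|/λ~s~): symmetric exponential
  decay, the minimal model of a secreted ligand spreading from a stripe
  source and decaying with distance. Default λ = 0.25 segment widths.
- **Threshold.** Cells die where S < θ; default θ = 0.22.

The defaults are a *calibration contract*, fixed once from the closed form
rather than fitted: mid-segment in wild type the two nearest sources are
0.4 widths away, giving S ≈ 2e^−1.6^ ≈ 0.40 > θ; with one ligand class
lost the gap widens to 0.5 per side, S ≈ 2e^−2.0^ ≈ 0.28, still above θ;
in a *ftz* mutant the de-sourced segments have their nearest remaining
sources 0.6 widths away, S ≈ 2e^−2.4^ ≈ 0.19 < θ. This places the
wild type safely above threshold, single-ligand mutants mildly buffered
(redundancy), and pair-rule gaps below threshold — one band per de-sourced
segment, seven in a 14-segment embryo. The grid spans [0, n_segments] at
0.01 segment-width resolution; bands are maximal runs of sub-threshold grid
points, and the sub-threshold "area" is the fraction of sub-threshold grid
points times the domain length, a measure under which adding a source is
exactly monotone.

Two deliberate consequences of the linear (non-periodic) domain: in a
single-ligand scenario the terminal segment's outer flank loses its nearest
source and a small sub-threshold band can appear at the field edge (the
real embryo's field abuts head and tail regions the model does not
represent), and the last *ftz* band runs to the domain edge and is slightly
wider than the interior bands. Scenario comparisons therefore use areas and
band counts, which are insensitive to these edge details. The model is a
static landscape: the developmental delay between mispatterning and death
onset is real but has no proposed mechanism, so it is not simulated.

## The synthetic-embryo generator

The generator emulates exactly the statistical structure the analysis
relies on:

- periodic bright stripes (default 14, spacing 60 px, width 8 px, intensity
  0.8 on a [0, 1] scale) with an optional sinusoidal lateral wiggle so that
  nearest-boundary distances are genuinely two-dimensional;
- sparse disk events (radius 3 px) whose intra-segment relative position u
  follows a configurable law (uniform or beta; beta(2, 2) is the shipped
  default, a smooth mid-segment–enriched, boundary-depleted shape of the
  kind observed in wild-type epidermis);
- a ventral-midline band (fraction of the D-V extent) in which events are
  sown uniformly in x and flagged, giving the exclusion logic positive
  ground-truth cases;
- 1D profile samples with Gaussian landmark bumps at per-sample jittered
  boundary positions, a signal channel with smooth cosine peaks phase-locked
  to the (jittered) boundaries, and a complementary antisignal channel
  `(2·baseline + amplitude) − signal` emulating the anticorrelated
  signaling/reporter pair;
- additive Gaussian noise clipped at zero, default sd = 10% of stripe
  intensity — the simplest model sufficient to stress thresholding.

Everything derives from one integer seed, and identical specs produce
bit-identical output. What the generator does **not** emulate: optics (no
point-spread function), nuclear texture, intensity gradients across the
field, curved embryo geometry beyond the stripe wiggle, or segmentation
ambiguity from touching cells (overlapping disks merge, which the tests
treat explicitly). Passing tests therefore demonstrate correctness of the
*quantification*, not robustness to every imaging artifact; on real data
the thresholds and area filters are the knobs that absorb those artifacts.

## Problem sizes

The test suite and the reproduction script use deliberately modest sizes
chosen to exercise every code path at tight tolerances: single embryos of
220×900 px for unit tests; 20 embryos for the seed-swept skeleton-recovery
and exhaustive-distance checks (8 stripes, 540×160 px, 40 events each);
20 embryos × 500 events for end-to-end distribution recovery (the
Kolmogorov–Smirnov distance to the generating beta(2, 2) CDF is ~0.03,
comfortably inside the 0.07 acceptance bound, with pixel quantization at
60 px segment width contributing ~0.01); and 10 jittered samples for
registration fidelity. These sizes give stable statistics at seconds-scale
runtimes.

## Known limitations

- Planar Euclidean distances; no geodesics on the embryo surface.
- Global-threshold segmentation; no learned pixel classification.
- The flanking-pair choice by median-x bracketing can misassign events in
  pathologically curved geometries where a stripe's median is far from its
  local centerline; the stripe wiggle amplitudes the generator produces are
  far from this regime.
- The survival model has no dynamics, no cell mechanics and no
  compartment-size competition; it is the minimal formalization of the
  threshold idea, meant for qualitative genotype comparisons.
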