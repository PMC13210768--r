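---
title: "Simulated fluorescence-microscopy fiber counting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated fluorescence-microscopy fiber counting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersense)
```

## The measurement problem

Airborne asbestos is monitored by drawing air through a membrane filter and
counting the fibers deposited on it under a microscope. A deposit is counted
as a fiber when it is longer than 5 µm, thinner than 3 µm, and has an aspect
ratio above 3:1 — the standard morphological counting rule. The count `N`
over `n` microscope fields of area `a` (mm²) on a collection spot of
effective area `A` (mm²), with a sampled air volume `V` (L), converts to an
airborne concentration

> C (f/L) = A · N / (a · n · V).

With the default geometry used throughout this package — a 15-mm circular
collection spot, a 0.66 mm × 0.44 mm field, one field, and 20 min of
sampling at 10 L/min — a single counted fiber corresponds to
`r fiber_concentration(1)$concentration_fl` f/L. That *single-fiber
equivalent* is the granularity of one measurement cycle and drives all of
the low-count statistics discussed below.

fibersense is a fully synthetic test bench for this measurement chain:
it generates ground-truth scenes and defocused z-stacks, fuses them into
extended-depth-of-field (EDF) composites, detects and measures fiber
candidates against the counting criteria, converts counts to
concentrations, and quantifies between-method agreement and
counting-statistics variability. Everything runs on simulated data, so
every stage can be scored against known truth.

## The synthetic scene model

`sample_scene()` draws one field of view. Object counts are Poisson with
requested means; the defaults, 6.5 fibers and 86.2 particles per
660 µm × 440 µm field, are typical per-field abundances for pulverized
asbestos-containing building materials. Geometry laws were chosen once, on
field realism grounds, and are not tuned:

* fiber length ~ lognormal(meanlog = log 9 µm, sdlog = 0.45): most fibers
  countable, with a realistic minority below the 5-µm cut;
* fiber width ~ lognormal(log 0.7 µm, 0.35), capped at 2.8 µm — stained
  asbestos fibers are thin, usually below the optical resolution;
* orientation uniform; curvature ~ N(0, 0.01 µm⁻¹), giving gently curved
  centerlines (quadratic Béziers re-scaled to the requested arc length);
* depth uniform over 6–16 µm below the filter surface, the depth band over
  which deposited fibers are distributed in practice;
* particle radii lognormal(log 0.8 µm, 0.3) capped at 1.5 µm, so a particle
  alone (aspect ratio 1) can never satisfy the counting rule.

About 15% of particles are deposited as near-linear agglomerates of 2–5
members that share brightness and depth: aerosol particles arrive partly as
clumps of one material, and it is exactly such chains of contiguous bright
particles that a morphological detector can mistake for a fiber. This is
the mechanism behind the high-background false-positive flag (see below);
making the clusters optically coherent is what makes that failure mode
reproducible in simulation.

Ground-truth countability (`true_countable_fibers()`) applies the three
criteria as strict inequalities to the true geometry, and flags fibers
whose centerlines approach within the sum of their half-widths as
aggregates: standard counting protocols exclude entangled or crossing
fibers, and the detector mirrors this with a skeleton-branching rule.

## Image formation

`render_zstack()` renders 25 focal planes at 2-µm steps by default. Each
object is blurred with a Gaussian of

> sigma(dz) = sqrt(sigma0² + (slope · |dz|)²),

where `dz` is its distance from the focal plane, `sigma0` = 0.25 µm
(diffraction scale for an NA-0.6 objective at ~510 nm emission) and
`slope` = 0.5 µm of blur per µm of defocus (geometric optics). A fiber has
a Gaussian cross-profile of FWHM equal to its width; defocus widens the
profile to `sqrt(sigma_w² + sigma_b²)` with the amplitude scaled by
`sigma_w / sigma_eff` (flux conservation across the line). Particles are
isotropic Gaussian blobs of sigma = radius/2 with area-law amplitude
scaling. The membrane background is a seeded low-pass noise field with a
5-µm correlation length (the entangled-cellulose texture of a mixed-ester
filter), defocused with the same model; because it is smooth it is
generated on a coarse grid and bilinearly upsampled. Per-plane noise is
Poisson shot noise on the signal plus additive Gaussian read noise
(default SD 2% of the background level). The default pixel pitch is
0.33 µm/pixel (a 2000 × 1334 px composite for the full field); this is a
declared default, configurable, not a claim about any particular camera.

Everything is seeded: identical seeds and parameters give bit-identical
scenes and stacks.

What the simulator does **not** model: a physically rigorous PSF
(Gibson–Lanni), spectral staining chemistry, color rendering, stage drift
or plane misregistration, nonspecifically stained non-asbestos fibers, and
mineral-dependent detection offsets. Passing tests therefore demonstrate
that the algorithmic chain is correct under this optical model, not that
any detector would reach the same scores on real filters.

## Focus stacking

`focus_stack()` scores per-pixel focus as local Laplacian energy: the sum
of the squared 4-neighbour discrete Laplacian over a window of radius 4 px
(~1.3 µm, matched to the fiber width scale). Each composite pixel is
copied from the plane with maximal score; provenance is recorded; ties go
to the lowest plane (nearest the filter surface), so a stack of identical
planes is returned unchanged.

Two numerical choices matter:

* **Exact arithmetic order.** The Laplacian is computed with replicated
  edges as `(up + down + left + right) − 4·center`, and the window sum is
  separable (column offsets accumulated first, then row offsets, zeros
  outside the image). This makes the whole selection exactly reproducible
  by an independent per-pixel implementation — the test suite checks
  bit-identity against a brute-force oracle on small stacks.
* **Selection denoising.** On smooth, shot-noise-limited images the
  Laplacian responds to photon noise more strongly than to defocused
  structure, so raw-energy argmax occasionally picks a defocused plane.
  The decision maps are therefore computed on planes pre-smoothed with a
  Gaussian of 1.5 px (`denoise_sigma`), and the per-plane score maps are
  themselves smoothed with sigma 2 px (`smooth_radius`) to suppress
  speckle in plane selection. Both affect *selection only* — composite
  values always come from the original planes — and both can be set to 0,
  which reduces the algorithm to the pure argmax the oracle replicates.

## Detection and morphometry

`detect_fibers()` chains four stages.

1. **Segmentation** (`segment()`). The background (smooth level plus
   filter texture) is estimated with a running median of radius 5 µm —
   large enough that thin objects cannot move the median — and
   subtracted. The residual is thresholded at 4 robust noise SDs — after
   flattening, detection is noise-limited, and a global Otsu threshold
   would ride up with the brightest fibers and drop faint ones (Otsu and
   fixed thresholds remain available) — so near-blank fields produce
   nothing. Components are
   labeled with 8-connectivity (thin diagonal fibers fragment under
   4-connectivity) and those under 12 px are dropped. Each surviving
   component is then re-thresholded at half its own robust (95th
   percentile, lightly smoothed) peak: the retained mask approximates the
   object's full-width-at-half-maximum footprint, independent of how far
   the signal happens to exceed the detection threshold.
2. **Morphometry** (`measure_component()`). The mask is thinned to a
   medial-axis skeleton by Guo–Hall thinning (chosen over Zhang–Suen,
   whose parallel sweeps can delete two-pixel-wide diagonal strokes and
   truncate thin diagonal fibers); the length is the longest geodesic
   through the skeleton's pixel graph (orthogonal steps 1, diagonal √2)
   plus one pixel for the half-pixel end caps plus the medial-axis inset
   at each path tip, so thinning artifacts at blunt ends do not shorten
   the measurement (a 30 × 3 px bar measures exactly 30 px). Width is
   `2 × median distance-transform value − 1` px over the skeleton.
   Endpoints are counted on a spur-pruned copy of the skeleton (spurs
   shorter than 1.5 µm removed); more than two endpoints marks a
   branched, aggregate-like object. Inside the detection chain the
   reported length is additionally *cap-corrected* by one measured width:
   the half-max footprint of a blurred fiber carries a rounded cap of
   about half a width at each tip, and subtracting it recovers the
   physical centerline length essentially unbiased (within ~0.3 µm on
   rendered test fibers).
3. **Classification** (`classify_fiber()`). Strictly longer than 5 µm,
   strictly thinner than 3 µm, aspect ratio strictly above 3, skeleton
   unbranched; the first failing rule, in that order, is the recorded
   rejection reason — a fixed priority makes audit output reproducible.
4. **Confidence** (`confidence_score()`). The product of logistic factors
   on the margins to each criterion and on peak-to-noise contrast; each
   factor is 0.5 exactly at its boundary, and the score is monotone in
   every margin. Candidates below the 0.32 default threshold are counted
   out with reason `low_confidence`. This score shares only its threshold
   interface with neural-detector objectness values; no numeric
   equivalence with any trained model is claimed.

Evaluation (`match_detections()`) pairs countable detections to countable
truth fibers greedily by centroid distance, one-to-one, within 3 µm (the
fiber width scale; the rule is a package choice). Unmatched detections are
false positives, unmatched countable truths false negatives, and particles
untouched by any countable detection true negatives — accuracy is
per-object over all annotated fibers and particles.

Fields whose total fluorescent object count exceeds 80 raise
`background_flag()`: dense particle fields are where chance chains of
contiguous particles inflate the false-positive rate, and the test suite
verifies that simulated >80-particle fields do produce more false
positives than ≤40-particle fields.

## Counting statistics and agreement

For a true concentration `C`, uniform deposition puts on average
`lambda = C·a·V/A` fibers in one field. `simulate_paired_series()` models
two instruments sampling the same well-mixed air as independent
Poisson(`lambda · n_fields`) counts converted back to concentrations; all
disagreement is counting noise on disjoint filter areas. Agreement is
summarized with relative differences, `100·(x−y)/((x+y)/2)` % — the
appropriate scale when differences grow with concentration — and
Bland–Altman limits of agreement `mean ± 1.96 · SD` (sample SD, n−1;
pairs with both members zero have an undefined ratio and are excluded and
reported rather than set to 0).

Two consequences of the Poisson model anchor the test suite. First, the
delta method gives SD(relative difference) ≈ `100·sqrt(2/lambda)` %, so
the limits of agreement widen as counts fall — the funnel that
`loa_funnel()` traces and that dominates single-field measurements near
the detection limit. Second, averaging `k` fields per method shrinks the
limits by `1/sqrt(k)`; the five-field configuration narrows them to
~0.45× of the single-field width, which is why multi-position imaging is
the main lever for measurement precision. Instrument-specific biases
(e.g. mineral-dependent sensitivity differences) are deliberately not
modeled: the simulation isolates the counting-statistics floor that any
such instrument shares.

## Problem sizes used in the tests

The shipped tests run the full chain at reduced scale, chosen once as
representative rather than exhaustive: detector-recovery uses 50 scenes on
330 × 220 µm fields (one quarter of the instrument field, same pixel
pitch) with 7-plane stacks covering the 4–16 µm depth band; the
depth-spread superset property uses 40 seeded trials on 200 × 140 µm
fields at the instrument's per-area fiber loading (at artificially high
densities, fibers separated only in depth overlap in projection and merge
on the composite); generator calibration uses 5000 scenes; all Monte-Carlo
agreement
checks use 2000 replicate pairs. Seeds are fixed in every stochastic
test.

## Known limitations

* The morphological detector is a classical stand-in: its scores on
  synthetic scenes say nothing numeric about any trained neural detector.
* Width below ~1 pixel is reported at the optical/pixel floor (a thin
  fiber's measured width is its blurred FWHM, not its physical width);
  classification is insensitive to this because real asbestos fibers are
  far below the 3-µm cut.
* Fibers are placed wholly inside the field; boundary clipping and
  field-edge counting rules are out of scope.
* The agreement module models no systematic inter-method bias, only
  counting noise.
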