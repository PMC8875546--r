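---
title: "Quantitative testis histomorphometry with cathi: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative testis histomorphometry with cathi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathi)
```

## The measurement problem

Semi-quantitative scoring of testicular histology (Johnsen-style scores, eyeball
estimates of tubule condition) is poorly reproducible and insensitive to mild
structural impairment. The alternative implemented here is fully quantitative
histomorphometry: on a calibrated raster image of a testis cross-section, every
structure of the standard morphometric model — the whole tissue section, each
seminiferous tubule, its lumen, and the spermatogenic epithelium (SE) between
them — is measured in micrometres, and a fixed set of derived quantities is
computed from those measurements. The derived set is:

* **Section level** — total tissue area and perimeter; the two longest
  perpendicular (Feret) diameters and their average; total tubule count; the
  histomorphometric **Bergmann–Kliesch score** (percentage of tubules containing
  elongated spermatids, the morphological signature of completed
  spermatogenesis); total interstitial area (section minus all tubules); tubule
  area ratio; and tubule number density (pieces per µm², which makes sections of
  different size comparable).
* **Tubule level**, on a random sample of cross-sectioned tubules — tubule and
  lumen area, perimeter, perpendicular diameters and average diameter; SE area
  (tubule minus lumen); SE area ratio; and SE thickness measured at five random
  points.
* **IHC level** — after H-DAB colour deconvolution: the positively-stained area
  percentage (DAB-positive pixels over counterstain-positive pixels) and the
  uncalibrated optical density `log10(255 / mean pixel value)` of the
  DAB-positive structures.

Longitudinally sectioned tubules are counted and included in the area sums, but
excluded from the per-tubule geometric sample: their profile geometry does not
reflect tubule calibre.

## The phantom: synthetic ground truth

No public image set accompanies this methodology, and manual measurements are
not a scalable oracle. The package therefore ships a parametric testis phantom
([`phantom_spec()`], [`generate_scene()`], [`render_he()`], [`render_ihc()`])
whose every rendered structure has an exact closed-form description:

* The section is a circle; tubules are ellipses with an annular epithelium
  around a concentric, homothetic lumen. Real tubules are irregular; ellipses
  were chosen deliberately because every target quantity (area πab, perimeter
  via elliptic integral, diameters 2a and 2b, radial SE gap) has a closed form
  to test against.
* Cross-sectioned tubules get aspect ratios in [1.0, 1.25]; longitudinal ones
  in [2.5, 3.2]. The segmentation classifier's cutoff (1.8) sits strictly
  between the two populations, so plane classification on phantoms has
  unambiguous ground truth.
* Packing is seeded rejection sampling, largest first, with a minimum 2 px gap
  between tubule bounding circles. The gap guarantees that the segmenter can
  separate neighbours; an infeasible request fails with an explicit error
  naming the attempt limit rather than looping forever.
* Spermatid-positive tubules carry six dark bars (7 × 1.6 px, aspect > 4)
  placed just inside the lumen boundary — a stylised rendering of elongated
  spermatid heads detached from the epithelium, and the defined target of the
  speckle detector.
* The IHC rendering is the Beer–Lambert forward model: per pixel,
  `RGB = round(255 · 10^(−M c))` with unit H-DAB stain vectors in the columns
  of `M`, DAB at a configurable OD on the positive structures, counterstain on
  all tissue. Rounding is round-half-to-even and the unquantized concentration
  fields are returned alongside the image.

Default dimensions (section radius 450 µm, 30 tubules of mean radius 45 µm at
1 µm/px, lumen fraction 0.55, 10 % longitudinal, 70 % spermatid-positive) are
rodent-scale rendering conventions chosen once for plausibility — roughly a
third of the tissue is tubular, several dozen tubules are visible, epithelium
occupies ~70 % of a tubule's cross-section. They are *not* derived from
measured species morphology, and any study using the phantom for calibration
should treat them as free parameters.

What the phantom does **not** emulate: staining texture and nuclei, irregular
tubule outlines, touching or overlapping tubules, partially cut edge tubules,
uneven illumination, and scanner noise. Passing the phantom suite therefore
demonstrates that the measurement and derivation chain is correct, not that
the segmenter generalises to real slides; the automated operators are
conventions validated only against phantoms, and real-slide use should supply
manually curated masks to the same measurement functions.

## Geometric conventions

All rasters use 0-based pixel indices with pixel centres at integer
coordinates; masks are pixel sets (a pixel is in or out, no partial coverage).
All measurements scale linearly (lengths) or quadratically (areas) with the
isotropic calibration in µm/px.

* **Area** is the foreground pixel count times the squared calibration.
* **Perimeter** is the length of the sub-pixel iso-contour at level 0.5 of the
  mask after Gaussian smoothing with σ = 1 px. Pixel-edge counting was
  rejected: it overestimates a circle's circumference by ~27 %. The smoothed
  marching-squares contour stays within 0.6 % of the true circumference for
  disks of radius 20–200 px and within 1 % on a square; σ is configurable, and
  only the outer contour is measured when the mask has holes.
* **Perpendicular diameters**: the first diameter is the maximum Feret
  (caliper) diameter over convex-hull vertices of pixel centres; the second is
  the caliper extent perpendicular to the first. Ties (e.g. a disk) resolve to
  the smallest direction angle in [0, π), making the result reproducible. The
  protocol's "e.g., horizontal and vertical" is treated as an example, not a
  constraint — axis-aligned diameters would make the measurement depend on
  image orientation.
* **SE thickness** casts five rays from the lumen centroid at seeded uniform
  angles and measures, per ray, the distance between the lumen-boundary and
  outer-boundary crossings. Boundary crossings are localised by bilinear
  interpolation of the binary mask at 0.1 px steps; nearest-neighbour lookup
  quantizes each crossing to half a pixel, which was measurably too coarse
  against analytic annuli. Rays that fail to cross both boundaries (possible
  for strongly non-convex lumina) are resampled up to a bounded number of
  times; re-entrant crossings use the first outward pair and warn.
* Masks smaller than 4 px are rejected as degenerate rather than measured;
  below rasterization scale the metrics are meaningless.

## Segmentation conventions

`segment_section` thresholds against near-white background, keeps the largest
connected component and fills holes. `segment_tubules` thresholds the dark
epithelium (gray ≤ 180 by default), closes 1-px gaps, fills each ring into a
full tubule region, optionally splits touching regions with a
distance-transform watershed (tolerance 10 px — high enough that a single
elongated profile, whose distance ridge is flat, is never split), and removes
regions under 500 µm² (debris). Each tubule's lumen is its largest pale
interior region, hole-filled so intraluminal speckles count as lumen. The
spermatid detector looks for at least 3 dark (gray ≤ 100), elongated
(eccentricity ≥ 0.9, length ≥ 3 px) blobs in the peri-luminal band — the lumen
dilated by 10 % of the tubule's equivalent radius. Every one of these numbers
is a parameter with the quoted default; none is claimed to transfer to real
H&E material.

Sampling for detailed measurement defaults to 100 tubules (the top of the
recommended 75–100 range); when fewer cross-sections exist, all are taken with
a warning, mirroring the advice to use every available cross-section in small
biopsies.

## IHC conventions

* Stain vectors default to the standard published H-DAB pair (hematoxylin
  (0.650, 0.704, 0.286), DAB (0.268, 0.570, 0.776), normalised); the residual
  third vector is their normalised cross product. The matrix must be
  invertible; its condition number is kept for audit.
* Per-channel OD is `−log10(max(I, 1)/255)`; clipping at 1 count bounds the OD
  of saturated pixels. Concentrations are the exact matrix inverse applied to
  the OD vector, with negative values clipped to zero (the clipped fraction is
  reported).
* The per-stain 8-bit encoding `I = round(255 · 10^(−c))` makes the
  uncalibrated-OD formula the exact inverse of the encoding: on a uniform
  field, the mean pixel value recovers the planted OD up to the 8-bit grid
  (half-count error, at most ~0.009 OD at moderate densities).
* Thresholding is dark-pass (positive ⟺ value ≤ T). The default T is Otsu's
  method on the ROI-restricted histogram, with a first-class manual override;
  whichever is used is recorded. Otsu is hand-computed on the 256-bin integer
  histogram because the histogram must be restricted to an arbitrary ROI pixel
  set. A constant channel makes Otsu meaningless and raises an error pointing
  to the manual mode — which is why the phantom pipeline uses a manual
  near-white counterstain cutoff (240): a uniformly counterstained field has
  exactly that degenerate histogram.
* The mean pixel value entering the OD formula is taken over the
  threshold-selected DAB pixels only, and cleared-background pixels (the
  white outside of a ROI) are excluded from every statistic.
* The positive-area percentage requires a counterstain denominator; for
  counterstain-free stains the package reports the OD and refuses the
  percentage with an explicit reason instead of inventing a denominator.

## Numerical limits worth knowing

**8-bit quantization bounds the deconvolution round-trip.** A planted
concentration c produces transmitted intensity `255·10^(−od)` per channel;
once any channel's OD exceeds ~1.37 the intensity falls below ~11 counts and
the half-count quantization error alone exceeds 0.02 OD after inversion. On a
joint grid of hematoxylin and DAB ODs the 0.02 round-trip bound holds up to
about 1.0 each (measured maximum 0.015) and degrades steeply beyond (≈0.16 at
2.0). The package's property tests assert the bound on [0, 1]; phantom
defaults (DAB 0.8, hema 0.3) sit comfortably inside it. Higher dynamic range
would require a >8-bit forward model, which the 8-bit workflow deliberately
does not use.

**Problem sizes.** The default phantom is a 912 × 912 px raster with 30
tubules; the full suite (generation, rendering, segmentation, measurement of
~27 sampled tubules, IHC round-trip) completes in about a minute, and those
are the sizes the shipped tests and the acceptance script use. All quantities
are computed at full double precision; CSV exports render 6 significant
digits, enough that re-reading a report is idempotent.

**Determinism.** Every stochastic step (packing, flag assignment, speckle
slots, thickness-ray angles, tubule sampling) runs under an explicit seed
through an RNG-state-preserving wrapper, so identical configurations produce
byte-identical CSV outputs and bitwise-identical PNG renders, and no package
call perturbs the caller's RNG stream.

## Known limitations

* The automated segmenter is phantom-grade by design; real-slide robustness
  (touching tubules, stain variation, debris) is out of scope and would need
  retuning or learned models.
* Edge-truncated tubules are not modelled; on real sections the area sums
  include them while the geometric sample should not, and the sampling
  operation only excludes longitudinal profiles.
* The thickness protocol measures along centroid rays; for strongly eccentric
  or non-convex lumina the five-ray mean is a convention, not an unbiased
  estimator of anatomical epithelium height.
* Calibration is assumed isotropic; anisotropic pixels are not supported.
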