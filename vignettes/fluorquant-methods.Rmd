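---
title: "Methods: standardized fluorescence quantification in bread-loafed specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized fluorescence quantification in bread-loafed specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

## The measurement model

A resected specimen is sliced into ~5 mm "bread loaves" and each slice is
imaged twice in a closed-box NIR imager — a white-light image for
delineation and a fluorescence image for quantification — on a fixed grid
of 0.085 mm pixels. Two regions are drawn by hand on the white-light
image: the macroscopic tumor and the outline of the bread loaf. Everything
downstream is automatic.

Two pipelines cover the two pharmacological situations:

* **Non-targeted dyes** (ICG-like) accumulate in a peritumoral rim. Signal
  is read in the halo `(T ⊕ 3 mm) \ T`, clipped to the loaf `L`;
  background in `L \ (T ⊕ 5 mm)`. The ratio of the two MFIs is the SBR.
* **Targeted dyes** (SGM-101-like) accumulate inside the tumor. Signal is
  read in `T` itself; background in the margin halo `(T ⊕ 5 mm) \ T ∩ L`.
  The ratio is the TBR.

The assumptions are minimal but worth stating: the tumor mask lies inside
the loaf mask (enforced by intersection at load time, with the clipped
area reported); intensities are non-negative arbitrary units with no
auto-gain, so ratios — not absolute MFIs — are the comparable quantity;
and analysis is per-slice 2-D, with no attempt to reconstruct 3-D margins.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `signal_halo_mm` | 3 | mm | width of the peritumoral signal halo (SBR pipeline). The first few millimeters around the tumor are the zone a surgeon actually inspects for delineation quality. |
| `background_margin_mm` | 5 | mm | distance beyond which loaf tissue counts as background (SBR), or width of the margin halo that *is* the background (TBR). May be widened to 10–15 mm for tissues with diffuse uptake. |
| `bin_width` | 0.001 | a.u. | histogram bin width for MFI computation. |
| `pixel_size_mm` | 0.085 | mm | physical pixel size; read from OME metadata when available, otherwise supplied or defaulted with a warning. |
| `alpha` | 0.05 | — | two-sided level for ICC confidence intervals. |

`signal_halo_mm` must not exceed `background_margin_mm`, otherwise the SBR
signal and background would overlap; the constructor rejects such
configurations rather than silently reordering them.

## Numerical choices

**Dilation.** `dilate_mm()` thresholds the exact Euclidean distance
transform of the mask complement at the real-valued radius
`distance_mm / pixel_size_mm` with a `≤` comparison. No structuring
element, no integer rounding: 3 mm at 0.085 mm/px is 35.294… px, and a
pixel belongs to the dilation iff its center is within that distance of
some mask pixel center. Squared distances are recovered as exact integers
before comparison, so the result is reproducible to the pixel across
implementations. The suite verifies equality with an exhaustive
brute-force oracle on hundreds of random masks.

**Rasterization.** A pixel belongs to a polygon ROI iff its *center* lies
inside under the even-odd rule. Coordinates are 0-based, origin at the
top-left pixel center, x rightwards, y downwards. This convention must be
fixed because DSC values depend on it; both GeoJSON polygons (the export
dialect of common annotation tools) and binary mask TIFFs are accepted and
normalized to masks internally. Polygons are clipped to the image; an ROI
covering no pixel center is an error, not an empty mask.

**MFI binning.** Bins are `[i·w, (i+1)·w)` anchored at zero with
bin-center representative values. The deviation from the arithmetic mean
is bounded by `w/2` (0.0005 a.u. at the default), attained only by
constants sitting exactly on a bin edge. Whether the original
implementation used centers or lower edges is unknowable from the outside;
the bound makes either choice equivalent at realistic intensities. A
consequence worth knowing: a ratio of two binned MFIs inherits a bias of
up to `(w/2)/background`, so checks that pin a ratio to ±0.2% use
background levels ≥ 0.3 a.u.

**ICC.** `icc_absolute_agreement()` implements McGraw & Wong's ICC(A,k) —
the estimand of a "two-way mixed-effects, absolute-agreement, mean-rating"
model — from the two-way ANOVA mean squares, with the F-based confidence
interval using Satterthwaite denominator degrees of freedom on the
single-rater form and the Spearman–Brown step-up to the mean-rating scale.
Degenerate matrices (no variance anywhere) are an error; *perfect*
matrices (identical raters, varying subjects) return estimate 1 with a
degenerate [1, 1] interval; negative estimates are returned as computed
and flagged, never truncated, because truncation hides degenerate
simulations. The point estimate is checked against an independent
`aov()`-based decomposition to 1e-10 on hundreds of random designs, and
against an externally computed worked example frozen in the tests.

**Rating bands.** The printed bands "0.5 to 0.75" and "0.75 to 0.9" are
ambiguous at their shared boundaries. We assign 0.75 to *moderate* and 0.9
to *good*, consistent with the strict inequalities of *poor* (< 0.5) and
*excellent* (> 0.9).

**ICC design stacking.** For interobserver reliability "over both
sessions" the subjects are loaf × session combinations (n = 2 × loaves)
and the raters the three observers (k = 3); for intraobserver reliability
the subjects are loaf × observer combinations and the raters the two
sessions (k = 2). These are the only complete-design readings consistent
with the stated k's; the builders reject incomplete designs listing the
missing cells rather than dropping rows.

## What the phantom emulates — and what it does not

`generate_phantom()` renders an elliptical loaf on a black field, a
circular (optionally lobed) tumor, and one of two dye patterns: a rim
`a·exp(−d/δ)` decaying with distance *d* from the tumor boundary (defaults
a = 0.65 a.u., δ = 1.5 mm), or a filled tumor at level *t*. The background
level *b* is modulated by a smooth three-sinusoid heterogeneity field
(wavelengths 8–20 mm, amplitude 10% of *b* by default) motivated by the
heterogeneous hepatic distribution of ICG. Gaussian noise (SD 0.005 a.u.)
is added to loaf pixels only — the field outside the specimen stays
exactly dark — and clipped at zero. Default levels (rim: b = 0.06;
filled: b = 0.04, t = 0.13) put the resulting SBR/TBR in the range
reported for clinical colorectal specimens while keeping every intensity,
including loaf-to-loaf scaling in evaluation datasets, inside the [0, 1]
a.u. storage range of the TIFF writer. The exponential rim shape and its
decay length are modeling choices: only the qualitative rim-vs-filled
distinction is given by the application.

The ground-truth ratio is computed by integrating the noiseless profile
over the *continuous* geometric regions (ellipse, disk/blob, mm-halos
around the true boundary) on a 3× subpixel midpoint grid. This route
shares nothing with the rasterized pipeline — no masks, no histogram — so
agreement between the two (within 2% on noiseless phantoms, in both the
tests and the acceptance script) is a genuine cross-validation of region
construction plus MFI computation, not a tautology.

Simulated observers extract the truth contour, resample it to 64 vertices,
and perturb each vertex radially by a per-observer bias plus Gaussian
jitter; self-intersecting draws are retried with fresh seed-derived noise.
Defaults (jitter SD 2 px ≈ 0.17 mm; biases 0/+1.5/−1.5 px) emulate
experienced observers with mild systematic over/under-delineation.

What passing tests on phantoms do **not** show: robustness to blurred or
ambiguous tumor boundaries in real white-light images, to multifocal or
non-star-shaped lesions beyond the lobed blobs generated here, to
formalin-fixation artifacts, or to the unpublished noise characteristics
of the actual imager. Phantom a.u. levels are nominal; only ratios are
meaningful.

## Problem sizes

Tests and the acceptance script run the full-geometry pipeline on a
reduced 360 × 280 px field of view at the instrument's 0.085 mm pixels
(the package default remains the full 1300 × 964 frame), with 10-loaf,
3-observer, 2-session evaluation cohorts; the ICC parameter-recovery
simulation uses n = 200 subjects × k = 3 raters × 1000 replicates, whose
5e-4 tolerance corresponds to ~5 standard errors of the Monte-Carlo mean
and covers the estimator's O(1/n) bias.

## Known limitations

* Storage is 32-bit integer TIFF in [0, 1] a.u. (quantization < 2.4e-10);
  true floating-point export is not supported by the underlying writer.
* Between-method significance testing beyond the CI-overlap rule (e.g.
  rank tests on paired ratios) is deliberately left to standard
  statistical routines on the exported CSVs.
* Delineation is consumed, never produced: automatic tumor segmentation is
  out of scope.
* The DSC/ICC harness requires the complete 3 × 2 design; unbalanced
  designs are rejected rather than approximated.
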