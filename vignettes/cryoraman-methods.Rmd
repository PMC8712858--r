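---
title: "Methods: frozen-cell Raman metrics and calcium responder analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frozen-cell Raman metrics and calcium responder analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoraman)
```

## What this package computes

Cryopreserving cells along a neuronal differentiation trajectory exposes
them to two controlled stresses — undercooling (how far below the
equilibrium freezing point ice is nucleated, `t_nuc`) and the
post-nucleation cooling rate (`B`). Low-temperature confocal Raman
microscopy images individual frozen cells label-free, and a handful of
quantitative metrics extracted from those hyperspectral images summarise
the cell's state: how much intracellular ice formed and in what morphology,
how strongly the membrane still partitions cryoprotective (CPA) solutes,
whether the protein (amide I) and cytochrome C distributions have become
punctate or dispersed (Moran's I), how much cell volume was lost
(equivalent diameter), and how dehydrated the interior is (C–H/O–H ratio).
Downstream, calcium imaging of thawed cultures classifies somata as
stimulus responders, and simple count-based assays quantify viability,
recovery and attachment. This package implements all of those
quantifications, plus seeded synthetic generators that emulate each
imaging modality with known ground truth, so every stage can be tested
end to end without any microscope.

## Raman heat maps

A cube holds intensities over (wavenumber, y, x) at a physical pixel pitch
(0.333 µm by default, matching the acquisition geometry the generator
emulates). A substance heat map is the per-pixel **trapezoidal integral**
of the spectrum over that substance's band window, optionally after
subtracting a straight baseline through the window endpoints. The
trapezoid is exact for the linear-baseline model and handles the
non-uniform wavenumber axes produced when only a subset of bands is
synthesized. Band positions live in one editable registry
(`default_band_registry()`): amide I 1655, C–H 2935, O–H/ice 3125,
cytochrome C 750, DMSO 670, glycerol 850, sucrose 1120 cm⁻¹. These are
literature-standard assignments used as stand-ins for instrument-specific
tables; windows span ±3 band sigma and are pairwise disjoint.

Maps are restored by **Richardson–Lucy deconvolution** (10 iterations by
default) with a Gaussian model of the theoretical point spread function,
FWHM = 0.61 λ/NA = 361 nm for a 532 nm laser at NA 0.90. Richardson–Lucy
was chosen because it preserves non-negativity and, with the
circular-boundary convolution used here, conserves total intensity to
machine precision. An FWHM below one pixel is ill-posed at the sampling
and is skipped with a notice. Deconvolution always precedes segmentation
and metric extraction; this ordering is a documented assumption.

**Segmentation** is Otsu thresholding (parameter-free and invariant to
positive rescaling, since maps are normalised to [0, 1] first), removal of
components below a minimum size, and hole filling. The cell is the largest
connected component of the filled union of the amide I and C–H masks.
Connectivity is 4-neighbour throughout (the `EBImage::bwlabel`
convention); component-size ties are broken by the smallest (y, x)
centroid. A constant map is a "no threshold" error, distinct from a valid
empty mask.

## Per-cell cryometrics

* **Ice.** Ice pixels are the above-Otsu pixels of the O–H/ice map inside
  the cell. `ice_area_fraction` is their share of the cell area. A cell is
  called **chunky** when the largest connected ice component covers at
  least 75 % of the cell (configurable): ice filling nearly the whole
  cytoplasm is the lethal morphology, as opposed to small dispersed
  crystals. The 0.75 default makes "nearly the entirety" operational.
* **Partition ratio.** Mean solute map value over a 3-pixel-wide
  extracellular annulus starting 2 pixels outside the cell boundary,
  divided by the intracellular mean with ice pixels excluded (ice displaces
  solution; toggleable). Intensity is assumed proportional to
  concentration with zero intercept — no calibration curve is applied.
  The annulus geometry avoids boundary blur while staying in the field.
* **Moran's I** with row-standardised 8-nearest-neighbour weights
  (Euclidean distance, equidistant neighbours broken by (y, x)
  lexicographic order). Row standardisation makes the total weight S₀ = n,
  so I = Σᵢⱼ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄) / Σᵢ(xᵢ−x̄)². The result carries the
  permutation-null expectation −1/(n−1) and the standard randomization
  variance, and the implementation is tested against an exhaustive
  double-sum oracle. One caveat worth knowing: with 8-NN weights a strict
  checkerboard is *not* negative (its four diagonal neighbours agree with
  the centre), so "dispersed" fields are diagnosed relative to the null
  expectation, not by sign alone. Whether to feed raw or deconvolved maps
  is exposed; the pipeline default is deconvolved.
* **Frozen diameter.** D = 2√(A/π) from the mask area, normalised by the
  mean fresh-cell diameter to give the volume-loss fraction.
* **C–H/O–H ratio.** Ratio of intracellular mean band integrals; rises as
  the interior dehydrates. Both this and the partition ratio are invariant
  to uniform detector gain, which the tests assert.

Cytochrome C release is reported only as its Moran's I value (plus group
statistics); no per-cell "released" boolean is invented, since the
original readout is distributional.

## Calcium responder analysis

Somata are local maxima of the Gaussian-smoothed temporal-maximum
projection, kept above the projection's Otsu threshold and separated by a
minimum distance (the brighter of two close maxima wins). Each soma ROI is
a disk of radius 2 px at the generator's scale — deliberately well inside
the soma core (Gaussian sigma 6 px) so the ROI mean dilutes a transient's
plateau by under 4 %. ΔF/F₀ uses the sample-background interpretation of
F₀: the time-averaged mean over the non-soma field, excluding a 20 px halo
around each soma so soma fluorescence tails do not inflate F₀.

A soma is a **responder** when the maximum first derivative of its ΔF/F₀
trace (forward differences × frame rate, no smoothing by default) exceeds
`threshold_factor` (default 1) times the largest first derivative observed
across a set of **background ROIs** extracted exactly like soma ROIs. The
set matters: soma and background ROI traces are exchangeable under pure
noise, so against m background records a non-responder exceeds the
threshold with probability ≈ 1/(m+1). One background trace would give 50 %
false positives at factor 1; the default m = 250 keeps the false-positive
rate well under 5 % while leaving an order-of-magnitude margin to a real
transient's derivative (rise time constant 0.5 s, typical of calcium
indicator onsets, gives a first-frame derivative of ≈1.5 × amplitude
per second at 4 frames/s). Whether "background" means ROIs or the whole
non-soma field is selectable in `extract_dff()`/`classify_responders()`.

## Synthetic data: what it emulates and what it does not

The Raman phantom builds a cube as a sum of Gaussian spectral bands scaled
by per-substance amplitude fields, blurred by the Gaussian PSF, with
additive Gaussian noise of sd `noise_level × √intensity` (a shot-noise
surrogate that avoids integer-count bookkeeping). The cell is a disk;
chunky ice grows as one central mass of exactly the requested area;
dispersed ice is a jittered grid of small crystallites with guaranteed
1-px gaps (disconnected under 4-connectivity), trimmed outermost-first to
the exact area — a deterministic crystallite model that keeps morphology
and total fraction independently controllable even at high coverage. The
amide I field is a Gaussian random field whose modulation depth and
correlation length both grow with the `protein_clustering` knob (0 gives
an exactly uniform field); the knob-to-Moran's-I mapping is validated
empirically as a rank correlation across the knob grid, not assumed.
Cytochrome C mixes mitochondria-like puncta with a dispersed component by
the `cytc_release` knob. The solute field is 1 inside the cell (0 on ice)
and `partition_ratio_true` outside.

The calcium generator places Gaussian-profile somata (baseline contrast 3×
background, as for indicator-loaded cells) on a jittered grid with 4-sigma
separation; responders follow a rising exponential of the requested
plateau amplitude from the stimulus time; pixel noise is white Gaussian.

Not emulated: spectral baselines and autofluorescence, cosmic rays,
realistic ice-crystal morphology, photobleaching, soma shape variability,
vendor file formats. Passing tests therefore demonstrate correctness of
the *measurement chain* under the stated forward model, not robustness to
every artefact of real instruments.

## Statistics layer

Two groups: two-tailed Student's t (equal variances). Three or more:
Shapiro–Wilk at α = 0.05 per group routes the family to pairwise t-tests
(the ANOVA-with-Bonferroni path) or, if any group looks non-normal or on
request, to Kruskal–Wallis with pairwise Wilcoxon rank-sum follow-ups.
All pairwise p-values are Bonferroni-adjusted with m = all pairs
(adjusted = min(1, m·p)); keeping one multiplicity rule across both paths
was a deliberate simplification. Binomial fractions get Wilson 95 %
intervals (well-behaved near 0 and 1, no continuity correction).

## Numerical and interface choices

* Coordinates are 0-free R conventions internally: row-major (y, x),
  masks as logical matrices; files use 8-bit label TIFFs for masks and
  32-bit float multi-page TIFFs for cubes/maps/movies. Float TIFF storage
  is only well-defined on [0, 1] in the `tiff` package, so files store
  affinely rescaled data with `intensity_scale`/`intensity_offset`
  recorded in the JSON sidecar and undone on read.
* All randomness flows through per-call seeds recorded in output sidecars;
  identical specs and seeds give bit-identical outputs, which the test
  suite asserts end to end (simulate → analyse → CSV, compared by MD5).
* Degenerate inputs fail loudly and specifically: constant maps
  (no Otsu threshold), empty cells, non-positive F₀ or intracellular
  solute means (a floor can be enforced instead), too-few pixels for
  Moran's I.

## Problem sizes used by the test suite

The acceptance-style tests run 50 phantom seeds per recovery setting
(ice fraction, partition ratios {1, 1.5, 2.4, 4}, shrinkage
{1.0, 0.85, 0.70}), 20 seeds per ice morphology, 20 full-length calcium
movies (740 frames, 160² px, 20 somata), 100 random Moran fields against
the brute-force oracle plus a 10,000-permutation null, and 2,000
null replicates per statistical path. `scripts/acceptance.R` reruns the
same measurements at moderately smaller batch sizes (20 seeds per setting,
8 movies, 1,000 replicates) chosen to keep a full from-scratch rerun
under a few minutes on one core; each reported value carries its n.

## Known limitations

Single cell per phantom field; concentration linearity is assumed, so
partition ratios are only as quantitative as that assumption; the chunky
threshold and annulus geometry are conventions (configurable) rather than
fitted; Moran's I significance uses the randomization variance, which is
approximate for very small masks — the permutation machinery in the tests
is the reference there; the calcium threshold constant is not printed in
any instrument protocol, so `threshold_factor` is exposed rather than
fixed.
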