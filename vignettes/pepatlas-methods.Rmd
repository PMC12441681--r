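---
title: "Methods: single-cell peptide mapping, colocalization and 3D atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell peptide mapping, colocalization and 3D atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pepatlas)
```

## Overview

`pepatlas` integrates two co-acquired views of the same tissue section: a
fluorescence microscopy image in which all peptidergic cells are labeled
(~1 µm pixels), and a MALDI mass spectrometry imaging (MSI) dataset
(~20 µm pixels, one spectrum per pixel, m/z 500–4500). Because the ganglion
neurons measure 5–14 µm, a single MSI pixel cannot resolve individual cells;
the microscopy layer supplies the cell geometry and the MSI layer the peptide
content. The pipeline is:

1. read imzML/ibd, TIC-normalize, extract one ion image per target m/z;
2. preprocess the fluorescence (8-bit conversion with percentile
   auto-contrast, rolling-paraboloid background subtraction), segment cells;
3. resample each ion image onto the microscopy grid through a rigid
   transform with bilinear (linear) interpolation and mask it to cell
   pixels — the per-peptide *mapping image*, quantized to 8 bit by the
   section-wise maximum;
4. binarize mapping stacks and compute pooled-area Tanimoto/Manders
   colocalization over all sections of an animal;
5. stack registered masks into voxel volumes and export STL isosurfaces.

## Models and key formulas

**Peptide masses.** Monoisotopic [M+zH]ᶻ⁺ m/z is
(Σ residue masses + 18.010565 + Σ modification deltas + z · 1.007276)/z,
with the standard 20-residue monoisotopic table. Fragment ions are singly
charged b (prefix + proton, N-terminal modifications applied) and y
(suffix + water + proton, C-terminal modifications applied); for every
internal position, b_i + y_(n−i) equals the neutral mass plus two protons,
which the tests assert exactly. MS/MS matching is greedy one-to-one by
ascending |ppm error| (ties: lower fragment index), with a default tolerance
of 500 ppm — chosen to accommodate the few-hundred-ppm accuracy typical of
reflectron MALDI-TOF fragment spectra while rejecting gross mismatches; it is
a plain argument, not a constant.

**TIC normalization** divides each spectrum by its intensity sum
(per-spectrum, the plain reading of "normalized by total ion count");
all-zero spectra are left untouched and reported. The normalization state is
a flag on the dataset so the operation cannot be applied twice.

**Ion images** sum all intensities with |m/z − target| ≤ tolerance (window
ends inclusive; default ±0.25 Da, configurable in Da or ppm, reflecting
reflectron-TOF peak widths at peptide masses). Sum—rather than max—matches
area-like semantics after TIC normalization and makes extraction linear in
the spectra, a property the tests exercise.

**Rigid registration.** A transform (dx, dy, θ, scale) maps moving-frame
physical coordinates (µm, relative to the image center, y downward) into the
fixed frame; θ is counter-clockwise as displayed and the rotation pivot is
the image center — self-consistent under inversion, which the
apply-then-invert test bounds at <2 % mean absolute error on smooth images
(bilinear smoothing is the only loss). Resampling maps each *output* pixel
center through the inverse transform and interpolates bilinearly; samples
outside the source are zero-filled and recorded in a validity mask so that
downstream statistics can exclude them. Constants are preserved exactly
inside the valid region. `estimate_transform` is an exhaustive normalized
cross-correlation grid search (optionally coarse-to-fine); correlation makes
the score invariant to affine intensity rescaling. The MSI grid is resampled
onto the microscopy grid (not vice versa), recorded in the output metadata;
this keeps cell geometry at full resolution.

**Background subtraction** is grayscale opening with a non-flat structuring
element of radius 25 px by default (the conventional setting for these
images): a sliding paraboloid z = −u²/(2r), which is separable and therefore
exact and fast, or a spherical ball cap. The result is clamped at the
opening, so it is never negative.

**Cell segmentation** thresholds the background-subtracted 8-bit image (Otsu
via EBImage by default, or a fixed cutoff), labels 8-connected components
(in-package labeling; the available library routine is 4-connected), and
keeps components whose equivalent diameter 2·√(area/π)·pixel_size lies in
[5, 14] µm — the published size range of these neurons. The defaults stand in
for an unpublished in-house procedure; every parameter is an argument.

**Mapping images** are the bilinear resample of an ion image masked to cell
pixels and scaled to 8 bit by the section-wise masked maximum (a global-max
mode exists for cross-section comparability). Full-pixel masking (rather
than sampling at centroids only) was chosen because it preserves intra-cell
gradients and makes the support-inclusion property exact.

**Colocalization.** Mapping images are promoted to 16 bit (×257, mapping
0→0 and 255→65535) and binarized. Two modes: the deterministic fixed
inclusive range 8400–65535 (default — it reproduces the published operating
range and is reproducible run to run) and the intermodes auto-threshold
(histogram down-binned to 256 levels, smoothed by a 3-bin running mean until
exactly two strict local maxima survive, threshold at the floor of the mode
midpoint, rescaled ×257; failure to become bimodal within 10 000 iterations
raises an error so callers fall back to the fixed range). Areas are pooled
over all sections of the stack *before* the ratios:

Tanimoto = O/(A + B − O), M1 = O/A, M2 = O/B,

so one coefficient describes a whole animal, not a mean of per-section
values. Two empty stacks give Tanimoto 0 by convention ("not colocalized" is
the conservative report); M1/M2 are NA when their denominator is zero. With
positive areas, 1/T = 1/M1 + 1/M2 − 1 holds to machine precision. The >0.6
rule of thumb for "colocalized" is descriptive, not a statistical test.

**3D atlas.** Registered per-peptide mask stacks become voxel volumes with
anisotropic spacing (z = 10 µm section thickness vs ~1 µm in-plane); vertices
are scaled, not resampled, to preserve the source data, and no inter-section
re-registration is applied by default (a hook exists). The isosurface is
marching tetrahedra: each voxel cube is split into six tetrahedra around its
main diagonal, which forces neighboring cubes to agree on face diagonals, so
the mesh is crack-free and — on zero-padded binary volumes — watertight, with
no ambiguous cases and no need for a large case table; triangle windings are
oriented outward by an inside-point test. STL output is binary (80-byte
header, 4-byte count, 50 bytes/triangle) or ASCII, and round-trips.

## The phantom generator

The synthetic ganglion emulates the study's data: an oval tissue (semi-axes
260 × 175 µm, tapering smoothly to 85 % at the first/last of 36 serial
sections to suggest a whole-organ stack), 50 non-overlapping cells per
section with diameters drawn inside 5–14 µm, three expression domains
(dorso-rostral, dorso-caudal, ventral; region assigned by cell position),
six peptide channels with per-region Bernoulli expression programs, one
ventral channel pair coupled with probability 0.9, per-cell lognormal
intensity (sd 0.3), a known rigid transform between the microscopy and MSI
frames, and additive Gaussian microscopy noise. All randomness derives from
one config seed; renders are byte-reproducible.

Two rendering choices deserve emphasis:

* **Transform-consistent MSI intensities.** Cells are far smaller than MSI
  pixels, so any forward model must decide what a pixel "sees". We choose
  per-channel pixel values such that bilinear readback at every cell
  position reproduces that cell's expression level exactly (the minimum-norm
  solution of the bilinear sampling system, clamped at zero). This is the
  forward model consistent with the pipeline's own linear-interpolation
  integration; a naive point-mass split would impose a sub-pixel geometry
  factor of 0.25–1 that no linear readback can undo.
* **Background-dominated TIC.** Every spectrum carries 400 random baseline
  peaks (exponential, mean 7.5) plus fixed matrix-cluster peaks, so the
  peptide signal is a few percent of the total ion count — as in real MALDI
  tissue spectra, where matrix and chemical background dominate. This keeps
  TIC normalization close to a constant rescaling, with ~5 % pixel-to-pixel
  variation, instead of letting co-expression load distort per-channel
  intensities.

What the phantom does **not** emulate: matrix crystal heterogeneity, isotope
envelopes, ion suppression between analytes, detector saturation, optical
point-spread beyond a 0.5 µm soft cell edge, section-to-section deformation,
and realistic fragment spectra. Passing the phantom suite therefore
demonstrates the correctness of the integration arithmetic and the
statistics under idealized physics, not instrument-level fidelity.

Cell diameters are drawn 1 µm inside the configured 5–14 µm bounds so the
soft-edged rendering keeps measured equivalent diameters within the
segmentation filter; packing enforces center distances of one (larger) cell
diameter plus 3 µm so adjacent soft discs do not merge under Otsu.

## Problem sizes and numerical choices

The end-to-end recovery test uses the study conditions — five seeds of
36 sections × 50 cells × 6 channels — and bounds the per-pair difference
between pipeline Tanimoto and ground-truth Tanimoto at |bias| < 0.1, with
co-expressed vs independent pair ordering preserved in ≥95 % of comparisons.
Unit-level properties run on smaller grids (64×64 registration phantoms,
12×12 random masks, 2×2 exhaustive enumerations). Degenerate inputs are
handled explicitly: constant images (auto-contrast → zeros; intermodes →
error), empty datasets/masks/volumes (errors or empty-flagged results as
documented), zero-TIC spectra (left as zeros, reported), and out-of-bounds
resampling (zero fill + validity mask).

imzML files are written in "processed" mode by default (per-pixel m/z axes)
with float64 arrays so round trips are lossless; "continuous" mode is
supported for shared axes. The UUID in the XML must match the first 16 ibd
bytes, and any declared array extending past the end of the ibd file aborts
the read — no partial datasets. An ibd SHA-1 is written when the digest
package is available.

## Limitations

* Registration is rigid only; tissue deformation between modalities is out
  of scope (the search is exhaustive NCC, robust but not sub-pixel).
* Touching cells are merged by the segmenter and then usually removed by the
  size filter; no watershed splitting is attempted.
* Colocalization is area-based (binary), not intensity-weighted; no
  permutation significance is computed.
* The per-section 8-bit maximum makes mapping intensities comparable within
  a section, not across animals, unless the global-max mode is used.
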