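---
title: "Median-smoothed-template alignment: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-smoothed-template alignment: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amst)
```

## The alignment problem

FIB-SEM acquires a volume slice by slice: the ion beam mills a few
nanometers off the block face and the electron beam images the freshly
exposed surface. Two independent error processes corrupt the resulting
stack. First, the field of view wanders slightly between slices
(translation jitter plus a slow cumulative drift). Second, periodic
auto-focus and auto-stigmation operations irradiate part of the imaging
surface, and the next slice is acquired with a locally altered effective
pixel size — an affine (scale/shear) distortion of individual slices that
no translation can undo.

Translation-only alignment strategies each fail in a characteristic way.
Slice-to-slice feature alignment preserves local structure but
accumulates its estimation errors into a long-range warp: straight
structures such as the flat, platinum-coated sample surface end up
crooked. Template matching against fiducial marks milled into the coating
preserves global morphology — the marks are straight lines along z — but
corrects nothing else, so the affinely distorted slices remain misaligned
away from the surface. Registering each slice affinely to its *neighbour*
is worse still: scale and shear errors then compound along z into a
systematic morphological trend.

The workflow implemented here escapes the dilemma with a fixed,
morphology-preserving reference:

1. **Pre-alignment**, translation only, by fiducial template matching
   (`align_tm()`) or slice-to-slice phase correlation
   (`align_feature()`).
2. **Template**: the pre-aligned stack is filtered with a median along
   the z-axis only (`compute_template()`, window 15 slices, no lateral
   mixing). Because a median ignores any minority of aberrant values,
   individually distorted slices are replaced by their neighbourhood
   consensus while in-plane content is untouched.
3. **Registration**: each *raw* slice is registered to its template
   slice with a full affine transform by mutual-information maximisation
   (`register_affine()`), and the raw data is resampled exactly once
   through the composed transform (`amst()`).

The per-slice transform follows the fixed-to-moving convention
\[
T_\mu(x) = A\,(x - c) + t + c,
\qquad \mu = (a_{11}, a_{12}, a_{21}, a_{22}, t_x, t_y),
\]
with \(c\) the image centre \(((W-1)/2, (H-1)/2)\) in 0-based pixel
coordinates; the aligned slice is \(I_M(T_\mu(x))\), the raw (moving)
image sampled through \(T_\mu\) with bilinear interpolation. Because each
slice depends only on its template slice, slices are processed
independently (and in parallel if requested) and the result is
deterministic regardless of processing order.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `median_window` | 15 | slices | z-median template window; a run of fewer than 8 aberrant slices cannot move it |
| `iterations` | 200 | – | gradient-descent cap per pyramid level |
| `bins` | 32 | – | joint-histogram bins of the MI metric |
| `pyramid_levels` | 3 | – | Gaussian pyramid depth (coarse to fine) |
| `presmooth_sigma` | 1.6 | px | Gaussian blur before any translation estimation |
| `coarse_init` | TRUE | – | phase-correlation translation step before the affine refinement |
| `tm_threshold` | 0.5 | NCC | below this peak score a template match is flagged low-confidence and interpolated from neighbours |
| `det_bounds` | [0.5, 2] | – | accepted `det(A)` of a final transform; violations fall back to translation only |

The defaults are the workflow's standard settings. The median window
should comfortably exceed the longest expected run of consecutive
distorted slices while staying shorter than the scale on which specimen
content changes; 15 slices at typical 5–10 nm slicing satisfies both by a
wide margin. The search window for template matching must stay smaller
than the spacing between repeated fiducial marks minus the largest
expected displacement, or the correlation can lock onto the wrong mark
(`align_tm()` defaults to twice the template extent; pass `search_radius`
explicitly when marks repeat closely).

## Numerical choices

**Mutual information.** 32-bin joint histogram with linear
(partial-volume) contributions: every pixel pair spreads its count over
the four neighbouring bins with bilinear weights, making the metric
piecewise-smooth in \(\mu\). Intensities are min–max scaled per image
before binning; only pixels whose warped sample falls inside the moving
image domain contribute. Values landing exactly on bin centres reproduce
the plain hard-binned histogram, which is what makes the closed-form test
values exact. MI is reported in bits.

**Optimizer.** Adaptive-step gradient ascent with central
finite-difference gradients on normalized parameters — matrix entries as
is, translations divided by the image extent, so one step unit moves
corners by comparable amounts for every component of \(\mu\). The step
grows by 1.25 after an accepted move, halves after a rejected one, and
the level terminates when it falls below `step_tol` (default `1e-5`,
about 2.5 milli-pixels at 256 px extent) or after `iterations` moves.
A 3-level Gaussian pyramid (blur \(\sigma = f/2\), subsample by
\(f = 4, 2, 1\)) provides the usual capture-range/precision trade-off.
Parameters are unconstrained during optimisation; the determinant sanity
check applies only to the final result, and a rejected slice falls back
to its translation-only initialisation with a warning — benign, because
the median template tolerates isolated aberrant slices.

**Translation estimation.** Hann-windowed phase correlation after
Gaussian presmoothing (\(\sigma = 1.6\) px), refined to sub-pixel
precision by a separable quadratic fit to the 3×3 neighbourhood of the
correlation peak. The contract is the translation estimate, not any
particular feature detector; phase correlation is deterministic and
dependency-free. The same estimator serves pre-alignment, the coarse
initialisation, and the evaluation metric, so the quality number measures
the alignment rather than a disagreement between two estimators.

**Template matching.** Exhaustive integer-grid normalized
cross-correlation over the search window, ties broken towards the search
centre (then smallest y, then x), followed by the same separable
quadratic sub-pixel refinement. Degenerate (zero-variance) templates or
windows are hard errors.

**Median boundaries.** At the stack ends the z-window shrinks to the
available slices rather than reflecting — reflection would double-weight
end slices, which are as likely as any to be distorted. Even-sized
shrunken windows take the *lower* median, preserving an actually observed
(integer) intensity. Background pixels introduced by the pre-alignment
participate at their fill value.

**Exactly one resampling.** The pre-alignment offset, the coarse
translation and the affine refinement are composed algebraically
(`compose_affine()`) and the raw slice is interpolated once. The test
suite verifies that a deliberately double-resampled variant is strictly
blurrier (mean gradient magnitude) while geometrically equivalent.

## The synthetic phantom

Real validation data for this problem would be a multi-gigabyte archive
download; the package instead ships a generator whose defaults are the
package's standard validation conditions: 64 slices of 256×256 at
5 nm/px (8 nm slicing), scale jitter ±1%, shear ±0.005, translation
jitter ±3 px, drift (0.2, 0) px/slice, every 10th slice an outlier at 4×
amplitude, Gaussian noise σ = 5 grey levels, seed 0. These exercise every
failure mode the method addresses at desk scale: local affine
distortions, periodic outliers, drift, and intensity noise.

The phantom volume is a band-limited 3-D Gaussian random field whose
zero level set becomes bright membrane-like ridges, beneath a flat dark
surface band carrying bright X-shaped fiducial marks at fixed (x, y) —
straight lines along z, exactly the reference structure that justifies
template matching. A dark margin above the band leaves room for the band
to move under distortion. The in-plane texture correlation length is
5 px; along z it is 8 slices, chosen so that specimen content is
coherent across the 15-slice median window, as real organelle-scale
structure is at nanometer slicing — with a much shorter correlation
length the median template would represent no slice at all, an artifact
of the phantom rather than a property of the method. Noise is added
*after* the geometric distortion, so registration must tolerate
non-identical intensities.

Outlier slices take the full 4×-amplified amplitude with random signs
rather than an amplified uniform draw: this makes the defining invariant
structural — every flagged slice's distortion strictly exceeds the
ordinary jitter bound, so flagged slices and only flagged slices produce
peaks in the displacement-error trace. The recorded ground truth stores
the *alignment* transforms (the inverse of each applied distortion),
which is what a perfect registration should recover, alongside the
distortions themselves.

What the phantom does *not* model: physically realistic SEM image
formation (charging, curtaining, detector noise statistics), z-thickness
variation, content-dependent distortion fields, or tile stitching.
Passing the synthetic suite therefore demonstrates correct recovery of
affine per-slice distortions under noise and drift — not robustness to
every artifact of real acquisitions.

## Quality evaluation

`evaluate_alignment()` implements the standard displacement-error
metric: crop a feature-bearing region (512×512 px, or the largest
centred square that fits), estimate the residual translation between
each pair of adjacent slices, and report its magnitude times the pixel
size, in nanometers. A well-aligned stack scores well below one pixel;
individually distorted slices appear as isolated peaks. Region choice is
deliberately manual (a judgment about where features support local
alignment); the phantom's default central region is feature-bearing by
construction. `trace_stats()` summarises a trace; `overlay_reslice()`
renders the classic red/cyan zy overlay of two alignments for visual
comparison.

For surface straightness on the phantom, the package tracks the fiducial
band by template matching on the aligned stack (`align_tm()` on the
result) and reports the range of its per-slice y-position. A fixed-window
row-profile correlation (`surface_profile()`) is also provided but is
reliable only on stacks without background fill at the canvas edge:
outlier slices leave fill rows after alignment, which biases a profile
window by up to a pixel even when the true geometric residual is a
fraction of that.

## Validation summary

The test suite validates each stage against independent oracles — a
brute-force per-voxel sort for the z-median, closed-form MI values and an
exhaustive MI grid search for the registration metric, constructed warps
with known parameters, and the generator's recorded ground truth for the
end-to-end run. At the default conditions the full workflow recovers the
per-slice transforms to a mean corner-displacement error below half a
pixel (about 2.3 nm at 5 nm/px) with the maximum below one pixel, versus
roughly 1.8 px for the translation-only pre-alignment; the
displacement-error trace drops from ~29 nm mean (peaks at the outlier
slices, above 60 nm) to ~0.5 nm; and the surface band stays straight to
within ~0.3 px where a feature-only pre-alignment wanders by more than
10 px. `scripts/acceptance.R` recomputes all of these from scratch.

Problem sizes throughout the suite (8×8×32 median stacks, 128² warp
recoveries, one 64×256² end-to-end run) are chosen so the whole
validation executes in a few minutes on a single core while still
exercising every code path at realistic parameter magnitudes.

## Known limitations

- The method corrects in-plane (x, y) distortions only; z-thickness
  variation is out of scope, as is any 3-D (volumetric) transform model.
- Runs of aberrant slices approaching half the median window defeat the
  template's outlier suppression; such stretches need manual curation at
  the pre-alignment stage.
- Drift correction is only as good as the pre-alignment: with
  feature-based pre-alignment the method inherits its accumulated drift
  (by design — the template must not invent a reference that is not in
  the data).
- TIFF (directories and multi-page) is the supported interchange format,
  with bit-exact round trips for 8/16-bit integer data; 32-bit float
  stacks must be scaled to [0, 1] for storage.
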