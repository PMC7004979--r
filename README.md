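# amst — alignment of FIB-SEM image stacks to a median-smoothed template

Serial-section electron microscopy (FIB-SEM) stacks suffer from two
kinds of misalignment: slice-to-slice translation jitter with slow
drift, and occasional slices whose effective pixel size is distorted by
the microscope's periodic auto-focus/auto-stigmation operations.
Translation-only alignment (fiducial template matching, or
slice-to-slice feature alignment) cannot correct the latter; naive
affine alignment of consecutive slices accumulates scale and shear
errors into long-range morphological distortion.

This package implements the three-step workflow that resolves both, for
microscopists and image-analysis pipelines working with volume EM:

1. **Pre-align** with translations only — by normalized cross-correlation
   template matching against fiducial marks in the sample's platinum
   coating (`align_tm()`), or by slice-to-slice phase correlation
   (`align_feature()`).
2. **Template** — median-filter the pre-aligned stack along z only
   (`compute_template()`, default window 15 slices). The median erases
   individually distorted slices while preserving in-plane morphology.
3. **Register** each *raw* slice to its template slice with a full
   affine transform by mutual-information maximisation, and resample the
   raw data exactly once (`amst()`).

Each per-slice transform is parameterised as

    T_mu(x) = A (x - c) + t + c,    mu = (a11, a12, a21, a22, tx, ty)

with `c` the image centre; the aligned slice is the raw (moving) image
sampled through `T_mu` with bilinear interpolation. Registration
maximises the mutual information of the 32-bin joint intensity
histogram by adaptive-step gradient descent (200 iterations per level of
a 3-level Gaussian pyramid), optionally initialised by a coarse
phase-correlation translation after Gaussian smoothing with
sigma = 1.6 px.

The package also provides the standard displacement-error evaluation
(`evaluate_alignment()`: residual local translation per slice
transition, in nanometers), red/cyan re-slice overlays
(`overlay_reslice()`), lossless TIFF stack I/O, and a seeded synthetic
phantom generator with exact per-slice ground truth
(`phantom_spec()`, `generate_phantom_volume()`, `distort_stack()`,
`recovery_error()`) so the whole pipeline is testable without any data
download.

## Worked example

Generate a distorted synthetic stack with known ground truth, align it,
and measure the recovery:

```r
library(amst)

spec <- phantom_spec()                  # 64 slices, 256x256, 5 nm/px, seed 0
vol  <- generate_phantom_volume(spec)   # undistorted ground-truth volume
dst  <- distort_stack(vol, spec)        # per-slice affine jitter + outliers
fp   <- fiducial_patch(vol, spec)       # fiducial template + true position

fit <- amst(dst$stack, "tm", template = fp$patch,
            template_position = fp$position, search_radius = 30)
print(fit)
#> <amst> 64 slices of 256 x 256 aligned to a median-smoothed template
#>   pre-alignment: tm;  median window: 15;  MI bins: 32
#>   |t|: mean 7.19 px, max 24.52 px;  det(A) in [0.9844, 1.0874]

re <- recovery_error(dst$truth, fit$transforms)       # vs ground truth
rp <- recovery_error(dst$truth, fit$prealignment)     # translation-only
c(amst = mean(re$error_px), prealign_only = mean(rp$error_px))
#>          amst prealign_only
#>     0.4586417     1.8057345
```

The affine refinement reduces the mean corner-displacement error from
1.81 px (translation-only pre-alignment, which cannot correct the
scale/shear jitter) to 0.46 px — 2.3 nm at 5 nm/px, below one pixel.
The displacement-error trace tells the same story in nanometers:

```r
st_raw <- trace_stats(evaluate_alignment(dst$stack))
st_fit <- trace_stats(evaluate_alignment(fit$aligned))
round(c(raw = st_raw$mean_nm, aligned = st_fit$mean_nm), 2)
#>     raw aligned
#>   28.73    0.48
```

Before alignment the trace averages ~29 nm with >60 nm peaks at exactly
the generator's flagged outlier slices (every 10th); after alignment it
averages ~0.5 nm with a 1.2 nm maximum. The fiducial band — a straight
line along z by construction — stays within 0.26 px of a straight
horizontal line across the aligned stack, while a feature-only
pre-alignment wanders by ~13 px (the classic crooked-surface artifact).

Real stacks enter through `load_stack()` (TIFF directory or multi-page
TIFF) and leave through `save_stack()`; a thin command-line wrapper with
`run`, `eval` and `simulate` subcommands ships at `inst/cli/amst.R`
(`system.file("cli", "amst.R", package = "amst")` once installed).

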