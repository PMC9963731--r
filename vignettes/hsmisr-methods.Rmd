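---
title: "Shift-and-add super-resolution for hyperspectral microscopy: models and methods"
author: "hsmisr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-and-add super-resolution for hyperspectral microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmisr)
```

## The measurement problem

A push-broom imaging spectrometer coupled to a light microscope captures one
spatial line times all spectral bands per exposure; the second spatial axis
comes from moving the motorised stage under the sensor. Because the stage can
be stepped far more finely than one pixel of the sensor's field of view, the
same histological field can be captured several times with deliberate
sub-pixel offsets. Multi-image super-resolution (MISR) exploits this: each
low-resolution (LR) frame samples the same scene on a slightly displaced
grid, and fusing the frames onto a finer grid recovers spatial detail that no
single frame contains. `hsmisr` implements the full chain — calibration,
sequence simulation, motion estimation, reconstruction and evaluation — for
hyperspectral (HS) cubes, with a bilinear interpolator (BI) as the
single-image baseline every result is compared against.

## Calibration

Raw push-broom counts mix the scene with the lamp's spectral profile and the
sensor's dark current. Both are characterised by reference captures taken
without a sample: a *white reference* (WR) of the bare light source and a
*dark reference* (DR) with the shutter closed. Both are L x W x B line
stacks (the instrument this models uses L = 100 lines) that are averaged to
a single 1 x W x B line each, because neither depends on the stage position;
the same line then calibrates every scan row of a cube:

$$CI(h, w, b) = \frac{RI(h, w, b) - DR(w, b)}{WR(w, b) - DR(w, b)}$$

Two numerical guards are applied. The denominator is floored at `denomFloor`
(default $10^{-6}$ of the white line's dynamic range) because halogen
illumination collapses in parts of the spectrum and WR can approach DR
there; floored elements are counted in the output metadata, and a cube whose
denominator floors *everywhere* is rejected as uncalibratable. Calibrated
values below zero — possible wherever sensor noise puts the raw count below
dark — are clipped to 0 (counted in `meta$clippedNegative`); values above 1
are left untouched, since nothing in the model bounds reflectance-like
ratios above.

## The observation model and the phantom

`generateSequence()` is the forward model the reconstruction inverts: select
a size x size window of a high-resolution cube at an anchor (the VHRI
reference), displace the window by integer HR-pixel shifts, and box-average
each displaced window by the escalation factor EF in {2, 4}. A +1 HR pixel
scene shift therefore appears as a -1/EF LR pixel *content* motion of the
frame relative to the reference, i.e. a half-pixel (EF = 2) or quarter-pixel
(EF = 4) frame motion. Labels are stored as exact integers in quarter-pixel
units (4 units = 1 LR pixel), with the sign convention fixed package-wide:
*labels store the content motion of the frame relative to the reference*, so
a scene shifted by $+k$ HR pixels is labelled $-4k/EF$ quarter-units. The
restoration stage undoes exactly this motion when depositing samples.

`defaultShiftPattern()` provides the capture pattern when none is given: a
deterministic clockwise ring walk from the origin that first visits one
representative of each of the EF^2 sub-pixel phases reachable at 1- and
2-pixel distances, then repeats phases at the skipped and larger offsets.
The visiting order within this constraint is the package's own choice — only
the coverage property (all phases, nearest offsets first, deterministic) is
load-bearing; any explicit shift list overrides it.

The synthetic phantom (`makePhantom()`) stands in for calibrated histology
fields so the entire pipeline is testable without instrument data. Band $b$
is built as

$$c_b\,\Big(1 + 0.25\,\big(\sqrt{\rho}\,S + \sqrt{1-\rho}\,Z_b\big)
  + 0.4\sqrt{1-\rho}\sum_k B_k\,(s_k(b)-\bar s_k)\Big) + \varepsilon$$

where $S$ is a shared field (band-limited Gaussian texture, correlation
length about 6 HR pixels, plus smooth elliptical "tissue" blobs $B_k$),
$Z_b$ are independent per-band smooth fields, $c_b$ a smooth positive
continuum, $s_k$ smooth per-blob spectral signatures and $\varepsilon$
additive Gaussian sensor noise. The mixing weights make `bandCorrelation`
$\rho$ the fraction of structured variance carried by the shared component,
so the first principal component captures roughly $\rho$ of the total
variance and the 65% sufficiency threshold for motion estimation (see below)
is met whenever $\rho \gtrsim 0.7$; at $\rho = 1$ every band is a scalar
multiple of the others up to noise. Defaults — 128 x 128 pixels, 16 bands,
6 blobs, $\rho = 0.9$, noise sd 0.01 (about 1% of the signal scale, matching
the near-Gaussian, band-uniform noise a cooled CCD shows after dark
correction) — are the study conditions used by the tests and the acceptance
script and were fixed once, up front.

What the phantom does **not** emulate: optical blur beyond box pooling,
spectral smile/keystone, stage positioning error (shifts are exactly
integral in HR pixels), compression artifacts, and the deeply non-Gaussian
texture statistics of real stained tissue. Passing tests on the phantom
therefore demonstrate correctness of the *algorithmic chain* under its own
observation model, not clinical image quality.

## Motion estimation

Band-wise contrast in HS microscopy varies wildly, so block matching runs on
a single synthetic band: the projection of every frame onto the first
principal component fitted on the *reference* frame (`fitPCABand()`,
`projectBand()`). The loadings are the first right singular vector of the
mean-centred pixels x bands matrix; `varianceRatio` is the leading
eigenvalue over the trace. A ratio below 0.65 — the level found sufficient
for sub-pixel estimation on pathology imagery — warns rather than errors,
since the projection may still be usable. The sign is fixed (largest
loading positive) for determinism.

The synthetic reference band is partitioned into non-overlapping
`mbSize` x `mbSize` macroblocks (default 16, the video-coding heritage
size); partial border blocks are dropped and the block grid is centred in
the image, so border blocks keep headroom for fractional resampling near the
edges — with corner-anchored blocks, negative sub-pixel displacements of an
edge block would leave the image and be unscorable. Each block is matched
into the frame band by full-search block matching: every integer
displacement in $[-r, +r]^2$ (default $r = 4$ LR pixels, comfortably above
the 1-2 HR pixel capture offsets) is scored by the sum of absolute
differences (SAD), skipping candidates whose window exits the frame. Ties
break deterministically: smaller Euclidean displacement first, then
row-major order. The integer winner is refined twice — its 8 half-pixel
neighbours, then the 8 quarter-pixel neighbours of that winner — with the
frame resampled bilinearly at fractional coordinates; bilinear is the
simplest interpolator consistent with the bilinear baseline used everywhere
else, and the SAD is non-increasing across rounds by construction.

Blocks whose variance is below $10^{-12}$ x (image dynamic range)^2 are
flagged *flat* and excluded from aggregation: untextured background would
otherwise vote (0, 0) spuriously. Because the stage motion is a single
global translation, the per-block vectors are reconciled by the
componentwise median over non-flat blocks (rounded to the nearest
quarter-unit, exact ties toward zero), which tolerates isolated mismatched
blocks; the fraction of blocks agreeing with the median is reported as a
diagnostic. An entirely flat frame is an error — motion is unobservable.

The matching direction is fixed: reference blocks are searched *in the
frame*, so the estimate directly reproduces the frame's content-motion label
under the simulator's sign convention.

## Reconstruction

`shiftAndAddBand()` deposits each LR pixel $(i, j)$ of frame $k$ at the HR
cell $(i\,EF - d_y EF/4,\; j\,EF - d_x EF/4)$ under the corner-anchored
mapping (LR sample $(i,j)$ owns HR cell $(i\,EF, j\,EF)$), used consistently
by upscaling, deposition and evaluation. For EF = 4 every quarter-unit
displacement is integral; for EF = 2 odd quarter-units fall between HR cells
and are rounded to the nearest cell (half-way ties round up) with a 0.5
weight penalty — rounding was chosen over discarding the frame to keep its
information while marking its positional uncertainty. The deposit weight is
1 for the reference frame and $1/(1 + \text{SAD}_k^{\text{norm}})$
otherwise, where $\text{SAD}_k^{\text{norm}}$ is the frame's mean winning
block SAD normalised by block area times the reference band's dynamic range.
This weighting is deliberately simple: monotone in match quality and
reducing to plain averaging when all matches are perfect; it is a pluggable
choice, not a calibrated model. Co-located deposits average by weight.

Cells that receive no deposit are *holes*. `fillHoles()` fills them with a
bilinear surface pass: per-row linear interpolation between the nearest
filled neighbours, blended (mean) with the per-column interpolation, nearest
value beyond the last filled sample; the pass repeats on the partially
filled grid (two passes always suffice, since after one pass every row and
column containing any sample is fully filled). Deposited cells never change.

The bilinear baseline `bilinearUpscale()` is *defined* as lattice deposition
of the single reference frame followed by this same hole-filling pass. The
blend of row- and column-interpolation reproduces the separable
corner-anchored bilinear surface exactly (the two passes agree analytically
at every cell, and the tests verify agreement with an independent two-pass
interpolation oracle to $10^{-12}$), and it makes the anchor identity — a
1-frame reconstruction *is* the bilinear baseline, bit for bit — hold by
construction rather than by numerical coincidence. This identity is the
degenerate end of the behaviour that reconstruction quality approaches
interpolation as frames are removed.

`superresolveCube()` loops the procedure over bands with the single shared
motion set estimated on the synthetic band, records per-band hole counts,
and preserves the wavelength axis.

## Evaluation

* **SSIM** — default is the standard 11 x 11 Gaussian-window (sigma 1.5)
  local form averaged over the valid map; the literal global-statistics
  variant is available as `window = "global"`. Constants $C_1 = (k_1 L)^2$,
  $C_2 = (k_2 L)^2$ with $k_1 = 0.01$, $k_2 = 0.03$.
* **PSNR** — $10 \log_{10}(R^2 / \text{MSE})$; identical bands return an
  `Inf` sentinel that `evaluateCubes()` excludes from averages and counts,
  because noiseless simulator runs legitimately reach MSE = 0.
* **SAM** — mean over pixels of the angle between reference and test
  spectra, reported in degrees (radians on request); the cosine is clamped
  to $[-1, 1]$ before `acos`, and all-zero test spectra contribute the
  maximum 90 degrees.
* **Scores** — `score1 = PSNR / SAM`; `score2` divides by runtime corrected
  by CPU and data-volume factors (both default 1, applying only to timings
  taken on foreign platforms).

For calibrated float cubes no data-type range exists, so both the SSIM
dynamic range $L$ and the PSNR peak $R$ default to the reference band's
max - min, per band; PSNR *gains* are unaffected by this choice since the
same $R$ enters both arms. Summary gains follow the conventions used for
reporting: SSIM gain as mean relative percent, PSNR gain as mean dB
difference.

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ef` | 2 | — | escalation factor; 2 and 4 supported |
| `mbSize` | 16 | LR px | video-coding macroblock heritage |
| `searchRange` | 4 | LR px | covers 1-2 HR px capture offsets with margin |
| `denomFloor` | 1e-6 x WR range | counts | guards WR ~ DR spectral gaps |
| flat-block threshold | 1e-12 x range^2 | — | excludes untextured blocks |
| `k1`, `k2` | 0.01, 0.03 | — | standard SSIM constants |
| `noiseSigma` | 0.01 | reflectance | ~1% of phantom signal scale |
| `bandCorrelation` | 0.9 | — | typical PC1 dominance of stained tissue |

## Problem sizes, determinism and degenerate inputs

The shipped checks run the phantom at 128 x 128 x 16 with 112 x 112
windows (LR frames 56 x 56 at EF 2, 28 x 28 at EF 4), 50 sequences for the
motion-recovery gate, 200 random instances for the search-oracle
equivalence, and N up to 24 for the saturation property — sizes chosen so
the whole chain is exercised in seconds while leaving several macroblocks
per frame. All randomness flows from explicit seeds: phantoms are
bit-reproducible given their spec, and the pipeline writes a version line
(package version, md5 of the canonicalised configuration, seed) into every
report. Degenerate inputs fail loudly and early: flat cubes cannot be
motion-estimated, all-hole grids cannot be filled, a frame whose deposits
all leave the grid is an error, and constant scenes round-trip the simulator
unchanged (motion is invisible on them, which the tests pin down).

## Known limitations

* Global 2-D translation only — no rotation, zoom or local motion; that is
  the instrument's geometry, not a general registration method.
* No deblurring: the forward model is box pooling, so the reconstruction
  sharpens sampling, not optics.
* EF = 2 cannot represent odd quarter-unit motions on its grid; the
  rounding-plus-downweighting rule is a documented compromise.
* The deposit weighting is a simple monotone heuristic; refined weighting
  schemes can replace it without touching the rest of the chain.
* MAT import is read-only and limited to plain numeric arrays (the common
  layout of public HS cubes); structs and cells are out of scope.
* On the phantom the SSIM/PSNR gains over bilinear interpolation are
  directionally consistent but numerically modest, because smooth synthetic
  texture is exactly the content bilinear interpolation handles best;
  sharper real-world texture is where shift-and-add pulls ahead.
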