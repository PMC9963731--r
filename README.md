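# hsmisr — multi-frame super-resolution for hyperspectral microscopy cubes

Push-broom hyperspectral microscopes can step their motorised stage far more
finely than one pixel of the sensor's field of view. Capturing the same
histological field several times with deliberate sub-pixel offsets turns a
hardware limit into a software problem: each low-resolution (LR) frame
samples the scene on a slightly displaced grid, and fusing the frames onto a
finer grid recovers spatial detail no single frame contains. `hsmisr` is an
R implementation of that pipeline for people working with hyperspectral
(HS) cubes — imaging scientists, digital-pathology groups, and anyone
benchmarking multi-image super-resolution (MISR) against single-image
interpolation.

## What the package computes

For a sequence of LR frames $y_k$ of one scene, each displaced by a global
sub-pixel motion $d_k$ (quarter-pixel resolution):

1. **Calibration** — raw counts are flat-fielded against averaged white/dark
   reference lines, $CI = (RI - DR)/(WR - DR)$, broadcast over scan rows.
2. **Sequence simulation** — a labelled LR sequence is generated from a
   high-resolution cube by window shifts + EF x EF box pooling (EF in
   {2, 4}), so ground-truth motion labels exist for validation; a synthetic
   phantom generator provides test scenes with controllable band
   correlation, blob signatures and sensor noise.
3. **Motion estimation** — all frames are projected onto the first principal
   component fitted on the reference frame (one high-variance synthetic
   band); 16 x 16 macroblocks are matched by full-search block matching
   minimising the sum of absolute differences (SAD), refined to half- then
   quarter-pixel by bilinear resampling, and reconciled to one global vector
   per frame by the componentwise median over non-flat blocks.
4. **Reconstruction** — *shift-and-add*: every LR pixel is deposited at its
   motion-compensated position on the EF-upscaled grid with a
   match-quality weight $1/(1+\mathrm{SAD}^{\mathrm{norm}})$; unfilled cells
   (*holes*) are interpolated by a bilinear surface pass. A 1-frame
   reconstruction is bit-identical to the bilinear baseline.
5. **Evaluation** — per-band SSIM and PSNR against the reference for the
   super-resolved cube and the bilinear-interpolation (BI) baseline, plus
   the mean spectral angle (SAM, degrees) and the composite scores
   `score1 = PSNR/SAM` and `score2 = score1 / (cf_cpu * cf_vol * runtime)`.

## Worked example

```r
library(hsmisr)

# phantom scene -> 8-frame EF=2 sequence -> estimate motion -> fuse -> score
report <- runPipeline(pipelineConfig(ef = 2, nFrames = 8, seed = 1))
report
#> MetricsReport: 16 bands | SSIM gain 0.48% | PSNR gain 0.252 dB | SAM 0.692 vs 0.728 deg

report$motionExact        # every estimated motion equals the simulator label
#> [1] TRUE
head(report$perBand, 3)
#>   band wavelength    ssimSr    ssimBi   psnrSr   psnrBi
#> 1    0        400 0.9556242 0.9481107 35.95381 35.59979
#> 2    1        440 0.9531405 0.9464894 35.00740 34.71706
#> 3    2        480 0.9598903 0.9534632 35.64703 35.36412
```

Reading the numbers: the 8-frame shift-and-add reconstruction beats bilinear
interpolation on **every** band (mean SSIM gain +0.48%, mean PSNR gain
+0.25 dB) and preserves spectra better (mean spectral angle 0.69° vs 0.73°
for the baseline). Motion recovery is exact at quarter-pixel resolution, so
fusing with estimated motions equals fusing with the simulator's ground
truth. Gains on the smooth phantom are deliberately conservative — bilinear
interpolation is at its best on smooth texture.

Lower-level entry points mirror the stages: `makePhantom()`,
`generateSequence()`, `fitPCABand()`/`estimateSequenceMotion()`,
`superresolveCube()`, `bilinearUpscaleCube()`, `evaluateCubes()`, plus
`readCube()`/`writeCube()` for ENVI and HDF5 cubes (MATLAB v5 import) and
`calibrateCube()` for white/dark reference calibration. A thin command-line
wrapper with subcommands `phantom`, `calibrate`, `simulate`,
`estimate-motion`, `sr`, `evaluate` and `pipeline` is installed at
`inst/cli/hsmisr.R`:

```sh
Rscript "$(Rscript -e 'cat(find.package("hsmisr"))')/cli/hsmisr.R" \
  pipeline --ef 2 --n 8 --seed 1 --out out/
```

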