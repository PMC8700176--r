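# prcnet

Convolutional positron-range correction for Ga-68 preclinical PET, as a
self-contained simulation-and-correction laboratory in R.

Ga-68 positrons travel a mean 3-D distance of about 3.5 mm before
annihilating, so Ga-68 PET images are blurred relative to the activity
map the scanner is trying to measure — a substantial resolution penalty
in small-animal imaging. `prcnet` builds the whole experimental loop for
studying CNN-based deblurring of this effect:

1. **Voxelized digital phantoms** — a procedural brain surrogate (4:1
   gray/white uptake, cold ventricles; translatable, rotatable,
   deformable), a five-rod cylinder (2/4/6/8/10 mm rods at 1.69e6 Bq/mL,
   target-to-background ratios 0–20), a cold-sphere cylinder, and a
   twenty-rod elliptical "hot-rod" phantom — 30 configurations in the
   default plan.
2. **An image-domain acquisition simulator** producing paired volumes per
   phantom: a *back-to-back gamma* image (no positron range; the
   reference/label) and a *Ga-68* image (range-blurred; the input). The
   expected image is `PSF ∗ (Range ∗ activity)` scaled by scan duration,
   sensitivity and voxel volume, with Poisson counting noise; the range
   kernel is isotropic with an exponential displacement-magnitude law of
   mean 3.5 mm.
3. **Patch datasets** — 32 × 32 input patches tiled over axial slices
   (stride 14 train / 21 test) paired with center-cropped labels, split
   at the phantom level (16/4 brains; rod5 TBR {0,4,5,8} train vs
   {2,10,16,20} test; sphere and hot-rod phantoms evaluation-only).
4. **Three valid-convolution networks** trained with momentum SGD
   (batch 128, lr 0.01, momentum 0.9, Xavier init, Euclidean loss):
   `CNN1` (3 layers, 9/1/5, 32→20), `CNN2` (4 layers, 7/5/3/3, 32→18)
   and `CNN3` (CNN2 with layer-wise dense connections and deeply
   supervised 1 × 1 heads). Backprop and the SGD engine are implemented
   in the package (R reference path + single-precision Rcpp/Armadillo
   engine); no external deep-learning framework is used.
5. **NU-4 style metrics** — whole-image RMSE and
   `PSNR = 20·log10(I_max/RMSE)`; per-rod recovery coefficients
   `RC = AVG_target/AVG_uniform` from axial line profiles; cold-sphere
   spill-over `SOR = AVG_cold/AVG_hot`; and their quadrature
   coefficients of variation, e.g.
   `CV_RC = sqrt((SD_target/AVG_target)² + (SD_uniform/AVG_uniform)²)`.

## Worked example

Simulate the cold-sphere phantom at desk scale and measure how the
positron range spills activity into the cold sphere:

```r
library(prcnet)

kern <- build_range_kernel(range_mean_mm = 3.5, voxel_size_mm = 0.8)
kern
#> <range_kernel> exponential law, mean 3.50 mm, support 24.8 mm, 63x63x63 taps

sph  <- make_sphere1_phantom(grid = phantom_grid(128, 60, 0.8))
pair <- simulate_pair(sph, acq_config(seed = 7), kernel = kern)

compute_sor(pair$gamma, sph)
#> <spillover_stats> (gamma) SOR 0.09503, CV_SOR 1.425
compute_sor(pair$ga68, sph)
#> <spillover_stats> (ga68) SOR 0.4063, CV_SOR 0.3077
compute_pair_stats(pair$gamma, pair$ga68)
#> <image_pair_stats> RMSE 25.36, PSNR 25.227 dB (V = 983040)
```

The gamma reference sees only the system PSF (SOR ≈ 0.10 at this voxel
size), while the Ga-68 image spills roughly four times as much activity
into the 10 mm cold sphere — the contrast a correction network is
trained to restore.

The full loop — phantoms → paired simulation → patch datasets → training
→ correction → evaluation — is one call:

```r
cfg <- run_config("runs/demo", seed = 1, preset = "desk",
                  architectures = "CNN1")
man <- run_pipeline(cfg)
man$metrics   # tidy table: family × variant × metric (× rod diameter)
```

The desk preset (128² in-plane grids at 0.8 mm, a reduced 10-phantom
plan, 2000 SGD iterations) runs in minutes on one CPU and writes
phantoms (NIfTI + JSON sidecars), image pairs, patch stores, model
checkpoints, a metrics report (JSON/CSV) and a reproducibility manifest
under the output directory. On the held-out phantoms the corrected
volumes show lower RMSE than the raw Ga-68 volumes, higher recovery
coefficients for the ≥4 mm rods, and a spill-over ratio between the
gamma and Ga-68 values. A thin CLI over the same functions is installed
at `inst/scripts/prcnet-pipeline.R`.

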