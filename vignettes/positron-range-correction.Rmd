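---
title: "Convolutional positron-range correction for Ga-68 preclinical PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolutional positron-range correction for Ga-68 preclinical PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prcnet)
```

## The problem

Ga-68 emits energetic positrons (mean energy 0.83 MeV) that travel a mean
3-D distance of about 3.5 mm in tissue before annihilating. A PET scanner
localizes the *annihilation*, not the decay, so Ga-68 images are blurred by
the positron-range distribution — a serious resolution loss for
small-animal scanners with sub-millimetre crystals. `prcnet` implements an
image-domain study of convolutional positron-range correction: networks
are trained to map Ga-68 images onto matched "back-to-back gamma" images
of the same object, i.e. simulated acquisitions in which both 511-keV
photons leave the decay voxel directly and no range blur exists. A
corrected image $I_{PRC}$ should move from $I_{Ga68}$ toward
$I_{\gamma}$.

## Forward model

Rather than full Monte Carlo photon transport and tomographic
reconstruction, the simulator works at image-domain fidelity:

$$\lambda \;=\; s \cdot T \cdot v \cdot \big(\mathrm{PSF} \ast
  (\mathrm{R} \ast a)\big), \qquad I \sim \mathrm{Poisson}(\lambda)$$

where $a$ is the activity-concentration map (Bq/mL), $\mathrm{R}$ the
positron-range kernel (omitted in gamma mode), $\mathrm{PSF}$ an isotropic
Gaussian system response, $v$ the voxel volume (mL), $T$ the scan duration
(s) and $s$ a sensitivity calibration (detected counts per decay). The
CNN method itself is agnostic to how the paired images arise; what
matters is that input and label differ exactly by the range blur plus
independent counting noise.

Key parameters and defaults (`acq_config()`):

* `range_mean_mm = 3.5` — mean 3-D annihilation displacement for Ga-68.
  The magnitude law is an exponential density
  $p(r) = \tau^{-1} e^{-r/\tau}$ with $\tau$ equal to the mean, emitted
  isotropically; a two-exponential mixture is available since empirical
  annihilation-point distributions have heavier cores and tails than a
  single exponential. The voxelized kernel groups voxels into one-voxel
  radial shells, gives each shell its analytic probability mass, truncates
  where the residual mass falls below 0.1% and renormalizes; it is
  radially symmetric by construction and sums to 1 within 1e-9.
* `psf_fwhm_mm = 1.5` — Gaussian system resolution, roughly what a
  2.3 mm-pitch BGO block detector reconstructs to.
* `scan_duration_s = 1200` — a 20 min emission scan.
* `sensitivity = 3.6e-4` — chosen so the five-rod phantom at 20 min
  collects on the order of 1e7 expected counts; a free calibration knob
  rather than a physically measured quantity.
* Convolution uses zero-padded FFTs; phantoms are constructed with margins
  comfortably larger than the kernel support, so edge mass loss is below
  0.5%. Noise is applied after all blurs.

## Phantoms

Four families on isotropic 0.4 mm grids (10 cm transaxial FOV; 80 mm
cylinders, 11.6 cm axial FOV for the brain):

* **brain** — a procedural brain surrogate: cortical shell and deep-nuclei
  blobs at relative activity 4, white matter 1, cold ventricles — the
  classic 4:1 gray/white uptake. Since the original voxel data of the
  physical brain phantom is not distributable, the surrogate is generated
  analytically; the networks only require structured, diverse activity
  maps. Each configuration applies an in-plane translation, an axial
  rotation and one of five mild affine deformations (exactly invertible,
  so phantoms are evaluated analytically in transformed coordinates and
  integer-voxel translations shift label masks exactly), with up to 1 mm
  of seeded jitter on structure positions. After transformation the map
  is rescaled to a total activity of exactly 3.7e6 Bq.
* **rod5** — 50 mm cylinder with rods of 2/4/6/8/10 mm at 1.69e6 Bq/mL;
  background at `rod / TBR`. `TBR = 0` is read as a cold background (hot
  rods on air/water), matching images of rods on a dark background.
* **sphere1** — the same cylinder with a 10 mm cold (water) sphere at its
  center.
* **rod20** — an elliptical cylinder (55 x 50 mm axes) with twenty rods in
  four diameter-grouped sectors (2/3/4/5 mm, five each); the 2 and 4 mm
  sectors are "white" (1.69e6 Bq/mL), the 3 and 5 mm sectors "gray"
  (8.44e5 Bq/mL). Rod positions are fixed package constants validated for
  overlap and bore containment; the exact layout is a design choice of
  the package, not a measured geometry.

The default plan enumerates 30 configurations: 20 brains (2 translations
x 2 rotations x 5 deformations), 8 rod5 (TBR 0, 2, 4, 5, 8, 10, 16, 20),
one sphere1 and one rod20.

## Datasets

Volumes are normalized by their global maximum (the scale is recorded and
restored after correction). Every axial slice is tiled with 32 x 32 input
patches on a deterministic raster — stride 14 for training, 21 for
testing — and each patch is paired with the center crop of its footprint
in the gamma volume (20 x 20 or 18 x 18, matching the network's
valid-convolution shrink). A deterministic strided grid is used rather
than random cropping so dataset sizes follow closed-form arithmetic; a
patch whose input window is identically zero carries no gradient signal
and is dropped. The phantom-level split holds out entire configurations:
brains split 16/4 (more generally 80/20 in plan order), rod5 TBR
{0, 4, 5, 8} train while {2, 10, 16, 20} test, and sphere1/rod20 are
evaluation-only and never patched.

## Networks

All convolutions are valid (no padding) to avoid border effects; hidden
activations are ReLU and the last layer is linear with one channel.

* **CNN1** — 3 layers, kernels 9/1/5, channels 64/32/1 (the shallow
  super-resolution architecture); total shrink 12, so 32 → 20.
* **CNN2** — 4 layers, kernels 7/5/3/3, channels 64/64/32/1; shrink 14,
  32 → 18.
* **CNN3** — the CNN2 backbone with layer-wise dense connections and deep
  supervision: the raw input and all earlier feature maps are
  center-cropped and concatenated into each later layer's input (under
  valid convolutions the spatial sizes shrink layer by layer, so
  crop-then-concat is the only consistent wiring; connections span all
  earlier stages), and each hidden stage feeds a 1 x 1 prediction head
  whose map is compared to the label. Head losses enter the objective
  with weight 0.3 each (a package default; configurable).

The kernel/channel configurations above are the minimal ones consistent
with the 32 → 20 and 32 → 18 output sizes and with the architecture
lineages these networks descend from (shallow super-resolution nets and
deeply supervised dense nets).

Weights are Xavier-initialized (zero-mean, variance
$2/(fan_{in}+fan_{out})$ with fans counted as kernel area times
channels); biases start at zero. Training is classical momentum SGD with
mini-batches of 128, learning rate 0.01 and momentum 0.9 under the
Euclidean loss. One numerical choice deserves emphasis: the training
objective is the batch RMSE itself, $\sqrt{\frac{1}{NK^2}\sum d^2}$,
whose gradient $d/(NK^2 \cdot RMSE)$ is self-normalizing — the effective
step adapts as the error shrinks, so the standard learning rate of 0.01 is
both stable and effective. The two plainer reductions are available as
options but behave worse at that learning rate: per-patch squared-error
sums carry the $K^2 = 400$ patch-area factor into the gradient and
diverge within tens of iterations, while the per-pixel mean squared
error is stable but converges several times slower at a fixed iteration
budget. `euclidean_loss()` reports the conventional mean-per-patch
summed squared error, a monotone transform of all three. No early
stopping, learning-rate schedule or augmentation is used; the iteration
budget is fixed by configuration.

Training runs in a single-precision im2col+GEMM engine with
double-precision master weights (bit-reproducible under a fixed seed,
exact no-op at zero learning rate, and segmentable for periodic test-loss
logging); a double-precision R implementation of the identical forward
and backward pass serves as the reference in gradient and consistency
tests. Whole-volume correction is slice-wise and fully convolutional:
slices are symmetrically padded by the half-shrink margin so output and
input shapes match, the volume-maximum scale is restored, and negative
intensities are clamped to zero.

## Metrics

Following a modified NU-4 style protocol, with the gamma image as
reference:

* RMSE over all voxels and $PSNR = 20\log_{10}(I_{max}/RMSE)$; $I_{max}$
  is taken from the *reference* image, which keeps PSNR comparable
  across corrections of the same object (configurable).
* **RC** per rod: the rod5 volume is averaged over the central 50 mm, the
  maximum-intensity pixel per rod anchors an axial line profile
  ($AVG_{target}, SD_{target}$), and a 10 mm ROI on the averaged sphere1
  cylinder provides $AVG_{uniform}, SD_{uniform}$;
  $RC = AVG_{target}/AVG_{uniform}$ and $CV_{RC}$ adds the two relative
  SDs in quadrature. The max search is restricted to the rod's label
  footprint dilated by one voxel; ties break to the smallest (row, col).
  On short desk grids the 50 mm window clamps to the available axial
  extent.
* **SOR**: in the sphere-center slice, a 10 mm ROI on the cold sphere
  versus a 10 mm ROI on the cylinder; $SOR = AVG_{cold}/AVG_{hot}$, with
  the quadrature $CV_{SOR}$. The hot/uniform ROI center is a fixed
  constant: on the cylinder at half its radius (+x direction from the
  centered sphere). A pixel belongs to an ROI when its center lies within
  the radius; when $AVG_{cold}$ is exactly zero $CV_{SOR}$ is flagged
  undefined rather than propagating NaN.

## Desk preset and what the tests show

The `desk` preset runs the entire pipeline on one CPU in minutes:
128 x 128 in-plane grids at 0.8 mm voxels (60 slices for cylinders, 150
for the brain so its full geometry fits), a reduced plan (five brains,
rod5 TBR {0, 5, 10}, sphere1, rod20; split: four brains + TBR {0, 5}
train, one brain + TBR 10 test) and 2000 SGD iterations of CNN1 —
roughly 28k training patches. Under these conditions the package
reproduces the directional findings: corrected volumes have lower RMSE
and higher PSNR against the gamma reference than the raw Ga-68 volumes;
recovery coefficients of the larger rods rise after correction; the cold
sphere's spill-over ratio falls from the Ga-68 value toward (but not
below) the gamma value; and the CV terms do not blow up. The `full`
preset (0.4 mm grids, 30 configurations, long training) exposes the
complete study conditions but is not exercised by the test suite.

The synthetic data emulates positron-range blur, system resolution and
counting noise, but not attenuation, scatter, randoms, detector-block
geometry or iterative-reconstruction artifacts. Passing tests therefore
demonstrate that the training/correction machinery inverts the modeled
degradation on held-out objects — not that the learned filters transfer
to a physical scanner.

## Degenerate inputs and numerical conventions

Zero-activity phantoms simulate to all-zero images with a recorded
warning; all-zero volumes normalize with scale 1; a sub-voxel mean range
degenerates the kernel to a discrete delta; FFT round-off negatives are
clipped before the Poisson draw; reflect padding at inference is
edge-inclusive symmetric. Sub-seeds for every stage derive
deterministically from one global seed, so reruns are bit-identical,
noise included.

## Known limitations

* The brain surrogate is anatomically schematic; it exists to give the
  networks diverse structured gradients, not to model a specific atlas.
* CNN1 at desk scale leaves the 2 mm rod essentially unrecovered (its RC
  can even drop slightly) — shallow networks recover little at sizes near
  the blur scale.
* Quantities that depend on full Monte Carlo transport and full-scale
  training (absolute RMSE/PSNR levels, exact RC/SOR values) are not
  reproduced numerically; only their orderings and directions are
  asserted.
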