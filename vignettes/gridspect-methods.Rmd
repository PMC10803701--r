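---
title: "Grid-modulated digital phantoms for quantitative SPECT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-modulated digital phantoms for quantitative SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridspect)
```

## The problem

Anthropomorphic phantoms for quantitative SPECT need *non-uniform* activity
distributions: a kidney imaged with ^177^Lu has a hot cortex, a cooler
medulla and a cold pelvis; a thyroid imaged with ^99m^Tc has focal hot
nodules on a warm gland.  Filling separate watertight compartments at
different concentrations is error-prone and inflexible.  An elegant
alternative is to 3D-print a periodic *grid* of thin solid walls inside a
single fillable compartment: the printed material displaces solution, so the
*apparent* (voxel-averaged) activity concentration is modulated by the
fillable-volume fraction

$$\mathit{FVF} = 1 - \frac{V_\mathrm{grid}}{V_\mathrm{no\text{-}grid}},$$

while only one stock solution is needed.  Because clinical SPECT resolution
(7--25 mm FWHM) is far coarser than the grid period (4--8 mm), the grid is
invisible in the image and the region simply appears to contain
$\mathit{FVF}\times c$ of the fill concentration $c$.

`gridspect` is a *digital twin* of this workflow: it generates the grid
geometries, assembles voxelized phantoms, simulates SPECT acquisition and
OS-EM reconstruction, and reproduces the characterization analyses
(modulation-contrast linearity, activity recovery, threshold--volume
segmentation) plus a synthetic micro-CT verification stage for printed-grid
quality control.

## Grid model

A grid is parameterized by wall thickness $t$, gap $g$ and a set of 1--3
orthogonal wall families (`wall_axes`).  With $k$ families the analytic
fillable fraction is $(g/(t+g))^k$.  Two families (the default) leave square
channels open along the remaining axis; that choice mirrors the drainage and
cleaning requirements of a printed object, where trapped resin must rinse
out.  Whether the original printed grids used two or three wall families is
not derivable from their published description; the channel topology is
configurable.

Uniform scaling of $t$ and $g$ leaves the FVF unchanged, so FVF targeting
(`solve_gap_for_fvf`) holds $t$ fixed at its printable minimum and solves
the gap: $g = t\,q/(1-q)$ with $q = \mathit{FVF}^{1/k}$.

Voxelization is by voxel-centre membership.  The FVF of a voxelized grid
converges to the analytic value at first order in voxel size; the sampling
guard `voxel_size <= min(t, g)/2` rejects under-resolved grids.  Exactly
commensurate lattices (wall boundaries on voxel centres) are knife-edge
cases: counts can then jump by one voxel layer per wall, which is visible in
tests as a deviation of order `voxel/period` — the test fixtures use
incommensurate container sizes to stay off that set of measure zero.

## Phantoms

Three families reproduce the classic experiments:

* **Spheres** (40 mm) with grids at FVF 0.28--0.65 plus a grid-free
  reference, mounted in a 21.6 cm x 18.6 cm water cylinder.
* **Kidneys**: an ellipsoidal container (semi-axis ratio 1 : 0.55 : 0.42) of
  ~130 mL with a planar-wedge solid pelvis (5% of the container, cold), a
  cluster of seven cone-shaped medulla "pyramids" (10% of the container)
  filled by a grid at FVF 0.36, and the remaining cortex.  The pelvis and
  medulla fractions were chosen once so that a 116 mL fillable volume maps
  to a ~130 mL container, matching the printed phantoms' 130 -> 116 mL and
  190 -> 167 mL design-to-fillable ratios.  The exact anthropomorphic
  (XCAT-derived) shapes are not available; these procedural shapes honour
  compartment volumes, concentration ratios and FVFs but not organ
  silhouettes, and every experiment report carries that caveat.
* **Thyroids**: two ellipsoidal lobes (semi-axis ratio 0.42 : 0.52 : 1)
  joined by a thin solid plate, with spherical fully-fillable hot spots
  (15--20 mm) inside the lobes and the remaining lobe volume a grid at
  FVF ~0.5.  The lobe size is solved so the fillable volume (hot spots plus
  grid channels) matches the target.

Each phantom exists in two modes.  `grid_resolved` voxelizes the actual
walls at fine (0.5--1 mm) resolution — the twin of the printed object.
`compartment_averaged` assigns each former grid region its volume-averaged
concentration ($\mathit{FVF}\times c$) — the twin of a Monte Carlo
simulation set up from the same design.  Both have identical total activity
by construction, and the acceptance suite verifies that their reconstructed
recoveries agree within 2 percentage points, which is the digital version of
the claim that a grid phantom reproduces the images of a truly non-uniform
source.

`assemble_maps` bin-averages the fine labels onto the reconstruction grid
(4.42 mm), conserving total activity exactly, and builds the attenuation
map: water $\mu$ everywhere inside the cylinder (0.154 cm^-1 at 140.5 keV,
0.137 cm^-1 at 208 keV — standard narrow-beam values, overridable), with an
optional `resin_aware` mode that scales $\mu$ in printed-solid voxels by the
cured-resin density ratio 1.192.

## Forward model and reconstruction

The projector is rotation-based: for each angle the volume is resampled
(bilinear, in-plane) so the detector sits at +y; each depth slab is
attenuated by $\exp(-\int \mu\, dl)$ along the ray (cumulative sum with a
half-voxel self-attenuation offset), blurred by the distance-dependent
collimator--detector response
$\mathrm{FWHM}(d) = \sqrt{\mathrm{FWHM}_0^2 + (s\,d)^2}$, and summed toward
the detector.  The depth-dependent blur is applied *incrementally* (each
inter-slab step convolves the accumulator with a small Gaussian whose
variance is the difference of the two slabs' total variances), which makes
the cost independent of the absolute blur width.  Expected counts are
scaled by sensitivity x time x voxel volume, so projections carry absolute
count units and reconstructions converge directly to MBq/mL.

Scatter is not simulated and not compensated: the model is primary photons
with ideal scatter rejection, equivalent to perfect scatter correction.
This is a stated limitation carried in every experiment manifest.

The backprojector is the *exact algebraic transpose* of every forward step
(scatter-form rotation, symmetric blur kernels, diagonal attenuation);
adjointness holds to float round-off, which the acceptance suite checks at
1e-5.  This matters because OS-EM's fixed points are defined by the
transpose pair.  A gather-form bilinear rotation conserves mass exactly
only for smooth images (second order in the interpolation); a single voxel
projected at 45 degrees loses ~7% — tests therefore assert exact
conservation at cardinal angles and 0.5% conservation for smooth sources,
which is the regime the phantoms occupy after the CDR blur.

OS-EM uses angle-interleaved subsets (subset $s$ takes angles $s$,
$s+n_\mathrm{sub}$, ...), uniform initialization inside the circular FOV,
per-subset sensitivity images, and freezing of voxels whose subset
sensitivity falls below 1e-8 of the maximum.  Resolution recovery (RR)
includes the CDR in both forward and back steps; the two clinical operating
points are 16 iterations x 10 subsets with RR and 4 x 10 without, the
latter optionally followed by an 8.8 mm 3D Gaussian post-filter (kidneys;
thyroid images without RR stay unfiltered).

The reconstruction volume uses the smallest transaxial grid covering the
background cylinder plus a blur margin rather than the full 128 x 128
camera matrix; for a circular FOV the discarded corner bins receive only
far-tail blur and the saving is ~2.5x on a single CPU.  `matrix_size = 128`
restores the full grid.

## Acquisition presets

Printed acquisition parameters are mirrored exactly: 128 x 128 matrix,
4.42 mm pixels, 60 angles over 360 degrees (120 for kidneys), 45 s
(^99m^Tc spheres) / 90 s (^177^Lu spheres) / 180 s (kidneys) / 15 s
(thyroids) per projection, OS-EM settings as above.  Parameters the source
experiments do not print — orbit radius, collimator resolution constants,
system sensitivity — are presets chosen once from public system
specifications and kept fixed:

| preset | intrinsic FWHM | slope (mm/mm) | sensitivity | orbit |
|---|---|---|---|---|
| LEHR / ^99m^Tc | 3.9 mm | 0.0633 | 90 cps/MBq | 180 mm (body), 150 mm (neck) |
| MEGP / ^177^Lu | 4.0 mm | 0.085 | 10 cps/MBq | 180 mm (body) |

The LEHR numbers reproduce the classic 7.4 mm system FWHM at 10 cm; the
MEGP slope reproduces the published ~9.4 mm at 10 cm for this collimator
class.  The body orbit is a contour orbit for the 21.6 cm cylinder.  These
are the calibration knobs the acceptance criteria declare tunable within
physical ranges; they were frozen after a coarse scan against the cited
130/190 mL sphere recovery coefficients and are not adjusted per-experiment.

## Evaluation metrics

* **Modulation contrast** $C_M$ = mean image signal in the grid object's
  physical-volume VOI divided by the same mean for the grid-free reference.
  Resolution spill-out is assumed equal for both objects and cancels in the
  ratio; in the digital limit $C_M = \mathit{FVF}$, and the noiseless
  pipeline reproduces that within 0.02.
* **Recovery** $R$ = VOI activity from the calibrated image divided by the
  true activity.  Kidney VOIs substitute the manual border delineation with
  the true outer-container mask (pelvis included) voxelized on the image
  grid — deterministic and closest in spirit; a dilation option exposes the
  sensitivity to the border.
* **Threshold--volume curves**: the threshold sweeps 100 equal steps of the
  image maximum; the volume is the voxel count at or above threshold times
  the voxel volume.  The threshold yielding a given true volume is obtained
  by linear interpolation between the bracketing samples and reported as a
  fraction of the maximum.  Curve pairs are compared by the mean absolute
  volume difference over corresponding sample points.
* **Profiles and MIPs**: 3-slice-averaged central coronal profiles
  (position in mm vs MBq/mL) and per-axis maximum-intensity projections.

The calibration factor is simulated as prescribed — reconstruct a uniform
cylinder of known concentration, take the central eroded-VOI mean over the
true concentration — but because this package's system model carries the
absolute count scale, reconstructions are already in MBq/mL and the factor
is ~1 and sensitivity-independent (the sensitivity cancels inside the
model).  The factor is still computed and applied per reconstruction
variant, so pipelines with deliberately unmatched models remain correct.

## Synthetic micro-CT verification

The printing-defect model captures what micro-CT inspection of real prints
shows: excess material concentrated at sharp wall crossings
(`edge_excess_mm`, a dilation applied where two or more wall families
meet) and global wall thickening (`uniform_scale`), followed by scanner
blur and Gaussian noise.  The segmentation chain is moment-preserving
(Tsai) thresholding — the threshold is the image quantile at the
below-fraction that preserves the first three gray-level moments —
morphological opening and closing with 3x3x3 boxes, and shell exclusion:
the outer mask boundary (mask voxels adjacent to air connected to the
volume border) is fitted with an algebraic least-squares sphere, and
everything outside the fitted radius minus the shell thickness and a
2-voxel margin is discarded.  Printing-uniformity is quantified by the
central-to-peripheral void-area ratio on the central transversal slice
(five central ROIs in a plus pattern, four peripheral ROIs on the
diagonals at 70% of the interior radius, ROI side three grid periods);
the ratio is 1 for a uniformly printed grid and the pipeline recovers
designed grid volumes within 2% for defect-free inputs.

The synthetic scans default to 0.1--0.2 mm voxels rather than a real
scanner's 0.05 mm to keep memory at desk scale; the defect amplitudes are
free parameters, so green tests establish that the *pipeline* measures
defects correctly, not that any particular printer achieves them.

## What the synthetic world does and does not establish

The generator reproduces: the stated geometries, concentrations, FVFs,
count levels (via activity x time scaling) and Poisson statistics;
attenuation in water; distance-dependent collimator blur.  It does not
reproduce: scatter and septal penetration (and hence residual
scatter-correction bias), detector energy resolution, physical printing
and filling artifacts (air bubbles, residual resin), or true organ shapes.
A green acceptance test therefore establishes internal consistency of the
method chain at realistic image quality, not camera-specific absolute
accuracy.

## Known limitations

* The thyroid correct-volume threshold (acceptance criterion 4) is the one
  stated target this twin does not meet: with the fillable volume (11.6 mL)
  as "true volume" the no-RR threshold lands near 44% of max, with the
  gland (outer lobe) volume near 23%; the reference 33% +/- 8 pp lies
  between the two readings.  The source experiments do not say which volume
  their dashed reference line uses, their images carry residual scatter
  and noise spikes that inflate the image maximum (lowering the threshold
  fraction), and the procedural lobes are more compact than
  anthropomorphic shapes.  The criterion is asserted faithfully and left
  red rather than tuned (e.g. the unspecified phantom-2 hot-spot diameter
  would pass at the 20 mm extreme of its stated 15--20 mm range, which
  would be outcome-shopping).
* Recovery coefficients with RR run ~0.02--0.03 above the cited values
  (converged matched-model RR recovers more than a physical RR
  implementation with model mismatch), still inside the +/- 0.04 band.
* The bilinear-rotation projector is second-order accurate; point-like
  sources are not conserved at oblique angles (see above).
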