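---
title: "Trabecular bone morphometry across CT modalities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular bone morphometry across CT modalities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabmorph)
```

## The measurement problem

Trabecular bone — the sponge-like interior compartment of the skeleton —
carries much of a bone's mechanical strength, and its microstructure changes
early in osteoporosis. The reference technique for quantifying that
microstructure *in vitro* is micro-CT, but micro-CT cannot image a patient.
Clinical multislice CT, whether with conventional energy-integrating
detectors (EID-CT) or the newer photon-counting detectors (PCD-CT), can — at
the price of voxels comparable in size to the trabeculae themselves
(≈ 0.1 mm), strongly anisotropic slice profiles, and more noise. The question
this package is built around is how faithfully structure parameters measured
on such degraded acquisitions track the micro-CT reference, and it provides
both the measurement pipeline and a simulation harness to study that
question on synthetic specimens with known ground truth.

The pipeline computes, for one segmented volume, the parameter set standard
in bone morphometry:

* **BVTV** — bone volume over total volume: the fraction of voxels segmented
  as bone in the analysed volume of interest.
* **Tb.Th** — trabecular thickness (mm), by sphere-fitting local thickness.
* **Tb.Sp** — trabecular separation (mm): the same local-thickness transform
  applied to the inverted mask (edge-to-edge gaps).
* **Tb.Sc** — trabecular spacing (mm): local thickness of the complement of
  the bone *skeleton*, i.e. midline-to-midline distances. Tb.Sc is the
  reciprocal of the more common trabecular number Tb.N; it is used here
  because it shares its unit with Tb.Th and Tb.Sp, which eases comparison.
* **Tb.Nd** — trabecular node density (1/mm³): skeleton voxels classified as
  network intersections, divided by the analysed volume.
* **s(Tb.Th), s(Tb.Sp), s(Tb.Sc)** — intra-volume dispersions: the
  population standard deviation of each 3D local map over its support.
* **CNR** — contrast-to-noise ratio: (mean bone − mean background intensity)
  / background intensity SD, both sampled on skeletonised representations so
  that partial-volume voxels at the bone–water interface contaminate neither
  sample.

## Local thickness: definition and numerical conventions

`local_thickness()` implements sphere-fitting local thickness: the value at a
foreground voxel `p` is the diameter of the largest sphere entirely inside
the structure that covers `p`. Numerically, the squared Euclidean distance
transform (computed exactly with the separable lower-envelope algorithm)
gives each voxel `q` the distance `r(q)` to the nearest background voxel
centre; spheres are then marked in order of decreasing radius, coverage being
decided at voxel centres (`||p − q|| < r(q)`), and the map records the
largest covering diameter `2·r(q)`.

Two conventions deserve to be stated explicitly because digitization makes
them visible at phantom scale:

* **Thickness is `2·EDT`**, the convention of the standard sphere-fitting
  implementations. A plate two voxels thick reads exactly two voxel widths
  (0.10 mm at 50 µm); a slab an odd number of voxels thick reads one voxel
  too wide (a 3-voxel slab reads 4 voxels), the well-known odd-width
  digitization bias of the method.
* **The volume faces are background.** The distance transform is capped by
  the distance to the first voxel layer outside the grid. Analysed volumes
  are interior crops of a larger specimen; without the cap, structures and
  gaps touching a face read up to twice too thick because no opposing
  surface is visible. The same border policy is used by the skeletonizer.

Local thickness requires isotropic voxels and refuses anisotropic input;
`analyze_scan()` resamples anisotropic acquisitions (cubic interpolation, to
the coarsest spacing component by default) before measuring, mirroring the
workflow of downsampling fine in-plane grids to the slice increment.

Tb.Sp is definitionally `local_thickness(!mask)` — the tests assert map
identity. Tb.Sc applies the same transform to the complement of the
skeleton; when the skeleton is a single structure with no intersections,
there is no neighbouring midline, the value is governed by the domain size,
and the function warns.

## Skeletonization and node counting

`skeletonize()` is a sequential, topology-preserving 3D thinning on the
standard 26/6 connectivity pairing. Each pass runs six directional
subiterations in a fixed order; candidates are marked on a snapshot (border
voxel in the current direction, not a curve endpoint, not a sheet point) so
that one subiteration removes at most one voxel layer, and each candidate is
deleted only if it is still a *simple point* at the moment of deletion
(foreground 26-components and adjacent background 6-components both equal to
one in its punctured neighbourhood). The component count of the mask is
therefore conserved exactly.

The retention rules make this a medial-surface-class skeleton: rod-like
structures thin to one-voxel curves, and plate-like structures thin to
one-voxel sheets rather than eroding onward to curves. A *sheet point* is a
voxel whose foreground neighbours are confined to the central plane of its
3×3×3 neighbourhood and whose in-plane configuration looks like the rim,
interior or corner of a wide sheet (a tangent direction with foreground on
both sides plus a two-voxel-deep inward continuation, or two perpendicular
two-voxel-deep continuations). Two-voxel ribbons and one-voxel strands fail
the test, so leftovers from thinning rods keep collapsing to single curves
while genuine sheets are stable. All retention rules are functions of the
current state and the loop runs to a fixed point, which makes the operation
deterministic and exactly idempotent. Known biases, visible in the tests and
accepted: oblique (non-axis-aligned) sheets erode more than axis-aligned
ones; a junction of three orthogonal arms through a single voxel is simple
and gets rearranged into a small diagonal triangle of junction voxels; rods
of even width thin to an off-centre curve.

A skeleton voxel is classified as a **node** when its 26-neighbourhood
skeleton voxels split into at least three branches, where branches are
connected components under 6-adjacency among the neighbours — two branches
that merely touch diagonally remain distinct. The naive "≥ 3 neighbours"
rule is not usable: in a "+" cross of two one-voxel lines, the first voxel
of each arm is diagonally adjacent to the perpendicular arms and has four
neighbours, so the naive rule reports five node voxels where there is one
intersection. The branch-count rule gives a straight or diagonal line 0, a
"+" cross exactly 1 (its centre), a planar "Y" 1, the interior and edges of
a one-voxel sheet 0, and one node voxel per junction of one-voxel curves.
Adjacent node voxels are *not* merged for Tb.Nd — the count is of voxels —
but on the rod-lattice phantom each junction thins to exactly one
26-connected node cluster; clusters span roughly one to five voxels at 50 µm
(the documented tolerance of voxel-count node density), while cluster counts
recover the junction count exactly.

## Segmentation

Reference-quality (micro-CT-like) volumes are segmented with **Otsu's
method**: 256 equal-width histogram bins over [min, max], exhaustive
maximization of the between-class variance, ties broken toward the lower
threshold, bone being the high-intensity class (`intensity ≥ threshold`).
The binning rule makes the mask invariant under any increasing affine
intensity transform.

Clinical-like volumes are segmented with an **automated region-growing
(ARG)** algorithm requiring no manual interaction: seeds are the voxels
above the 99.9th intensity percentile (safely inside bone); the region is
grown from the seeds with 26-connectivity over a descending sweep of
candidate thresholds (48 by default) between the seed level and the volume
minimum, each level scored by the *mean intensity-gradient magnitude over
the region surface*. While the region boundary rides the bone–water
interface this surface gradient is high and nearly constant; once the
threshold drops into the background noise, grown fringes and finally
percolation move the boundary into flat background and the gradient
collapses. Growth is accepted while the boundary still sits on that
high-gradient shell: the accepted threshold is the *lowest* sweep level
whose boundary gradient remains at least 90% of the sweep maximum
(`shell_fraction`). Sweep levels whose region covers most of the volume
(fraction ≥ 0.9) or has no interior boundary are excluded from selection.
On noise-free, separable two-class volumes ARG reproduces the Otsu mask
exactly; on the noisy plate phantom (contrast 1000, noise SD 100) it
recovers the bone fraction within 0.02. Two alternatives were examined and
rejected on measured sweep profiles: selecting the largest relative *drop*
of the boundary gradient fires at the percolation collapse (a threshold
deep inside the noise, overestimating the plate-phantom bone fraction
several-fold beyond tolerance), and selecting the gradient *argmax* picks
the most conservative edge point, whose location wanders between local
maxima on blurred trabecular volumes — per-specimen bone-fraction estimates
then scramble specimen ranks (Spearman against the reference modality
0.85–0.96 across cohort seeds, versus ≥ 0.97 for the shell rule, which also
reproduces the partial-volume *over*estimation of clinical modalities that
conservative edge thresholds miss). Because seeds, sweep levels and
gradients are all affine-equivariant, the ARG mask is invariant under
increasing affine intensity maps. Optional Gaussian pre-smoothing
(`smooth_sigma_vox` in `arg_config()`) denoises the working copy used for
growth and gradients; the cohort pipeline applies 0.6 voxels for the
clinical-like modalities (see below), while the default is no smoothing,
which preserves the exact Otsu equivalence on noise-free data.

`normalize_background()` applies one affine intensity map to the whole
volume so the segmented background (the water, i.e. the complement of the
bone mask within the volume of interest — not air outside the container)
gets mean 0 and *population* SD 500; it is idempotent and exact to 1e-6
relative. `stacked_histogram()` produces the per-class intensity histogram
used to inspect how cleanly a segmentation separates bone from background.

## The scanner simulator and the synthetic cohort

`simulate_scan()` degrades a binary ground-truth structure the way a scanner
would: map bone/water to calibrated intensities; convolve with an
anisotropic Gaussian PSF, folding the *excess* slice-thickness smearing into
the z sigma as `sigma_z_eff² = psf_z² + (sqrt(max(0, T² − d²))/2.355)²` for
slice thickness `T` and increment `d` (so overlapping thick slices — e.g.
200 µm slices sampled every 50 µm — blur beyond their sampling, while a
profile with `T = d` adds nothing beyond its stated PSF, and a delta-PSF
profile on an identical grid returns the calibrated truth exactly); sample
onto the acquisition grid (in-plane pixel, in-plane pixel, slice increment)
with cubic interpolation; and add white Gaussian noise. Real CT differs in
ways deliberately out of scope: reconstruction-kernel shaping, beam
hardening, correlated noise, photon-counting statistics. Passing tests
therefore demonstrate correct behaviour of the *measurement* chain under
resolution/noise degradation of this simple class, not scanner realism.

Three bundled profiles carry the study geometries: micro-like (35 µm
isotropic, PSF σ 15 µm, noise SD 40), PCD-like (50 µm in-plane, 200 µm slice
thickness, 50 µm increment, PSF σ 25 µm, noise SD 70) and EID-like (100 µm
in-plane, 400 µm thickness, 100 µm increment, PSF σ 60 µm, noise SD 140), on
a bone/water contrast of 1000. The PSF and noise magnitudes are package
constants chosen a priori to reproduce the qualitative ordering of the three
device classes (micro-CT sharpest and cleanest, then PCD, then EID), not any
device's measured values.

`make_specimen_cohort()` generates Gaussian-random-field specimens:
thresholded smoothed white noise, the threshold set at the quantile giving
each specimen's target BVTV (drawn uniformly from 0.05–0.15, the range
reported for cadaveric radius specimens by micro-CT). The field correlation
length defaults to 0.08 mm, which makes the reference-modality trabecular
thickness come out near 0.15 mm — thin enough, relative to the clinical
profiles' resolution, that degradation actually stresses the network, and
consistent with the ≈ 0.1 mm human trabecular width reported in the
literature. Specimens default to 3 mm cubes at 35 µm voxels (86³ grids): a
size chosen so the full three-modality, fourteen-specimen validation runs in
a few minutes on one CPU while still containing hundreds of trabeculae; the
generator accepts larger domains unchanged. One cohort seed derives all
per-specimen and per-scan seeds by fixed offsets.

`cohort_morphometry()` runs the full pipeline per scan — Otsu for the
reference modality, ARG for the clinical ones, isotropic resampling where
the grid is anisotropic — and returns one row of the nine parameters per
(specimen, modality). The clinical modalities are segmented with 0.6 voxels
of ARG pre-smoothing: the simulator's white noise roughens the grown mask
surface, and without denoising the roughness sprouts spurious skeleton
branches whose node voxels swamp the genuine, resolution-driven node loss
(measured: PCD-like node density ≈ the reference's without smoothing, about
one-fifth of it with). What the synthetic cohort is expected to reproduce is
qualitative: thickness inflation ordered micro < PCD < EID, node-density
loss ordered micro > PCD > EID, CNR ordered micro > PCD > EID, and strong
rank preservation of BVTV across modalities. The absolute over/underestimation
factors of the real study depend on scanner physics the simulator does not
model and are *not* calibration targets.

## Statistics

The comparison layer is deliberately nonparametric, as is standard when
n = 14 and normality is rejected for several parameters: medians and
quartiles (linear-interpolation "type 7" rule — the convention is stated
because quartile definitions differ visibly at n = 14), over/underestimation
factors as ratios of medians (full precision kept; displayed rounded to one
decimal), and Spearman rank correlations computed as the Pearson correlation
of mid-ranks, with two-sided p-values from the t approximation on n − 2
degrees of freedom (an exact permutation option exists for n ≤ 8) and 95%
confidence intervals via the Fisher z transform. No multiple-testing
correction is applied; p-values are reported raw. `shapiro_wilk()` wraps the
standard Royston algorithm and is advisory only. `build_comparison_table()`
assembles the per-(modality, parameter) table of median/quartiles, median
ratio and factor versus the reference, and the correlation results, erroring
if the modalities do not cover identical specimen sets.

## Degenerate inputs and numerical choices

Constant volumes cannot be segmented (no threshold exists) and constant
backgrounds cannot be normalized — both are errors, not warnings. Empty
masks cannot be skeletonized or measured. Cubic interpolation uses the Keys
kernel (a = −0.5) with mirror boundaries; it reproduces linear ramps to
machine precision and may overshoot near sharp edges — overshoot is left
unclipped because downstream segmentation is threshold-based and clipping
would bias the background noise statistics that CNR divides by. Otsu ties go
to the lower threshold; ARG sweep ties go to the higher threshold; both
rules exist purely so results are reproducible. The local-thickness sphere
coverage test uses a strict inequality with a 1e-9 slack on integer-valued
squared distances, making the C++ route agree with the brute-force oracle to
numerical precision.

## Limitations

The simulator omits reconstruction kernels, beam hardening and correlated
noise; synthetic cohort results validate the measurement chain, not scanner
physics. Thinning on a cubical grid is anisotropic: oblique plates erode
more than axis-aligned ones, and node clusters at junctions span several
voxels, so voxel-count node density is comparable across modalities but
biased upward relative to junction counts. Registration is consumed, not
estimated: `apply_rigid_transform()` resamples through an externally
supplied rigid transform. Cortical bone is not treated as a separate
compartment; the whole volume of interest enters BVTV and Tb.Nd
denominators.
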