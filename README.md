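# trabmorph

Trabecular bone morphometry from multimodal CT volumes, in R.

Trabecular bone — the lattice-like interior compartment of the skeleton —
loses mass and connectivity early in osteoporosis, and its microstructure is
a determinant of bone strength beyond mineral density alone. The reference
measurement is micro-CT of excised specimens; clinical multislice CT
(photon-counting, PCD-CT, or energy-integrating, EID-CT) can image patients
but with voxels as large as the trabeculae themselves. `trabmorph`
implements the full measurement chain used to compare such modalities
against micro-CT, plus a synthetic-specimen generator and scanner simulator
so the whole chain can be validated against known ground truth.

For one segmented volume the package computes the standard parameter set:

| parameter | meaning | unit |
|---|---|---|
| BVTV | bone volume / total volume | fraction |
| Tb.Th | trabecular thickness (largest inscribed sphere) | mm |
| Tb.Sp | trabecular separation (local thickness of the inverted mask) | mm |
| Tb.Sc | trabecular spacing (local thickness of the inverted *skeleton*; midline-to-midline) | mm |
| Tb.Nd | trabecular node density (skeleton intersections / volume) | 1/mm³ |
| s(Tb.Th), s(Tb.Sp), s(Tb.Sc) | intra-volume dispersion: SD of each 3D local map | mm |
| CNR | (mean bone − mean water) / SD water, sampled on skeletons | — |

Core machinery (all in compiled code): an exact Euclidean distance transform
and sphere-fitting local thickness; topology-preserving 3D thinning that
reduces rods to curves and plates to one-voxel sheets; branch-count node
classification; Otsu and automated region-growing (ARG) segmentation; an
anisotropic-PSF scanner simulator. The statistics layer provides median/IQR
summaries, over/underestimation factors (ratios of medians), Spearman rank
correlations with p-values and Fisher-z confidence intervals, and
Shapiro-Wilk normality checks.

Volumes are read and written as NIfTI (`.nii`/`.nii.gz`), MetaImage
(`.mhd` + `.raw`) or multi-page TIFF stacks with a YAML spacing sidecar;
spacing metadata (micrometres) round-trips bit-exactly.

## Worked example

Measure a parallel-plate phantom with known geometry (0.1 mm plates,
0.4 mm gaps, 50 µm voxels), then push a synthetic trabecular specimen
through a clinical-like acquisition and the full pipeline:

```r
library(trabmorph)

plate <- make_plate_phantom(thickness_mm = 0.1, gap_mm = 0.4,
                            domain_mm = 3, voxel_um = 50)
round(as.data.frame(measure_volume(NULL, plate$mask)), 4)
#>   bvtv tb_th s_tb_th  tb_sp s_tb_sp  tb_sc s_tb_sc tb_nd cnr
#> 1  0.2   0.1       0 0.3981  0.0145 0.4938  0.0308     0  NA
```

Each measured value sits within one voxel (0.05 mm) of the closed-form
truth: thickness 0.1, separation 0.4, spacing 0.5 (the plate period), bone
fraction 0.2, and no network nodes in parallel plates.

```r
truth <- make_gaussian_field_phantom(target_bvtv = 0.09, seed = 7)
scan  <- simulate_scan(truth, scanner_presets()$pcd, seed = 7)   # 50 um / 200 um slices
ana   <- analyze_scan(scan, method = "arg",
                      config = arg_config(smooth_sigma_vox = 0.6))
round(as.data.frame(ana$result), 3)
#>    bvtv tb_th s_tb_th tb_sp s_tb_sp tb_sc s_tb_sc tb_nd   cnr
#> 1 0.026 0.185   0.057 1.404   0.487 1.544     0.5 1.407 4.834
```

The same phantom pushed through the micro-CT-like profile and segmented with
Otsu reads Tb.Th 0.151 mm, Tb.Nd 8.4/mm³ and CNR 24.2: relative to that
reference, the clinical-like acquisition sees thicker trabeculae, a fraction
of the network nodes and a fifth of the contrast-to-noise — the
partial-volume signature the package is designed to quantify. `make_specimen_cohort()` +
`cohort_morphometry()` + `build_comparison_table()` scale this to a
multi-specimen, three-modality comparison table with factors and Spearman
correlations against the reference modality.

A thin command-line wrapper over these functions is installed at
`inst/scripts/trabectl.R` (verbs: `segment`, `skeletonize`, `measure`,
`simulate`, `compare`).

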