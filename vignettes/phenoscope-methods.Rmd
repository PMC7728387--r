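---
title: "Methods: simulating and quantifying a paired GFP localization screen"
author: "phenoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying a paired GFP localization screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenoscope re-implements, as a tested pipeline, the image-quantification
procedures of a yeast phenomic screen that compares GFP-fusion protein
abundance and localization between a wild-type and a deletion-mutant
background: per-cell mean-intensity fold-change screening with fixed hit
cut-offs and two-round confirmation, 3D mitochondrial morphometry and
strain-level mitochondrial fractions, nucleus-centered line-profile
localization scoring with a six-category change classifier, and the
closed-form assay statistics around them (doubling time, delta delta Ct,
normalizations, Welch t, ANOVA + Tukey). Because the original raw images
are not public, every stage is exercised end to end on synthetic
micrographs with known per-cell ground truth. This vignette documents the
models, the defaults, and the design decisions, and what passing the tests
does and does not demonstrate about real data.

## The virtual microscope

A field is a calibrated multi-channel z-stack. `acquisition_spec()` fixes:

* `pixel_size_xy = 0.1038` um/px. This is derived from the only printed
  calibration available for the assay geometry: a 60-pixel line profile
  spanning 6.23 um.
* `z_step = 0.3` um, 30 slices. The number of slices matches a
  conventional spinning-disk stack of a yeast field; the step itself is
  instrument-specific and is configurable.
* A Gaussian PSF with `psf_sigma_xy = 0.15` um and `psf_sigma_z = 0.35`
  um, applied as a separable, intensity-conserving convolution. These are
  plausible spinning-disk confocal values; the real instrument's voxel
  anisotropy and photon conversion are not recoverable from any published
  number, so the defaults are declared, not inferred.
* A camera model of Poisson shot noise at `photon_scale = 50` photons per
  intensity unit followed by additive Gaussian read noise
  (`noise_read_sd = 0.02`), clamped at zero.

Cells are spheres (diameter ~3.6-4.4 um) on a jittered grid, strictly
non-overlapping by default. Each carries one of five GFP distributions
(`cell_spec()`): uniform cytoplasmic signal; a nucleus of 0.35x the cell
diameter (the nucleus size is nowhere stated in the assay; 0.35 is a
typical yeast nucleus-to-cell ratio) with a dome-shaped nucleoplasmic
profile, brightest at the centre, as nuclear GFP appears in projected
stacks; discrete Gaussian foci placed in the cytoplasm outside the
nucleus; a mitochondrial tubule network; or a 0.25 um peripheral shell.
Per-cell mean GFP intensity is linear in `intensity_scale`, which is how
abundance effects are injected. The brightfield channel renders a dark
interior with a bright rim straddling the cell boundary (real
bright-field optics are out of scope), and the DAPI channel renders the
nuclei.

Tubule networks are persistent random walks confined to 0.8x the cell
radius, dilated to a 0.25 um radius, and kept out of the nuclear sphere.
Rasterization is volume-preserving: per-voxel coverage is estimated on a
sub-grid and binarized column by column so that voxel count x voxel volume
tracks the covered volume even when the tubule radius (0.25 um) is smaller
than the axial step (0.3 um); a naive centre-in/out rule misses the
analytic volume of such thin cylinders by up to ~30% depending on
sub-voxel placement, the volume-preserving rule stays within 10%
(`cylinder_mask()`). When a cell specifies a target mitochondrial volume
(`mito_volume_um3`), tubules are added segment by segment until the
rasterized network reaches it, so injected volume factors are realized in
the ground truth irrespective of tubule overlap.

All randomness flows from one integer seed through a documented splitting
scheme (`child_seed()`, a multiplicative congruential step mod 2^31 - 1);
identical inputs give bit-identical fields, and the caller's RNG state is
never disturbed.

Ground truth carries voxel label volumes for cells, nuclei and
mitochondria plus a per-cell table of class, true mean GFP (noise-free,
post-PSF), and true volumes (exactly voxel count x voxel volume). Fields
can be written to disk as one multi-page 32-bit TIFF per channel with a
JSON calibration sidecar, 16-bit label TIFFs and a CSV truth table
(`write_field()`); no OME metadata writer is available to the package, so
this plain layout is its interchange format.

## Segmentation and the sphere cell volume

`segment_cells()` works on the mid-stack brightfield slice: median filter
(radius 2), Sobel edge magnitude, Otsu threshold of the normalized edge
image, hole filling, a small opening, an optional erosion (default 0), and
a distance-transform watershed to split touching cells; regions outside
100-5000 px^2 (defaults at the 0.1038 um/px calibration) are dropped and
border-touching regions flagged. The stages mirror what a manual
ImageJ-macro ROI workflow does, since no algorithm is specified anywhere
for the original analysis; whether the original macro worked on one focal
plane or a projection is also unstated, and the mid-stack-slice choice is
declared, not inferred. Normalizing before thresholding makes the
pipeline exactly invariant to intensity scaling. Diameters are the
major/minor axes of each region's best-fit ellipse — the automated
counterpart of the assay's two manual diameter measurements — and the cell
volume is the sphere through their mean:

$$V_{cell} = \frac{4}{3}\pi r^3,\qquad r = \frac{d_a + d_b}{4}.$$

`detect_nuclei()` Otsu-thresholds the max-projected DAPI channel and keeps,
per cell, the blob with the largest in-cell overlap (ties to the lower
blob label).

## The intensity screen

The abundance measure is the mean grey value per cell: the GFP stack is
projected over z (maximum projection by default, matching a
compressed-stack workflow; selectable) and averaged over each cell ROI.
Mean-per-cell is insensitive to the mutant's larger cell size. The
per-gene statistic is the paired fold change: the average per-cell mean of
the mutant image divided by that of its paired wild-type image; with two
fields per genotype, fields are paired in order and the two ratios
averaged (the aggregation across the two fields is not specified anywhere;
the arithmetic mean of per-pair ratios is this package's choice). Genes
are ranked by fold change (ties broken by gene name for reproducibility)
and called as primary hits with strict cut-offs, fold > 1.3 or < 0.7;
boundary values are non-hits. Confirmation requires being a hit with the
same direction in an independently rendered second round.

One caveat the simulation makes visible: under shot noise, a maximum
projection is a biased functional, and the bias grows with the signal, so
max-projection fold estimates are mildly compressed toward 1 (a 3.77-fold
injection reads ~3.5). This cannot flip calls at the 1.3/0.7 cut-offs for
the injected effect sizes, but where a calibrated fold matters the mean
projection (unbiased by linearity) is the right choice, and the tests that
assert fold recovery to 5% use it.

The simulated screen's defaults are the screen's stated acquisition
design: two fields per genotype per gene with 35 cells each (the screen
guaranteed at least 35), log-normal cell-to-cell expression heterogeneity
(CV ~15%), and mutant cells enlarged to ~2x volume (diameter x1.26). The
whole-screen configuration renders at a coarser calibration (0.25 um/px, 3
slices of 1 um, 38 x 38 um frames) so that a 360-gene, three-seed screen
benchmark runs in minutes; per-cell means average hundreds of voxels
either way, and the fold-change statistics are calibration-independent.

## Mitochondrial morphometry

Per cell, mitochondrial voxels are segmented from the cell's sub-volume by
an automatic threshold (`segment_mito_voxels()`). The default rule places
the threshold halfway between the sub-volume's background (median) and its
structure peak (99.9th percentile): the half-maximum contour of a
PSF-broadened tubule sits near the true tubule surface, so this tracks the
underlying volume far better than an Otsu split, which lands inside the
halo and nearly triples the voxel count on synthetic tubules (an Otsu rule
floored at background mean + 3 sd is kept as `method = "otsu"`). A
contrast guard (foreground mean at least 2x the sub-volume median) returns
an empty mask when the bright tail is just noise on a structureless cell,
and components under 5 voxels are removed as speckles. Volume is voxel
count x voxel volume; surface area counts exposed voxel faces with
anisotropic face areas (a deterministic overestimate of up to ~1.5x for
smooth shapes — mesh extraction would be slower and stochastic to
tie-break). Equivalence to any particular ImageJ plugin's internal
thresholding is not claimed, only internal consistency against the
generator's ground truth.

Elongation features come from a topology-preserving 3D thinning skeleton
(sequential deletion of simple border points, six directional sub-passes,
endpoints kept): total length is the weight of a minimum spanning forest
over skeleton voxels with anisotropic centre-to-centre distances, branch
points are skeleton voxels with three or more skeleton neighbours, and
components are counted at 26-connectivity.

The strain-level summary is the mitochondrial fraction: each cell's
mitochondrial volume divided by the strain's mean sphere-approximated cell
volume (per-cell normalization is available but off by default, matching
how the assay defines the fraction). Two groups are compared by Welch's
t-test over per-cell fractions; three or more by one-way ANOVA with Tukey
HSD.

For recovering *contrasts* between strains, `run_mito_contrast()` measures
volumes by an intensity-calibrated estimator rather than a per-cell
thresholded count: the sub-volume is Richardson-Lucy deconvolved against
the known PSF, split into background and structure by Otsu, and the
background-subtracted structure integral is divided by one tubule
amplitude estimated from the pooled structure voxels of the whole
experiment (90th percentile). The motivation is measurable in simulation:
thresholded counts inflate sparse networks more than dense ones (halos
merge), biasing a 3.0x injected volume ratio to ~2.6x, while intensity
integrals are conserved by the optics, making the ratio insensitive to
packing (recovered within ~3%). The amplitude is a property of the
fluorophore and exposure, so estimating it once per experiment is both
physically sensible and what cancels the strain asymmetry.

The morphometry experiments run at 0.15 um/px with 16 slices of 0.3 um,
17 cells per replicate and 3 replicates per strain (51 cells per strain,
just over the assay's 50-cell floor), with log-normal per-cell
mitochondrial volume heterogeneity (CV 0.2, normalized to sample mean 1 so
the injected strain-level factor is exact). The wild-type target volume is
1.8 um^3, ~5% of a 4.1 um cell — a realistic resting mitochondrial
fraction for fermenting yeast.

## Localization profiles and the change classifier

`line_profile()` samples 60 bilinear values along a line centered on the
nucleus centroid (6.23 um at the default calibration; the centre sample,
0-based index 30, lies on the centroid), horizontal by default — whether
the original lines were placed at a fixed or per-cell angle is unstated,
and profiles at any angle agree for radially symmetric cells.
`mean_profile()` averages replicate means, weighting replicates equally
regardless of cell counts.

Per-cell features (`localization_features()`): nuclear, cytoplasmic and
peripheral-shell (0.3 um) mean intensities and the nuclear/cytoplasmic
ratio; the number of discrete puncta (projected components above 2x the
in-cell median with area 0.05-2 um^2 — the upper bound admits small merged
foci but excludes whole-cell blobs); the in-cell coefficient of variation;
and the mitochondrial skeleton length per cell area. The skeleton feature
deconvolves first and applies stricter guards (contrast 3x, components of
at least 0.1 um^3), because deconvolution sharpens shot noise on
structureless cells into speckles that would otherwise skeletonize into
long spurious traces.

A cell is nuclear-enriched when its nuclear/cytoplasmic ratio exceeds 1.5;
"prominent nuclear localization" is a judgement call in the original
manual counting and 1.5 is an invented, configurable default.
`percent_nuclear()` is scale-invariant by construction.

`classify_change()` replaces three-researcher visual categorization with
an ordered, fully configurable rule list over population feature means:
(1) cytoplasm-to-punctate when mean puncta rise by >= 3 and the CV by >=
50%; (2, 3) nucleus-to-cytoplasm / cytoplasm-to-nucleus when the
nuclear/cytoplasmic ratio crosses 1.5 downward/upward; (4)
periphery-to-cytoplasm when the peripheral/cytoplasmic ratio falls below
1.2 from above; (5) mitochondrial elongation when skeleton length rises by
>= 50%; else (6) increased/decreased abundance when the fold change is
outside [0.7, 1.3]; otherwise "no change". Feature rules run before the
abundance rule so that, e.g., a punctate shift with a 1.65-fold abundance
rise is classified by its localization change, as the original
categorization did. The six-category benchmark
(`run_localization_benchmark()`) builds one paired gene set per category
(30 cells per genotype, 3 seeds in the tests) and recovers the generated
category for all pairs at the default thresholds.

## Assay statistics

`doubling_time()` fits log OD600 against time by least squares over the
3-7.5 h exponential window and returns ln 2 / slope; with exactly two
points this is algebraically the printed two-point formula
Δt·log2 / log(OD₂/OD₁), and the result is invariant to OD scaling and to
the log base (fixed internally to natural log). The growth simulator is a
logistic trajectory whose early-exponential doubling time equals the
input; with the default carrying capacity of 2.0 (a realistic saturation
OD) the late window bends away from exponential, so round-trip tests use a
large capacity where the window is purely exponential.

`delta_delta_ct()` computes per-replicate ΔCt = Ct_target − Ct_reference
and strain-level relative expression 2^−(mean ΔCt_strain − mean
ΔCt_baseline), so the baseline strain is exactly 1; amplification
efficiency is fixed at 2 (standard-curve correction is out of scope), and
whether technical replicates were averaged before biological ones in the
original analysis is unstated — per-replicate ΔCt then strain means is
this package's declared choice. `normalize_to_total()` and
`normalize_to_wt()` are the elementwise ratios used for quantitative
westerns and WT-normalized colorimetric readouts. `welch_t()` and
`anova_tukey()` wrap the base R tests and reject degenerate groups by
name; the Tukey family-wise error under a three-equal-group null measures
at its nominal ~5% (bounded by 7% in the acceptance test at 1000
simulations).

## Problem sizes and what the tests show

The test and acceptance workloads are scaled to what the properties need:
360 genes x 2 genotypes x 2 fields x 35 cells for the screen (3 seeds), 51
cells per strain x 2 strains for morphometry contrasts, 30 cells per
genotype x 6 categories x 3 seeds for the classifier benchmark, 10 fields
of 40 cells for segmentation, and 1000 simulations for the Tukey null.

Passing them shows that every computational step is internally consistent
and recovers known effects under the declared optics and noise model. It
does not show robustness to what the generator does not emulate: real
bright-field contrast and focus drift, autofluorescence and spectral
bleed-through, photobleaching, dead or budding cells, segmentation errors
feeding downstream stages (the screen and morphometry benchmarks measure
against ground-truth labels; segmentation fidelity is benchmarked
separately), non-Gaussian PSF tails, or a camera whose gain differs from
the declared photon scale. Real deployments should treat the thresholds
(hit cut-offs aside, which are the assay's own) as starting points and
re-validate the classifier rules on annotated examples.
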