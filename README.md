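# phenoscope

Quantification pipeline for paired wild-type / mutant phenomic microscopy
screens of GFP-fusion yeast strains — with a built-in synthetic-micrograph
generator so every stage is testable against known ground truth.

High-content screens of GFP-fusion collections compare each protein's
abundance and localization between two genetic backgrounds from
multi-channel z-stacks: cells are outlined on brightfield, the mean GFP
grey value per cell is averaged per image, and the mutant/wild-type ratio
of those averages is ranked against fixed cut-offs (fold > 1.3 or < 0.7)
with a second round of imaging to confirm hits. Follow-up assays quantify
3D mitochondrial volume from the GFP stack and normalize it by the
strain's sphere-approximated cell volume ("mitochondrial fraction",
V = 4/3·π·r³ with r half the mean of two diameters), score nuclear
enrichment from 60-sample (6.23 µm) nucleus-centered line profiles, and
categorize each paired change (increased abundance, cytoplasm→punctate,
nucleus→cytoplasm, cytoplasm→nucleus, periphery→cytoplasm, mitochondrial
elongation). Around the imaging sit closed-form assay statistics: doubling
time Δt·log2/log(OD₂/OD₁) over the 3–7.5 h window, ΔΔCt relative
expression (2^−ΔΔCt), total-protein and WT normalizations, Welch t-tests
and ANOVA + Tukey.

phenoscope implements all of that in R, plus a calibrated simulator
(`generate_field()`, `generate_screen_dataset()`,
`generate_growth_curve()`) that renders yeast-like cells of five
localization classes through a Gaussian PSF and a Poisson + read-noise
camera, and returns voxel-level ground truth. The raw images behind the
original screens are not public, so the package's benchmarks are
property-based: inject a known effect, run the full pipeline, and check it
is recovered.

## Worked example

A 20-gene paired screen with three injected effects at the fold sizes of
representative hits, measured end to end from rendered images:

```r
library(phenoscope)
hp  <- screen_hit_plan(c("GSY2", "ACO2", "DUR12"), c(1.65, 0.51, 3.77))
res <- run_screen(20, hp, seed = 9)
res[res$primary_hit, c("gene", "fold_change", "direction", "confirmed", "true_fold")]
#>     gene fold_change direction confirmed true_fold
#> 1  DUR12   3.7506208        up      TRUE      3.77
#> 2   GSY2   1.6936450        up      TRUE      1.65
#> 20  ACO2   0.5500378      down      TRUE      0.51
```

All three injected effects are called in the right direction at the strict
1.3/0.7 cut-offs and survive confirmation in an independent second round;
the 17 null genes are not called. The mitochondrial follow-up works the
same way — injecting a 3× mitochondrial volume into cells of 1.76× volume
and recovering their ratio as a fraction change:

```r
eff <- run_mito_contrast(mito_scale = 3.0, cell_volume_scale = 1.76, seed = 1)
round(eff$fraction_ratio, 3)   # 1.687  (injected: 3/1.76 = 1.705)
eff$test$p_value               # 4.1e-18 (Welch t over per-cell fractions)
```

The numbered scripts under `analysis/` run the whole study as a narrative
— example field rendering, the 360-gene screen, mitochondrial
morphometry, localization profiling, and the assay statistics — writing
their tables under `results/`.

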