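# cristamorph

Morphometry of presynaptic mitochondrial ultrastructure and cytochrome-c
density in synaptic boutons.

Synaptic transmission dominates the brain's energy budget, and the
mitochondria parked inside presynaptic boutons pay for it. Their output
capacity is written in their architecture: the surface area of crista
membrane (CM) per organelle volume tracks respiratory capacity, and
sheet-like (lamellar) cristae outperform tubular ones. `cristamorph` is an R
implementation of the measurement pipeline used to ask whether stronger
synapses carry stronger mitochondria, for electron microscopists and
quantitative neuroscientists who have segmentations, profile tables,
immunogold coordinates or STORM molecule lists in hand — plus a synthetic
generator with analytic ground truth so the whole pipeline is verifiable
without any raw images.

## What it computes

| Stage | Measures |
|---|---|
| Electron tomography | iso-surface meshes of OMM/IBM/CM from labeled volumes; CM density = A(CM)/V(mito) (1/nm); crista shape factor CSF = A(CM)/V(lumen) (1/nm); z-scaling for beam-induced section thinning |
| Serial sections | active-zone area = sum of chords x section thickness; Cavalieri mitochondrial volume; LP/HP bouton classification (single nonperforated AZ < 0.09 um^2 vs multiple/perforated > 0.09 um^2) |
| Immunogold | particle-to-membrane distances; membrane association (<= 40 nm, inclusive); linear labeling density per um |
| STORM | photon-count SLP filtering; 2D convex hulls around per-mitochondrion clusters; SLP density (SLP/um^2); paired-channel area correlation; Homer-volume median split |
| Statistics | median/IQR summaries, Shapiro-Wilk-gated Mann-Whitney U (exact for small tie-free groups), Pearson/Spearman, percent differences |

Key identities: `cm_density = a_cm / v_mito`, `csf = a_cm / v_lumen`,
`percent_difference(a, b) = (a - b) / b * 100`, and the group CM-surface
ratio `(density_a * volume_a) / (density_b * volume_b)`.

## Worked example

Measure a voxel phantom with exactly known geometry, then compare two
synthetic bouton cohorts generated at the published hippocampal CA1 group
targets:

```r
library(cristamorph)

p <- generate_mito_phantom(mito_phantom_spec(voxel_size = 6))
measure_mitochondrion(p$volume, id = "phantom_1")
#>          id   a_omm    v_mito     a_cm ... cm_density     csf
#> 1 phantom_1 1260019 108804976 495373.6      0.004553 0.10244
p$ground_truth$cm_density   # 0.00463053 -> recovered within ~2%
p$ground_truth$csf          # 0.0985021

cohort <- generate_population(population_spec(ca1_reference_targets(), seed = 1))
compare_groups(cohort$cm_density[cohort$group == "PV"],
               cohort$cm_density[cohort$group == "CB1R"])
#> <comparison_result> mann_whitney_u: U = 100, p = 0.0001827 (significant at alpha = 0.05)
#>   medians 0.04311 vs 0.02299 (+87.5%)
```

The phantom's CM density and CSF come from closed-form geometry, so the
measured values validate the meshing; the cohort comparison shows the
fast-spiking (PV+) boutons' higher CM density re-emerging through the full
statistical pipeline at the study's sample size (n = 10 per group here, hence
the sample percent difference scatters around the generative +79.7%).

Published worked-example arithmetic reproduces directly:

```r
percent_difference(0.0408, 0.0227)                      # 79.7 (CA1 CM density)
group_cm_surface_ratio(0.0408, 119e6, 0.0227, 73.4e6)   # 2.91 (CA1 CM surface)
group_cm_surface_ratio(0.0552, 41.8e6, 0.0262, 18.9e6)  # 4.66 (DG CM surface)
```

An end-to-end run (`run_pipeline(run_config(seed = 1))`) simulates cohorts,
measures a phantom, analyzes a STORM field and a gold field, and writes
per-cohort report tables (JSON + text) with content hashes; the same config
and seed give byte-identical reports.

## Layout

- `R/`, `src/` — implementation (R + Rcpp voxel-grid numerics)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/mitochondrial-morphometry.Rmd` — the model, estimators,
  numerical choices and limitations
- `inst/scripts/run_pipeline.R` — command-line pipeline wrapper
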