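---
title: "Quantifying presynaptic mitochondrial ultrastructure with cristamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic mitochondrial ultrastructure with cristamorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cristamorph)
```

## The scientific problem

Synaptic transmission is the dominant energy consumer of the brain, and
presynaptic mitochondria supply it. Their output capacity is set by their
internal architecture: the surface area of crista membrane (CM) packed into a
given organelle volume correlates with respiratory capacity, and sheet-like
(lamellar) cristae support more efficient respiratory-chain organization than
tubular ones. `cristamorph` implements the measurement pipeline needed to ask
whether boutons with stronger synapses carry "stronger" mitochondria:

* **Tomographic morphometry** — from segmented electron-tomographic volumes to
  per-mitochondrion CM density (CM area / mitochondrial volume, 1/nm) and
  crista shape factor (CSF, CM area / crista lumen volume, 1/nm; higher means
  more lamellar).
* **Serial-section stereology** — active-zone areas by the chord-sum estimator
  (sum of per-section apposition lengths x section thickness) and
  mitochondrial volumes by the Cavalieri estimator, plus the morphological
  low-/high-performance (LP/HP) bouton classification.
* **Immunogold counting** — membrane-association of gold particles (40 nm
  inclusive cutoff) and linear labeling densities.
* **STORM analysis** — photon-count filtering of localization lists, 2D convex
  hull delineation of individual mitochondria, cytochrome-c SLP density, and
  the Homer-volume median split of boutons into LP/HP groups.
* **Group statistics** — medians and IQRs, Shapiro-Wilk-gated reporting with
  the two-sided Mann-Whitney U test, Pearson/Spearman correlation, percent
  differences.

Raw EM and STORM data of the original study are not public, so every stage is
validated against a synthetic generator with analytic ground truth rather than
against deposited images. The generator's defaults encode the published group
medians and IQRs, which also drive the worked-example ratios the pipeline
reports.

## The phantom model and its ground truth

`mito_phantom_spec()` describes an idealized mitochondrion: a capsule or
ellipsoid outer-membrane (OMM) mid-surface; an inner boundary membrane (IBM)
offset inward by the membrane separation (default 20 nm); and cristae as
parallel rounded lamellae or capsule-shaped tubes. All areas and volumes have
exact closed forms (Steiner formulas for the dilated rectangle; quadrature of
the exact area element for the ellipsoid), so the voxelized phantom is an
oracle for the meshing pipeline.

Two modeling choices matter:

* **Rounded crista rims.** Lamellae are a core rectangle `w x h` dilated by a
  ball of radius `t/2` rather than sharp-edged slabs. Real crista rims are
  curved (rim curvature is where ATP-synthase dimers concentrate), and a
  sharp 90-degree rim is also a pathology for any smoothing-based mid-surface
  extractor: it gets rounded by the extraction itself, biasing CM area low by
  several percent no matter the resolution. With smooth rims the recovery
  error is dominated by resolution and falls with voxel size.
* **Feature size = smallest curvature radius.** Iso-surface extraction
  displaces a surface inward by roughly the squared transition width times
  its total curvature `kappa1 + kappa2`, so the curvature radius, not the
  lumen thickness, is the binding resolution limit. Recovery tolerances are
  claimed for voxels no larger than a third of `phantom_feature_size()`
  (`t/2` for lamellae) on singly-curved rims; the doubly-curved caps of
  tubular cristae shift twice as fast and need about eight voxels per tube
  radius. `seeded_phantom_grid()` encodes these validated resolutions.

```{r phantom}
spec <- mito_phantom_spec()   # capsule, 5 rounded lamellae, 4-nm voxels
phantom_ground_truth(spec)[c("a_omm", "v_mito", "cm_density", "csf")]
```

## Meshing and measurement

`mesh_from_labels()` builds a scalar field per compartment — 1 inside, 0
outside, 0.5 on the membrane shell itself — smooths it with a small Gaussian
and extracts the 0.5 level set by marching tetrahedra. Assigning the shell
the iso-value makes the extracted surface pass through the shell mid-surface,
so membrane thickness never contributes to area. A voxel-exact `"block"` mode
(every exposed voxel face) provides the oracle for the divergence-theorem
volume integrator: its volume equals voxel count x voxel volume identically.

Numerical choices, fixed after error scans on phantoms:

* smoothing bandwidth 0.9 voxels for the large, smooth OMM/IBM envelopes
  (staircase suppression dominates) and 0.55 voxels for the CM (curvature
  shrinkage dominates); both are exposed as arguments;
* no mesh smoothing after extraction, keeping the voxel-exact oracles valid;
* z-coordinates are stretched by `z_scale_factor()` (original / reconstructed
  section thickness, compensating beam-induced thinning) **before** any
  measurement — the order is fixed and tested;
* mitochondrial volume is the volume enclosed by the OMM mesh (the organelle's
  conventional boundary); crista lumen volume is enclosed by the CM mesh, and
  crista meshes that open at a junction are closed by minimal planar centroid
  fans (`cap_mesh_holes()`) before integration;
* meshes of unknown provenance are re-oriented per connected component before
  volume integration; degenerate triangles contribute zero area.

On a seeded grid of ten phantom geometries (capsule/ellipsoid x
lamellar/tubular) at the validated resolutions, the pipeline recovers OMM
area and mitochondrial volume within 2% and CM density and CSF within 5%;
the test suite asserts exactly this.

## The synthetic cohort generator

`generate_population()` draws per-group, per-metric samples from two-parameter
lognormal distributions — the natural family for positive, right-skewed
morphometric quantities — fitted so the distribution median equals the target
median exactly and the quartile ratio matches the target IQR (the closest a
two-parameter family can come to three targets). Group targets for the two
study systems ship as `ca1_reference_targets()` (fast-spiking PV+ vs
regular-spiking CB1R+ basket-cell boutons, n = 10 per group for tomography,
28/29 for STORM) and `dg_reference_targets()` (HP vs LP perforant-path
boutons, n = 10/9 and 21/21). Where a dispersion was never published (CA1
mitochondrial volumes are literature medians), the relative IQR of the
matching dentate-gyrus metric is reused; this affects only cohort dispersion,
never medians. Metrics are drawn independently within a group — the joint
structure of interest is carried by group membership, and no between-metric
correlation targets exist to calibrate against.

Because these are parametric emulations, passing tests show that the
*pipeline* recovers what the generator encodes (medians, IQRs, group
contrasts, signs and approximate magnitudes at study sample sizes). They
cannot re-establish the original biological findings, and features of real
data — between-metric correlation within a bouton, segmentation error,
anisotropic localization precision, detector artifacts — are deliberately out
of scope (no PSF rendering, no tilt-series projection, no camera noise).

Other generators follow the same pattern: `generate_serial_bouton()` slices
analytic discs and spheres at midpoint-placed planes so the chord-sum and
Cavalieri estimators can be checked against pi r^2 and 4/3 pi r^3;
`generate_storm_field()` places Poisson counts uniformly in elliptical
footprints, jitters them with 25-nm Gaussian localization noise and draws
photon counts from separated lognormals (the photon threshold that defines an
SLP is acquisition-dependent, so it is an explicit parameter everywhere and
recorded in outputs, with the default documented in `run_config()`);
`generate_gold_field()` places particles along a membrane polyline at a set
linear density with Gaussian offsets. Every generator takes a single integer
seed, restores the caller's RNG state, and records the generator algorithm in
its output.

## Statistics

Group comparisons report medians and IQRs (quartiles by linear interpolation,
`quantile()` type 7 — the convention is echoed in every report and pinned by a
snapshot test) and the two-sided Mann-Whitney U test: exact when both groups
are small (min n <= 8) and tie-free, otherwise the normal approximation with
continuity and tie corrections. The Shapiro-Wilk gate runs on every sample
and is logged, but the rank test is reported regardless of its outcome —
median/IQR summaries and rank comparisons belong together, and this mirrors
standard practice in the field. Correlations are gated: Pearson when both
variables pass Shapiro-Wilk, Spearman otherwise. Per-animal samples are only
pooled after a logged between-animal Mann-Whitney check (`pool_animals()`).
No multiple-testing correction is applied, matching the reporting style the
package mirrors. Boundary rules are explicit: the LP/HP active-zone threshold
(0.09 um^2) uses strict inequalities with the boundary unclassified; the
40-nm gold cutoff is inclusive; Homer-volume ties at the median go to LP.

Problem sizes used by the default test and acceptance runs — chosen as
routine validation sizes — are: ten phantoms at voxel = feature/3, 2000 null
simulations for the type-I error (5% +/- 2%), cohorts of 10^4 per group for
the large-n round trip, and 100 seeded replicates at the study's sample
sizes for sign reproduction.

## Known limitations

* Cluster membership of SLPs is an input (`cluster_id`), mirroring the manual
  confocal-overlay assignment of the original workflow; no density-based
  clustering is applied in validated paths.
* The convex hull is 2D (x, y) even for 3D acquisitions, so hull areas are
  projections; this matches the delineation the measures are defined on.
* Convex hulls underestimate the footprint of a finite sample (hulls sit
  inside the true outline), so SLP densities carry a small positive bias that
  shrinks with localization count; the recovery test budgets for it.
* The ellipsoid IBM is modeled as a concentric ellipsoid with semi-axes
  shortened by the membrane separation, not as a true offset surface.
* Perforation of active zones is an input flag; detecting it from images is
  out of scope, as is any image segmentation or registration.
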