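---
title: "stereomap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stereomap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomap)
```

This vignette is the package's own account of its science: the models it
implements, the tunable parameters that matter, what the synthetic phantoms
do and do not emulate, and the choices made where the underlying procedure
left the design open.

# 1. The bead-mapping model

## Coordinates and conventions

Everything downstream of I/O works in physical nanometres, in `(z, y, x)`
order. Voxel `(k, j, i)` (0-based) sits at `(k·sz, j·sy, i·sx)` nm —
voxel-center convention. FIB-SEM voxels are strongly anisotropic (in-plane
~2–2.6 nm, milling step 10–20 nm), which is exactly why voxel indices are
confined to the I/O layer: index arithmetic across axes is a standing
source of silent errors.

Two metadata vectors orient the analysis: `apical_direction` (cell body →
bundle tips) and `mechano_direction` (shortest row → tallest row, the
excitatory deflection sense). Both are normalized on input; vectors within
1° of parallel are rejected.

## Surface extraction

The segmentation is downsampled **in-plane only** (majority-vote pooling of
`factor × factor` blocks in y, x; ties go to the smaller label, background
competing like any label). Rationale: acquisition voxels of ~2 × 2 × 15 nm
become near-isotropic ~10 × 10 × 15 nm at factor 4, whereas a 3-axis resize
would throw away milling-axis resolution that is already the bottleneck.
A 3-axis interpretation can be emulated by pre-pooling; in-plane is the
default (`resize_factor = 4`). Phantoms generated directly at the
post-resize scale use `resize_factor = 1`.

Border voxels are labeled voxels with at least one six-connected background
neighbor (volume boundaries count as background). A seeded uniform 10%
subsample of border voxels (`keep_fraction = 0.10`) is the working surface
cloud — matching the source workflow, and making every downstream result
reproducible given the seed.

## Morphometry

* **Axis**: first principal component of the surface cloud, sign-fixed
  apically. PCA is standard, testable and rotation-equivariant; clouds
  whose first two principal values agree within 5% are rejected as
  axis-ambiguous.
* **Tip and taper**: means over a thin *end band* — all points whose axial
  projection lies within 1% of the axial extent of the respective extreme
  (`end_band_frac = 0.01`, roughly one to two milling steps on real
  volumes). Averaging a band is robust to single outlying voxels. A
  fixed-count cap (e.g. "the 5% most extreme points") is *not* used: on a
  capped 2.4-µm cylinder such a cap reaches ~100–170 nm down the shaft and
  biases the height by ~7%, violating the 2-voxel recovery target the
  estimator must meet on rasterized phantoms.
* **Height**: `(tip − taper) · axis`.
* **Diameter**: twice the interquartile mean of radial distances of
  mid-band points (normalized axial position 0.25–0.75, avoiding taper and
  tip cap), measured about the axis line through the mid-band centroid.
  The interquartile mean coincides with the median on symmetric radius
  distributions but is stable on voxelized surfaces, where radial
  distances concentrate on discrete shells and a sample median can jump by
  a whole shell (~6%) between subsampling seeds. The mid-band centroid is
  used as the radial center because the taper end point is estimated from
  few points and its transverse noise would inflate radii.
  Note border-voxel centers sit up to one voxel *inside* the true
  membrane, so diameters read systematically low by about one in-plane
  voxel — within the stated tolerance, and irrelevant to density ratios.

## Bead projection

Beads are reduced to centroids of 26-connected components (unweighted mean
of voxel centers). Each centroid takes the `k = 10` nearest points of the
pooled surface cloud (all cilia); the cilium owning the majority of those
points wins; ties go to the owner of the single nearest point. The bead's
surface point is the winning cilium's nearest point; beads farther than
`cutoff_nm = 100` from it are discarded. The underlying method names kNN
with k = 10 but not the aggregation rule; majority-over-k is the standard
reading and is robust in the crotch between adjacent cilia. The distance to
the *globally* nearest surface point is logged alongside
(`nearest_distance_nm`) for audit; the two differ only in rare split votes.

## Canonical atlas and density map

Each cilium is (1) spun about its own axis so that its *local
mechanosensitivity normal* — the in-plane perpendicular of the local row
tangent, computed from the base centroids of its two nearest same-row
neighbors — maps onto the global mechano direction ("opening the V"); (2)
translated taper → origin and rotated axis → +h. The canonical frame
`(h, m, l)` is right-handed with `m` the mechanosensitivity direction.
Height fractions are **per cilium** (axial position / that cilium's
height, clamped to [0, 1]) so tips coincide at fraction 1 across a row;
this reconciles "200-nm segments" with equal-height-fraction binning for
cilia of varying height. Azimuth is measured from +m toward +l.

Bins: `n_seg = max(1, round(row mean height / 200 nm))` segments — 12, 10,
6 at the printed row means — times four sector quadrants with boundaries at
±45° and ±135° (the sector names are given by the field; the boundaries are
a documented choice). Sector area is one quarter of a cylindrical shell at
the row's mean diameter, `π·d·200/4`. At the printed diameters this gives
0.0247, 0.0286, 0.0203 µm²; the printed study values 0.025/0.028/0.021
differ by ≤ 0.001, attributable to unrounded diameter means. Density is
`count / (area · n_cilia)` — the per-cilium average surface density, which
equals the generating intensity λ on phantoms. Kinocilia are canonicalized
but excluded from the map by default (low counts in the source data).

# 2. The coat-densitometry model

Staining is defined as `s(x) = B − I(x)`: tannic acid darkens the image, so
subtracting from background makes cell-free regions ≈ 0 and the actin core
≈ 1 after normalization. `B` is a cell-free ROI mean if provided, else the
mean raw intensity over the first 20 nm of the profile. Profiles are
sampled along the box axis at native pixel pitch with bilinear
interpolation, averaged across the box width, regridded to 1 nm by linear
interpolation, and divided by the mean staining over the 140–200 nm actin
window. The whole chain is invariant to affine gray rescaling.

Summary windows (configurable): coat 30–85 nm, membrane 85–105 nm, with
the inner leaflet fixed at 100 nm by the box-midline rule and the membrane
spanning ~15 nm including both leaflets. The underlying procedure specifies
the box and the actin window but not the summary windows. Groups are
compared per window with a two-sample two-tailed equal-variance Student's t
test (`welch = TRUE` switches to Welch). Box placement is an annotation
input, not automated detection, mirroring the manual placement in the
source workflow. A 200-nm box sampled at native pitch ends just short of
200 nm, so the actin window is clipped to the covered grid rather than
rejected.

# 3. The phantoms: what they emulate, what they do not

## Bundle phantom

The stated world (all defaults of `bundle_phantom_spec()`):

| parameter | default | provenance |
|---|---|---|
| rows × cilia | 3 × 6 | bundle scale of the source volumes (desk-sized) |
| row mean heights | 2390 / 1930 / 1240 nm | printed row means |
| row height SDs | 160 / 140 / 70 nm | printed row SDs |
| row diameters | 157 / 182 / 129 nm | printed row means |
| voxel spacing | 15 (z) × 10 × 10 nm | post-resize analysis scale; desk-sized volumes |
| V opening angle | 90° | typical OHC bundle geometry |
| spacing along row | 400 nm | separated surfaces (diameters ≤ 182 nm) |
| taper fraction | 0.15, shrinking to 40% of shaft radius | basal taper of real stereocilia |
| bead intensity λ | 50 beads·µm⁻², ×10 within 300 nm of the tip | tip enrichment of the label (≈ 2000 beads total) |
| bead offset | \|N(15, 5)\| nm radially outward | antibody + 10-nm gold linkage; **modeling choice**, no measured value exists |
| decoys | 20, rejection-sampled > 125 nm from every surface | exercises the 100-nm discard rule; the 25-nm margin (one voxel diagonal) keeps decoys beyond the cutoff from the *rasterized* surface too |

Cilia are capped cylinders (hemispherical tip, linear basal taper) with
analytic surface areas, so Poisson draws per (height-fraction bin × sector)
patch have closed-form expectations and every bead is recorded with its
true cilium, height fraction, sector (computed from the analytic arm
geometry), and offset. Determinism: identical spec + seed reproduces the
volumes and tables bit-identically.

Not emulated: imaging physics (backscatter contrast, charging, curtaining),
stack misalignment, segmentation errors, tip links and other link
structures, cilium curvature or splay, and beads clustered by antibody
bivalency. A green phantom test therefore establishes the *computational*
chain (segmentation → geometry → assignment → binning), not robustness to
acquisition artifacts.

## Coat phantom

Each section is a straight membrane seen edge-on: background gray 200,
bands subtracted as staining — coat (amplitude 80, 30–81 nm), a 4-nm
electron-lucent cleft, membrane (120, 85–100 nm), actin core (100, beyond
100 nm) — plus i.i.d. Gaussian pixel noise (SD 8 gray). Pixel size defaults
to 1.92 nm (one of the four acquisition magnifications). The mutant group
scales the coat amplitude (default 0.3×).

The cleft matters: after 1-nm regridding, a step edge at exactly 85 nm
would straddle the membrane-window boundary, and a coat reduction would
mechanically shift the membrane summary — the membrane window could then
never act as the internal control it is in the real data, where membrane
staining is unchanged between genotypes. The cleft is part of the stated
world, decided from the window geometry.

One consequence worth stating plainly: because the membrane window is a
*true* null, its two-sided t-test p-value is uniform on [0, 1], so the
expected fraction of replicates with p > 0.05 is exactly 95%. Any check of
the form "p > 0.05 in ≥ 95% of N replicates" is a near-fair coin for any
honest noise level — the replicate suite reports the observed fraction, it
does not chase the threshold.

# 4. Numerical choices and degenerate inputs

* Ties in majority votes → owner of the single nearest surface point; ties
  in label pooling → smaller label id.
* Sector boundaries are half-open (`[-45, 45)` anterior, etc.); azimuths
  are wrapped to [−180, 180).
* `floor(height_fraction · n_seg)` is clamped to the top segment so beads
  at exactly fraction 1 are counted.
* Single-cilium rows get an identity azimuth correction with a warning;
  row tangents within ~1° of the cilium axis are rejected as degenerate.
* Empty bead masks yield empty tables, not errors; empty density maps
  write header-only CSVs.
* Zero within-group variance in the t test is handled explicitly
  (identical groups → t = 0, p = 1; disjoint constants → p = 0).
* TIFF support is deliberately narrow: uncompressed 8/16-bit grayscale,
  strip-organized, little- or big-endian read, little-endian write. It is
  validated by round trips and against an independent Python reader in the
  test suite.

# 5. Known limitations

* Continuous (mesh-based) closest-point projection is out of scope; the
  surface is always a point cloud, so bead distances carry half-voxel
  noise.
* Diameters read ~1 in-plane voxel low (border-voxel centers are inside
  the membrane); heights read ~1 milling step low. Both cancel in density
  *ratios* but matter if absolute calibration is needed.
* The representative row surface is a decimated overlay point cloud;
  triangulation is not provided.
* The azimuth correction assumes the local row tangent is estimable from
  the two nearest same-row base centroids; at the V vertex the tangent
  blends the two arms and bead sectors near the boundary can flip.
* No statistical comparison between density maps is provided (the map is
  descriptive); the coat comparison is per summary window, per location,
  not a functional-data test.
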