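---
title: "Methods: 3D chromatin cartography of the root apical meristem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D chromatin cartography of the root apical meristem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meristemap)
```

## The problem

Plant nuclei differ markedly in size, shape, ploidy and chromatin
organisation between cell types, and these differences are organised in
space: the root apical meristem (RAM) lays out proliferation, transition and
elongation zones along its axis and concentric tissue layers around it.
meristemap turns multi-channel confocal stacks of whole root tips — a DNA
stain, euchromatin (H3K4me1) and heterochromatin (H3K9me1/2) marks, an EdU
replication label and a cell-wall stain — into per-nucleus feature tables in
*root coordinates*, so that nuclear morphology, relative ploidy, chromatin
asymmetry and replication state can be analysed as functions of a cell's
position and fate rather than of its pixel coordinates.

The pipeline is: segment nuclei in the DNA channel; extract per-nucleus
morphometry; fit the root axis and convert to cylindrical coordinates
`(z, r, φ)` with the quiescent center (QC) at `z = 0`; assign positional
fate (layer, cell file, trichoblast/atrichoblast subtype, zone); then run
the downstream quantifications (ploidy, colocalization, configuration
codes, EdU patterns, run-length clustering).

## Segmentation and morphometry

Nuclei are detected by thresholding the DNA channel (Otsu on a 256-bin
histogram by default; an absolute threshold can be configured) and labelling
26-connected components. Touching nuclei are split by a seeded watershed:
internal DNA-void cavities are filled, an anisotropic chamfer distance
transform (26-neighbour weights equal to the physical step lengths) is
computed, and seeds are placed on its local maxima, keeping per component
only maxima at least half the component's peak depth and at least
`min_seed_sep_um` (default 2 µm) apart, strongest first. Seeds grow by
priority flood and the result is intersected with the unfilled mask, so
nucleolar cavities stay unlabelled. These concrete rules replace interactive
curation; the residual volume window (`curate()`, default 5–500 µm³)
removes background speckles and fusion remnants.

Per nucleus we report: volume (voxel count × voxel volume), surface area by
boundary-face counting (each exposed voxel face weighted by its physical
area — a deterministic convention that an independent per-voxel summation
can verify exactly, unlike marching-cubes estimators), bounding extents
W/H/D along the stack axes, per-channel integrated intensity and
intensity-weighted center of mass, and the asymmetry vector (centroid minus
DNA center of mass) with its norm. All outputs are in µm-based units,
converted once at extraction time; nothing downstream sees voxel units.

The nucleolus is measured as the largest connected low-DNA cavity fully
enclosed by the nucleus mask (6-connected complement within a padded
bounding box); a cavity touching the nucleus surface does not count.

## The root coordinate frame

The axis is fitted by averaging the nucleus centroids in axial bins along
the first principal axis and passing one smoothing spline per Cartesian
coordinate through the bin means (default 4 effective degrees of freedom:
enough for a smooth bend, stiff enough not to chase the radial layer
structure of the tube-shaped cloud). Fitting raw centroids instead of bin
means makes the spline meander through the cloud — the binning is
load-bearing. The curve is reparametrised by arclength, `z = 0` anchored at
the projection of the user-supplied QC position (the QC is identified
visually, not auto-detected), and oriented so `z` increases shootward.

The azimuth `φ` is measured in a parallel-transported normal frame, so file
indices are stable along the root but arbitrary up to a global rotation;
all statistics and tests therefore compare partitions, never absolute file
labels. Forward mapping finds the foot point by Newton iteration on
`(p − c(t))·c′(t) = 0` from a coarse grid initialisation; the inverse
evaluates the same splines and the exact inverse of the same piecewise
linear arclength interpolant, which is why the round trip is identity to
~1e-13 µm rather than merely to spline accuracy.

Positional fate uses explicit, documented conventions:

* **Layer** — half-open, inner-inclusive radial bins (a nucleus exactly on
  a boundary belongs to the inner layer); beyond the outermost bound the
  call is LRC within the cap's longitudinal extent, otherwise unassigned;
  below the QC a radial rule separates columella from LRC.
* **File** — circular single-linkage clustering of `φ` per layer, split at
  azimuthal gaps exceeding `max(3 × median gap, 0.05 rad)`; numbering
  starts after the largest gap, so indices are deterministic.
* **T/AT** — per-file mean axial spacing in the proliferation domain,
  2-means split; the tighter-spaced class is trichoblast, reflecting the
  ~1.8× thinner T cells. If the class means differ by less than 1.3× the
  call is refused (all `NA`) rather than guessed; borderline files are
  resolved by alternation with their azimuthal neighbours.
* **Zone** — per file, the PD/TD boundary is the tip-side end of the first
  spacing interval exceeding `k_td` (default 1.5) times the median spacing
  of the file's tip-most quarter; TD/EZ uses `k_ez` (default 3). Raw
  spacings are used — robustness comes from pooling the per-file
  boundaries across files by the median, and smoothing would suppress a
  step at a file's end. Using the interval's tip-side end rather than its
  midpoint halves the systematic late bias at a spacing step.

## Ploidy

The median integrated DNA intensity of nuclei within `|z| ≤ 15` µm of the
QC (excluding columella and LRC) is assigned 2C — the cells surrounding the
QC are unreplicated — and every nucleus gets `C = 2·I/I_ref`. The median
(not mean) resists a contaminating 4C nucleus in the window. C is reported
continuously; `ploidy_class()` optionally bins to the nearest power of two.
The estimate is invariant under any uniform intensity rescaling. Axial
trends come from per-layer least squares (`ploidy_trend()`); a single 2C→4C
transition is located by a two-segment piecewise-constant fit
(`ploidy_changepoint()` — by construction it finds one change point, so
multi-step profiles should be analysed zone by zone).

The shape factor is the ratio of axial to radial bounding extent, obtained
by projecting the stack-axis extents onto the local tangent and radial
directions with a quadrature rule exact for axis-aligned ellipsoids.
Whether "width" means axial or radial is a convention; here axial is the
numerator, held fixed everywhere, so T nuclei (flattened along the root
axis) have shape factor < 1.

## Chromatin colocalization and configuration codes

Two colocalization measures are provided. The *hue-range* method maps the
red (heterochromatin) and green (euchromatin) channels of each signal pixel
to the 0–255 hue scale and counts pixels in the exclusive-red (0–15),
overlay (16–58) and exclusive-green (59–255) ranges; the three fractions
sum to 1 and are scale-invariant. The *peripheral-profile* method samples a
maximum-projected equatorial plane at uniform azimuthal steps along a
reference line just inside the mask boundary (nearest in-mask pixel, never
mixing with background) and correlates profiles across channels; sampling
is rotation-equivariant, so a rotated nucleus yields a circularly shifted
profile.

Per-nucleus *configuration codes* formalise axial chromatin asymmetry: each
nucleus is split into hemisphere pairs along the local root axis (code 1 =
rootward-enriched, toward the QC; 2 = shootward) and along the lateral
direction orthogonal to both the axis and the radial direction (codes 3/4).
A mark receives a code when one hemisphere holds at least
`enrichment_threshold` (default 0.55 — marginally above 0.5, encoding
"visibly polarised" while staying tunable) of its integrated signal, axial
checks taking precedence; otherwise it is `uniform`. The joint code is
euchromatin-first (`"1_2"` = euchromatin rootward, heterochromatin
shootward, the arrangement expected immediately after a transverse
division). The polarity convention (1 = rootward) is arbitrary but fixed;
all frequency statistics are invariant to it, and reversing the root's
orientation swaps codes 1 and 2 exactly.

`configuration_frequencies()` tests the joint-code table against the
uniform null implied by random post-mitotic rearrangement: chi-squared
goodness of fit over the code space (Monte Carlo multinomial fallback,
flagged, when any expected count falls below 1) plus per-code binomial
tests with Benjamini–Hochberg adjustment — the adjustment choice is ours,
as per-bar tests on frequency data do not come with one canonically.
`anaphase_region_intensity()` profiles a mark against signed distance from
a supplied division plane in equal-width bins per daughter side; for
interphase nuclei the default plane is transverse through the centroid,
since recent divisions in the RAM are overwhelmingly transverse.

## EdU replication patterns and spatial clustering

Background statistics of the EdU channel outside all nuclei set a noise
floor (mean + 3 SD); a nucleus is S0 when its integrated signal is within
the floor for its size. Labelled nuclei are S1 (homogeneous) when the
EdU-positive fraction of the mask reaches `coverage_threshold` (default
0.6), else S2 (spotted) when at least `min_spots` (default 3) local-maximum
foci at least 1 µm apart are found. Mixed appearances resolve by the
dominance rule — coverage above threshold is S1 regardless of spots — so
classes stay mutually exclusive; nuclei matching neither archetype are
resolved (S2 with any focus, else S1) and flagged ambiguous. In practice
such calls are made by eye; these thresholds are explicit, documented
substitutes, exposed in `run_config()`, and all are background-relative,
making calls invariant to uniform rescaling.

Clustering along files uses maximal runs: nuclei of each file are ordered
by `z` (ties by id, deterministically), patterns mapped to state groups
(default S1∪S2 = labelled vs S0), and run lengths pooled across files into
histograms. Run-length totals conserve state counts exactly — this is an
invariant, tested exhaustively against a brute-force scanner on all binary
sequences up to length 12. Under i.i.d. labelling the labelled run length
is geometric with success probability `1 − p`; the generator's Markov
patch option (`edu_cluster_rho`) raises mean run length above that law,
giving a directional test of spatial coordination. Two distributions are
compared by a chi-squared homogeneity test with tail bins pooled until all
expected counts reach 5.

## The synthetic root generator

No imaging data are distributed with the package; every claim is validated
on synthetic roots with complete ground truth. `synthetic_params()` defines
the study conditions; the defaults are fixed once and describe a
desk-scale Arabidopsis-like root tip:

* geometry: 120 µm of axis above the QC; layer bounds at 8/13/18/24/30 µm
  (vascular→epidermis) with the lateral root cap to 34 µm, ending at
  `z = 80` µm; files every 7 µm of circumference; proliferation-domain
  spacing 7 µm, doubling in the transition domain (z > 60) and ×3.5 in the
  elongation zone (z > 95) — the cell-size increase that defines the zones;
* epidermis: alternating T/AT files, T spacing 1/1.8 of AT, T nuclei
  axially flattened to 0.5 aspect;
* nuclei: ellipsoids of 2 µm radial semi-axis (0.9 axial aspect), a
  central nucleolus of 0.3 radius fraction, and 8 peripheral chromocenters
  (quasi-uniform golden-spiral placement under a random rotation, so foci
  stay mutually resolvable) as truncated Gaussians of σ = 0.35 µm — counts
  and sizes are free parameters of the generator, not fitted to data;
* intensities: integrated DNA exactly `C × 1000` a.u. before noise;
  heterochromatin lives in the chromocenters, euchromatin fills the
  nucleus minus nucleolus; EdU follows the assigned S0/S1/S2 archetype,
  with S2 foci placed on chromocenters so late replication colocalizes
  with heterochromatin;
* ploidy: inner layers and LRC stay 2C; epidermis and cortex step
  2C→4C→8C across the zones, with nuclear linear dimension growing as
  `(C/2)^(1/6)` so endoreduplicated nuclei are visibly larger without
  violating layer clearances;
* configuration codes: drawn per nucleus (default distribution favouring
  `1_2`, zero mass on `3_3`/`4_4`); hemisphere enrichment 0.8, imposed
  voxelwise by iterative proportional fitting so the coded hemisphere holds
  exactly the target fraction while the orthogonal axis stays balanced —
  without the balancing step, the lumpy 8-speckle heterochromatin signal
  randomly exceeds the classification threshold on the wrong axis;
* rasterisation: 0.4 × 0.4 × 0.8 µm voxels (mild z-anisotropy, as in
  confocal stacks), about 300 × 195 × 98 voxels at the defaults; additive
  Gaussian noise and constant background are available but default to 0.

`generate_feature_table()` draws from the same placement model without
rasterising (features computed analytically, multiplicative noise
`table_cv`), which is what the tabular stages are tested on at scale.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: optical point-spread blur and depth attenuation,
touching/fused nuclei beyond mild overlaps, irregular (non-ellipsoidal)
nuclear shapes, mitotic figures as image objects (mitosis is handled at
table level only), tapering layer radii, and biological covariation beyond
what is parameterised. The validation shows the *machinery* is correct and
calibrated, not that real roots meet its assumptions.

## Numerical choices and degenerate inputs

Tie-breaks and edge rules are all deterministic: radial bins inner-
inclusive; file numbering from the largest azimuthal gap; z-ties in run
extraction broken by id (with a warning); a flat DNA channel yields zero
labels with a warning rather than an error; an empty calibration window,
empty mask, or zero-variance profile is an error. Problem sizes in the test
suite (a ~240-nucleus raster for segmentation and configuration work, a
~1300-nucleus raster for the EdU classifier, 10⁴-nucleus sequences and
1000-replicate simulations for the statistical calibration checks) were
chosen as the smallest sizes at which the targeted effects are
unambiguous.

## Known limitations

* The axis fit needs nuclei spread along the root; it is unreliable below
  a few dozen centroids and refuses fewer than 20.
* `ploidy_changepoint()` fits exactly one transition.
* File clustering assumes files are azimuthally separated by more than
  their internal jitter; heavily disordered tissue would need a different
  clustering primitive.
* The T/AT classifier needs at least two files with three or more
  proliferation-domain nuclei and real spacing contrast.
* Configuration codes assume the division plane is transverse unless a
  plane is supplied.
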