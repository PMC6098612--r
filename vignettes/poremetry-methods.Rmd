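---
title: "Measuring pore size six ways: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pore size six ways: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremetry)
```

## The problem

Scaffolds for bone regeneration are open-pore foams whose pore size governs
cell ingrowth and vascularization. Reported "pore sizes" depend heavily on
the estimator: a 3D sphere-fitting transform over a micro-CT volume, four
different planar parameters on 2D sections, or manual axis measurements on
SEM micrographs all answer subtly different questions about the same void
space. Since real pore networks are irregular and interconnected, no ground
truth exists for real specimens, and raw scans are rarely shared. This
package therefore pairs the six estimators with synthetic phantoms whose
pore sizes *are* known, so that each estimator's biases can be demonstrated
and regression-tested rather than argued about.

## Containers and conventions

Volumes are 3D arrays in `(section, row, column)` order with isotropic
voxels; `voxel_size` is the pitch in micrometres (4.5 µm is the default
scanning pitch in the run configuration). `binary_volume` marks the solid
scaffold phase `TRUE`. Sections are cut perpendicular to the first axis,
matching the convention of cutting cylindrical specimens transversely.

## The 3D estimator: maximal inscribed spheres

The local thickness at a pore voxel is the diameter of the largest ball
that lies entirely in the pore phase and covers the voxel. Three numerical
choices matter:

* **Effective radius.** A candidate ball centered at c has radius
  ρ(c) = EDT(c) − ½ voxel, where EDT is the exact Euclidean distance to the
  nearest non-pore voxel *center*. Subtracting half a voxel makes a slab of
  gap t measure t and a lone pore voxel measure one voxel. The residual
  discretization is below 0.05 voxel (an off-axis background center can
  overstate the face distance by at most that much on the structures the
  tests exercise); all tolerances in the tests are one voxel or wider.
* **Midpoint candidates.** Balls anchored only at voxel centers measure
  even-width gaps one voxel low, because the true maximal ball sits between
  two voxel centers. Candidate centers therefore also include the midpoints
  of axis-adjacent pore-voxel pairs, whose distances come from the same
  separable transform evaluated at half-offset query points. The
  brute-force oracle uses the identical candidate-set definition but
  evaluates it exhaustively (no distance transform, no ridge reduction, no
  painting), and the two paths agree voxel-wise well within the ±1 voxel
  band the tests assert.
* **Boundary policy.** The VOI boundary and the grid border count as solid
  for ball containment. This prevents peripheral pores from inflating into
  open space, at the cost of biasing edge voxels low — visible as a thin
  low-valued rim in thickness fields, and the reason the uniform-slab test
  uses a grid much wider than the gap.

The 3D pore-size sample is voxel-weighted (one value per pore voxel), the
standard weighting of structure-separation outputs; a per-region weighting
(one maximal value per connected pore) is available but is not the default,
since whether published 3D distributions are voxel- or pore-weighted is
usually unstated.

## The planar parameters

Computed per 8-connected pore region on evenly spaced sections (default 5),
excluding the outermost 5% of the VOI extent. Border-touching regions are
excluded by default because truncated pores bias every parameter low; a
`keep` policy is available, as is a `merge_regions` mode that treats each
section's whole pore phase as one object — under high interconnection the
merged mode inflates AECD (and MD) dramatically, which is the plausible
mechanism behind published section-level AECD values exceeding MD even
though the isodiametric inequality forbids it for a single region. Neither
mode is claimed to replicate any particular software's object separation.

* **MD** — maximum pairwise distance between pixel centers (via convex
  hull) plus one pixel of extent correction, so a single pixel measures one
  pitch.
* **BICD** — maximum of the region's circle-fitting transform (equivalently
  2·max EDT up to the half-pixel center discretization). Using the
  transform maximum keeps MT ≤ BICD an exact identity (a mean never exceeds
  its maximum).
* **AECD** — 2·sqrt(area/π) from the pixel count.
* **MT** — mean of the 2D local thickness over region pixels.

Per region the chain MT ≤ BICD ≤ AECD ≤ MD holds up to rasterization (the
tests assert a 2-pixel band): the inscribed circle's area bounds the area,
and the isodiametric inequality bounds the area by π·MD²/4.

Shape anchoring in the 2D phantoms: curved shapes are rasterized around a
pixel center so a candidate center coincides with the true inscribed-circle
center; rectangles are anchored per axis so each side spans a whole number
of pixel footprints. Center-sampling rasterization decides membership by
the pixel center.

## The SEM proxy

Manual measurement is modeled as selection plus a statistic. Selection:
regions with AECD below a visibility cutoff are never picked (small pores
are overlooked even though they contribute area), selection is uniform or
area-proportional, without replacement, until a fixed number of pores per
image (default 40) or exhaustion. Statistic: (maximum Feret + minimum
Feret)/2, the caliper-style long/short axis average; fitted-ellipse axes
would be a defensible alternative but caliper extremes are closest to
manual practice. Raising the cutoff can only remove the smallest eligible
pores, so the proxy's median is non-decreasing in the cutoff — this
one-sided censoring is the mechanism by which manual measurements run high
relative to voxel-weighted 3D values. The cutoff is a free parameter, not a
calibrated reproduction of any observer.

## Preprocessing

* **Adaptive threshold**: solid iff intensity strictly exceeds the local
  mean over a truncated cubic window plus an offset. A window with zero
  intensity range carries no local contrast, so such voxels fall back to
  the volume-wide mean; this makes a noise-free two-valued rendering
  round-trip exactly while a constant volume stays all-pore under the
  strict inequality. The windowed *mean* is the simplest defensible
  statistic where a vendor's exact variant is undocumented; radius and
  offset are config-exposed.
* **Despeckle**: 26-connected solid components below a voxel-count
  threshold flip to pore, then small enclosed pore components flip to
  solid; the background-connected pore space is exempt, and components
  exactly at the threshold are retained. Idempotent.
* **Shrink-wrap VOI**: the solid phase is dilated by a Euclidean ball of
  the closing radius; everything not reachable from the grid border through
  the complement of that envelope is inside; the envelope is pulled back by
  the same radius, keeping voxels whose distance to the exterior is *at
  least* the radius. The non-strict comparison makes the wrap extensive (it
  never drops solid voxels) and lets a radius-r closing bridge surface gaps
  of about 2r voxels. The radius must be chosen to seal surface pore
  openings — about half the typical pore diameter in voxels; with a smaller
  radius, surface-connected pore space is honestly classified as exterior.
* **Connectivity**: 26 in 3D and 8 in 2D for the phase of interest (the
  mainstream micro-CT convention), 6 for complement/background operations.

## Phantoms: what they emulate and what they do not

The overlapping-sphere foam reproduces interconnected pores of controlled
diameter with an exact per-sphere record; the random-field foam reproduces
the irregular lamellar wall texture of freeze-dried scaffolds (with
optional geometric anisotropy along the section axis) but has no per-pore
truth. The renderer models the degradations that matter for size
estimation: Gaussian blur as a partial-volume stand-in (strong enough blur
pulls sub-resolution walls below the binarization midpoint, opening false
interconnections), additive noise, and isolated bright speckles in the pore
space, which any sphere/circle-fitting estimator is sensitive to —
inserting a solid voxel can only shrink fitted spheres, never grow them,
and the tests assert exactly that monotonicity. Not modeled: X-ray physics
(beam hardening, ring artifacts), scanner geometry, SEM topography (a
micrograph is not a true plane section), or scaffold chemistry. Passing
tests therefore demonstrate correctness of the estimators and the stated
biases' mechanisms, not calibration to any real specimen.

Where no published value pins a generator parameter, defaults were chosen
once at field-plausible scales: foam porosities of 0.3–0.5, pore diameters
of tens of µm at 1–2 µm voxels (sized so grids of 36³–80³ voxels hold
dozens of pores), wall texture at correlation lengths of 5–6 voxels,
speckle rates ≤ 1%. Test and acceptance runs use those grid sizes, chosen
so the full suite completes in well under a minute of compute per module
while leaving border effects below quartile level where a test asserts
exact quantiles.

## Statistics

Samples are summarized by median and quartiles (inclusive linear
interpolation, R type 7 — the rule is named in every output because it
moves the quartile CV by a few percent), with CV = (Q3 − Q1)/median.
Group comparisons use `kruskal.test` with tie correction, followed by
Dunn's z on the pooled ranking with Bonferroni multiplication (capped at
1); pairwise Mann–Whitney × Bonferroni is available via `posthoc = "mw"`
since "Bonferroni procedure" names a correction, not a specific pairwise
statistic. Two-sample comparisons use `wilcox.test`, exact for small
tie-free samples. Normality/outlier screening (Shapiro–Wilk, Levene, and
relatives) is deliberately out of scope: those tests only motivate going
non-parametric, which this package does from the start.

## Scoring

The semi-quantitative comparison is data, not code: a CSV of eight
qualities × six estimators with entries 0/1/2 and column totals. The
packaged grid ranks 3D (9) ahead of MT and SEM (6) and MD/BICD/AECD (5).
The assessment is openly subjective; alternative weightings are expressed
by editing the CSV, and the loader validates entries, completeness and
duplicate qualities.

## Reproducibility

Every run is a pure function of its configuration and seed: phantom
generation, speckle placement and observer selection all draw from seeded,
state-restoring RNG scopes, and `run_analyze` embeds the config hash and
seed in every output, so identical config + seed gives a byte-identical
JSON report. The acceptance script re-derives the headline numbers from
scratch under a caller-supplied seed.

## Known limitations

* The half-voxel radius convention is exact for axis-aligned background but
  can overstate thickness by up to ~0.04 voxel for off-axis background
  centers; all assertions use ≥ 1-voxel bands.
* The shrink-wrap's exterior/interior split depends on the closing radius
  relative to surface pore openings; undersized radii misclassify open
  surface pores as exterior (documented above, and visible as reduced VOI
  porosity).
* Per-region 2D sampling on small grids can produce very few regions;
  statistical comparisons need grids several pore diameters wide.
* The observer model captures visibility censoring and area bias only; it
  makes no claim about any particular operator's selection behavior.
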