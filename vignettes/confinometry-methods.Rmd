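---
title: "Quantifying matrix confinement: pores, fibrils, invasion and elasticity"
author: "confinometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying matrix confinement: pores, fibrils, invasion and elasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confinometry)
```

## The scientific problem

Cancer cells invading a three-dimensional extracellular matrix must squeeze
their stiffest organelle, the nucleus, through pores that are typically much
smaller than the nuclear diameter. Whether a cell population invades, and how
deep, therefore depends jointly on the *geometry of the matrix* (pore size,
fibril thickness), the *mechanics of the matrix* (Young's modulus), and the
*mechanics of the cell* (cytoskeletal and nuclear stiffness, nuclear shape
and chromatin state). `confinometry` implements the full quantitative chain
used in such studies:

1. **Network structure** — pore-size distributions by residual sphere
   fitting and fibril/bundle thickness by medial-axis analysis, for 3D
   collagen stacks and 2D actin images;
2. **Invasion assays** — nucleus detection in gridded epifluorescence
   z-stacks, matrix-surface estimation, the 8 µm invasion rule, percent
   invasive, invasion depth and cumulative depth distributions;
3. **Nuclear morphometry** — segmentation and ellipsoid-equivalent shape
   metrics plus a chromatin intensity-variation score;
4. **AFM elasticity** — Hertz spherical-contact fits of force–distance
   curves under three probing protocols with residual-RMS quality gating;
5. **Statistics** — Mann–Whitney condition comparisons with 5/1/0.1%
   significance labels and printed-style fold changes.

Because raw confocal/AFM data of this kind are rarely deposited, every stage
is paired with a seeded synthetic generator that produces inputs *with ground
truth attached*. The generators are first-class, tested code: all claims the
test suite makes about the analysis stages are claims about their behaviour
on these synthetic inputs.

## Pore size by residual sphere fitting

A binarized network separates the fiber phase from the fluid phase
(`binarize_network()`, global Otsu by default). One analysis step of
`pore_size_spheres()` then:

1. computes the exact Euclidean distance transform (EDT) of the fluid phase
   with per-axis anisotropic spacing — distances are physical micrometres,
   never voxels;
2. ranks every fluid voxel as a candidate centre by decreasing distance
   (lexicographic voxel order breaks ties, making the algorithm fully
   deterministic);
3. greedily accepts a maximal inscribed sphere at every candidate whose
   centre is not inside an already-accepted sphere. Accepted spheres may
   overlap.

Each *residual step* deletes the accepted spheres from the fluid phase and
repeats on the residual space, capturing interstitial pores hidden between
the primary spheres. 2D actin analyses use exactly one residual step; 3D
analyses add steps while a step still covers at least 1% of the fluid volume
(capped at 5).

**Reported pore size.** The sample pore size is the median of the pooled
pore-diameter distribution with each pore weighted by the fluid volume it
newly covers — equivalently, the median over fluid voxels of the largest
accepted sphere containing each voxel. An unweighted count median is
degenerate for any space-covering scheme: the covering necessarily ends in a
long tail of near-voxel-scale spheres wedged against fibers, and at realistic
densities that tail outnumbers the physically meaningful pores. Volume
weighting makes the statistic consistent with the local-thickness definition
of pore size used by the brute-force verifier (below) and insensitive to the
tail.

**Resolution floor.** Accepted spheres below two voxels in diameter are
excluded from the reported pore set (they still count as covered space).
This mirrors the resolution limit of the images themselves — structures
near the voxel size cannot be measured, only rasterized — and the same
two-voxel floor is enforced for generated fibers.

**Boundary handling.** Volume faces are solid for pore fitting: spheres may
not extend outside the imaged cube, so edge pores are truncated rather than
unbounded. For fiber-phase analyses the outside instead *continues* the
solid, so fibrils crossing a face are not artificially thinned.

### The brute-force verifier and a measured estimator bias

`local_thickness_oracle()` computes, for every voxel of a phase, the
diameter of the largest sphere fully inside the phase that contains the
voxel, by exhaustively painting the inscribed sphere of every phase voxel in
decreasing-radius order. Its cost grows with the total painted volume, so it
is intended for moderate grids; it is the independent check for the greedy
algorithm, and the bisection target for `calibrate_fiber_count()` when a
network is requested by pore size rather than by fiber count.

On structured geometries the two approaches agree closely: a solid block
with a carved spherical void is reported as one pore of the void diameter
(within a voxel diagonal), and on a square lattice of parallel fibers with
centre spacing $s$ and diameter $d$ both land within a few percent of the
continuum diagonal-gap value $s\sqrt{2} - d$.

On random straight-fiber (Mikado) networks, however, the greedy covering
median sits **systematically below** the local-thickness median — by about
14–20% in 3D across the densities we generate, and by a few percent in the
dense 2D mesh regime. The mechanism is intrinsic to centre suppression: when
the natural centre of a pore falls just inside a previously accepted
neighbouring sphere, it is suppressed, and its region is later covered by
smaller spheres centred in the wedge between the accepted ones. Every such
wedge voxel is assigned a sphere smaller than the largest sphere that
actually contains it. The effect grows with the breadth of the pore-size
distribution, which is why regular phantoms barely show it and polydisperse
Mikado networks show it fully. We verified that the plausible variants do
not remove it: weighting pores by their full sphere volume over-counts
overlapping mid-size spheres (worse), restricting candidates to distance
local maxima reduces coverage further, and count medians are degenerate as
described. The bias is therefore reported as a property of this estimator
class, and round-trip comparisons between the greedy median and the oracle
median on Mikado geometry should be read with it in mind.

## Fibril and bundle thickness

`structure_thickness()` runs on the fiber phase: measurement points are the
medial-axis voxels (the ridge of the EDT — in-phase local maxima of the
distance map), distributed along each fibril; the local diameter at a point
is twice its distance to the fluid phase. A single analysis step is used, no
residual steps. On ideal cylinders the mean recovers the true diameter
within one voxel across diameters of 4–20 voxels; the voxel size is the
resolution floor of the estimate, and diameters below roughly five voxels
carry a rasterization bias of a few tenths of a voxel (low), visible in the
244 nm regime sampled at 50 nm voxels. Using the distance ridge rather than
topological thinning sidesteps spur branches entirely — rasterization
whiskers are not distance maxima — at the cost of slightly denser
measurement-point sets at fibril crossings.

## Invasion assays

The acquisition layout emulated by `invasion_stack_spec()` is a grid of
epifluorescence nucleus stacks (11 × 11 positions with 4 µm z-spacing in the
emulated protocol) over one well. The analysis chain:

- `detect_nuclei()` — difference-of-Gaussians band-pass at the nucleus
  scale (inner sigma = expected radius/√3, the blob-optimal scale; outer
  1.6× larger), 3D local maxima, a robust threshold at 10 MADs above the
  median response (chosen so that a multi-million-voxel acquisition
  produces well under one false maximum in pure noise), subvoxel
  centroid refinement, and duplicate suppression within one nucleus
  radius. Two nuclei closer than the merge radius collapse into one
  detection — a documented limitation of any single-scale detector.
- `estimate_surface()` — the adherent cell layer dominates the z
  histogram, so the surface is the modal bin (width = z-spacing, bins
  anchored at the shallowest record, making the estimator exactly
  shift-equivariant); the returned z₀ is the median z within that bin.
  Ties break toward the shallower mode. One surface per well.
- `classify_invasive()` — depth = z − z₀, positive downward; a cell is
  invasive iff depth > 8 µm, *strictly*, so a cell at exactly 8 µm is
  non-invasive. The threshold absorbs small surface roughness into the
  adherent class.
- `summarize_invasion()` — percent invasive per replicate, then mean ± sd
  across replicates; invasion depth is the mean depth *of invasive cells
  only* (a mixture with the surface layer could never reach the hundreds
  of micrometres that deep-invading lines show), then mean ± sd across
  replicates.
- `cumulative_depth()` — the right-continuous ECDF of depth;
  `deepest_fraction()` selects the deepest 10% of invasive cells, keeping
  all records tied at the cut.

The depth generator is a point mass at the surface plus an exponential tail
— two parameters that reproduce the qualitative shape of measured cumulative
depth curves. It does not emulate cell–cell exclusion, matrix heterogeneity,
or detection-confounding debris; tests passing on it validate the geometry
and bookkeeping of the chain, not detector performance on real stacks.

## Nuclear morphometry

`segment_nucleus()` applies an Otsu threshold within the subvolume, keeps
the connected component containing the seed point and fills interior holes.
`shape_metrics()` derives axis lengths from the eigen-decomposition of the
voxel-coordinate covariance: for a uniform solid ellipsoid the variance
along a principal semi-axis $a$ is $a^2/5$ in 3D ($a^2/4$ in 2D), so axis
length $2\sqrt{5\lambda}$ returns the true axis lengths of an ideal
ellipsoid in any orientation. Minor axis, major axis, aspect ratio and
volume (voxel count × voxel volume) follow. Masks thinner than two voxels
along a principal axis are flagged low-confidence.

`chromatin_variation()` is an explicit surrogate, not a reconstruction of
any published chromatin-heterogeneity algorithm: the coefficient of
variation of background-subtracted intensities inside the mask. It is zero
for uniform nuclei, strictly increasing in the generator's speckle contrast,
and invariant to global intensity rescaling — sufficient to *rank*
condensation states between conditions.

## AFM elasticity

The Hertz spherical-contact model relates force to indentation,

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

with Young's modulus $E$ (Pa), Poisson ratio $\nu$, bead radius $R$ and
indentation $\delta = z - z_0$ beyond the contact point $z_0$. Fits
(`hertz_fit()`) are linear least squares in $\delta^{3/2}$ after removing a
constant baseline, with $z_0$ a free parameter refined jointly (coarse grid
plus local optimization) — vendor software keeps its contact-point method
proprietary, so the package owns it. Protocols (`run_protocol()`):

- **matrix**: 45 µm bead (R = 22.5 µm), 5 nN setpoint, *retract* segment,
  full window, fits pooled per location;
- **cytoskeleton**: 6 µm bead, 0.5 nN, approach segment, full window,
  mean over accepted points per cell;
- **nucleus**: 6 µm bead, 5 nN, approach segment, *topmost 10% of the
  force range* of the indentation part — the deep-indentation portion in
  which the nucleus dominates the response — mean over accepted repeats
  per cell.

Two conventions deserve flags. First, $\nu = 0.5$ (incompressible) is the
package default for both cells and matrix; it is a convention, not a
measured value, and it is configurable. Second, "topmost 10%" is anchored on
the force range; anchoring on indentation depth is available as
`window = "top10-depth"`. Cell protocols fit the approach segment by
default (the vendor-default convention), the matrix protocol the retract
segment; both are configurable.

Quality gating (`rms_filter()`): a fit is accepted iff its residual RMS is
at most 150 pN — inclusive at the threshold, identical for every condition.
On clean synthetic curves the accept set is stable for thresholds anywhere
in 100–200 pN, while a single injected 2 nN spike reliably pushes a curve
over the gate. Cells whose repeats are all rejected are excluded and
reported, never silently dropped.

Noiseless round trips recover $E$ to better than 0.1% across 50–1000 Pa for
both bead radii and both windows; fitted moduli scale exactly linearly under
force scaling and as $R^{-1/2}$ under a misdeclared bead radius — useful
diagnostics of the Hertz form itself.

## Statistics

All condition contrasts use the two-sided Mann–Whitney U test
(`mann_whitney_u()`, backed by `stats::wilcox.test`): exact enumeration when
both samples are small (min(n, m) ≤ 8) and tie-free, otherwise the
tie-corrected normal approximation with continuity correction. Significance
labels follow the 5/1/0.1% convention with strict inequalities. Fold changes
are treated/control means rounded half-up to two decimals, matching how such
ratios are conventionally printed. No multiple-testing correction is applied
(the emulated analyses apply none); the report footer says so.

## Synthetic generators: what they emulate, and what they do not

- **Fiber networks** are straight random chords (Mikado model) dilated to a
  Gaussian-distributed diameter, blurred with a separable Gaussian PSF and
  corrupted with Gaussian (optionally Poisson) noise. Real collagen fibrils
  curve, branch and bundle; none of that is modelled, because the
  downstream consumers are pore/thickness statistics, not fibril mechanics.
  Requested by *pore size*, a network is resolved to a fiber count by
  bisection against the local-thickness oracle (5% relative tolerance).
- **Nucleus stacks** render nuclei as 3D Gaussian blobs with exact truth
  tables; **nucleus subvolumes** are rotated solid ellipsoids with optional
  log-normal speckle texture.
- **Force curves** sample the exact Hertz force on a regular position grid
  up to the setpoint, with baseline offset/slope, Gaussian force noise and
  optional spike artifacts.
- Every generator draws all randomness from one private stream seeded per
  call: identical specs give bit-identical outputs, and generation never
  perturbs the caller's RNG state.

Default acquisition geometries are desk-scaled: the emulated protocols image
150 µm cubes for pore analysis and 25 µm cubes at 0.05 µm voxels for fibril
thickness, while the package defaults and test suite use 37 µm cubes at
0.29 µm voxels (128³), 9.6 µm cubes at 0.05 µm voxels, and 51.2 µm 2D fields
at 25 nm pixels (2048²) — sizes chosen so the full chain, including the
quadratic-cost oracle, runs comfortably on one CPU while keeping ≥ 12 voxels
across every structure of interest. The confocal voxel sizes themselves are
package choices, not measured values.

## Numerical conventions

- EDT distances are measured between voxel centres; an inscribed sphere at
  a voxel has radius EDT − h/2 (h = finest voxel edge), which guarantees
  voxel-level containment in the phase. Thickness measurements use the raw
  2 × EDT diameter at ridge points, which is exact for on-grid slabs and
  unbiased within one voxel for cylinders.
- Candidate ordering is descending distance, then ascending linear voxel
  index; all stages are deterministic given a seed.
- `weighted_median` returns the smallest value whose cumulative weight
  reaches half the total — no interpolation, so reported medians are
  always observed pore diameters.
- Degenerate inputs fail loudly: constant images, empty phases, seeds in
  background, shuffled force files, sub-noise setpoints and infeasible
  pore targets all raise errors rather than returning numbers.

## Known limitations

- The greedy covering median under-estimates the local-thickness median on
  polydisperse random networks (measured ~14–20% in 3D), as analysed above.
- Fibril thickness at ≤ 5 voxels diameter is biased low by a few tenths of
  a voxel; sub-voxel structures are not measurable at all.
- The nucleus detector is single-scale and merges nuclei closer than one
  nucleus radius; detection parameters are validated on synthetic stacks
  only.
- The chromatin score is a ranking surrogate, not a calibrated
  heterogeneity measure.
- Hertz fitting assumes a rigid sphere on an elastic half-space: no
  bottom-effect correction for thin samples, no viscoelasticity, no
  cantilever calibration.
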