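---
title: "Morphometry of the segmented axial nerve cord: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of the segmented axial nerve cord: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancmorph)
```

## The problem

The axial nerve cord (ANC) of the octopus arm is organized into repeating
segments of neuronal cell bodies separated by neuron-poor septa through
which nerves exit. Quantifying that organization requires a small set of
morphometric statistics computed from two kinds of raw material: manual
SWC reconstructions of individual nerves traced outward from their ANC
exit, and tables of manual measurements (segment widths, sucker widths,
nuclei counts) made on stained sections. `ancmorph` implements the full
quantitative chain — trace validation, Sholl branching profiles, exit
trajectory vectors, circular coverage statistics, the factorial
measurement analysis, and particle-style nuclei counting — together with
a synthetic-data module that generates each input with known ground
truth, so the whole pipeline is testable without microscopy data.

## Sholl profiles of traced nerves

A nerve is a rooted tree of 3D points in micrometres. Its branching
profile is the number of intersections between the traced fiber and
spheres of radius $r = s, 2s, 3s, \dots$ centered at the nerve's exit
point (the trace root), with spacing $s = 10\ \mu m$ by default. Shells
extend to the smallest multiple of $s$ at or beyond the most distant
*node* (spheres are geometric objects, so the range is set by Euclidean
distance, not cable length).

Crossings are computed exactly. Along an edge from $p$ to $q$ the
squared distance to the center is a quadratic
$f(t) = a t^2 + b t + c$ on $t \in [0,1]$; each simple root of
$f(t) = r^2$ strictly inside the edge is one crossing. This makes the
conventions unambiguous:

* a re-entrant edge (out through the sphere and back in) has two simple
  roots and contributes 2 — we count intersections, not visits;
* a tangency is a double root and contributes 0;
* a node lying exactly on a sphere counts once if and only if the sign
  of $\mathrm{dist} - r$ strictly before the node differs from its sign
  immediately after along at least one child edge (so a fiber that
  touches a shell at a node and retreats contributes nothing). Exact
  coincidence is decided with an absolute tolerance of
  $10^{-9}(1 + r)\ \mu m$, far below tracing precision, so it only
  matters for deliberately constructed geometry.

The test suite checks this implementation against an independent
brute-force oracle (`sholl_profile_dense()`) that resamples every edge
at $0.01\ \mu m$ and counts sign changes; the two must agree at every
shell on randomly generated trees.

Profiles are summarized with an ordinary least-squares polynomial of
degree 5 (`fit_profile()`). Fitting is refused, not silently downgraded,
when a profile has fewer than `degree + 1` shells. No weighting or
smoothing is applied. For cross-specimen comparison, shell radii are
divided by the cable length of the longest nerve — operationally, the
nerve flagged as reaching the skin. When no trace carries that flag the
package falls back to the maximum cable length in the set and warns,
since the two definitions coincide in the intended use.

We compute Sholl in full 3D. A projected (2D) variant would give
different counts for strongly non-planar nerves; figures that show
profiles in two dimensions are projections for display only.

## Average trajectory

The exit direction of a nerve is summarized by the vector from the
trace root to the center of the traced process. The default center is
the unweighted mean of all node coordinates, root included, which
matches a centroid taken directly over a tracer's exported point list.
Because manual traces have uneven node density, an arc-length-weighted
centroid (each edge contributing its midpoint weighted by its length) is
offered as `weighting = "arc_length"`; the two agree for evenly sampled
traces. Trajectories are equivariant under rotation and invariant under
translation, which the suite verifies with random rigid motions, and
cone-grown synthetic traces must keep their trajectory inside the
generating cone.

## Angular coverage ("suckerotopy")

Oral nerve tips tagged by the side of the ANC they arise from (ExA or
InA) are translated so their centroid sits at the origin, projected to
the transverse plane by dropping the proximal–distal coordinate, and
scaled to unit vectors, creating a circle of labelled tips. The
statistic is the fraction of that circle attributable to each group.

We define the partition by placing a boundary at the circular midpoint
between each adjacent pair of differently-labelled tips; a group's
extent is the total arc it owns. This is exactly the nearest-tip rule —
every angle on the circle belongs to the group of its nearest tip in
circular distance — and therefore the extents always sum to 360°, which
is why reported group pairs are complementary percentages. A bare
per-group angular span would not have that property. Two
differently-labelled tips at the same angle produce a zero-width arc
there, a deliberate, deterministic tie rule.

Two centering conventions matter more than they appear to:

* **Tip centroid** (the default, and what one does with real data when
  the sucker center is unknown). For strongly asymmetric tip clouds the
  centroid sits away from the circle's geometric center, and measuring
  angles from it systematically compresses the larger group's apparent
  extent — a bias of several percentage points at a 65/35 split of an
  ideal circle.
* **Known center** (`center_and_normalize(tips, center = ...)`), used
  whenever the circle center is available independently — always the
  case for synthetic data, where the generator's origin is the center.

The recovery tests and the acceptance script use the known center, so
that the quantity being tested is the partition estimator itself rather
than the centering heuristic; the vignette flags the centroid bias as a
caveat for interpreting coverage fractions from real, strongly
asymmetric tip sets.

## Segment and sucker measurements

The measurement stage reproduces the arithmetic conventions of the
manual protocol exactly:

* `segments_per_sucker(a, p, n)` = mean of the anterior and posterior
  counts, divided by the number of suckers spanned (6 by default);
* `summarize_widths()` pools anterior and posterior sides into one mean
  per (position, territory), then forms the per-position total as the
  mean of the ExA and InA means — not the pooled grand mean, so an
  unbalanced territory cannot tilt the total;
* `cell_density()` = nuclei count / patch area;
* `cross_sectional_area()` = width × height;
* sem = sd/√n with the n−1 denominator.

The factorial stage (`two_way_anova_tukey()`) fits
`response ~ position * territory`, reports F and p per factor and for
the interaction, and follows with Tukey HSD pairwise comparisons on the
pooled error term, at α = 0.05. Sums of squares are Type II, which
coincide with the classical two-way ANOVA for the balanced designs the
protocol produces (n = 24 per condition) but remain well-defined when
cells are lost. If any cell has fewer than two replicates the
interaction is refused (additive model, with a warning) rather than
silently absorbed. Side (anterior/posterior) is averaged out before the
ANOVA rather than entering as a third factor, consistent with the
two-step averaging convention above.

## Nuclei counting

`count_nuclei()` re-implements particle-analysis counting as an
explicit, parameterized procedure: binarize at a global threshold
(intensity ≥ t), label connected components (8-connectivity by default,
the common particle-analysis convention; 4-connectivity available),
discard components below a minimum area, and report counts, centroids
and areas in physical units via the pixel size. Otsu's method is
offered (`otsu_threshold()`) but is not the default, since a fixed
threshold is the declared baseline. For density, a component belongs to
a rectangle iff its centroid lies in the half-open region
$[x_0,x_1)\times[y_0,y_1)$ — deterministic for border-touching
particles and safe against double counting across adjacent rectangles.
On images of well-separated blobs the count is provably exact and
monotone non-increasing in both threshold and minimum area; these
properties are tested, and the 4-connected labelling is cross-checked
against an independent implementation.

## What the synthetic generators emulate

Each generator is a pure function of its parameters and one integer
seed, drawn through a named stream per generator so regeneration is
bit-identical and adding generators never shifts existing fixtures.
Defaults encode the study conditions:

* `gen_trace()` grows straight paths, Y-trees, outward-biased random
  trees and cone-confined paths, and emits the dense-oracle Sholl
  profile as ground truth. Random trees use edge lengths of 5–15 μm and
  a 0.7 radial bias — branchy, mostly outward growth resembling traced
  nerves at the tens-to-hundreds of μm scale.
* `gen_tipset()` draws tips uniformly within per-group angular arcs,
  with radial jitter (sd 0.05) and out-of-plane jitter (sd 0.1). The
  default arcs give ExA 65% of the circle and InA 35%, the observed
  order of asymmetry between the external and internal ANC sides. The
  emitted ground truth is each arc's width plus half of each flanking
  inter-group gap, over 360 — the large-sample limit of the midpoint
  partition.
* `gen_segment_table()` draws widths as
  `base − taper·position + offset·1[ExA] + N(0, sd)` with defaults of
  50 μm base, 10 μm taper per position step, 8 μm ExA−InA offset, 4 μm
  noise and 12 replicates per (position, side, territory) cell — i.e.
  n = 24 per (position, territory) condition after pooling sides — plus
  sucker records targeting 7.5 segments per sucker. Density rises
  distally and is slightly higher on InA. Magnitudes are
  synthetic defaults chosen to be realistic for arm tissue at this
  scale, not measured data.
* `gen_nuclei_image()` places Gaussian blobs (peak 1, σ = 3 px) with
  centers at least 8σ apart, guaranteeing the thresholded components
  stay disjoint, and emits the true centers.

What they deliberately do **not** emulate: imaging noise and uneven
illumination, touching or overlapping nuclei, tracing errors (broken or
merged paths), tissue deformation, and anatomical correlation between
nerves. Tests passing on this material therefore validate the
computational chain — geometry, partitioning, arithmetic, inference
calibration — not robustness to acquisition artifacts.

## Problem sizes and runtime choices

The test suite runs the Sholl/oracle comparison on 100 random trees,
coverage recovery on 100 tip sets of 200 tips per group, ANOVA
calibration on 1,000 null tables (expecting the per-factor rejection
rate to sit in 2.5–7.5% at α = 0.05) plus 200 powered tables at a
3σ offset, and nuclei exactness on 50 images of 160×160 px. These sizes
give binomial standard errors comfortably inside the asserted bands
while keeping a full run around one to two minutes; the acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch at the same sizes.

## Known limitations

* One SWC file is treated as one nerve; reconstructions that split a
  nerve across files must be merged upstream.
* The coverage statistic is plane-dependent: projecting before versus
  after unit normalization gives different fractions for strongly
  tilted tip clouds. We project first (dropping the proximal–distal
  axis), and expose the axis as a parameter.
* The centroid-centering bias described above applies to real tip sets
  whose true circle center is unknown.
* Polynomial Sholl fits use raw powers of the radius; for profiles
  extending past a few hundred μm the design matrix is ill-conditioned
  at degrees much above 5, which is one more reason the degree is never
  raised silently.
* No watershed splitting: touching nuclei count as one particle.
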