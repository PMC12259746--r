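---
title: "Methods: graph-based habitat connectivity and fragmentation on land-cover rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based habitat connectivity and fragmentation on land-cover rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habnet)
```

## The problem

habnet quantifies how easily forest-dwelling wildlife — the motivating case
is a medium-sized forest mustelid such as the stone marten — can move
between patches of native hardwood forest across a human-modified landscape,
and how that capacity changed between two classification epochs. The
landscape is a categorical 30 m land-cover raster with six classes
(agricultural/herbaceous, artificial, conifers, hardwoods, eucalyptus,
water). The analysis chain is:

1. a **resistance (friction) surface** from the land-cover classes plus
   rasterized, buffered roads, railways and highways;
2. **habitat patches**: connected hardwood regions above a minimum area;
3. **least-cost effective distances** between all patch pairs over the
   resistance surface, and one deterministic corridor polyline per linked
   pair;
4. a **habitat graph** (patches = nodes, pairs within a dispersal threshold
   = edges) carrying connectivity metrics (BC, IIC, PC, EC) and
   fragmentation indices (SPLIT, EM, EL, ED);
5. two-epoch **change accounting**, and an **occurrence-record distance
   analysis** against a seeded random-point null.

## The model and its parameters

### Resistance

Each cover class receives a unitless multiplier of traversed distance:
hardwoods 1, conifers 10, agricultural/herbaceous and eucalyptus 20, water
100, artificial 1000; railways 150, roads 100, highways 1000, burned in
with 30/30/40 m buffers. A cell belongs to a buffer when its **center**
lies inside it — an area-fraction rule would make membership depend on
sub-cell geometry that a 30 m product cannot support. Where a buffer
overlaps resistant cover the cell takes the **maximum** of the two values:
infrastructure can only add to, never relieve, the difficulty of crossing a
cell. The max rule also makes burning monotone and idempotent, which the
test suite asserts. Highways share the artificial-surface value (1000);
there is no infinite-cost "absolute barrier" state.

### Effective distance

Movement is modelled on the 8-connected cell lattice. A step between
adjacent cells costs the **mean of the two cell resistances × cell size**,
multiplied by √2 for diagonal steps — the usual cost-distance convention;
the alternative (charging the target cell's resistance alone) changes
distances and is not offered. Movement between cells of one patch is free,
so patch-to-patch distance is edge-to-edge, not centroid-to-centroid.
Distances are reported in *cost-weighted meters*: in pure hardwood
(resistance 1) one cost-meter is one meter. The 5 km dispersal threshold is
applied on this effective scale (`theta` = 5000 cost-m): a friction layer
exists precisely so that "how far an animal can disperse" is measured in
movement cost rather than straight-line meters. The threshold is
configurable for sensitivity analysis.

All-pairs distances are Dijkstra shortest paths on the weighted lattice
(via igraph). The corridor polyline for a pair is reconstructed on the
optimal-move subgraph with fully deterministic tie-breaking: among all
minimum-cost routes, the fewest-step one, then the smallest cell index at
every predecessor choice. Both layers are validated against exhaustive
path enumeration on small grids.

### Patches

Habitat is the hardwoods class (configurable). Components are labelled
with 8-connectivity by default — diagonally touching forest is one patch,
matching common landscape-metric tools and avoiding the splitting of
visually continuous forest; 4-connectivity is available. The minimum patch
area of 20 ha (200,000 m²; ~222.3 cells) is compared as `area >= min_area`
on the exact cell-count area, so a 223-cell patch (20.07 ha) passes and a
221-cell one (19.89 ha) does not. Perimeter counts exposed rook faces;
areas are pure cell counts (no polygonization), which keeps every area
identity exact.

### Connectivity metrics

With patch areas $a_i$, landscape area $A$, link counts $nl_{ij}$ (minimum
edge count on the thresholded graph) and effective distances $d_{ij}$:

$$\mathrm{IIC} = \frac{1}{A^2}\sum_i\sum_j \frac{a_i a_j}{1 + nl_{ij}},
\qquad
\mathrm{PC} = \frac{1}{A^2}\sum_i\sum_j a_i a_j e^{-\alpha d_{ij}},
\qquad
\mathrm{EC} = \sqrt{\sum_i\sum_j a_i a_j e^{-\alpha d_{ij}}}$$

Sums run over **ordered** pairs including $i = j$ ($nl_{ii} = 0$,
$d_{ii} = 0$), exactly as the double sums are written; the convention
cancels in all relative comparisons. Disconnected pairs contribute zero.
IIC has no kernel, so it is constant across a dispersal-distance sweep —
the expected signature in a by-distance table — while PC and EC are
non-decreasing in the nominal distance. $\mathrm{EC} = A\sqrt{\mathrm{PC}}$
holds exactly and is asserted at 1e-9 on seeded landscapes.

**Kernel calibration.** The exponent $\alpha$ is set so that
$e^{-\alpha d} = p_\theta$ at the nominal dispersal distance, with
$p_\theta = 0.5$ (median-dispersal convention) by default. This choice is
not dictated by the metric definitions — any published PC value depends on
it — so it is logged in every output header and configurable.

**Betweenness.** BC of patch $i$ sums
$a_j^{\beta} a_k^{\beta} e^{-\alpha d_{jk}}$ over ordered pairs whose
*route* passes through $i$. The flux formula alone, summed without the
route restriction, is independent of $i$; the restriction to paths through
$i$ is what makes it a centrality, so the restricted sum is implemented.
The route between two patches is the minimum-total-effective-distance path
on the thresholded graph, ties broken by fewer hops and then by smallest
predecessor id, making the selected route unique; an exhaustive-enumeration
oracle checks the whole accounting on all small graphs. $\beta$ defaults to
0.5 (areas temper, but do not dominate, position). On a graph where every
pair is directly linked all BC values are legitimately zero.

### Fragmentation

$$\mathrm{SPLIT} = \frac{A_t^2}{\sum_i a_i^2},\quad
\mathrm{EM} = \frac{\sum_i a_i^2}{A_t},\quad
\mathrm{EL} = \sum_i E_i,\quad
\mathrm{ED} = \frac{\mathrm{EL}}{A_t}\,10^4,$$

with $A_t$ the total retained-patch area and $E_i$ the patch perimeter.
$\mathrm{EM}\times\mathrm{SPLIT} = A_t$ exactly. ED's $10^4$ factor, taken
literally with meters and square meters, yields meters of edge per hectare
of habitat; the reporting layer also emits km and km/km². (Published
by-epoch tables sometimes label EM in km² where the accompanying totals
only balance in hectares; the package sidesteps the ambiguity by carrying
m² internally and labelling every converted column.)

### Change accounting

Two change operations are deliberately distinct: `percent_change`
($(new-old)/old \times 100$, used for metric tables) and
`share_point_change` (difference of cover shares in percentage points, used
for the cover-composition table — verified against the printed rows of the
motivating tables, where the "relative change" column is a share
difference, not a percent change of area). Rounding to two decimals happens
only at presentation; the reciprocal identity
$(1+\Delta_1/100)(1+\Delta_2/100)=1$ is tested before rounding.

### Accuracy assessment

The confusion matrix is oriented rows = predicted, columns = validated;
the transpose would swap commission ($1 - C_{ii}/P_i$) and omission
($1 - C_{ii}/R_i$). Validation units are pixels. Kappa is
$(N\sum C_{ii} - \sum R_i P_i)/(N^2 - \sum R_i P_i)$, with the degenerate
denominator ($N^2 = \sum R_i P_i$, a single effective class) defined as 0
with a warning.

### Occurrences

Records are filtered to research grade and an exclusion list (livestock and
other non-representative taxa). Each record's distance is the Euclidean
distance to the nearest point of the union of patch cells and corridor
polylines — straight-line, because "distance from a record to the network"
is an observation-space quantity, not a movement cost. The null model draws
uniform points in the landscape boundary (rejection sampling, seeded; the
full raster extent by default) and applies the same distance operator. The
heatmap kernel is Epanechnikov with compact support equal to the influence
radius (default 5 km), so "influence of r per record" is literal; a
Gaussian would leak beyond the stated radius.

## The synthetic generator

Real inputs (a classified Landsat product, an official infrastructure
layer, a citizen-science export) are not required: `generate_landcover`
grows spatially autocorrelated class blobs by seeded multi-class region
growing until each class hits its target share exactly (subject only to
integer cell rounding), `generate_infrastructure` draws extent-crossing
polylines, `generate_occurrences` places records near habitat with
probability `attraction` (within two cells of a habitat cell, hence ≤ 60 m
at 30 m resolution) and uniformly otherwise, and `perturb_epoch` converts a
stated fraction of a class into another, boundary-first, to emulate a
decade of land-cover change. Default shares (farmland 64.5%, artificial
3.4%, conifers 5.3%, hardwoods 16.1%, eucalyptus 10.4%, water 0.3%) mirror
an Atlantic rural basin at the first epoch. Region growing was chosen over
noise thresholding because patch-extraction tests need controllable ground
truth; `generate_patch_truth` goes further and guarantees isolated blobs of
exact cell counts.

What the generator does *not* emulate: classification error structure
(confusions concentrate between spectrally similar forest classes in real
products), the river-following geometry of riparian hardwood corridors,
road networks that follow valleys, and the accessibility bias of
citizen-science sampling. Tests passing on synthetic data therefore
validate the *computational* pipeline — exact geometry, graph algorithms,
metric algebra, determinism — not the ecological realism of any particular
resistance parameterization.

## Numerical choices and degenerate inputs

- Areas and link counts are integer-exact; distances are floating point.
  Oracle comparisons and identity assertions use 1e-9 relative tolerance;
  corridor reconstruction uses a 1e-7 relative tolerance when testing
  membership in the optimal-move subgraph.
- Unreachable patch pairs carry `Inf` in the cost matrix (not an error);
  kernels map them to zero contribution; `least_cost_path` on such a pair
  is an error that names the disconnection.
- Empty patch sets: IIC/PC/EC return 0, SPLIT/EM/ED raise errors (the
  indices are undefined), extraction warns and returns an empty set.
- All RNG flows through per-call seeds (`with_seed` restores the caller's
  RNG state), so every generator is a pure function of (spec, seed) and
  pipeline reruns are byte-identical.
- Problem sizes in the shipped analyses and tests (40-80 cells per side,
  200 oracle cases, 100-landscape identity sweeps) were chosen so the full
  suite re-runs in a few minutes on one core while still exercising
  multi-patch, multi-component topologies.

## Known limitations

- One resistance table for one focal-species profile; no directional,
  seasonal or species-stacked resistance.
- Single optimal polylines, not corridor swaths or circuit-theory
  current maps.
- No node-removal importance partitions (dIIC/dPC).
- The equirectangular lon/lat projection for occurrence CSVs is a
  basin-scale approximation; supply projected x/y columns for anything
  larger.
- Reproducing the absolute published values of the motivating study
  requires its deposited classified rasters and a dated occurrence
  download; the package reproduces the printed *change* arithmetic and all
  metric identities instead, and validates the computational chain on
  synthetic ground truth.
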