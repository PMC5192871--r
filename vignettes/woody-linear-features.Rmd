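---
title: "Modelling woody linear features from canopy height along boundary networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling woody linear features from canopy height along boundary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlfmap)
```

## The problem

Hedges and lines of trees — woody linear features — run along field
boundaries, connect habitats, and matter for biodiversity, carbon and water
regulation, yet national habitat maps record areal land cover and say nothing
about what stands on the boundaries between parcels. Field survey programmes
such as the GB Countryside Survey map linear features exhaustively, but only
inside a stratified sample of 1-km squares; their national figures are length
estimates, not maps. `wlfmap` implements a simple, national-scale alternative:
given a boundary line framework and a canopy height surface, classify every
boundary segment as *woody* or *other* from the height of vegetation along it.

## The model

The pipeline has five stages.

**1. Canopy height.** A canopy height model (CHM) is the difference between a
digital surface model (DSM, altitude at the top of canopies) and a digital
terrain model (DTM, bare-ground altitude):
$\mathrm{CHM} = \mathrm{DSM} - \mathrm{DTM}$. Both grids must be aligned;
cells missing in either are missing in the CHM. `canopy_height()` implements
this; grids are plain matrices with top-left georeferencing, cell $(r,c)$
covering a half-open square so that every point belongs to exactly one cell
(points on an interior edge fall east/south; the extent's own closing edges
clamp into the last row/column, where no neighbour exists to take them).

**2. Masking.** Woody boundary features are not looked for where they cannot
occur or cannot be detected: built-up, woodland, littoral and sublittoral
land cover, and ground above 300 m altitude. `apply_mask()` sets the CHM to
**zero** there (not missing — the model asserts "no woody feature here",
reserving nodata for genuinely absent input). Woodland masking matters most:
continuous canopy would otherwise make every boundary through a wood look
hedged. The altitude screen may be supplied on a coarser grid (national
terrain screens are often 50-m products against 5-m canopy data); it is
resampled to the CHM grid by nearest neighbour, the natural choice for a
categorical pass/fail screen. The cutoff is configurable; 300 m is the
default operative value.

**3. The linear framework.** Field polygons are dissolved into a boundary
network by `polygons_to_network()`: every edge shared by two adjacent
polygons appears once, edges are chained through degree-2 vertices, and
segments end exactly at junctions (boundary-graph vertices of degree ≠ 2).
An isolated ring with no junctions stays one closed segment. A segment
framework noded at junctions is what makes *per-feature* attribution
meaningful: each segment is one stretch of boundary between intersections.
`generalize_network()` offers standard split-point (perpendicular-distance)
simplification; the default tolerance is 0 (off) because no single tolerance
suits all inputs and fidelity is the safer default. `split_segments()` nodes
arbitrary line inputs by cutting at crossings and T-junctions.

One representational choice deserves a note: chaining stops at junctions,
not at polygon corners, so a 2×2 block of fields yields 8 segments (4
interior spokes and 4 two-edge outer arcs) built from the 12 unit edges of
the dissolved arrangement. Tests compare both the segment structure and the
underlying edge set against brute-force enumeration.

**4. Attribution and classification.** `attribute_network()` samples the
masked CHM at points every `sample_step` metres along each segment (default:
one cell size, approximating cell-traversal statistics; both endpoints are
always sampled) and records the minimum, mean and maximum height over
non-missing samples. `label_network()` then applies three inclusive
thresholds, a segment being **woody** iff

$$\min h \ge -0.13 \,\mathrm{m} \quad\wedge\quad \overline{h} \ge 0.58
\,\mathrm{m} \quad\wedge\quad \max h \le 58 \,\mathrm{m}.$$

Each threshold has a physical reading: the minimum-height floor is negative
because a ditch running beside a hedge pulls the lowest return below ground
level; the mean floor sits well below hedge height so gappy hedges still
qualify; the ceiling is the height of the tallest tree expected in GB —
anything higher along a boundary is an artefact or a building. The
comparisons are inclusive so the threshold values themselves classify as
woody. Whether height statistics should come from points along the line or
from every cell the line touches is not prescribed anywhere; point sampling
at cell-size spacing was chosen because it is well-defined for any step,
cheap, and directly checkable against a hand enumeration.

**5. Estimation, calibration, validation** — described below.

## Stratified expansion and threshold calibration

National survey estimates come from a stratified random sample of 1-km
squares: strata ("land classes") partition all squares, and the national
total is

$$\hat{T} = \sum_s N_s \, \bar{y}_s,$$

with $N_s$ the stratum's square population and $\bar{y}_s$ the mean woody
length over its sampled squares. `clip_to_squares()` splits segments at
square borders (so length is conserved and each piece belongs to exactly one
square — border-collinear pieces are assigned half-open, clamped at the
lattice's outer edge) and `stratified_total()` computes $\hat{T}$ in km. An
unweighted variant (summing sample squares without population scaling) is
available, since survey reports sometimes quote such sums, but the weighted
form is the primary estimator.

`calibrate_thresholds()` reverses the direction of inference: given a survey
target total, find thresholds whose classified network reproduces it. The
three thresholds are varied **sequentially in 0.01-m increments** — a
coordinate search in the fixed order (min floor, mean floor, max ceiling).
Because segment statistics do not depend on the thresholds, the network is
attributed once and every candidate evaluation is a vectorised relabelling,
so a full search costs seconds, not hours. Two numerical points:

* The objective $|\hat{T}(\theta) - T^\ast|$ is *piecewise constant*: it
  changes only when a threshold crosses one of the segments' order
  statistics. A one-step hill climb therefore stalls on plateaus; each
  coordinate pass instead scans the whole 0.01-m grid of its range and moves
  to the best value, with ties keeping the incumbent (which also guarantees
  the result is never worse than the start). Sweeps repeat until one changes
  nothing (`max_sweeps` caps them).
* The search ranges are part of the model, not free knobs. The minimum-height
  floor is a *sub-zero ditch allowance*: its range should top out at 0.
  Allowing it above zero lets the search "improve" on badly mismatched
  targets by annihilating every segment (estimate zero), a degenerate
  absorbing state for coordinate descent. Likewise the ceiling range should
  bracket plausible tallest-tree heights. The defaults encode this.

The per-stratum fit is reported alongside the GB-level objective but not
optimised: no multi-stratum loss is defined for this calibration, and the
national total is the quantity the thresholds were historically tuned to.

## Validation by buffered point sampling

Two independently digitised line frameworks never coincide exactly, so
segment-to-segment overlay would count line-work disagreement as
classification error. The evaluation instead:

1. collapses multi-feature survey boundaries to one label with woody
   dominance (`dominant_label()`: any woody member makes the boundary woody);
2. buffers both networks by 5 m and restricts comparison to the buffer
   intersection (`agreement_region()`);
3. samples labelled points every 5 m along each network inside the region
   (`sample_labeled_points()`);
4. pairs each reference point with its nearest model point within 10 m
   (twice the buffer radius — farther points cannot share a boundary's
   buffer pair; ties break to the lowest index, and the direction is
   configurable since neither direction is canonical);
5. accumulates a 2×2 confusion matrix and reports row percent agreement and
   Cohen's kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, with the conventional
   Landis–Koch verbal bands as annotation.

The agreement region is held implicitly: a point is inside iff its distance
to *each* network is at most the radius — exactly membership in the
intersection of the two round-capped buffers. Every query the procedure
makes (point membership, area) is answered from that definition; area is
computed by fine rasterisation (cell-centre counting) and is tested against
an independent brute-force rasteriser to within 1%.

`density_map()` summarises a classified network as per-cell woody length
over cell area (m/km² for 1-km cells), with `stratum_density_means()`
aggregating cell densities to land-class means; total density × area equals
total clipped woody length exactly, which the tests assert.

## The synthetic landscape generator

No national terrain, surface or land-cover product can ship with a package,
so `generate_landscape()` builds landscapes with known ground truth:

* a field mosaic from a perturbed grid: nodes at the field scale (default
  200 m, a typical lowland field edge), interior nodes jittered by ±30%;
* the truth network dissolved from the mosaic, with each boundary carrying a
  hedge with a stratum-dependent probability (defaults 0.55/0.25 across
  west-to-east bands, echoing hedged lowland versus sparser upland country);
* a smooth sinusoidal terrain surface (default relief 120 m, safely below
  the 300-m screen so masking is not triggered by default);
* canopy painted onto cells whose centres lie within half a hedge width
  (default 5 m wide, one cell) of a hedge line: heights uniform on 1–4 m
  (managed hedge heights), a gap fraction set to zero canopy (default 15%),
  occasional emergent trees up to 25 m, and, beside some hedges, a shallow
  ditch depression of −0.1 m — within the −0.13-m allowance the minimum
  floor exists for;
* woodland and built-up patches with their own (tall) canopy, to give the
  mask real work;
* Gaussian surface noise of configurable standard deviation (default 0);
* a census stratum table (every square listed as sampled), which estimation
  tests subsample.

All draws come from one stream seeded explicitly, in a fixed documented
order, so identical parameters give bit-identical landscapes on any
platform. What the generator does **not** emulate: radar sensor physics and
its speckle, correlated height error, curved or braided boundaries, real
land-class definitions, partial canopy over boundary walls. Passing tests on
these landscapes therefore demonstrates the *pipeline's* correctness — exact
recovery when the truth is in-threshold, graceful degradation with gaps and
noise — not field accuracy on real radar data, where height error is neither
zero-mean-independent nor absent.

`degrade_truth()` drops and jitters truth segments to mimic the line-work
mismatch between frameworks, exercising the buffered validation path: with
1-m vertex jitter against a 5-m buffer, well over 95% of points still match.

## Worked example

```{r example, eval = FALSE}
ls <- generate_landscape(landscape_params(extent_km = 2, seed = 7))
chm <- apply_mask(canopy_height(ls$dsm, ls$dtm), ls$landcover, ls$dtm)
model <- classify_network(ls$truth, chm)
glance(validate_networks(model, ls$truth))
est <- stratified_total(square_lengths(clip_to_squares(model)), ls$strata)
```

## Problem sizes and tolerances

The test suite and the acceptance script run landscapes of 2–5 km extent at
5-m resolution (up to a 1000×1000 grid, ~1,300 boundary segments), sizes at
which every stage completes in seconds on one core while still exercising
thousands of segments and hundreds of squares; the calibration experiment
uses the 5-km extent. Geometric identities (length conservation under
splitting and clipping, density mass balance) are asserted to 10⁻⁶ m;
vertex-identity keys use a 10⁻⁶-m grid; Monte-Carlo estimator checks use 200
replicates and a two-standard-error band.

## Known limitations

* A single planar metric CRS is assumed throughout; no reprojection.
* Polygon inputs must share identical vertex chains along common edges
  (true of any topologically clean mosaic); near-coincident but unequal
  lines are not conflated.
* The classification is binary woody/other; walls, fences, banks and water
  are not discriminated from one another.
* Percent agreement and kappa are reported without standard errors; the
  survey's published variance estimator is out of scope.
* National applications of this kind of screen have used cutoffs of both
  300 m and 350 m; 300 m is the default here and the cutoff is exposed in
  configuration rather than fixed.
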