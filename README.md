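# d2plot: DNA density and distance-to-periphery analysis of single-cell 3D genomes

Single-cell Hi-C reconstructions (Dip-C, NucDynamics) turn a cell's contact
map into a particle cloud: one particle per 20 kb (diploid) or 100 kb
(haploid) genomic bin, each with an x/y/z coordinate. `d2plot` computes two
global physical properties for every particle — smoothed **DNA density**
and **DisTP**, the distance to the nuclear periphery — and integrates them
into a 2D matrix of *physical states* (the "D² plot") that links nuclear
organization to transcriptional activity. It is aimed at chromatin and
nuclear-organization researchers who have reconstructed single-cell
structures and want a genome-wide, cross-cell-comparable readout of where
each locus sits (interior vs. lamina) and how crowded its neighbourhood is.

## Method

For each cell:

1. **Cube-length normalization.** Nuclei differ in size, so the cell is
   voxelized with a cell-specific cube length: the mean distance from each
   particle to its k-th nearest neighbour (k = 7). This keeps the average
   particle count per cube comparable across cells.
2. **Smoothed density.** With `C_j` the particle count of cube `j`, the
   density of cube `i` is
   `D_i = ( Σ_{j∈S} C_j / max(‖i−j‖, 1) ) / |S|`,
   where `S` is the set of in-grid cubes within Euclidean index distance 3.
3. **Membrane cubes.** The grid is flood-filled from outside; a cube is
   part of the membrane (nuclear-envelope proxy) territory while its local
   particle total over a 5×5×5 window stays below 3, so dissociated
   outlier particles do not stop the fill.
4. **DisTP.** For each filled cube, the mean of the 10 smallest distances
   to membrane cubes, in cube-length units.

Per-cell tables are pooled on a 15×15 density × DisTP grid (standard
diploid bounds 1–3.2 × 1.21–16, or bounds fitted as mean ± 1.96 SD of
density and the [min, 95th-percentile] DisTP range). States carrying fewer
than 200 (segment, cell) observations are excluded. The occupancy
probability `P_ga` — the fraction of cells in which segment `g` falls in
state `a` — weights marker values `NV_g` (genome-wide z-scores) into state
enrichment scores

    E_a = Σ_g P_ga · NV_g / Σ_g P_ga        (z-scored across states)

with a matching occupancy-weighted SD as the stochasticity of `E_a`. Ward
clustering of states over a transcription-marker panel yields the
four-area activation model (active / intermediate / repress & histone /
repress & repeat); a segment's **activation index** `AI_g = Σ_{a∈active∪intermediate} P_ga`
tracked across differentiation stages classifies it as constantly active
(CA), repressed-to-active (RA), or constantly repressed (CR) by stage-wise
10 % quantiles.

A synthetic-nucleus generator (`synth_config()`, `generate_ensemble()`)
produces confined polymer-like ensembles with known chromatin classes and
marker loadings, so the whole pipeline is testable without any download.

## Worked example

```r
library(d2plot)

# 1. simulate a small ensemble of 8 diploid nuclei (20 kb bins)
cfg <- synth_config(n_cells = 8, n_chroms = 2, particles_per_chrom = 500,
                    seed = 11)
ens <- generate_ensemble(cfg)

# 2. per-cell density and distance-to-periphery
tables <- lapply(ens$structures, score_cell)
tables[[1]]
#> cell_d2 'synth_cell_001': 2000 segments (0 outlier particles dropped), resolution 20000 bp
head(as.data.frame(tables[[1]]), 3)
#>   chrom hap start   density    distp
#> 1     1 pat     0 0.1846542 4.492003
#> 2     1 pat 20000 0.1771491 3.980823
#> 3     1 pat 40000 0.1686087 4.435642
```

Each row is one haplotype-resolved 20 kb bin: `density` is the smoothed
particle concentration of its cube (cell-normalized units), `distp` its
distance to the membrane in cube lengths (here ~4 cubes from the
envelope).

```r
# 3. pooled D2 plot: 15 x 15 physical states + occupancy P_ga
oc <- build_occupancy(tables, bounds = fit_bounds(tables), min_segments = 50)
oc$plot
#> d2_plot: 15x15 states (84 non-empty), 8 cells, bounds [-0.1102606, 1.224916] x [1.485301, 7.482119]

# 4. a synthetic marker loading on DisTP, mapped as state enrichment
trk <- generate_marker_track(tables, alpha = 0, beta = 1, noise_sd = 0.1,
                             seed = 3, name = "interior_marker")
em <- enrichment(trk, oc$occupancy, oc$plot)
subset(em, !empty)[1:3, ]
#>    state density_bin distp_bin empty       e_raw         e_z
#> 48    48           2         3 FALSE -0.01272435 -0.11147411
#> 49    49           3         3 FALSE -0.82056887 -1.17082867
#> 63    63           2         4 FALSE  0.04169155 -0.04011665
```

The marker was built to increase with DisTP (`beta = 1`), and its
enrichment is indeed depleted (negative `e_z`) in the low-DisTP rows shown.

```r
# 5. validate DisTP against a LAD-style track: periphery probability
#    (fraction of cells with DisTP below a cut) vs. the track, averaged
#    in 2 Mb windows with 3-sigma trimming
lad <- data.frame(segment = trk$segment, value = -trk$value)
periphery_lad_correlation(tables, lad, distp_cut = 3.5)[c("r", "n")]
#> $r
#> [1] 0.9072894
#> $n
#> [1] 20
```

A track anti-correlated with interior position behaves like lamina DamID:
Pearson r ≈ 0.91 over the 20 aggregated windows.

`run_demo("out_dir", seed = 1)` runs the full pipeline — ensemble, D²
plot, three marker enrichments, 4-area model, CA/RA/CR calls across three
synthetic stages — and writes every table to `out_dir`. The same pipeline
is scriptable through the CLI (`inst/cli/d2.R`): subcommands `synth`,
`compute`, `plot-states`, `enrich`, `cluster`, `trajectory`,
`validate-lad`, `demo`.

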