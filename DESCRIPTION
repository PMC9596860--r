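Package: d2plot
Title: DNA Density and Distance-to-Periphery Analysis of Single-Cell 3D Genomes
Version: 0.1.0
Authors@R:
    person("Yuan", "Hong", email = "yuan.hong@example.org", role = c("aut", "cre"))
Description: Computes two global physical properties of reconstructed
    single-cell 3D genome structures: smoothed DNA density and distance to
    the nuclear periphery (DisTP). Particles from Dip-C style '.3dg' tables
    are voxelized on a cell-specific cube grid, membrane cubes are detected
    by outlier-tolerant flood fill, and every genomic segment receives a
    (density, DisTP) pair. Per-cell tables are aggregated into a 15x15
    density-DisTP state grid (the "D2 plot") with per-segment occupancy
    probabilities, onto which genomic and epigenomic marker tracks are
    mapped as z-scored enrichment scores with stochasticity estimates.
    Physical states are Ward-clustered into a four-area transcriptional
    activation model (active, intermediate, repress-and-histone,
    repress-and-repeat), and per-bin activation indices across cell stages
    classify differentiation trajectories as constantly active, repressed
    to active, or constantly repressed. Includes a synthetic nucleus
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
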