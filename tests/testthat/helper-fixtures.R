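# Shared synthetic fixtures, built once per test run (lazy, cached).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small diploid ensemble: 6 cells x 2 chroms x 500 segs x 2 haps
# (2000 hap-resolved segments per cell)
small_ensemble <- function() fixture("small_ens", function() {
  cfg <- synth_config(n_cells = 6, n_chroms = 2, particles_per_chrom = 500,
                      seed = 42)
  ens <- generate_ensemble(cfg)
  tables <- lapply(ens$structures, score_cell)
  occ <- build_occupancy(tables, bounds = fit_bounds(tables),
                         min_segments = 30)
  list(ens = ens, tables = tables, plot = occ$plot, occ = occ$occupancy)
})

# tiny structure of n particles uniform in a ball
random_structure <- function(n, seed = 1, radius = 5, res = 20000) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n * 3), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 9, , drop = FALSE][seq_len(n), ] * radius / 3
  genome_structure(data.frame(chrom = "1", hap = "none",
                              pos = (seq_len(n) - 1) * res,
                              x = pts[, 1], y = pts[, 2], z = pts[, 3]),
                   resolution = res, cell_id = paste0("rand", seed))
}

# hand-built occupancy/plot pair from a dense segments-x-states P matrix
toy_occ <- function(P, nbins = 15, n_cells = 1, empty = NULL,
                    counts = NULL) {
  nstates <- nbins^2
  stopifnot(ncol(P) == nstates)
  if (is.null(rownames(P))) {
    rownames(P) <- paste("1", "none", seq_len(nrow(P)) - 1, sep = ":")
  }
  if (is.null(counts)) counts <- P * n_cells
  if (is.null(empty)) empty <- colSums(counts) == 0
  segs <- rownames(P)
  parts <- strsplit(segs, ":", fixed = TRUE)
  seg_df <- data.frame(segment = segs,
                       chrom = vapply(parts, `[`, "", 1),
                       hap = vapply(parts, `[`, "", 2),
                       bin = as.integer(vapply(parts, `[`, "", 3)),
                       stringsAsFactors = FALSE)
  plot <- structure(list(bounds = standard_bounds(), nbins = nbins,
                         state_counts = colSums(counts), empty = empty,
                         min_segments = 1, n_cells = n_cells),
                    class = "d2_plot")
  occ <- structure(list(P = P, counts = counts, segments = seg_df,
                        n_cells = n_cells, resolution = 20000),
                   class = "occupancy_matrix")
  list(plot = plot, occ = occ)
}

# marker track whose NV column is taken verbatim (for hand-set NV values)
toy_track <- function(segments, nv, name = "toy") {
  structure(data.frame(segment = segments, value = nv, nv = nv,
                       stringsAsFactors = FALSE),
            class = c("marker_track", "data.frame"), name = name,
            kind = "signal")
}

# a cell_d2 table straight from vectors
toy_cell <- function(density, distp, res = 20000, cell_id = "toy",
                     chrom = "1", hap = "none") {
  n <- length(density)
  structure(data.frame(chrom = rep(chrom, n), hap = rep(hap, n),
                       start = (seq_len(n) - 1) * res,
                       density = density, distp = distp,
                       stringsAsFactors = FALSE),
            class = c("cell_d2", "data.frame"), resolution = res,
            cell_id = cell_id, n_dropped = 0L)
}
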