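#' Axis bounds for the D2 plot
#'
#' @param density_lo,density_hi,distp_lo,distp_hi Axis limits.
#' @param source `"standard"` or `"fitted"`.
#' @return An `axis_bounds` object.
#' @export
axis_bounds <- function(density_lo, density_hi, distp_lo, distp_hi,
                        source = "fitted") {
  if (density_lo >= density_hi || distp_lo >= distp_hi) {
    stop("axis bounds must satisfy lo < hi")
  }
  structure(list(density_lo = density_lo, density_hi = density_hi,
                 distp_lo = distp_lo, distp_hi = distp_hi, source = source),
            class = "axis_bounds")
}

#' Standard diploid axis bounds (density 1-3.2, DisTP 1.21-16)
#'
#' The standard range used for all diploid cell types at 20 kb resolution;
#' DisTP is in cube-length units.
#' @return An `axis_bounds` object.
#' @export
standard_bounds <- function() {
  axis_bounds(1, 3.2, 1.21, 16, source = "standard")
}

#' Fit axis bounds from pooled per-cell tables
#'
#' Density bounds are the pooled mean +/- 1.96 SD (retaining about 95% of
#' approximately normal densities); the DisTP range runs from the pooled
#' minimum to the 95th percentile, dropping the top 5% of bins farthest
#' from the periphery.
#'
#' @param cell_tables List of `cell_d2` tables.
#' @return An `axis_bounds` object with `source = "fitted"`.
#' @export
fit_bounds <- function(cell_tables) {
  dens <- unlist(lapply(cell_tables, `[[`, "density"), use.names = FALSE)
  dtp <- unlist(lapply(cell_tables, `[[`, "distp"), use.names = FALSE)
  if (!length(dens)) stop("no pooled values")
  if (sd(dens) == 0 || sd(dtp) == 0) stop("zero variance in pooled values")
  axis_bounds(mean(dens) - 1.96 * sd(dens), mean(dens) + 1.96 * sd(dens),
              min(dtp), quantile(dtp, 0.95, names = FALSE),
              source = "fitted")
}

#' Map (density, DisTP) pairs to physical-state indices
#'
#' Each axis is divided into `nbins` equal bins over its bounds; bins are
#' left-closed/right-open except the last, which is closed at the upper
#' bound. Values outside the bounds are outliers and map to `NA`.
#'
#' @param density,distp Numeric vectors.
#' @param bounds An `axis_bounds`.
#' @param nbins Bins per axis (default 15).
#' @return Integer state ids in `1..nbins^2`
#'   (`state = density_bin + nbins * distp_bin + 1`, bins 0-based), `NA`
#'   for outliers.
#' @export
assign_state <- function(density, distp, bounds, nbins = 15) {
  if (any(!is.finite(density)) || any(!is.finite(distp))) {
    stop("non-finite density/distp value")
  }
  bd <- axis_bin(density, bounds$density_lo, bounds$density_hi, nbins)
  bt <- axis_bin(distp, bounds$distp_lo, bounds$distp_hi, nbins)
  as.integer(bd + nbins * bt + 1L)
}

axis_bin <- function(v, lo, hi, nbins) {
  b <- floor(nbins * (v - lo) / (hi - lo))
  b[v == hi] <- nbins - 1
  b[v < lo | v > hi] <- NA
  b
}

#' Physical-state coordinates on the D2 plot
#'
#' @param plot A `d2_plot`.
#' @return data.frame with `state`, 0-based `density_bin` / `distp_bin`,
#'   bin-center values `density_center` / `distp_center`, per-state
#'   occurrence `count` and the `empty` flag.
#' @export
state_centers <- function(plot) {
  nb <- plot$nbins
  st <- seq_len(nb^2)
  db <- (st - 1L) %% nb
  tb <- (st - 1L) %/% nb
  b <- plot$bounds
  data.frame(
    state = st, density_bin = db, distp_bin = tb,
    density_center = b$density_lo +
      (db + 0.5) * (b$density_hi - b$density_lo) / nb,
    distp_center = b$distp_lo + (tb + 0.5) * (b$distp_hi - b$distp_lo) / nb,
    count = plot$state_counts, empty = plot$empty)
}

#' Build the D2 plot and segment-by-state occupancy matrix
#'
#' Pools the per-cell tables, assigns every (segment, cell) observation to
#' a physical state, and computes `P_ga`: the fraction of all cells in
#' which segment g falls in state a (the denominator is the total cell
#' count, so rows sum to at most 1 — outlier or unobserved cells create a
#' shortfall). States carrying fewer than `min_segments` (segment, cell)
#' occurrences are flagged empty; their occupancy columns are zeroed for
#' downstream statistics but the raw counts are retained for audit.
#'
#' @param cell_tables List of `cell_d2` tables with a common resolution.
#' @param bounds An `axis_bounds` (default [standard_bounds()]).
#' @param nbins Bins per axis (default 15).
#' @param min_segments Occurrence threshold below which a state is empty
#'   (default 200).
#' @return List with `plot` (a `d2_plot`: bounds, nbins, per-state counts,
#'   empty mask) and `occupancy` (an `occupancy_matrix`: dense `P`, raw
#'   `counts`, segment table, `n_cells`).
#' @export
build_occupancy <- function(cell_tables, bounds = standard_bounds(),
                            nbins = 15, min_segments = 200) {
  if (!length(cell_tables)) stop("need at least one cell")
  res <- unique(vapply(cell_tables, attr, numeric(1), "resolution"))
  if (length(res) != 1) {
    stop("inconsistent resolutions across cells: ", paste(res, collapse = ", "))
  }
  n_cells <- length(cell_tables)
  nstates <- nbins^2
  obs <- do.call(rbind, lapply(cell_tables, function(tb) {
    data.frame(segment = segment_ids(tb, res),
               state = assign_state(tb$density, tb$distp, bounds, nbins),
               stringsAsFactors = FALSE)
  }))
  obs <- obs[!is.na(obs$state), , drop = FALSE]
  segs <- sort(unique(obs$segment))
  si <- match(obs$segment, segs)
  counts <- matrix(
    tabulate((si - 1L) * nstates + obs$state, nbins = length(segs) * nstates),
    nrow = length(segs), ncol = nstates, byrow = TRUE)
  rownames(counts) <- segs
  state_counts <- colSums(counts)
  empty <- state_counts < min_segments
  parts <- strsplit(segs, ":", fixed = TRUE)
  seg_df <- data.frame(segment = segs,
                       chrom = vapply(parts, `[`, "", 1),
                       hap = vapply(parts, `[`, "", 2),
                       bin = as.integer(vapply(parts, `[`, "", 3)),
                       stringsAsFactors = FALSE)
  plot <- structure(list(bounds = bounds, nbins = nbins,
                         state_counts = state_counts, empty = empty,
                         min_segments = min_segments, n_cells = n_cells),
                    class = "d2_plot")
  occ <- structure(list(P = counts / n_cells, counts = counts,
                        segments = seg_df, n_cells = n_cells,
                        resolution = res),
                   class = "occupancy_matrix")
  list(plot = plot, occupancy = occ)
}

#' @export
print.d2_plot <- function(x, ...) {
  cat("d2_plot: ", x$nbins, "x", x$nbins, " states (", sum(!x$empty),
      " non-empty), ", x$n_cells, " cells, bounds [",
      format(x$bounds$density_lo), ", ", format(x$bounds$density_hi),
      "] x [", format(x$bounds$distp_lo), ", ", format(x$bounds$distp_hi),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("occupancy_matrix: ", nrow(x$P), " segments x ", ncol(x$P),
      " states, ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

# occupancy with empty-state columns zeroed (the downstream form)
effective_P <- function(occ, plot) {
  P <- occ$P
  P[, plot$empty] <- 0
  P
}

#' Write occupancy + plot as a sparse-triplet TSV
#'
#' @param occ An `occupancy_matrix`.
#' @param plot The matching `d2_plot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(occ, plot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- plot$bounds
  writeLines(c(
    sprintf("# nbins=%d n_cells=%d min_segments=%g resolution=%g",
            plot$nbins, plot$n_cells, plot$min_segments, occ$resolution),
    sprintf("# bounds=%.17g,%.17g,%.17g,%.17g source=%s",
            b$density_lo, b$density_hi, b$distp_lo, b$distp_hi, b$source)),
    con)
  idx <- which(occ$counts > 0, arr.ind = TRUE)
  out <- data.frame(segment = rownames(occ$counts)[idx[, 1]],
                    state = idx[, 2], count = occ$counts[idx])
  out <- out[order(out$segment, out$state), ]
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy file written by [write_occupancy()]
#'
#' @param path Input path.
#' @return List with `plot` and `occupancy`, as from [build_occupancy()].
#' @export
read_occupancy <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- function(k, line) as.numeric(sub(paste0(".*", k, "=([0-9.eE+-]+).*"),
                                           "\\1", line))
  nbins <- as.integer(meta("nbins", hdr[1]))
  n_cells <- as.integer(meta("n_cells", hdr[1]))
  min_segments <- meta("min_segments", hdr[1])
  res <- meta("resolution", hdr[1])
  bv <- as.numeric(strsplit(sub("# bounds=([^ ]+).*", "\\1", hdr[2]), ",")[[1]])
  src <- sub(".*source=([a-z]+).*", "\\1", hdr[2])
  bounds <- axis_bounds(bv[1], bv[2], bv[3], bv[4], source = src)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  segs <- sort(unique(df$segment))
  nstates <- nbins^2
  counts <- matrix(0, nrow = length(segs), ncol = nstates,
                   dimnames = list(segs, NULL))
  counts[cbind(match(df$segment, segs), df$state)] <- df$count
  state_counts <- colSums(counts)
  empty <- state_counts < min_segments
  parts <- strsplit(segs, ":", fixed = TRUE)
  seg_df <- data.frame(segment = segs,
                       chrom = vapply(parts, `[`, "", 1),
                       hap = vapply(parts, `[`, "", 2),
                       bin = as.integer(vapply(parts, `[`, "", 3)),
                       stringsAsFactors = FALSE)
  list(plot = structure(list(bounds = bounds, nbins = nbins,
                             state_counts = state_counts, empty = empty,
                             min_segments = min_segments, n_cells = n_cells),
                        class = "d2_plot"),
       occupancy = structure(list(P = counts / n_cells, counts = counts,
                                  segments = seg_df, n_cells = n_cells,
                                  resolution = res),
                             class = "occupancy_matrix"))
}
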