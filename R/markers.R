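#' Construct a marker track over haplotype-resolved segments
#'
#' A marker track holds, per segment, the raw indexed value and `NV`: its
#' genome-wide population z-score over non-missing segments. `NV` is the
#' normalized value entering the enrichment equations.
#'
#' @param name Track name.
#' @param segment Character vector of segment ids (`chrom:hap:bin`).
#' @param value Numeric raw values (NA = missing).
#' @param kind `"signal"`, `"coverage_fraction"` or `"point_median"`.
#' @return A `marker_track` data.frame with columns `segment`, `value`,
#'   `nv`.
#' @export
marker_track <- function(name, segment, value,
                         kind = c("signal", "coverage_fraction",
                                  "point_median")) {
  kind <- match.arg(kind)
  ok <- !is.na(value)
  if (sum(ok) < 2) stop("marker track needs at least 2 non-missing values")
  s <- sd_pop(value[ok])
  if (s == 0) stop("zero variance: cannot z-score marker '", name, "'")
  nv <- rep(NA_real_, length(value))
  nv[ok] <- (value[ok] - mean(value[ok])) / s
  structure(data.frame(segment = segment, value = value, nv = nv,
                       stringsAsFactors = FALSE),
            class = c("marker_track", "data.frame"), name = name, kind = kind)
}

#' Map binned (chrom, bin) values onto a haplotype-resolved segment universe
#'
#' Unphased marker data are duplicated to both haplotypes: every segment
#' `chrom:hap:bin` receives the value indexed at `(chrom, bin)`. Segments
#' with no indexed value are missing.
#'
#' @param name Track name.
#' @param binned data.frame with `chrom`, `bin`, `value` from one of the
#'   `index_*` functions.
#' @param segments Segment universe: an `occupancy_matrix`, or a character
#'   vector of segment ids, or a data.frame with a `segment` column.
#' @param kind Track kind, see [marker_track()].
#' @return A `marker_track` over the given universe.
#' @export
make_track <- function(name, binned, segments, kind = "signal") {
  if (inherits(segments, "occupancy_matrix")) segments <- segments$segments
  ids <- if (is.character(segments)) segments else segments$segment
  parts <- strsplit(ids, ":", fixed = TRUE)
  key <- paste(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 3))
  value <- binned$value[match(key, paste(binned$chrom, binned$bin))]
  marker_track(name, ids, value, kind = kind)
}

intervals_by_chrom <- function(intervals) {
  if (any(intervals$start < 0)) stop("negative coordinates")
  if (any(intervals$end < intervals$start)) stop("end < start")
  split(intervals, intervals$chrom)
}

#' Index a bedGraph-style signal into fixed-size genomic bins
#'
#' The value of a bin is the coverage-weighted mean of all interval values
#' overlapping it (`sum(overlap_len * value) / sum(overlap_len)`); bins
#' with no covered base are missing and are simply absent from the result.
#' Intervals are 0-based half-open.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `value`.
#' @param resolution Bin size in bp.
#' @return data.frame with `chrom`, `bin` (0-based index), `value`.
#' @export
index_signal <- function(intervals, resolution) {
  out <- lapply(intervals_by_chrom(intervals), function(iv) {
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    if (!nrow(iv)) return(NULL)
    ir <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
    nb <- max(iv$end - 1) %/% resolution + 1
    bins <- IRanges::IRanges(start = (seq_len(nb) - 1) * resolution + 1,
                             width = resolution)
    hits <- IRanges::findOverlaps(bins, ir)
    ov <- IRanges::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
    b <- S4Vectors::queryHits(hits)
    wsum <- tapply(ov * iv$value[S4Vectors::subjectHits(hits)], b, sum)
    lsum <- tapply(ov, b, sum)
    data.frame(chrom = iv$chrom[1],
               bin = as.integer(names(lsum)) - 1L,
               value = as.numeric(wsum / lsum), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (is.null(out)) out <- data.frame(chrom = character(), bin = integer(),
                                      value = numeric())
  out
}

#' Index an interval set as per-bin coverage fractions
#'
#' The value of a bin is the union length of intervals within it divided
#' by the bin size (no double counting of overlaps). Bins from 0 to the
#' last covered bin of each chromosome are reported, including zeros.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param resolution Bin size in bp.
#' @return data.frame with `chrom`, `bin`, `value` in `[0, 1]`.
#' @export
index_coverage <- function(intervals, resolution) {
  out <- lapply(intervals_by_chrom(intervals), function(iv) {
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    if (!nrow(iv)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1, end = iv$end))
    nb <- (max(IRanges::end(ir)) - 1) %/% resolution + 1
    bins <- IRanges::IRanges(start = (seq_len(nb) - 1) * resolution + 1,
                             width = resolution)
    hits <- IRanges::findOverlaps(bins, ir)
    ov <- IRanges::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
    cov <- rep(0, nb)
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- agg
    data.frame(chrom = iv$chrom[1], bin = seq_len(nb) - 1L,
               value = cov / resolution, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (is.null(out)) out <- data.frame(chrom = character(), bin = integer(),
                                      value = numeric())
  out
}

#' Keep only repeat families broad enough for bin-level statistics
#'
#' At 20 kb resolution only broadly distributed repeat families carry
#' signal; families with 20,000 genomic occurrences or fewer are dropped
#' (strictly more than `min_occurrences` are kept).
#'
#' @param catalog data.frame of repeat instances with a `family` column.
#' @param min_occurrences Occurrence threshold (default 20000).
#' @return The catalog restricted to retained families.
#' @export
filter_repeats <- function(catalog, min_occurrences = 20000) {
  if (!nrow(catalog)) return(catalog)
  n <- table(catalog$family)
  keep <- names(n)[n > min_occurrences]
  catalog[catalog$family %in% keep, , drop = FALSE]
}

#' Index per-site percentages (e.g. CpG methylation) as per-bin medians
#'
#' Sites without reads are discarded; the bin value is the median
#' percentage of the remaining sites. Bins without sites are missing.
#'
#' @param sites data.frame with `chrom`, `pos`, `reads`, `percent`.
#' @param resolution Bin size in bp.
#' @return data.frame with `chrom`, `bin`, `value`.
#' @export
index_point_median <- function(sites, resolution) {
  sites <- sites[sites$reads > 0, , drop = FALSE]
  if (!nrow(sites)) {
    return(data.frame(chrom = character(), bin = integer(), value = numeric()))
  }
  key <- interaction(sites$chrom, sites$pos %/% resolution, drop = TRUE)
  med <- tapply(sites$percent, key, median)
  ks <- strsplit(names(med), ".", fixed = TRUE)
  out <- data.frame(chrom = vapply(ks, `[`, "", 1),
                    bin = as.integer(vapply(ks, `[`, "", 2)),
                    value = as.numeric(med), stringsAsFactors = FALSE)
  out[order(out$chrom, out$bin), ]
}

# align a track's NV to the occupancy's segment order
aligned_nv <- function(track, occ) {
  track$nv[match(occ$segments$segment, track$segment)]
}

#' Marker enrichment score per physical state
#'
#' The raw enrichment of state a is the occupancy-weighted mean of the
#' marker's z-scored values:
#' `E_a = sum_g P_ga * NV_g / sum_g P_ga`,
#' computed over non-empty states with missing-NV segments excluded from
#' both sums. Raw scores are then z-scored (population SD) across
#' non-empty states.
#'
#' @param track A `marker_track`.
#' @param occ An `occupancy_matrix`.
#' @param plot The matching `d2_plot`.
#' @return An `enrichment_map` data.frame: `state`, `density_bin`,
#'   `distp_bin`, `empty`, `e_raw`, `e_z` (both `NA` at empty states).
#' @export
enrichment <- function(track, occ, plot) {
  nv <- aligned_nv(track, occ)
  ok <- !is.na(nv)
  P <- effective_P(occ, plot)[ok, , drop = FALSE]
  denom <- colSums(P)
  live <- !plot$empty
  if (any(denom[live] == 0)) {
    stop("non-empty state with zero occupancy mass; ",
         "was the empty-state filter applied?")
  }
  e_raw <- rep(NA_real_, plot$nbins^2)
  e_raw[live] <- as.numeric(crossprod(P[, live, drop = FALSE],
                                      nv[ok])) / denom[live]
  finish_enrichment_map(e_raw, plot, attr(track, "name"))
}

finish_enrichment_map <- function(e_raw, plot, name) {
  live <- !plot$empty
  s <- sd_pop(e_raw[live])
  e_z <- rep(NA_real_, length(e_raw))
  if (is.na(s) || s == 0) {
    warning("enrichment scores constant across states; z-scores set to 0")
    e_z[live] <- 0
  } else {
    e_z[live] <- (e_raw[live] - mean(e_raw[live])) / s
  }
  sc <- state_centers(plot)
  structure(data.frame(state = sc$state, density_bin = sc$density_bin,
                       distp_bin = sc$distp_bin, empty = plot$empty,
                       e_raw = e_raw, e_z = e_z),
            class = c("enrichment_map", "data.frame"), name = name)
}

#' Mean-based alternative enrichment score
#'
#' Instead of weighting by single-cell occupancy, every segment is placed
#' at the state of its cross-cell mean density and mean DisTP, and the
#' state score is the plain mean of NV over the segments landing there:
#' `E'_a = sum_{g in G_a} NV_g / N(G_a)`, z-scored across non-empty
#' states. Agrees with [enrichment()] in rank when per-segment
#' distributions are unimodal.
#'
#' @param track A `marker_track`.
#' @param cell_tables List of `cell_d2` tables (to compute per-segment
#'   means).
#' @param plot The `d2_plot` defining bounds, bins and the empty mask.
#' @return An `enrichment_map` (same shape as [enrichment()]).
#' @export
enrichment_mean_based <- function(track, cell_tables, plot) {
  sm <- segment_means(cell_tables)
  nv <- track$nv[match(sm$segment, track$segment)]
  st <- assign_state(sm$density_mean, sm$distp_mean, plot$bounds, plot$nbins)
  ok <- !is.na(nv) & !is.na(st) & !plot$empty[st]
  e_raw <- rep(NA_real_, plot$nbins^2)
  agg <- tapply(nv[ok], st[ok], mean)
  e_raw[as.integer(names(agg))] <- as.numeric(agg)
  live <- !plot$empty
  if (any(is.na(e_raw[live]))) {
    # non-empty states where no segment mean lands stay NA and are
    # excluded from the z-score
    live <- live & !is.na(e_raw)
  }
  plot2 <- plot
  plot2$empty <- !live
  finish_enrichment_map(e_raw, plot2, attr(track, "name"))
}

#' Stochasticity of a marker's enrichment score per state
#'
#' The occupancy-weighted SD of the marker around its state mean:
#' `SD_a = sqrt( sum_g P_ga * (NV_g - E_a)^2 / sum_g P_ga )`.
#'
#' @inheritParams enrichment
#' @return data.frame with `state`, `empty`, `e_raw`, `sd` (`NA` at empty
#'   states).
#' @export
enrichment_sd <- function(track, occ, plot) {
  nv <- aligned_nv(track, occ)
  ok <- !is.na(nv)
  P <- effective_P(occ, plot)[ok, , drop = FALSE]
  nv <- nv[ok]
  denom <- colSums(P)
  live <- !plot$empty
  if (any(denom[live] == 0)) stop("non-empty state with zero occupancy mass")
  e_raw <- rep(NA_real_, plot$nbins^2)
  sd_a <- rep(NA_real_, plot$nbins^2)
  e_raw[live] <- as.numeric(crossprod(P[, live, drop = FALSE], nv)) /
    denom[live]
  dev2 <- outer(nv, e_raw[live], function(a, b) (a - b)^2)
  sd_a[live] <- sqrt(colSums(P[, live, drop = FALSE] * dev2) / denom[live])
  data.frame(state = seq_len(plot$nbins^2), empty = plot$empty,
             e_raw = e_raw, sd = sd_a)
}

#' Gene-set (bin-set) enrichment over the genomic background
#'
#' The occupancy distribution of the set across states is divided by the
#' distribution of all segments; both are normalized to sum to 1 over
#' non-empty states. A ratio above 1 marks states where the set is
#' over-represented.
#'
#' @param set Character vector of segment ids (or data.frame with a
#'   `segment` column).
#' @param occ An `occupancy_matrix`.
#' @param plot The matching `d2_plot`.
#' @return data.frame with `state`, `empty`, `ratio` (`NA` where the
#'   background is zero or the state is empty).
#' @export
gene_set_enrichment <- function(set, occ, plot) {
  if (is.data.frame(set)) set <- set$segment
  if (!length(set)) stop("empty bin set")
  rows <- match(set, occ$segments$segment)
  rows <- rows[!is.na(rows)]
  if (!length(rows)) stop("no set segments found in the occupancy matrix")
  live <- !plot$empty
  fg <- colSums(occ$counts[rows, , drop = FALSE])
  bg <- colSums(occ$counts)
  fg[!live] <- 0; bg[!live] <- 0
  fg <- fg / sum(fg); bg <- bg / sum(bg)
  ratio <- rep(NA_real_, length(fg))
  ratio[live & bg > 0] <- fg[live & bg > 0] / bg[live & bg > 0]
  data.frame(state = seq_along(ratio), empty = plot$empty, ratio = ratio)
}
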