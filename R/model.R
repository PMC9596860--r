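#' Default transcription-related marker panel
#'
#' The panel used for the four-area clustering: strong/weak transcription
#' and promoter/enhancer chromatin states, active and repressive histone
#' modifications, and the two major repeat classes. User-configurable;
#' this default lists the 15 enumerated names.
#' @return Character vector of marker names.
#' @export
default_marker_panel <- function() {
  c("Txn-St", "Txn-W", "Pr-Ac", "Pr-W", "En-St", "En-W", "H3K27ac",
    "H3K36me3", "H3K4me3", "H3K4me2", "Alu", "H3K9me3", "H3K27me3", "L1",
    "Ht-L")
}

#' Default active-marker subset used for ranking clusters
#' @return Character vector of marker names.
#' @export
default_active_markers <- function() {
  c("Txn-St", "Pr-Ac", "En-St", "H3K27ac", "H3K4me3")
}

#' Assemble a states-by-markers enrichment matrix
#'
#' @param emaps Named list of `enrichment_map`s (one per marker).
#' @return Matrix of z-scored enrichments, rows = non-empty states
#'   (rownames = state ids), columns = markers.
#' @export
enrichment_matrix <- function(emaps) {
  live <- !emaps[[1]]$empty
  E <- vapply(emaps, function(m) m$e_z[live], numeric(sum(live)))
  if (is.null(colnames(E))) {
    colnames(E) <- vapply(emaps, attr, "", "name")
  }
  rownames(E) <- which(live)
  E
}

#' Cluster physical states into the four-area activation model
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on the
#' states-by-markers enrichment matrix, cut at `k` clusters. For `k = 4`,
#' clusters are ranked by their mean enrichment over the active-marker
#' subset: the top cluster is `active`, the second `intermediate`, and the
#' two repressed clusters are told apart by whether repressive histone
#' marks or repeat markers dominate (`repress_histone` vs
#' `repress_repeat`).
#'
#' @param E States-by-markers matrix from [enrichment_matrix()].
#' @param k Number of clusters (default 4; labels only for 4).
#' @param active_markers,repressive_markers,repeat_markers Marker-name
#'   subsets used for ranking and labeling.
#' @return An `area_model`: data.frame `states` (`state`, `cluster`,
#'   `label`), plus the `hclust` object and greedy-optimal `leaf_order`.
#' @export
cluster_states <- function(E, k = 4,
                           active_markers = default_active_markers(),
                           repressive_markers = c("H3K9me3", "H3K27me3"),
                           repeat_markers = c("L1", "Ht-L")) {
  if (k > nrow(E)) stop("k exceeds the number of states")
  d <- dist(E)
  hc <- hclust(d, method = "ward.D2")
  ord <- greedy_leaf_order(hc, as.matrix(d))
  cl <- cutree(hc, k = k)
  states <- as.integer(rownames(E))
  df <- data.frame(state = states, cluster = as.integer(cl),
                   label = NA_character_, stringsAsFactors = FALSE)
  if (k == 4) {
    marker_mean <- function(rows, set) {
      cols <- intersect(set, colnames(E))
      if (!length(cols)) return(NA_real_)
      mean(E[rows, cols, drop = FALSE])
    }
    act <- vapply(1:4, function(g) marker_mean(cl == g, active_markers),
                  numeric(1))
    rk <- order(act, decreasing = TRUE)
    labels <- character(4)
    labels[rk[1]] <- "active"
    labels[rk[2]] <- "intermediate"
    rep2 <- rk[3:4]
    hist_m <- vapply(rep2, function(g) marker_mean(cl == g, repressive_markers),
                     numeric(1))
    reps_m <- vapply(rep2, function(g) marker_mean(cl == g, repeat_markers),
                     numeric(1))
    # each repressed cluster takes the label of its dominant marker group;
    # on a clash, the one with the higher repeat mean is repress_repeat.
    # With neither marker set present, fall back to activation rank.
    if (all(is.na(hist_m)) && all(is.na(reps_m))) {
      hist_m <- c(1, 0); reps_m <- c(0, 1)
    }
    hist_m[is.na(hist_m)] <- -Inf
    reps_m[is.na(reps_m)] <- -Inf
    pref <- ifelse(hist_m - reps_m >= 0, "repress_histone", "repress_repeat")
    if (pref[1] == pref[2]) {
      # both clusters prefer the same group: the one with the larger
      # repeat-over-histone margin takes repress_repeat
      i_rep <- which.max(reps_m - hist_m)
      pref[i_rep] <- "repress_repeat"
      pref[-i_rep] <- "repress_histone"
    }
    labels[rep2] <- pref
    df$label <- labels[cl]
  }
  structure(list(states = df, hclust = hc, leaf_order = states[ord]),
            class = "area_model")
}

#' @export
print.area_model <- function(x, ...) {
  cat("area_model:", nrow(x$states), "states in",
      length(unique(x$states$cluster)), "clusters\n")
  if (!all(is.na(x$states$label))) print(table(x$states$label))
  invisible(x)
}

# greedy subtree-flip leaf ordering: at each merge choose the orientation
# minimizing the distance between the adjacent boundary leaves
greedy_leaf_order <- function(hc, dmat) {
  orders <- vector("list", nrow(hc$merge))
  get_leaves <- function(i) if (i < 0) -i else orders[[i]]
  for (m in seq_len(nrow(hc$merge))) {
    L <- get_leaves(hc$merge[m, 1])
    R <- get_leaves(hc$merge[m, 2])
    best <- NULL; best_d <- Inf
    for (fl in list(L, rev(L))) {
      for (fr in list(R, rev(R))) {
        dd <- dmat[fl[length(fl)], fr[1]]
        if (dd < best_d) { best_d <- dd; best <- c(fl, fr) }
      }
    }
    orders[[m]] <- best
  }
  orders[[nrow(hc$merge)]]
}

ols_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Property strength: the local slope of activation along each axis
#'
#' For every DisTP row d the strength of a property p is the OLS slope of
#' the active-marker mean enrichment (y) against the property value (x):
#' for density, x runs over the density-bin centers of the non-empty
#' states in row d; for DisTP, x runs over the DisTP-bin centers of rows
#' d-1, d, d+1 (clipped at the grid edge).
#'
#' @param E States-by-markers matrix from [enrichment_matrix()].
#' @param plot The `d2_plot`.
#' @param active_markers Marker subset averaged into y.
#' @return data.frame with `distp_bin` (0-based), `s_density`, `s_distp`
#'   (`NA` where fewer than 2 distinct x values exist).
#' @export
property_strength <- function(E, plot,
                              active_markers = default_active_markers()) {
  sc <- state_centers(plot)
  states <- as.integer(rownames(E))
  cols <- intersect(active_markers, colnames(E))
  if (!length(cols)) stop("no active markers present in E")
  y <- rowMeans(E[, cols, drop = FALSE])
  db <- sc$distp_bin[states]
  xd <- sc$density_center[states]
  xt <- sc$distp_center[states]
  nb <- plot$nbins
  out <- data.frame(distp_bin = 0:(nb - 1), s_density = NA_real_,
                    s_distp = NA_real_)
  for (d in 0:(nb - 1)) {
    in_row <- db == d
    out$s_density[d + 1] <- ols_slope(xd[in_row], y[in_row])
    near <- db >= d - 1 & db <= d + 1
    out$s_distp[d + 1] <- ols_slope(xt[near], y[near])
  }
  out
}

#' Per-segment activation index
#'
#' The probability mass of a segment's physical-state occupancy falling in
#' the active or intermediate areas: `AI_g = sum_{a in A} P_ga`, bounded
#' in \[0, 1\]. Area labels fitted on a reference cell type transfer to any
#' occupancy matrix built on the same bounds and bin grid.
#'
#' @param occ An `occupancy_matrix`.
#' @param areas An `area_model` with four labeled areas.
#' @param plot The `d2_plot` matching `occ`.
#' @return Named numeric vector of AI per segment.
#' @export
activation_index <- function(occ, areas, plot) {
  if (max(areas$states$state) > plot$nbins^2) {
    stop("area model and occupancy use different state grids")
  }
  sel <- areas$states$state[areas$states$label %in%
                              c("active", "intermediate")]
  P <- effective_P(occ, plot)
  ai <- rowSums(P[, sel, drop = FALSE])
  names(ai) <- occ$segments$segment
  ai
}

#' Classify per-segment trajectories across ordered stages
#'
#' Per stage, segments at or above the (1-q) quantile of AI are `active`,
#' at or below the q quantile `repressed`, otherwise `medium`. Modes:
#' `CA` = active at every stage; `CR` = repressed at every stage;
#' `RA` = not active at the first stage but active at the last;
#' everything else `unclassified`.
#'
#' @param ai Matrix of activation indices, rows = segments, columns =
#'   ordered stages.
#' @param q Quantile cut (default 0.10).
#' @return List with `classes` (character matrix like `ai`) and `mode`
#'   (character vector per segment).
#' @export
classify_modes <- function(ai, q = 0.10) {
  if (ncol(ai) < 2) stop("need at least 2 stages")
  classes <- matrix("medium", nrow(ai), ncol(ai),
                    dimnames = dimnames(ai))
  for (s in seq_len(ncol(ai))) {
    hi <- quantile(ai[, s], 1 - q, names = FALSE)
    lo <- quantile(ai[, s], q, names = FALSE)
    classes[ai[, s] >= hi, s] <- "active"
    classes[ai[, s] <= lo & ai[, s] < hi, s] <- "repressed"
  }
  all_active <- rowSums(classes == "active") == ncol(ai)
  all_rep <- rowSums(classes == "repressed") == ncol(ai)
  ra <- classes[, 1] != "active" & classes[, ncol(ai)] == "active"
  mode <- rep("unclassified", nrow(ai))
  mode[ra] <- "RA"
  mode[all_active] <- "CA"
  mode[all_rep] <- "CR"
  names(mode) <- rownames(ai)
  list(classes = classes, mode = mode)
}

#' Correlate DisTP-derived periphery probability with a LAD track
#'
#' Per segment, the periphery probability is the fraction of cells with
#' DisTP below `distp_cut`. Probabilities and LAD coverage are averaged
#' within consecutive `agg_bp` windows, bins outside mean +/- 3 SD on
#' either variable are trimmed, and a two-sided Pearson correlation is
#' computed.
#'
#' @param cell_tables List of `cell_d2` tables.
#' @param lad_track A `marker_track` of LAD coverage (or data.frame with
#'   `segment`, `value`).
#' @param distp_cut DisTP threshold defining "at the periphery"
#'   (default 2).
#' @param agg_bp Aggregation window in bp (default 2e6).
#' @return List with `r`, `p`, `n` (windows used).
#' @export
periphery_lad_correlation <- function(cell_tables, lad_track, distp_cut = 2,
                                      agg_bp = 2e6) {
  res <- attr(cell_tables[[1]], "resolution")
  n_cells <- length(cell_tables)
  all <- do.call(rbind, lapply(cell_tables, function(tb) {
    data.frame(segment = segment_ids(tb, res), chrom = tb$chrom,
               hap = tb$hap, start = tb$start, low = tb$distp < distp_cut,
               stringsAsFactors = FALSE)
  }))
  f <- factor(all$segment)
  i <- match(levels(f), all$segment)
  seg <- data.frame(segment = levels(f), chrom = all$chrom[i],
                    hap = all$hap[i], start = all$start[i],
                    prob = as.numeric(tapply(all$low, f, sum)) / n_cells,
                    stringsAsFactors = FALSE)
  seg$lad <- lad_track$value[match(seg$segment, lad_track$segment)]
  seg <- seg[!is.na(seg$lad), , drop = FALSE]
  win <- interaction(seg$chrom, seg$hap, seg$start %/% agg_bp, drop = TRUE)
  prob_w <- as.numeric(tapply(seg$prob, win, mean))
  lad_w <- as.numeric(tapply(seg$lad, win, mean))
  keep <- abs(prob_w - mean(prob_w)) <= 3 * sd(prob_w) &
    abs(lad_w - mean(lad_w)) <= 3 * sd(lad_w)
  prob_w <- prob_w[keep]; lad_w <- lad_w[keep]
  if (length(prob_w) < 3) stop("fewer than 3 windows after trimming")
  ct <- cor.test(prob_w, lad_w, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(prob_w))
}

#' Fraction of high-density observations along the DisTP axis
#'
#' The top `top_frac` of pooled densities define the high-density regions;
#' per integer DisTP bin, the fraction of observations above that
#' threshold is reported. An interior-rising profile is the chromocenter
#' signature; a flat profile at about `top_frac` means density and radial
#' position are decoupled.
#'
#' @param cell_tables List of `cell_d2` tables.
#' @param top_frac Upper density fraction (default 0.05).
#' @return data.frame with `distp_bin` (integer, floor of DisTP),
#'   `frac_high`, `n`.
#' @export
high_density_profile <- function(cell_tables, top_frac = 0.05) {
  dens <- unlist(lapply(cell_tables, `[[`, "density"), use.names = FALSE)
  dtp <- unlist(lapply(cell_tables, `[[`, "distp"), use.names = FALSE)
  thr <- quantile(dens, 1 - top_frac, names = FALSE)
  b <- floor(dtp)
  high <- tapply(dens > thr, b, mean)
  n <- tapply(dens, b, length)
  data.frame(distp_bin = as.integer(names(high)),
             frac_high = as.numeric(high), n = as.integer(n),
             row.names = NULL)
}

#' Cross-cell stochasticity of density and DisTP per segment
#'
#' Per segment, the mean and population SD of density and DisTP across the
#' cells in which it was scored, plus the Pearson correlation between
#' density mean and density SD (the cell-type-specific anchoring
#' statistic). SD is missing for segments seen in fewer than 2 cells.
#'
#' @param cell_tables List of at least 2 `cell_d2` tables.
#' @return List with `table` (per-segment data.frame) and
#'   `density_mean_sd_cor`.
#' @export
per_bin_stochasticity <- function(cell_tables) {
  if (length(cell_tables) < 2) stop("need at least 2 cells")
  res <- attr(cell_tables[[1]], "resolution")
  all <- do.call(rbind, lapply(cell_tables, function(tb) {
    data.frame(segment = segment_ids(tb, res), density = tb$density,
               distp = tb$distp, stringsAsFactors = FALSE)
  }))
  f <- factor(all$segment)
  n <- as.integer(table(f))
  sd_or_na <- function(v) {
    s <- as.numeric(tapply(v, f, sd_pop))
    s[n < 2] <- NA_real_
    s
  }
  tab <- data.frame(
    segment = levels(f), n_cells = n,
    density_mean = as.numeric(tapply(all$density, f, mean)),
    density_sd = sd_or_na(all$density),
    distp_mean = as.numeric(tapply(all$distp, f, mean)),
    distp_sd = sd_or_na(all$distp),
    stringsAsFactors = FALSE, row.names = NULL)
  ok <- complete.cases(tab[, c("density_mean", "density_sd")])
  list(table = tab,
       density_mean_sd_cor = if (sum(ok) >= 3)
         cor(tab$density_mean[ok], tab$density_sd[ok]) else NA_real_)
}
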