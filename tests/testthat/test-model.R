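test_that("Ward clustering recovers separated blobs and matches the
           brute-force merge sequence", {
  # 4 tight blobs in marker space are recovered exactly
  set.seed(41)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
  X <- centers[rep(1:4, each = 6), ] + matrix(rnorm(48, sd = 0.05), ncol = 2)
  rownames(X) <- seq_len(24)
  colnames(X) <- c("m1", "m2")
  am <- cluster_states(X, k = 4)
  truth <- rep(1:4, each = 6)
  expect_equal(length(unique(paste(am$states$cluster, truth))), 4)

  # k = 1: everything in one cluster
  am1 <- cluster_states(X, k = 1)
  expect_equal(unique(am1$states$cluster), 1L)
  expect_error(cluster_states(X, k = 30), "exceeds")

  # merge sequence on 6 hand-placed 1-D points equals the exhaustive
  # Ward-objective oracle
  pts <- matrix(c(0, 0.9, 2.5, 6, 6.4, 10), ncol = 1)
  rownames(pts) <- 1:6
  colnames(pts) <- "m"
  hc <- hclust(dist(pts), method = "ward.D2")
  expect_equal(hclust_merge_pairs(hc), oracle_ward_merges(pts))
})

test_that("four-area labeling uses active, histone and repeat marker means", {
  # 4 blobs with a designed marker signature
  nm <- c("act1", "act2", "H3K9me3", "H3K27me3", "L1")
  E <- rbind(
    matrix(rep(c(2, 2, -1, -1, -1), each = 5), nrow = 5),    # active
    matrix(rep(c(0.5, 0.5, 0, 0, 0), each = 5), nrow = 5),   # intermediate
    matrix(rep(c(-1, -1, 2, 2, -0.5), each = 5), nrow = 5),  # rep histone
    matrix(rep(c(-1, -1, -0.5, -0.5, 2), each = 5), nrow = 5))# rep repeat
  E <- E + matrix(rnorm(100, sd = 0.05), nrow = 20)
  colnames(E) <- nm
  rownames(E) <- 1:20
  am <- cluster_states(E, k = 4, active_markers = c("act1", "act2"),
                       repressive_markers = c("H3K9me3", "H3K27me3"),
                       repeat_markers = "L1")
  lab <- am$states$label
  expect_equal(lab[1:5], rep("active", 5))
  expect_equal(lab[6:10], rep("intermediate", 5))
  expect_equal(lab[11:15], rep("repress_histone", 5))
  expect_equal(lab[16:20], rep("repress_repeat", 5))
})

test_that("property strength is the closed-form OLS slope", {
  ens <- small_ensemble()
  trk <- generate_marker_track(ens$tables, alpha = -1, beta = 0,
                               noise_sd = 0, seed = 2)
  em <- enrichment(trk, ens$occ, ens$plot)
  E <- enrichment_matrix(list(act = em))
  ps <- property_strength(E, ens$plot, active_markers = "act")
  expect_equal(nrow(ps), 15)

  # oracle check on one populated row
  sc <- state_centers(ens$plot)
  states <- as.integer(rownames(E))
  rows_with_fit <- ps$distp_bin[!is.na(ps$s_density)]
  d <- rows_with_fit[ceiling(length(rows_with_fit) / 2)]
  in_row <- sc$distp_bin[states] == d
  x <- sc$density_center[states][in_row]
  y <- E[in_row, "act"]
  expect_equal(ps$s_density[ps$distp_bin == d],
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
               tolerance = 1e-12)

  # exact linear input: y = -0.5 * density center across one DisTP row
  pl2 <- structure(list(bounds = standard_bounds(), nbins = 15,
                        state_counts = rep(1, 225),
                        empty = rep(FALSE, 225), min_segments = 1,
                        n_cells = 1),
                   class = "d2_plot")
  sc2 <- state_centers(pl2)
  row0 <- which(sc2$distp_bin == 0)          # the 15 states of row d = 0
  X2 <- cbind(act = -0.5 * sc2$density_center[row0])
  rownames(X2) <- row0
  ps2 <- property_strength(X2, pl2, active_markers = "act")
  expect_equal(ps2$s_density[1], -0.5, tolerance = 1e-12)

  # constant y: slope exactly 0
  X3 <- cbind(act = rep(0.7, 15))
  rownames(X3) <- row0
  ps3 <- property_strength(X3, pl2, active_markers = "act")
  expect_equal(ps3$s_density[1], 0)
  expect_true(is.na(ps3$s_density[5]))       # rows without states
})

test_that("activation index sums occupancy over active areas", {
  P <- matrix(0, nrow = 3, ncol = 225)
  P[1, 1] <- 0.3; P[1, 2] <- 0.2; P[1, 3] <- 0.5
  P[2, 1] <- 1
  P[3, 3] <- 0.6
  toy <- toy_occ(P)
  areas <- structure(list(states = data.frame(
    state = 1:3, cluster = 1:3,
    label = c("active", "intermediate", "repress_repeat"))),
    class = "area_model")
  ai <- activation_index(toy$occ, areas, toy$plot)
  expect_equal(unname(ai), c(0.5, 1, 0))

  # enlarging the active set never decreases AI
  areas2 <- areas
  areas2$states$label[3] <- "intermediate"
  ai2 <- activation_index(toy$occ, areas2, toy$plot)
  expect_true(all(ai2 >= ai))
})

test_that("trajectory modes follow the stage-wise decile rules", {
  set.seed(10)
  n <- 200
  ai <- matrix(runif(3 * n), ncol = 3,
               dimnames = list(paste0("s", 1:n), paste0("stage", 1:3)))
  # plant known patterns well inside the deciles
  ai[1, ] <- c(0.999, 0.999, 0.999)   # CA
  ai[2, ] <- c(0.001, 0.001, 0.001)   # CR
  ai[3, ] <- c(0.5, 0.5, 0.9999)      # RA
  md <- classify_modes(ai, q = 0.10)
  expect_equal(unname(md$mode[1:3]), c("CA", "CR", "RA"))

  # quantile-based: invariant to strictly monotone transforms
  md2 <- classify_modes(exp(3 * ai), q = 0.10)
  expect_equal(md$mode, md2$mode)
  expect_equal(md$classes, md2$classes)
  expect_error(classify_modes(ai[, 1, drop = FALSE]), "2 stages")
})

test_that("periphery probability correlates with LAD coverage", {
  ens <- small_ensemble()
  tables <- ens$tables
  res <- attr(tables[[1]], "resolution")
  # identity track: LAD value defined as the periphery probability itself
  all <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(segment = segment_ids(tb, res), low = tb$distp < 2)
  }))
  prob <- tapply(all$low, all$segment, sum) / length(tables)
  lad <- data.frame(segment = names(prob), value = as.numeric(prob))
  out <- periphery_lad_correlation(tables, lad, distp_cut = 2,
                                   agg_bp = 2e6)
  expect_equal(out$r, 1, tolerance = 1e-9)
  expect_true(out$n >= 3)

  # a contrived 10-SD outlier window is trimmed before correlating
  lad_out <- lad
  lad_out$value <- lad_out$value + rnorm(nrow(lad), sd = 0.01)
  first_win <- (as.integer(sub(".*:", "", lad_out$segment)) * res) %/% 2e6 == 0 &
    startsWith(lad_out$segment, "1:pat")
  lad_out$value[first_win] <- 1e3
  out2 <- periphery_lad_correlation(tables, lad_out, distp_cut = 2,
                                    agg_bp = 2e6)
  # oracle: aggregate + trim by hand
  seg_tab <- data.frame(segment = names(prob), prob = as.numeric(prob))
  seg_tab$lad <- lad_out$value[match(seg_tab$segment, lad_out$segment)]
  parts <- strsplit(seg_tab$segment, ":")
  win <- paste(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
               (as.integer(vapply(parts, `[`, "", 3)) * res) %/% 2e6)
  pw <- tapply(seg_tab$prob, win, mean)
  lw <- tapply(seg_tab$lad, win, mean)
  keep <- abs(pw - mean(pw)) <= 3 * sd(pw) & abs(lw - mean(lw)) <= 3 * sd(lw)
  expect_equal(out2$r, cor(pw[keep], lw[keep]), tolerance = 1e-9)
  expect_equal(out2$n, sum(keep))
})

test_that("high-density profile is flat for exchangeable densities and the
           threshold is the 95th percentile", {
  set.seed(33)
  dens <- runif(20000)
  dtp <- runif(20000, 1, 9)
  tb <- toy_cell(dens, dtp)
  prof <- high_density_profile(list(tb), top_frac = 0.05)
  expect_true(all(abs(prof$frac_high - 0.05) < 0.02))
  thr <- oracle_quantile(dens, 0.95)
  expect_equal(mean(dens > thr), 0.05, tolerance = 0.001)
})

test_that("per-bin stochasticity uses population SDs across cells", {
  tb1 <- toy_cell(c(1, 2), c(3, 4))
  tb2 <- toy_cell(c(3, 2), c(5, 4))
  st <- per_bin_stochasticity(list(tb1, tb2))
  row <- st$table[st$table$segment == "1:none:0", ]
  expect_equal(row$density_mean, 2)
  expect_equal(row$density_sd, 1)   # population SD of (1, 3)
  expect_equal(row$distp_mean, 4)

  # identical cells: SD exactly 0
  st0 <- per_bin_stochasticity(list(tb1, tb1))
  expect_true(all(st0$table$density_sd == 0))

  # random ensembles match a direct column-wise oracle
  ens <- small_ensemble()
  st2 <- per_bin_stochasticity(ens$tables)
  res <- attr(ens$tables[[1]], "resolution")
  all <- do.call(rbind, lapply(ens$tables, function(tb) {
    data.frame(segment = segment_ids(tb, res), density = tb$density)
  }))
  seg <- st2$table$segment[100]
  v <- all$density[all$segment == seg]
  expect_equal(st2$table$density_mean[100], mean(v), tolerance = 1e-12)
  expect_equal(st2$table$density_sd[100], sd_pop_oracle(v), tolerance = 1e-12)
  expect_error(per_bin_stochasticity(ens$tables[1]), "2 cells")
})
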