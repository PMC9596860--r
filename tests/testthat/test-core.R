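make_structure <- function(xyz, res = 20000) {
  genome_structure(data.frame(chrom = "1", hap = "none",
                              pos = (seq_len(nrow(xyz)) - 1) * res,
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                   resolution = res, cell_id = "t")
}

test_that("cube length equals the mean k-th nearest-neighbour distance", {
  # 8 unit-cube corners: every corner's 7th nearest is the opposite corner
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(compute_cube_length(make_structure(corners), k = 7), sqrt(3))

  # 9 collinear points, spacing 1: hand-summed k=7 distances total 48
  line <- cbind(0:8, 0, 0)
  expect_equal(compute_cube_length(make_structure(line), k = 7), 48 / 9)

  # random cloud matches the exhaustive O(n^2) oracle exactly
  set.seed(7)
  pts <- matrix(runif(300), ncol = 3)
  expect_equal(compute_cube_length(make_structure(pts), k = 7),
               oracle_knn_mean(pts, 7), tolerance = 1e-12)

  expect_error(compute_cube_length(make_structure(corners), k = 0), "k")
  expect_error(compute_cube_length(make_structure(corners), k = 8),
               "k\\+1 particles")
})

test_that("voxelization follows the floor convention and conserves counts", {
  xyz <- rbind(c(0, 0, 0), c(0.2, 0.3, 0.1), c(1.5, 0.1, 0.4),
               c(2.5, 2.5, 2.5), c(1.1, 0.2, 0.9), c(0.4, 1.7, 0.3),
               c(2.9, 0.1, 1.5), c(1.5, 1.5, 1.5))
  g <- build_mesh(make_structure(xyz), cube_length = 1)
  expect_equal(g$origin, c(0, 0, 0))
  expect_equal(g$counts[1, 1, 1], 2)  # origin particle + 0.4-apart neighbour
  expect_equal(sum(g$counts), 8)
  expect_equal(g$particle_cube[1], 1L)

  set.seed(11)
  st <- random_structure(200, seed = 3)
  g2 <- build_mesh(st, cube_length = 0.7)
  expect_equal(sum(g2$counts), 200)
  expect_error(build_mesh(st, cube_length = 0), "positive")
})

test_that("smoothed density matches the exhaustive neighbourhood oracle", {
  empty <- cube_grid(array(0L, dim = c(4, 4, 4)))
  expect_true(all(compute_density(empty)$density == 0))

  counts <- array(0L, dim = c(9, 9, 9))
  counts[5, 5, 5] <- 10L
  g <- compute_density(cube_grid(counts), smooth_range = 3)
  oracle <- oracle_density(counts, 3)
  expect_equal(g$density[5, 5, 5], oracle[5, 5, 5], tolerance = 1e-12)
  expect_equal(g$density[6, 5, 5], oracle[6, 5, 5], tolerance = 1e-12)

  # homogeneity: doubling the counts doubles every density
  g2 <- compute_density(cube_grid(counts * 2L), smooth_range = 3)
  expect_equal(g2$density, g$density * 2, tolerance = 1e-12)
  expect_error(compute_density(cube_grid(counts), smooth_range = -1), ">= 0")
})

test_that("membrane detection tolerates outliers and respects cavities", {
  # a single cube with 5 particles in a 7^3 grid: the 5x5x5 window of the
  # filled cube and of each Chebyshev-1 neighbour sees all 5 particles
  counts <- array(0L, dim = c(7, 7, 7))
  counts[4, 4, 4] <- 5L
  g <- detect_membrane(cube_grid(counts), min_particles = 3, window = 5)
  mem <- g$membrane
  expect_equal(mem, oracle_membrane(counts, 3, 5))
  core <- mem[2:8, 2:8, 2:8]
  expect_false(any(core[3:5, 3:5, 3:5]))      # filled cube + 26 neighbours
  expect_true(core[1, 1, 1])                  # far corners are membrane
  expect_true(all(mem[1, , ] & mem[9, , ]))   # pad shell reached

  # hollow shell: interior cavity unreachable, hence not membrane
  shell <- array(0L, dim = c(9, 9, 9))
  shell[3:7, 3:7, 3:7] <- 5L
  shell[4:6, 4:6, 4:6] <- 0L
  gs <- detect_membrane(cube_grid(shell), min_particles = 3, window = 5)
  expect_equal(gs$membrane, oracle_membrane(shell, 3, 5))
  core <- gs$membrane[2:10, 2:10, 2:10]
  expect_false(any(core[4:6, 4:6, 4:6]))

  # dissociated single particle far from a dense cluster becomes membrane
  iso <- array(0L, dim = c(14, 5, 5))
  iso[2, 3, 3] <- 20L
  iso[13, 3, 3] <- 1L
  gi <- detect_membrane(cube_grid(iso), min_particles = 3, window = 5)
  expect_equal(gi$membrane, oracle_membrane(iso, 3, 5))
  expect_true(gi$membrane[14, 4, 4])  # the outlier cube (padded frame)

  expect_error(detect_membrane(cube_grid(iso), window = 4), "odd")
})

test_that("DisTP reproduces worked slab and isolated-cube geometry", {
  # slab: membrane plane one layer below a filled half-space
  counts <- array(0L, dim = c(21, 21, 6))
  counts[, , 2:6] <- 3L
  g <- cube_grid(counts)
  mem <- array(FALSE, dim = dim(counts) + 2L)
  mem[2:22, 2:22, 2] <- TRUE  # core layer z = 1 is the membrane plane
  g$membrane <- mem
  g <- compute_distp(g, top_k = 10)
  center <- g$distp[11, 11, 2]  # one layer above the plane
  expect_equal(center, (1 + 4 * sqrt(2) + 4 * sqrt(3) + sqrt(5)) / 10,
               tolerance = 1e-9)
  # and the enumeration oracle agrees everywhere
  memc <- which(mem, arr.ind = TRUE) - 1L
  fill <- which(counts > 0 & !mem[2:22, 2:22, 2:7], arr.ind = TRUE)
  expect_equal(g$distp[fill], oracle_distp(fill, memc, 10), tolerance = 1e-9)

  # single filled cube fully surrounded by membrane
  c2 <- array(0L, dim = c(3, 3, 3))
  c2[2, 2, 2] <- 1L
  g2 <- cube_grid(c2)
  mem2 <- array(TRUE, dim = c(5, 5, 5))
  mem2[3, 3, 3] <- FALSE
  g2$membrane <- mem2
  g2 <- compute_distp(g2, top_k = 10)
  expect_equal(g2$distp[2, 2, 2], (6 + 4 * sqrt(2)) / 10, tolerance = 1e-9)

  expect_error(compute_distp(cube_grid(c2)), "membrane mask")
})

test_that("DisTP is larger at the center of a solid ball than at its surface", {
  sh <- c(15, 15, 15)
  ctr <- c(8, 8, 8)
  counts <- array(0L, dim = sh)
  ax <- as.matrix(expand.grid(1:15, 1:15, 1:15))
  r <- sqrt(colSums((t(ax) - ctr)^2))
  counts[ax[r <= 6, ]] <- 3L
  g <- detect_membrane(compute_density(cube_grid(counts)), 3, 5)
  g <- compute_distp(g, top_k = 10)
  center_d <- g$distp[8, 8, 8]
  surf <- ax[r > 5 & r <= 6, , drop = FALSE]
  surf_d <- g$distp[surf]
  expect_true(all(center_d > surf_d))
})

test_that("core fields match brute-force oracles on random small grids", {
  set.seed(202)
  for (trial in 1:12) {
    sh <- sample(4:9, 3, replace = TRUE)
    counts <- array(rpois(prod(sh), 0.7), dim = sh)
    g <- cube_grid(counts)
    g <- compute_density(g, smooth_range = 3)
    expect_equal(g$density, oracle_density(counts, 3), tolerance = 1e-10)
    g <- detect_membrane(g, min_particles = 3, window = 5)
    expect_equal(g$membrane, oracle_membrane(counts, 3, 5))
    mem_idx <- which(g$membrane)
    filled <- which(counts > 0 & !g$membrane[2:(sh[1] + 1), 2:(sh[2] + 1),
                                             2:(sh[3] + 1)], arr.ind = TRUE)
    if (length(mem_idx) >= 10 && nrow(filled) > 0) {
      g <- compute_distp(g, top_k = 10)
      expect_equal(g$distp[filled],
                   oracle_distp(filled, arrayInd(mem_idx, sh + 2L) - 1L, 10),
                   tolerance = 1e-10)
    }
  }
})

test_that("score_cell is invariant to input order and rigid motion", {
  st <- small_ensemble()$ens$structures[[1]]
  tb <- score_cell(st)
  # particles sharing a cube share (density, distp)
  grid <- build_mesh(st, compute_cube_length(st))
  dup <- which(duplicated(grid$particle_cube) |
                 duplicated(grid$particle_cube, fromLast = TRUE))
  if (length(dup) >= 2) {
    i <- dup[grid$particle_cube[dup] == grid$particle_cube[dup[1]]]
    expect_equal(tb$density[i[1]], tb$density[i[2]])
    expect_equal(tb$distp[i[1]], tb$distp[i[2]])
  }

  # particle order must not matter
  set.seed(5)
  perm <- sample(nrow(st))
  st_perm <- genome_structure(as.data.frame(st)[perm, ],
                              resolution = attr(st, "resolution"),
                              cell_id = "perm")
  tb_perm <- score_cell(st_perm)
  key <- paste(tb$chrom, tb$hap, tb$start)
  m <- match(key, paste(tb_perm$chrom, tb_perm$hap, tb_perm$start))
  expect_equal(tb$density, tb_perm$density[m], tolerance = 1e-12)
  expect_equal(tb$distp, tb_perm$distp[m], tolerance = 1e-12)

  # translation + 90-degree rotation: same distributions up to
  # cube-boundary reassignment of a few particles
  rot <- as.data.frame(st)
  tmp <- rot$x
  rot$x <- -rot$y + 11.3
  rot$y <- tmp - 4.7
  rot$z <- rot$z + 2.25
  tb_rot <- score_cell(genome_structure(rot,
                                        resolution = attr(st, "resolution"),
                                        cell_id = "rot"))
  expect_equal(mean(tb_rot$density), mean(tb$density), tolerance = 0.05)
  expect_equal(mean(tb_rot$distp), mean(tb$distp), tolerance = 0.05)
  # distributions agree and per-segment ranks are largely preserved;
  # differences reflect cube-boundary reassignment only
  mr <- match(key, paste(tb_rot$chrom, tb_rot$hap, tb_rot$start))
  expect_equal(quantile(tb_rot$density, 1:9 / 10),
               quantile(tb$density, 1:9 / 10), tolerance = 0.05)
  expect_equal(quantile(tb_rot$distp, 1:9 / 10),
               quantile(tb$distp, 1:9 / 10), tolerance = 0.05)
  expect_gt(cor(tb$density, tb_rot$density[mr], method = "spearman",
                use = "complete.obs"), 0.9)
  expect_gt(cor(tb$distp, tb_rot$distp[mr], method = "spearman",
                use = "complete.obs"), 0.9)
})

test_that("cube normalization equalizes particles-per-cube across cell sizes", {
  per_cube <- vapply(c(4, 7, 10, 13), function(R) {
    cfg <- synth_config(n_cells = 1, n_chroms = 2, particles_per_chrom = 150,
                        nucleus_radius = R, seed = 9)
    st <- generate_ensemble(cfg)$structures[[1]]
    g <- build_mesh(st, compute_cube_length(st))
    mean(g$counts[g$counts > 0])
  }, numeric(1))
  expect_lt((max(per_cube) - min(per_cube)) / mean(per_cube), 0.20)

  # and the meshed radius (half max pairwise filled-cube distance, cube
  # units) varies far less than the raw radii do
  radii <- c(4, 7, 10, 13)
  mesh_radius <- vapply(radii, function(R) {
    cfg <- synth_config(n_cells = 1, n_chroms = 2, particles_per_chrom = 150,
                        nucleus_radius = R, seed = 9)
    st <- generate_ensemble(cfg)$structures[[1]]
    g <- build_mesh(st, compute_cube_length(st))
    filled <- which(g$counts > 0, arr.ind = TRUE)
    max(dist(filled)) / 2
  }, numeric(1))
  rel_spread <- function(x) (max(x) - min(x)) / mean(x)
  expect_lt(rel_spread(mesh_radius), rel_spread(radii))
})
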