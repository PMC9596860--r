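#' Cube-length normalization constant for a cell
#'
#' Cells differ in nuclear size, so raw reconstruction coordinates are not
#' comparable across cells. The cube length of the voxel grid is set to the
#' mean, over all particles, of the Euclidean distance to each particle's
#' k-th nearest other particle, which keeps the average number of particles
#' per cube approximately constant across cells.
#'
#' @param structure A `genome_structure`.
#' @param k Neighbour rank (default 7).
#' @return The cube length, in the structure's coordinate unit.
#' @export
compute_cube_length <- function(structure, k = 7) {
  if (k < 1) stop("k must be >= 1")
  coords <- as.matrix(structure[, c("x", "y", "z")])
  if (nrow(coords) < k + 1) stop("need at least k+1 particles")
  .knn_kth_mean(coords, as.integer(k))
}

#' Construct a cube grid (voxelization) directly from per-cube counts
#'
#' Low-level constructor, mainly for testing geometric operations on
#' hand-built grids. [build_mesh()] is the normal entry point.
#'
#' @param counts 3D integer array of per-cube particle counts.
#' @param origin Length-3 numeric, coordinate of the grid corner.
#' @param cube_length Edge length of one cube.
#' @return A `cube_grid` list with fields `origin`, `cube_length`, `shape`,
#'   `counts`, and placeholders `density`, `membrane`, `distp`.
#' @export
cube_grid <- function(counts, origin = c(0, 0, 0), cube_length = 1) {
  if (length(dim(counts)) != 3) stop("counts must be a 3D array")
  if (cube_length <= 0) stop("cube_length must be positive")
  structure(list(origin = as.numeric(origin), cube_length = cube_length,
                 shape = dim(counts), counts = counts,
                 particle_cube = NULL, density = NULL, membrane = NULL,
                 distp = NULL),
            class = "cube_grid")
}

#' @export
print.cube_grid <- function(x, ...) {
  cat("cube_grid ", paste(x$shape, collapse = "x"), ", cube length ",
      format(x$cube_length), ", ", sum(x$counts), " particles\n", sep = "")
  invisible(x)
}

#' Voxelize a genome structure on a cube grid
#'
#' Each particle is assigned to the cube
#' `floor((coord - origin) / cube_length)` per axis; the origin is the
#' per-axis minimum coordinate, so the grid exactly covers the particles.
#'
#' @param structure A `genome_structure`.
#' @param cube_length Cube edge length, typically from
#'   [compute_cube_length()].
#' @return A `cube_grid` with `counts` tallied and a per-particle cube
#'   index stored in `particle_cube`.
#' @export
build_mesh <- function(structure, cube_length) {
  if (cube_length <= 0) stop("cube_length must be positive")
  coords <- as.matrix(structure[, c("x", "y", "z")])
  origin <- unname(apply(coords, 2, min))
  idx <- floor(sweep(sweep(coords, 2, origin), 2, cube_length, "/"))
  storage.mode(idx) <- "integer"
  shape <- apply(idx, 2, max) + 1L
  lin <- unname(idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3]) + 1L)
  counts <- array(tabulate(lin, nbins = prod(shape)), dim = shape)
  g <- cube_grid(counts, origin = origin, cube_length = cube_length)
  g$particle_cube <- lin
  g
}

# integer offsets (dx,dy,dz) with Euclidean norm <= r, with weights
# w = max(norm, 1); the self term (0,0,0) carries weight 1
smoothing_offsets <- function(r) {
  s <- -r:r
  off <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  nrm <- sqrt(rowSums(off^2))
  off <- off[nrm <= r, , drop = FALSE]
  list(off = off, w = pmax(sqrt(rowSums(off^2)), 1))
}

#' Smoothed DNA density per cube
#'
#' The density of cube i is the inverse-distance-weighted average of
#' particle counts over the neighbourhood S of cubes within Euclidean
#' index-distance `smooth_range`:
#' `D_i = sum_{j in S} C_j / max(||i-j||, 1) / num(S)`.
#' `num(S)` counts every in-grid cube of the ball, empty cubes included;
#' out-of-grid cubes are excluded, so boundary cubes average over a smaller
#' S. The self term (j = i) is included with weight 1.
#'
#' @param grid A `cube_grid` with counts tallied.
#' @param smooth_range Neighbourhood radius in cube units (default 3).
#' @return The grid with `density` filled.
#' @export
compute_density <- function(grid, smooth_range = 3) {
  if (smooth_range < 0) stop("smooth_range must be >= 0")
  sh <- grid$shape
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
  acc <- array(0, dim = sh)
  nS <- array(0, dim = sh)
  so <- smoothing_offsets(smooth_range)
  rng <- function(n, d) {
    lo <- max(1, 1 - d); hi <- min(n, n - d)
    if (lo > hi) integer(0) else lo:hi
  }
  for (m in seq_len(nrow(so$off))) {
    dx <- so$off[m, 1]; dy <- so$off[m, 2]; dz <- so$off[m, 3]
    xi <- rng(nx, dx); yi <- rng(ny, dy); zi <- rng(nz, dz)
    if (!length(xi) || !length(yi) || !length(zi)) next
    acc[xi, yi, zi] <- acc[xi, yi, zi, drop = FALSE] +
      grid$counts[xi + dx, yi + dy, zi + dz, drop = FALSE] / so$w[m]
    nS[xi, yi, zi] <- nS[xi, yi, zi, drop = FALSE] + 1
  }
  grid$density <- acc / nS
  grid
}

# box-filter particle totals over a window^3 Chebyshev neighbourhood on the
# padded grid (zeros outside); separable, one axis at a time
window_totals <- function(padded, window) {
  r <- (window - 1L) %/% 2L
  d <- dim(padded)
  out <- padded
  for (axis in 1:3) {
    n <- d[axis]
    acc <- array(0, dim = d)
    for (s in -r:r) {
      lo <- max(1, 1 - s); hi <- min(n, n - s)
      if (lo > hi) next
      ai <- lo:hi
      src <- ai + s
      if (axis == 1) {
        acc[ai, , ] <- acc[ai, , , drop = FALSE] + out[src, , , drop = FALSE]
      } else if (axis == 2) {
        acc[, ai, ] <- acc[, ai, , drop = FALSE] + out[, src, , drop = FALSE]
      } else {
        acc[, , ai] <- acc[, , ai, drop = FALSE] + out[, , src, drop = FALSE]
      }
    }
    out <- acc
  }
  out
}

#' Detect membrane cubes by outlier-tolerant flood fill
#'
#' Membrane cubes stand in for the nuclear envelope. The grid is padded by
#' one cube on every side and flood-filled from the pad inward through
#' face-adjacent cubes. A cube is traversable — and, once reached, labeled
#' membrane — when its local particle total over a
#' `window x window x window` Chebyshev neighbourhood is below
#' `min_particles` ("3 particles in 5 cubes" by default). The tolerance
#' makes dissociated outlier particles part of the membrane territory
#' instead of stopping the fill; enclosed interior cavities are never
#' reached and are never membrane.
#'
#' @param grid A `cube_grid` with counts tallied.
#' @param min_particles Minimum local particle total for a cube to stop the
#'   fill (default 3).
#' @param window Odd window width in cubes (default 5, i.e. Chebyshev
#'   radius 2).
#' @return The grid with `membrane`: a logical array over the padded grid
#'   (dims `shape + 2`; core cube (i,j,k) sits at padded index (i+1,j+1,k+1)).
#' @export
detect_membrane <- function(grid, min_particles = 3, window = 5) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  pd <- grid$shape + 2L
  padded <- array(0, dim = pd)
  padded[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- grid$counts
  wt <- window_totals(padded, window)
  traversable <- wt < min_particles
  visited <- array(FALSE, dim = pd)
  # seeds: traversable cells of the pad shell
  shell <- array(FALSE, dim = pd)
  shell[c(1, pd[1]), , ] <- TRUE
  shell[, c(1, pd[2]), ] <- TRUE
  shell[, , c(1, pd[3])] <- TRUE
  seeds <- which(shell & traversable)
  visited[seeds] <- TRUE
  frontier <- arrayInd(seeds, pd)
  strides <- c(1L, pd[1], pd[1] * pd[2])
  nbr_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), times = 6), , drop = FALSE] +
      nbr_off[rep(1:6, each = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= pd[1] &
      cand[, 2] >= 1 & cand[, 2] <= pd[2] &
      cand[, 3] >= 1 & cand[, 3] <= pd[3]
    cand <- cand[ok, , drop = FALSE]
    lin <- (cand[, 1] - 1L) * strides[1] + (cand[, 2] - 1L) * strides[2] +
      (cand[, 3] - 1L) * strides[3] + 1L
    new <- traversable[lin] & !visited[lin] & !duplicated(lin)
    lin <- lin[new]
    visited[lin] <- TRUE
    frontier <- cand[new, , drop = FALSE]
  }
  grid$membrane <- visited
  grid
}

# membrane mask restricted to the core (unpadded) grid
membrane_core <- function(grid) {
  pd <- dim(grid$membrane)
  grid$membrane[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)]
}

#' Distance to the nuclear periphery per filled cube
#'
#' DisTP of a filled (non-membrane, non-empty) cube is the mean of the
#' `top_k` smallest Euclidean distances from its center to membrane-cube
#' centers, in cube-length units. Averaging over the 10 nearest membrane
#' cubes (rather than taking the single minimum) damps the discreteness of
#' the grid and the effect of any mislabeled membrane cube.
#'
#' @param grid A `cube_grid` with the membrane mask computed.
#' @param top_k Number of nearest membrane cubes to average (default 10).
#' @return The grid with `distp`: array over the core grid, `NA` except at
#'   filled cubes.
#' @export
compute_distp <- function(grid, top_k = 10) {
  if (is.null(grid$membrane)) stop("membrane mask not computed")
  mem_idx <- which(grid$membrane)
  if (length(mem_idx) < top_k) {
    stop("fewer than top_k (", top_k, ") membrane cubes: ", length(mem_idx))
  }
  # padded coords -> core frame: core cube i is padded i+1
  mem <- arrayInd(mem_idx, dim(grid$membrane)) - 1L
  filled <- grid$counts > 0 & !membrane_core(grid)
  fidx <- which(filled)
  distp <- array(NA_real_, dim = grid$shape)
  if (length(fidx)) {
    q <- arrayInd(fidx, grid$shape)
    distp[fidx] <- .topk_mean_dist(matrix(as.numeric(q), ncol = 3),
                                   matrix(as.numeric(mem), ncol = 3),
                                   as.integer(top_k))
  }
  grid$distp <- distp
  grid
}

#' Score one cell: per-particle density and DisTP
#'
#' Runs the full geometric pipeline — cube-length normalization,
#' voxelization, density smoothing, membrane detection, DisTP — and maps
#' the per-cube fields back onto particles. Particles falling in membrane
#' cubes (dissociated outliers) are dropped; the count is stored in the
#' `n_dropped` attribute.
#'
#' @param structure A `genome_structure`.
#' @param knn Neighbour rank for the cube length (default 7).
#' @param smooth_range Density smoothing radius in cubes (default 3).
#' @param membrane_min_particles,membrane_window Membrane detection
#'   parameters (defaults 3 and 5).
#' @param distp_k Number of nearest membrane cubes averaged for DisTP
#'   (default 10).
#' @return A `cell_d2` table: one row per retained particle with columns
#'   `chrom`, `hap`, `start`, `density`, `distp`.
#' @export
score_cell <- function(structure, knn = 7, smooth_range = 3,
                       membrane_min_particles = 3, membrane_window = 5,
                       distp_k = 10) {
  len <- compute_cube_length(structure, k = knn)
  grid <- build_mesh(structure, len)
  grid <- compute_density(grid, smooth_range = smooth_range)
  grid <- detect_membrane(grid, min_particles = membrane_min_particles,
                          window = membrane_window)
  grid <- compute_distp(grid, top_k = distp_k)
  dens <- grid$density[grid$particle_cube]
  dtp <- grid$distp[grid$particle_cube]
  keep <- !is.na(dtp)
  cell_d2(data.frame(chrom = structure$chrom[keep], hap = structure$hap[keep],
                     start = structure$pos[keep], density = dens[keep],
                     distp = dtp[keep], stringsAsFactors = FALSE),
          resolution = attr(structure, "resolution"),
          cell_id = attr(structure, "cell_id"),
          n_dropped = sum(!keep))
}
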