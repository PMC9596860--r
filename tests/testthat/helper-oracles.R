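# Independent brute-force oracles for the geometric operations. These are
# deliberately naive (O(n^2) scans, scalar BFS) and share no code with the
# package implementation.

oracle_knn_mean <- function(coords, k) {
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  mean(apply(d, 1, function(r) sort(r)[k]))
}

# exhaustive Eq-1 density: for every cube, enumerate all in-grid cubes
# within Euclidean index distance r; weight max(dist, 1); denominator
# counts all enumerated cubes, empty included
oracle_density <- function(counts, r) {
  sh <- dim(counts)
  ax <- expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]), k = seq_len(sh[3]))
  coords <- as.matrix(ax)
  cnt <- counts[coords]
  out <- array(NA_real_, dim = sh)
  for (m in seq_len(nrow(coords))) {
    dd <- sqrt(colSums((t(coords) - coords[m, ])^2))
    in_s <- dd <= r
    out[coords[m, , drop = FALSE]] <-
      sum(cnt[in_s] / pmax(dd[in_s], 1)) / sum(in_s)
  }
  out
}

# scalar-queue flood fill over the 1-padded grid; traversable iff the
# window^3 particle total (Chebyshev window) is < min_particles
oracle_membrane <- function(counts, min_particles = 3, window = 5) {
  sh <- dim(counts)
  pd <- sh + 2L
  padded <- array(0, dim = pd)
  padded[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- counts
  r <- (window - 1) %/% 2
  wt <- array(0, dim = pd)
  for (i in 1:pd[1]) for (j in 1:pd[2]) for (k in 1:pd[3]) {
    wt[i, j, k] <- sum(padded[max(1, i - r):min(pd[1], i + r),
                              max(1, j - r):min(pd[2], j + r),
                              max(1, k - r):min(pd[3], k + r)])
  }
  trav <- wt < min_particles
  vis <- array(FALSE, dim = pd)
  queue <- list()
  for (i in 1:pd[1]) for (j in 1:pd[2]) for (k in 1:pd[3]) {
    if ((i == 1 || i == pd[1] || j == 1 || j == pd[2] ||
         k == 1 || k == pd[3]) && trav[i, j, k] && !vis[i, j, k]) {
      vis[i, j, k] <- TRUE
      queue[[length(queue) + 1]] <- c(i, j, k)
    }
  }
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (o in 1:6) {
      nb <- cur + off[o, ]
      if (any(nb < 1) || any(nb > pd)) next
      if (trav[nb[1], nb[2], nb[3]] && !vis[nb[1], nb[2], nb[3]]) {
        vis[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  vis
}

# full distance-matrix DisTP: query/ref are integer coordinate matrices
oracle_distp <- function(query, ref, top_k = 10) {
  apply(query, 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    mean(sort(d)[seq_len(top_k)])
  })
}

# greedy Ward merge sequence by exhaustive evaluation of the ESS increase
# n1*n2/(n1+n2) * ||c1 - c2||^2 for every cluster pair at every step
oracle_ward_merges <- function(X) {
  X <- as.matrix(X)
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      ca <- colMeans(X[clusters[[a]], , drop = FALSE])
      cb <- colMeans(X[clusters[[b]], , drop = FALSE])
      na <- length(clusters[[a]]); nb <- length(clusters[[b]])
      cost <- na * nb / (na + nb) * sum((ca - cb)^2)
      if (cost < best_cost) { best_cost <- cost; best <- c(a, b) }
    }
    merges[[length(merges) + 1]] <-
      sort(c(sort(clusters[[best[1]]])[1], sort(clusters[[best[2]]])[1]))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  merges
}

# hclust merge matrix -> the same representation as oracle_ward_merges:
# each merge as the two smallest original leaf labels of the two clusters
hclust_merge_pairs <- function(hc) {
  reps <- list()
  out <- list()
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else reps[[v]]
    L <- get(hc$merge[m, 1]); R <- get(hc$merge[m, 2])
    out[[m]] <- sort(c(min(L), min(R)))
    reps[[m]] <- c(L, R)
  }
  out
}

# type-7 sample quantile from first principles (sort-based)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

sd_pop_oracle <- function(x) sqrt(mean((x - mean(x))^2))

spearman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  cor(rank(a[ok]), rank(b[ok]))
}
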