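#' Configuration for the synthetic nucleus generator
#'
#' The generator emulates a multi-cell ensemble of confined, polymer-like
#' nuclear structures with controllable coupling between chromatin class
#' and radial position, plus interior chromocenter blobs. Chromosomes are
#' random walks of "domain" centers (soft self-avoidance, rejection outside
#' the nuclear sphere); each domain carries a block of consecutive genomic
#' segments scattered around it with a class-specific spread, which is what
#' creates density contrast (compact = dense, loose = sparse).
#'
#' @param n_cells Number of cells in the ensemble.
#' @param n_chroms Chromosomes per haplotype.
#' @param particles_per_chrom Segments (particles) per chromosome.
#' @param resolution Bin size in bp (default 20000).
#' @param haplotypes Haplotype labels; `c("pat","mat")` gives a diploid
#'   cell, `"none"` a haploid one.
#' @param nucleus_radius Nuclear radius, arbitrary length unit.
#' @param step_length Per-segment walk scale; domain centers step
#'   `step_length * sqrt(domain_size)`.
#' @param radial_bias Named numeric in \[-1, 1\] per class
#'   (`active`, `repressed`, `chromocenter`, `neutral`); positive pushes
#'   toward the periphery, a segment with bias b is drawn toward radius
#'   fraction `(1 + b) / 2`. The `neutral` class (unbiased, medium spread)
#'   is only used when supplied through `segment_classes`.
#' @param chromocenter_fraction Fraction of segments collapsed into
#'   interior high-density blobs.
#' @param active_fraction Fraction of non-chromocenter segments labeled
#'   active-like (the rest are repressed-like).
#' @param inverted If `TRUE`, the class-to-radius mapping is flipped (the
#'   rod-photoreceptor architecture: heterochromatin interior, euchromatin
#'   peripheral).
#' @param domain_size Consecutive segments per domain block.
#' @param jitter_sd Named numeric: spatial spread of segments around their
#'   domain center per class, same unit as `nucleus_radius`.
#' @param radial_sd Named numeric: SD of a biased domain's radial position
#'   around its class target, as a fraction of `nucleus_radius`. A small
#'   value for the repressed class produces the thin dense peripheral
#'   heterochromatin rim of conventional nuclei.
#' @param radial_strength Blend weight in \[0, 1\] pulling biased domains
#'   toward their target radius.
#' @param peripheral_plaques If `TRUE` (default), repressed domains
#'   cluster into shared peripheral foci (LAD-like plaques), producing a
#'   dense heterochromatin rim; if `FALSE` every plaque-mechanism class
#'   falls back to the plain radially biased walk, which decouples density
#'   from radial position (a human-like regime).
#' @param class_mechanism Named character vector mapping each class to a
#'   placement mechanism: `"walk"` (radially biased random-walk domains),
#'   `"plaque"` (domains cluster into shared peripheral foci), or `"blob"`
#'   (domains collapse into the shared interior chromocenter blobs).
#' @param n_plaques Number of peripheral plaque foci per cell.
#' @param max_radius_frac Optional named numeric: per-class ceiling on the
#'   radial position of individual particles, as a fraction of
#'   `nucleus_radius`. The default excludes active-like chromatin from the
#'   lamina shell (euchromatin is depleted at the nuclear lamina); jitter
#'   draws beyond the ceiling are retried.
#' @param segment_classes Optional explicit class vector (length
#'   `n_chroms * particles_per_chrom`, shared by haplotypes), overriding
#'   the random block assignment.
#' @param seed Integer seed; each cell uses an RNG stream derived from
#'   `(seed, cell index)`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cells = 20, n_chroms = 3, particles_per_chrom = 500,
                         resolution = 20000, haplotypes = c("pat", "mat"),
                         nucleus_radius = 10, step_length = 0.8,
                         radial_bias = c(active = -0.2, repressed = 0.6,
                                         chromocenter = -0.4, neutral = 0),
                         chromocenter_fraction = 0.10, active_fraction = 0.45,
                         inverted = FALSE, domain_size = 20,
                         jitter_sd = c(active = 2.0, repressed = 0.5,
                                       chromocenter = 0.28, neutral = 1.2),
                         radial_sd = c(active = 0.15, repressed = 0.04,
                                       chromocenter = 0.05, neutral = 0.15),
                         radial_strength = 0.85, peripheral_plaques = TRUE,
                         class_mechanism = c(active = "walk",
                                             repressed = "plaque",
                                             chromocenter = "blob",
                                             neutral = "walk"),
                         n_plaques = 24,
                         max_radius_frac = c(active = 0.85),
                         segment_classes = NULL, seed = 1) {
  if (nucleus_radius <= 0) stop("nucleus_radius must be positive")
  if (step_length >= nucleus_radius) stop("step_length must be < nucleus_radius")
  if (chromocenter_fraction < 0 || chromocenter_fraction > 1 ||
      active_fraction < 0 || active_fraction > 1) {
    stop("fractions must be in [0, 1]")
  }
  if (any(abs(radial_bias) > 1)) stop("radial_bias values must be in [-1, 1]")
  cfg <- list(n_cells = n_cells, n_chroms = n_chroms,
              particles_per_chrom = particles_per_chrom,
              resolution = resolution, haplotypes = haplotypes,
              nucleus_radius = nucleus_radius, step_length = step_length,
              radial_bias = radial_bias,
              chromocenter_fraction = chromocenter_fraction,
              active_fraction = active_fraction, inverted = inverted,
              domain_size = domain_size, jitter_sd = jitter_sd,
              radial_sd = radial_sd, radial_strength = radial_strength,
              peripheral_plaques = peripheral_plaques,
              class_mechanism = class_mechanism, n_plaques = n_plaques,
              max_radius_frac = max_radius_frac,
              segment_classes = segment_classes, seed = seed)
  class(cfg) <- "synth_config"
  cfg
}

cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) * 7919 + cell_index * 104729) %% 2147483647)
}

random_unit <- function(n = 1) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# class labels per (chrom, bin), shared across haplotypes and cells
assign_classes <- function(cfg) {
  if (!is.null(cfg$segment_classes)) {
    cl <- cfg$segment_classes
    if (length(cl) != cfg$n_chroms * cfg$particles_per_chrom) {
      stop("segment_classes must have length n_chroms * particles_per_chrom")
    }
    return(cl)
  }
  n <- cfg$n_chroms * cfg$particles_per_chrom
  n_blocks <- ceiling(n / cfg$domain_size)
  p_cc <- cfg$chromocenter_fraction
  probs <- c(active = (1 - p_cc) * cfg$active_fraction,
             repressed = (1 - p_cc) * (1 - cfg$active_fraction),
             chromocenter = p_cc)
  block_cl <- sample(names(probs), n_blocks, replace = TRUE, prob = probs)
  rep(block_cl, each = cfg$domain_size)[seq_len(n)]
}

#' Generate a synthetic multi-cell ensemble with ground truth
#'
#' @param cfg A [synth_config()].
#' @return A list with `structures` (list of `genome_structure`, one per
#'   cell) and `truth`: a list holding the per-segment `classes` data.frame
#'   (`chrom`, `bin`, `class`) and the generating `config`.
#' @export
generate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cell_seed(cfg$seed, 0L))
  classes <- assign_classes(cfg)
  chroms <- as.character(seq_len(cfg$n_chroms))
  class_df <- data.frame(
    chrom = rep(chroms, each = cfg$particles_per_chrom),
    bin = rep(seq_len(cfg$particles_per_chrom) - 1L, times = cfg$n_chroms),
    class = classes, stringsAsFactors = FALSE)
  structures <- lapply(seq_len(cfg$n_cells), function(ci) {
    set.seed(cell_seed(cfg$seed, ci))
    synth_one_cell(cfg, class_df, cell_id = sprintf("synth_cell_%03d", ci))
  })
  list(structures = structures,
       truth = list(classes = class_df, config = cfg))
}

synth_one_cell <- function(cfg, class_df, cell_id) {
  R <- cfg$nucleus_radius
  bias <- cfg$radial_bias
  if (cfg$inverted) bias <- -bias
  n_blobs <- 3L
  blob_dir <- random_unit(n_blobs)
  blob_r <- R * (1 + bias[["chromocenter"]]) / 2
  blob_centers <- blob_dir * blob_r
  # peripheral heterochromatin plaques: plaque-mechanism domains cluster
  # into shared foci at the repressed target radius, like LAD patches
  # under the lamina
  rep_target <- R * (1 + bias[["repressed"]]) / 2
  n_plaques <- as.integer(cfg$n_plaques)
  plaque_centers <- random_unit(n_plaques) *
    pmin(pmax(rep_target + rnorm(n_plaques, sd = cfg$radial_sd[["repressed"]] * R),
              0), 0.93 * R)
  mechanism_of <- function(cl) {
    m <- if (cl %in% names(cfg$class_mechanism)) {
      cfg$class_mechanism[[cl]]
    } else "walk"
    if (m == "plaque" && !cfg$peripheral_plaques) m <- "walk"
    m
  }
  out <- vector("list", length(cfg$haplotypes) * cfg$n_chroms)
  m <- 0L
  for (hap in cfg$haplotypes) {
    for (ch in unique(class_df$chrom)) {
      cls <- class_df$class[class_df$chrom == ch]
      n_seg <- length(cls)
      dom <- (seq_len(n_seg) - 1L) %/% cfg$domain_size + 1L
      n_dom <- max(dom)
      dom_cls <- cls[match(seq_len(n_dom), dom)]
      centers <- walk_domain_centers(n_dom, cfg, R)
      # pull biased domains toward their class target radius
      for (d in seq_len(n_dom)) {
        dc <- dom_cls[d]
        mech <- mechanism_of(dc)
        if (mech == "blob") {
          b <- blob_centers[sample.int(n_blobs, 1), ]
          centers[d, ] <- b + rnorm(3, sd = 0.35)
        } else if (mech == "plaque") {
          p <- plaque_centers[sample.int(n_plaques, 1), ]
          centers[d, ] <- p + rnorm(3, sd = 0.6)
        } else {
          bb <- bias[[dc]]
          if (bb != 0) {
            cur_r <- sqrt(sum(centers[d, ]^2))
            u <- if (cur_r < 1e-9) random_unit(1)[1, ] else centers[d, ] / cur_r
            target <- R * (1 + bb) / 2 + rnorm(1, sd = cfg$radial_sd[[dc]] * R)
            target <- min(max(target, 0), 0.96 * R)
            new_r <- (1 - cfg$radial_strength) * cur_r +
              cfg$radial_strength * target
            centers[d, ] <- u * new_r
          }
        }
      }
      # keep every domain center safely inside the sphere so segment
      # jitter can always be placed
      cr <- sqrt(rowSums(centers^2))
      too_far <- cr > 0.93 * R
      if (any(too_far)) {
        centers[too_far, ] <- centers[too_far, , drop = FALSE] *
          (0.93 * R / cr[too_far])
      }
      xyz <- matrix(NA_real_, n_seg, 3)
      for (i in seq_len(n_seg)) {
        sdv <- cfg$jitter_sd[[cls[i]]]
        rmax <- if (cls[i] %in% names(cfg$max_radius_frac)) {
          cfg$max_radius_frac[[cls[i]]] * R
        } else R
        for (try in 1:100) {
          p <- centers[dom[i], ] + rnorm(3, sd = sdv)
          # soft lamina exclusion: enforce the class ceiling for the
          # first attempts, fall back to the nuclear radius
          lim <- if (try <= 50) min(rmax, R) else R
          if (sum(p^2) <= lim^2) break
          if (try == 100) {
            stop("infeasible packing: could not place a particle inside ",
                 "the nucleus; increase nucleus_radius")
          }
        }
        xyz[i, ] <- p
      }
      m <- m + 1L
      out[[m]] <- data.frame(
        chrom = ch, hap = hap,
        pos = (seq_len(n_seg) - 1) * cfg$resolution,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
    }
  }
  genome_structure(do.call(rbind, out), resolution = cfg$resolution,
                   cell_id = cell_id)
}

# random walk of domain centers inside the sphere, soft self-avoidance
walk_domain_centers <- function(n_dom, cfg, R) {
  step <- cfg$step_length * sqrt(cfg$domain_size)
  d_min <- 0.5 * step
  centers <- matrix(NA_real_, n_dom, 3)
  centers[1, ] <- random_unit(1) * runif(1, 0, 0.6 * R)
  for (d in seq_len(n_dom - 1L)) {
    placed <- FALSE
    for (try in 1:50) {
      cand <- centers[d, ] + random_unit(1)[1, ] * step
      if (sum(cand^2) > (0.95 * R)^2) next
      prev <- centers[seq_len(d), , drop = FALSE]
      dd <- sqrt(rowSums(sweep(prev, 2, cand)^2))
      if (try < 25 && any(dd < d_min)) next  # soft avoidance: give up late
      centers[d + 1L, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("infeasible packing: random walk could not stay inside the ",
           "nucleus; increase nucleus_radius")
    }
  }
  centers
}

#' Per-segment cross-cell summary of density and DisTP
#'
#' @param cell_tables List of `cell_d2` tables from one ensemble.
#' @return data.frame with `segment`, `chrom`, `hap`, `bin`, `n_cells`
#'   (cells in which the segment was scored), `density_mean`, `distp_mean`.
#' @export
segment_means <- function(cell_tables) {
  res <- attr(cell_tables[[1]], "resolution")
  all <- do.call(rbind, lapply(cell_tables, function(tb) {
    data.frame(segment = segment_ids(tb, res), chrom = tb$chrom,
               hap = tb$hap, bin = tb$start %/% res,
               density = tb$density, distp = tb$distp,
               stringsAsFactors = FALSE)
  }))
  f <- factor(all$segment)
  i <- match(levels(f), all$segment)
  data.frame(segment = levels(f), chrom = all$chrom[i], hap = all$hap[i],
             bin = all$bin[i],
             n_cells = as.integer(table(f)),
             density_mean = as.numeric(tapply(all$density, f, mean)),
             distp_mean = as.numeric(tapply(all$distp, f, mean)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a synthetic marker track with known loadings
#'
#' The track value of segment g is
#' `alpha * z(mean density_g) + beta * z(mean DisTP_g) + Normal(0, noise_sd)`
#' where the means are taken across the scored cells of the ensemble and
#' `z()` is the population z-score. The true loadings are recorded on the
#' returned track, enabling parameter-recovery tests of the enrichment
#' machinery.
#'
#' @param cell_tables List of `cell_d2` tables (the scored ensemble).
#' @param alpha,beta Loadings on z-scored mean density and mean DisTP.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param name Track name.
#' @return A `marker_track` (see [make_track()]) with attribute
#'   `ground_truth = list(alpha, beta, noise_sd)`.
#' @export
generate_marker_track <- function(cell_tables, alpha, beta, noise_sd = 0,
                                  seed = 1, name = "synthetic") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sm <- segment_means(cell_tables)
  set.seed(cell_seed(seed, 997L))
  value <- alpha * zscore(sm$density_mean) + beta * zscore(sm$distp_mean) +
    rnorm(nrow(sm), sd = noise_sd)
  tr <- if (sd_pop(value) == 0) {
    # degenerate track (e.g. zero loadings and zero noise): NV undefined
    warning("constant synthetic track; NV set to 0")
    structure(data.frame(segment = sm$segment, value = value, nv = 0,
                         stringsAsFactors = FALSE),
              class = c("marker_track", "data.frame"), name = name,
              kind = "signal")
  } else {
    marker_track(name = name, segment = sm$segment, value = value,
                 kind = "signal")
  }
  attr(tr, "ground_truth") <- list(alpha = alpha, beta = beta,
                                   noise_sd = noise_sd)
  tr
}

zscore <- function(x) {
  s <- sd_pop(x)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score")
  (x - mean(x)) / s
}

sd_pop <- function(x) {
  n <- sum(!is.na(x))
  if (n < 1) return(NA_real_)
  sqrt(sum((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE) / n)
}
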