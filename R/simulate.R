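#' Simulation configuration for a synthetic chromosome
#'
#' Bundles the parameters of the synthetic Hi-C generator: chromosome size in
#' bins, distance-decay exponent of the polymer background, expected total
#' read-pair depth, the range of planted TAD sizes, per-boundary insulation
#' depths and an optional A/B compartment checkerboard.
#'
#' The insulation depth of a boundary is the multiplicative factor applied to
#' the expected count of a contact that crosses it: 1 means no insulation,
#' values near 0 mean nearly complete insulation. Contacts crossing several
#' boundaries multiply the depths of every boundary crossed.
#'
#' @param n_bins Number of bins on the synthetic chromosome.
#' @param bin_size Bin width in base pairs (default 10 kb, the TAD-calling
#'   resolution).
#' @param decay_exponent Positive exponent \eqn{\alpha} of the background decay
#'   \eqn{(1+|i-j|)^{-\alpha}}.
#' @param depth Expected total read pairs over the upper triangle (>= 0; 0
#'   produces an all-zero matrix).
#' @param tad_size_range Length-2 integer vector, min and max planted TAD size
#'   in bins.
#' @param insulation_depths Numeric vector of depths in (0, 1], recycled over
#'   planted boundaries.
#' @param compartment_block_bins Period (in bins) of the A/B checkerboard, or
#'   NULL for no compartment structure.
#' @param compartment_same Expected-count factor for same-label bin pairs.
#' @param compartment_cross Factor for cross-label pairs. The defaults 1.3 and
#'   0.77 are symmetric on the log scale so the correlation-map PC1 is
#'   sign-balanced.
#' @param chrom Chromosome name used in all emitted files.
#' @param seed Integer master seed; every stochastic draw derives from it.
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_bins = 200, tad_size_range = c(20, 40), seed = 7)
#' @export
sim_config <- function(n_bins,
                       bin_size = 10000L,
                       decay_exponent = 1,
                       depth = 2e6,
                       tad_size_range = c(60L, 120L),
                       insulation_depths = 0.3,
                       compartment_block_bins = NULL,
                       compartment_same = 1.3,
                       compartment_cross = 0.77,
                       chrom = "chrS",
                       seed = 1L) {
  stop_if_not_scalar_num(n_bins, "n_bins", lower = 2)
  stop_if_not_scalar_num(bin_size, "bin_size", lower = 1)
  stop_if_not_scalar_num(decay_exponent, "decay_exponent", lower = 1e-8)
  stop_if_not_scalar_num(depth, "depth", lower = 0)
  if (length(tad_size_range) != 2L || any(tad_size_range < 1) ||
      tad_size_range[1] > tad_size_range[2]) {
    stop("'tad_size_range' must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (n_bins < 2 * max(tad_size_range)) {
    stop("'n_bins' must be at least twice the maximum TAD size", call. = FALSE)
  }
  if (any(insulation_depths <= 0) || any(insulation_depths > 1)) {
    stop("all 'insulation_depths' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(compartment_block_bins)) {
    stop_if_not_scalar_num(compartment_block_bins, "compartment_block_bins", lower = 1)
  }
  structure(
    list(
      n_bins = as.integer(n_bins),
      bin_size = as.integer(bin_size),
      decay_exponent = decay_exponent,
      depth = depth,
      tad_size_range = as.integer(tad_size_range),
      insulation_depths = insulation_depths,
      compartment_block_bins = if (is.null(compartment_block_bins)) NULL else
        as.integer(compartment_block_bins),
      compartment_same = compartment_same,
      compartment_cross = compartment_cross,
      chrom = chrom,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Plant the ground-truth chromosome architecture
#'
#' Tiles the chromosome with TADs whose sizes are drawn uniformly from
#' \code{tad_size_range}, records the internal boundaries between them,
#' assigns each boundary an insulation depth (recycling
#' \code{insulation_depths}), lays down the A/B checkerboard when configured
#' and draws a gene-density track that is enriched in A bins (the orientation
#' reference for compartment calling).
#'
#' All intervals are 0-based half-open in bin units; a boundary index \code{b}
#' means the downstream TAD starts at bin \code{b}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{planted_architecture} with elements
#'   \code{boundaries} (strictly increasing internal boundary bins),
#'   \code{tads} (two-column matrix, half-open bin intervals),
#'   \code{boundary_depths}, \code{compartment_label} (per-bin "A"/"B" or NA)
#'   and \code{gene_density} (per-bin counts, higher in A bins).
#' @export
plant_architecture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_bins
  rng <- config$tad_size_range
  with_seed(child_seed(config$seed, 1L), {
    sizes <- integer(0)
    pos <- 0L
    repeat {
      remaining <- n - pos
      if (remaining <= rng[2]) {
        if (remaining >= rng[1] || length(sizes) == 0L) {
          sizes <- c(sizes, remaining)
        } else {
          # leftover shorter than the minimum TAD: absorb into the last TAD
          sizes[length(sizes)] <- sizes[length(sizes)] + remaining
        }
        break
      }
      s <- resample(rng[1]:rng[2], 1L)
      sizes <- c(sizes, s)
      pos <- pos + s
    }
    starts <- cumsum(c(0L, sizes[-length(sizes)]))
    ends <- cumsum(sizes)
    boundaries <- starts[-1L]
    depths <- rep_len(config$insulation_depths, length(boundaries))
    label <- rep(NA_character_, n)
    if (!is.null(config$compartment_block_bins)) {
      blk <- config$compartment_block_bins
      label <- rep(c("A", "B"), each = blk, length.out = n + 2L * blk)[seq_len(n)]
    }
    lambda <- ifelse(!is.na(label) & label == "A", 5, 1)
    gene_density <- stats::rpois(n, lambda)
    structure(
      list(
        n_bins = n,
        bin_size = config$bin_size,
        chrom = config$chrom,
        boundaries = as.integer(boundaries),
        tads = cbind(start = as.integer(starts), end = as.integer(ends)),
        boundary_depths = depths,
        compartment_label = label,
        gene_density = as.numeric(gene_density)
      ),
      class = "planted_architecture"
    )
  })
}

#' @export
print.planted_architecture <- function(x, ...) {
  cat(sprintf("planted_architecture: %d bins (%s), %d TADs, %d boundaries\n",
              x$n_bins, x$chrom, nrow(x$tads), length(x$boundaries)))
  if (any(!is.na(x$compartment_label))) {
    cat(sprintf("  compartments: %d A / %d B bins\n",
                sum(x$compartment_label == "A", na.rm = TRUE),
                sum(x$compartment_label == "B", na.rm = TRUE)))
  }
  invisible(x)
}

# Expected (noise-free) contact surface for a planted architecture, scaled so
# the upper-triangle total equals `depth`. Shared by the sampler and by tests
# that need the closed-form expectation.
expected_contact_surface <- function(arch, config) {
  n <- arch$n_bins
  idx <- seq_len(n) - 1L
  d <- abs(outer(idx, idx, "-"))
  e <- (1 + d)^(-config$decay_exponent)
  # multiplicative insulation: product of depths of all boundaries crossed
  tad_id <- findInterval(idx, c(0L, arch$boundaries)) # 1..n_tads
  cum_logdepth <- cumsum(c(0, log(arch$boundary_depths)))
  cl <- cum_logdepth[tad_id]
  e <- e * exp(-abs(outer(cl, cl, "-")))
  if (any(!is.na(arch$compartment_label))) {
    same <- outer(arch$compartment_label, arch$compartment_label, "==")
    fac <- ifelse(same, config$compartment_same, config$compartment_cross)
    e <- e * fac
  }
  tot <- sum(e[upper.tri(e, diag = TRUE)])
  if (config$depth == 0 || tot == 0) return(e * 0)
  e * (config$depth / tot)
}

#' Simulate a Hi-C contact matrix from a planted architecture
#'
#' Expected counts follow a distance-decay background
#' \eqn{A (1+|i-j|)^{-\alpha}} modulated by the planted TAD block structure (a
#' contact crossing boundaries is attenuated by the product of their insulation
#' depths) and, when compartments are planted, a same/cross-label checkerboard
#' factor. The scale \eqn{A} is chosen so the expected upper-triangle total
#' equals \code{config$depth}. Counts are Poisson draws, symmetrized exactly.
#'
#' @param arch A \code{\link{plant_architecture}} result.
#' @param config The matching \code{\link{sim_config}}.
#' @return A raw \code{\link{contact_matrix}}.
#' @export
simulate_contact_map <- function(arch, config) {
  stopifnot(inherits(arch, "planted_architecture"), inherits(config, "sim_config"))
  if (arch$n_bins != config$n_bins) {
    stop("architecture and config disagree on n_bins", call. = FALSE)
  }
  e <- expected_contact_surface(arch, config)
  n <- arch$n_bins
  counts <- matrix(0, n, n)
  up <- upper.tri(e, diag = TRUE)
  with_seed(child_seed(config$seed, 2L), {
    counts[up] <- stats::rpois(sum(up), e[up])
  })
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, chrom = arch$chrom, bin_size = arch$bin_size)
}

#' Remove planted boundaries from an architecture
#'
#' Deletes the given boundaries and merges the TADs they separated, emulating
#' boundary loss after perturbation (e.g. factor knockdown). The remaining
#' boundaries keep their insulation depths; compartments and gene density are
#' untouched.
#'
#' @param arch A \code{planted_architecture}.
#' @param drop Indices into \code{arch$boundaries} (not bin values) to remove.
#' @return A new \code{planted_architecture}.
#' @export
ablate_architecture <- function(arch, drop) {
  stopifnot(inherits(arch, "planted_architecture"))
  if (length(drop) == 0L) return(arch)
  keep <- setdiff(seq_along(arch$boundaries), drop)
  b <- arch$boundaries[keep]
  arch$boundaries <- b
  arch$boundary_depths <- arch$boundary_depths[keep]
  arch$tads <- cbind(start = c(0L, b), end = c(b, arch$n_bins))
  arch
}

#' Specification of one synthetic factor's peak set
#'
#' @param name Factor name.
#' @param n_peaks Number of peaks to place.
#' @param boundary_fraction Fraction of peaks whose summits land inside
#'   boundary bins; the rest are uniform over non-boundary bins.
#' @param group_id Integer co-occupancy group label; factors sharing a group id
#'   draw their summits from a shared latent CRE pool (with independent
#'   dropout), planting co-occupancy structure. Use 0 for an independent
#'   factor.
#' @param peak_width Peak width in bp (summit-centered).
#' @return A \code{factor_spec} list.
#' @export
factor_spec <- function(name, n_peaks, boundary_fraction = 0.2, group_id = 0L,
                        peak_width = 200L) {
  stop_if_not_scalar_num(n_peaks, "n_peaks", lower = 0)
  stop_if_not_scalar_num(boundary_fraction, "boundary_fraction", 0, 1)
  structure(
    list(name = as.character(name), n_peaks = as.integer(n_peaks),
         boundary_fraction = boundary_fraction, group_id = as.integer(group_id),
         peak_width = as.integer(peak_width)),
    class = "factor_spec"
  )
}

# Draw a pool of summit positions: `frac` of them centered inside boundary
# bins (sampled without replacement), the rest uniform over non-boundary bins.
draw_summit_pool <- function(arch, n, frac) {
  bs <- arch$bin_size
  n_bound <- round(n * frac)
  if (n_bound > length(arch$boundaries)) {
    stop(sprintf("requested %d boundary peaks but only %d boundary bins exist",
                 n_bound, length(arch$boundaries)), call. = FALSE)
  }
  pos <- numeric(0)
  if (n_bound > 0) {
    bb <- resample(arch$boundaries, n_bound)
    pos <- bb * bs + sample.int(bs, n_bound, replace = TRUE) - 1L
  }
  n_rest <- n - n_bound
  if (n_rest > 0) {
    other_bins <- setdiff(seq_len(arch$n_bins) - 1L, arch$boundaries)
    ob <- resample(other_bins, n_rest, replace = TRUE)
    pos <- c(pos, ob * bs + sample.int(bs, n_rest, replace = TRUE) - 1L)
  }
  sort(pos)
}

#' Simulate factor peak sets with planted co-occupancy
#'
#' For each factor, \code{boundary_fraction} of the summits are placed inside
#' boundary bins and the rest uniformly over non-boundary bins. Factors that
#' share a nonzero \code{group_id} sample their summits without replacement
#' from a shared latent pool, so their peak sets co-occur up to independent
#' dropout; factors with \code{group_id = 0} are placed independently.
#'
#' @param arch A \code{planted_architecture}.
#' @param specs List of \code{\link{factor_spec}} objects.
#' @param seed Integer seed.
#' @param dropout Pool-dropout rate for grouped factors in [0, 1): the shared
#'   pool has \code{ceiling(max(n_peaks)/(1-dropout))} positions and each
#'   member samples its own \code{n_peaks} from it.
#' @return Named list of peak data frames (one per factor) with columns
#'   \code{chrom, start, end, name, score, strand, summit} (summit absolute
#'   bp), ordered by position.
#' @export
simulate_peaks <- function(arch, specs, seed = 1L, dropout = 0) {
  stopifnot(inherits(arch, "planted_architecture"), length(specs) > 0)
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)", call. = FALSE)
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "factor_spec")) stop("specs must be factor_spec objects", call. = FALSE)
    s
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  with_seed(child_seed(seed, 3L), {
    gids <- vapply(specs, `[[`, integer(1), "group_id")
    pools <- list()
    for (g in unique(gids[gids != 0L])) {
      members <- specs[gids == g]
      n_pool <- ceiling(max(vapply(members, `[[`, integer(1), "n_peaks")) /
                          (1 - dropout))
      frac <- mean(vapply(members, `[[`, numeric(1), "boundary_fraction"))
      pools[[as.character(g)]] <- draw_summit_pool(arch, n_pool, frac)
    }
    out <- lapply(specs, function(s) {
      if (s$n_peaks == 0L) {
        summits <- numeric(0)
      } else if (s$group_id != 0L) {
        pool <- pools[[as.character(s$group_id)]]
        summits <- sort(resample(pool, min(s$n_peaks, length(pool))))
      } else {
        summits <- draw_summit_pool(arch, s$n_peaks, s$boundary_fraction)
      }
      half <- s$peak_width %/% 2L
      start <- pmax(0, summits - half)
      end <- pmin(arch$n_bins * arch$bin_size, summits + (s$peak_width - half))
      data.frame(
        chrom = rep(arch$chrom, length(summits)),
        start = as.integer(start), end = as.integer(end),
        name = if (length(summits)) paste0(s$name, "_", seq_along(summits)) else character(0),
        score = rep(0L, length(summits)), strand = rep(".", length(summits)),
        summit = as.integer(summits),
        stringsAsFactors = FALSE
      )
    })
    out
  })
}

#' Simulate a per-bin signal track (transcription-like)
#'
#' Counts are Poisson(\code{background}) off-target and Poisson(\code{amplitude})
#' in bins overlapping the target intervals, emulating a nascent-transcription
#' (GRO-seq-like) readout concentrated at chosen regions.
#'
#' @param arch A \code{planted_architecture}.
#' @param target_intervals Two-column matrix/data.frame of bp intervals
#'   (0-based half-open), or NULL for a stationary track.
#' @param amplitude Expected on-target count per bin (>= background).
#' @param background Expected off-target count per bin (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of per-bin counts (length \code{n_bins}).
#' @export
simulate_signal_track <- function(arch, target_intervals, amplitude, background,
                                  seed = 1L) {
  stopifnot(inherits(arch, "planted_architecture"))
  if (background < 0 || amplitude < background) {
    stop("need amplitude >= background >= 0", call. = FALSE)
  }
  n <- arch$n_bins
  lambda <- rep(background, n)
  if (!is.null(target_intervals) && NROW(target_intervals) > 0) {
    ti <- as.matrix(target_intervals)[, 1:2, drop = FALSE]
    for (k in seq_len(nrow(ti))) {
      b0 <- max(0L, floor(ti[k, 1] / arch$bin_size))
      b1 <- min(n, ceiling(ti[k, 2] / arch$bin_size))
      if (b1 > b0) lambda[(b0 + 1L):b1] <- amplitude
    }
  }
  with_seed(child_seed(seed, 4L), stats::rpois(n, lambda))
}

#' Write a synthetic dataset (matrix, bins, peaks, tracks, truth) to disk
#'
#' Emits the generator outputs in plain-text exchange formats: the contact
#' matrix as an upper-triangle triplet file, the bin table as BED, peaks as
#' BED6+summit, tracks as bedGraph and the planted truth as TSV tables that
#' round-trip through \code{\link{read_architecture}}.
#'
#' @param arch Planted architecture.
#' @param cm Contact matrix.
#' @param peaks Named list of peak data frames (may be NULL).
#' @param tracks Named list of per-bin numeric tracks (may be NULL).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_synthetic_dataset <- function(arch, cm, peaks = NULL, tracks = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.triplet.tsv"),
    bins = file.path(dir, "bins.bed")
  )
  write_triplet_matrix(cm, paths[["matrix"]])
  write_bins_bed(arch$n_bins, arch$bin_size, arch$chrom, paths[["bins"]])
  for (nm in names(peaks)) {
    p <- file.path(dir, paste0("peaks_", nm, ".bed"))
    write_peaks_bed(peaks[[nm]], p)
    paths[[paste0("peaks_", nm)]] <- p
  }
  for (nm in names(tracks)) {
    p <- file.path(dir, paste0("track_", nm, ".bedgraph"))
    write_bedgraph(tracks[[nm]], arch$bin_size, arch$chrom, p)
    paths[[paste0("track_", nm)]] <- p
  }
  tp <- write_architecture(arch, dir)
  invisible(c(paths, tp))
}
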