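peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

boundary_granges <- function(tadset, flank = 0) {
  b <- tadset$boundaries$bin
  bs <- tadset$bin_size
  GenomicRanges::GRanges(
    seqnames = tadset$chrom,
    ranges = IRanges::IRanges(start = b * bs + 1L - flank,
                              end = (b + 1L) * bs + flank)
  )
}

#' Assign peaks to boundary / intra-TAD / gap categories
#'
#' A peak counts as boundary-overlapping when it intersects any boundary bin
#' extended by \code{flank} bp on each side; boundary assignment takes
#' precedence over intra-TAD, so every peak lands in exactly one category.
#' Peaks inside the chromosome extent but not on a boundary are intra-TAD;
#' peaks beyond the binned extent are "gap". Each boundary is flagged
#' +factor when at least one peak overlaps it.
#'
#' @param peaks Peak data frame (\code{chrom,start,end,...}).
#' @param tadset A \code{tad_set} on the same chromosome.
#' @param flank Boundary flank in bp (default 0: the boundary is its bin).
#' @return A \code{factor_boundary_stats} list: per-category counts and
#'   fractions, the per-peak category vector and the per-boundary presence
#'   flags.
#' @export
assign_peaks <- function(peaks, tadset, flank = 0) {
  stopifnot(inherits(tadset, "tad_set"))
  if (nrow(peaks) > 0 && !all(peaks$chrom == tadset$chrom)) {
    bad <- unique(peaks$chrom[peaks$chrom != tadset$chrom])
    stop("peak chromosomes not in TAD set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_b <- nrow(tadset$boundaries)
  chrom_end <- tadset$n_bins * tadset$bin_size
  if (nrow(peaks) == 0L) {
    return(structure(
      list(n_peaks = 0L, counts = c(boundary = 0L, intra = 0L, gap = 0L),
           fractions = c(boundary = 0, intra = 0, gap = 0),
           category = character(0),
           boundary_flag = rep(FALSE, n_b)),
      class = "factor_boundary_stats"
    ))
  }
  pg <- peaks_to_granges(peaks)
  cat <- rep("intra", nrow(peaks))
  flag <- rep(FALSE, n_b)
  if (n_b > 0) {
    bg <- boundary_granges(tadset, flank)
    hits <- GenomicRanges::findOverlaps(pg, bg)
    cat[unique(S4Vectors::queryHits(hits))] <- "boundary"
    flag[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  off <- peaks$end <= 0 | peaks$start >= chrom_end
  cat[off & cat != "boundary"] <- "gap"
  counts <- c(boundary = sum(cat == "boundary"), intra = sum(cat == "intra"),
              gap = sum(cat == "gap"))
  structure(
    list(n_peaks = nrow(peaks), counts = counts,
         fractions = counts / nrow(peaks), category = cat,
         boundary_flag = flag),
    class = "factor_boundary_stats"
  )
}

#' Average signal profile around anchors (metagene)
#'
#' Extracts a window of \code{2*flank_bins+1} bins centered on every anchor
#' bin, drops windows truncated by chromosome ends, averages column-wise and
#' scales to reads-per-million of the whole track (library-size
#' normalization).
#'
#' @param track Per-bin numeric track.
#' @param anchors 0-based anchor bin indices (e.g. boundary bins).
#' @param flank_bins Window half-width in bins.
#' @param n_out Optional output length; the profile is linearly interpolated
#'   to \code{n_out} points when given.
#' @return Numeric RPM profile with attribute \code{n_anchors}.
#' @export
metagene_profile <- function(track, anchors, flank_bins, n_out = NULL) {
  n <- length(track)
  total <- sum(track)
  keep <- anchors - flank_bins >= 0L & anchors + flank_bins <= n - 1L
  if (!any(keep)) stop("all anchor windows are truncated", call. = FALSE)
  win <- vapply(anchors[keep], function(a) {
    track[(a - flank_bins + 1L):(a + flank_bins + 1L)]
  }, numeric(2L * flank_bins + 1L))
  prof <- rowMeans(win)
  if (total > 0) prof <- prof * 1e6 / total
  if (!is.null(n_out) && n_out != length(prof)) {
    prof <- stats::approx(seq_along(prof), prof, n = n_out)$y
  }
  attr(prof, "n_anchors") <- sum(keep)
  prof
}

#' Flag boundary-associated factors from metagene profiles
#'
#' A factor is boundary-associated (baRBP-style) when the mean of its
#' boundary metagene profile over the central window exceeds
#' \code{ratio_threshold} times the mean over the distal flank window (the
#' intra-TAD reference).
#'
#' @param profiles Named list of metagene profiles (equal length, center at
#'   the middle position).
#' @param ratio_threshold Central/flank enrichment ratio cutoff (default 1.2).
#' @param central_halfwidth Bins on each side of the center included in the
#'   central window (default 1).
#' @param flank_range Distance range (bins from the center, both sides) of the
#'   flank window (default c(10, 20)).
#' @return Data frame: factor, central, flank, ratio, barbp flag. Zero flank
#'   signal yields NA with a warning. Threshold and windows are recorded as
#'   attributes.
#' @export
classify_ba <- function(profiles, ratio_threshold = 1.2, central_halfwidth = 1L,
                        flank_range = c(10L, 20L)) {
  stopifnot(length(profiles) > 0)
  out <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    lp <- length(p)
    c0 <- (lp + 1L) %/% 2L
    central_idx <- max(1L, c0 - central_halfwidth):min(lp, c0 + central_halfwidth)
    fl <- flank_range
    flank_idx <- c(
      intersect(seq_len(lp), (c0 - fl[2]):(c0 - fl[1])),
      intersect(seq_len(lp), (c0 + fl[1]):(c0 + fl[2]))
    )
    central <- mean(p[central_idx])
    flank <- mean(p[flank_idx])
    ratio <- if (is.na(flank) || flank == 0) NA_real_ else central / flank
    data.frame(factor = nm, central = central, flank = flank, ratio = ratio,
               barbp = !is.na(ratio) && ratio > ratio_threshold)
  })
  res <- do.call(rbind, out)
  if (any(is.na(res$ratio))) {
    warning("zero flank signal for: ",
            paste(res$factor[is.na(res$ratio)], collapse = ", "))
  }
  attr(res, "ratio_threshold") <- ratio_threshold
  attr(res, "central_halfwidth") <- central_halfwidth
  attr(res, "flank_range") <- flank_range
  res
}

#' Stratify boundaries by anchor-factor x test-factor status
#'
#' Classifies every boundary into the four groups +CTCF+f, +CTCF-f, -CTCF+f,
#' -CTCF-f (anchor factor named CTCF by convention) and summarizes insulation
#' scores and adjacent-TAD domain scores per group, with two-sided Wilcoxon
#' comparisons (+f vs -f) within each anchor stratum, BH-adjusted.
#'
#' @param anchor_flag,test_flag Logical per-boundary presence flags.
#' @param IS Per-boundary insulation scores (optional).
#' @param domain_scores_adjacent Per-boundary numeric summaries of adjacent-TAD
#'   domain scores (optional; e.g. mean of the two flanking TADs).
#' @param anchor_name,test_name Labels used in the group names.
#' @return A list with \code{groups} (per-boundary label), \code{sizes},
#'   \code{proportions}, per-group IS/domain-score summaries and the
#'   within-stratum test table.
#' @export
boundary_groups <- function(anchor_flag, test_flag, IS = NULL,
                            domain_scores_adjacent = NULL,
                            anchor_name = "CTCF", test_name = "factor") {
  stopifnot(length(anchor_flag) == length(test_flag))
  lab <- paste0(ifelse(anchor_flag, "+", "-"), anchor_name,
                ifelse(test_flag, "+", "-"), test_name)
  lev <- c(paste0("+", anchor_name, "+", test_name),
           paste0("+", anchor_name, "-", test_name),
           paste0("-", anchor_name, "+", test_name),
           paste0("-", anchor_name, "-", test_name))
  groups <- factor(lab, levels = lev)
  sizes <- table(groups)
  summarize <- function(x) {
    if (is.null(x)) return(NULL)
    t(vapply(levels(groups), function(g) {
      v <- x[groups == g & !is.na(x)]
      c(n = length(v), mean = mean(v), median = stats::median(v))
    }, numeric(3)))
  }
  tests <- NULL
  if (!is.null(IS)) {
    rows <- lapply(c(TRUE, FALSE), function(a) {
      x <- IS[anchor_flag == a & test_flag & !is.na(IS)]
      y <- IS[anchor_flag == a & !test_flag & !is.na(IS)]
      p <- if (length(x) >= 3 && length(y) >= 3) {
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
      } else NA_real_
      data.frame(
        stratum = paste0(ifelse(a, "+", "-"), anchor_name),
        n_plus = length(x), n_minus = length(y),
        median_plus = stats::median(x), median_minus = stats::median(y),
        pvalue = p
      )
    })
    tests <- do.call(rbind, rows)
    tests$qvalue <- stats::p.adjust(tests$pvalue, "BH")
  }
  list(groups = groups, sizes = sizes,
       proportions = as.numeric(sizes) / length(groups),
       is_summary = summarize(IS),
       domain_score_summary = summarize(domain_scores_adjacent),
       is_tests = tests)
}

#' Fraction of intervals in A overlapping B
#'
#' Fraction of A intervals with at least 1 bp of overlap with any B interval,
#' plus the reverse direction and their mean as a symmetric variant.
#'
#' @param a,b Interval data frames (\code{chrom,start,end}, 0-based half-open).
#' @return List with \code{a_in_b}, \code{b_in_a}, \code{symmetric}.
#' @export
interval_overlap_fraction <- function(a, b) {
  frac <- function(x, y) {
    if (nrow(x) == 0L) return(NA_real_)
    if (nrow(y) == 0L) return(0)
    gx <- peaks_to_granges(x)
    gy <- peaks_to_granges(y)
    mean(IRanges::overlapsAny(gx, gy))
  }
  ab <- frac(a, b)
  ba <- frac(b, a)
  list(a_in_b = ab, b_in_a = ba, symmetric = mean(c(ab, ba), na.rm = TRUE))
}

#' Rank factors by central boundary metagene signal
#'
#' Descending order of the mean profile value over the central window
#' (center +/- 1 bin); ties broken alphabetically.
#'
#' @param profiles Named list of metagene profiles.
#' @param central_halfwidth Bins on each side of the center included in the
#'   central window (default 1).
#' @return Data frame: factor, central value, rank (1 = most enriched).
#' @export
rank_factors <- function(profiles, central_halfwidth = 1L) {
  central <- vapply(profiles, function(p) {
    c0 <- (length(p) + 1L) %/% 2L
    idx <- max(1L, c0 - central_halfwidth):min(length(p), c0 + central_halfwidth)
    mean(p[idx])
  }, numeric(1))
  ord <- order(-central, names(profiles))
  data.frame(factor = names(profiles)[ord], central = central[ord],
             rank = seq_along(ord), row.names = NULL)
}
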