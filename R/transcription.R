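#' Quantify a binned track over intervals (RPM)
#'
#' Sums the track over the bins each interval touches (a bin contributes its
#' full value when it overlaps the interval by at least 1 bp; the track is
#' expected to be binned at or below the interval resolution) and normalizes
#' to reads per million of the whole track.
#'
#' @param intervals Data frame with \code{start,end} in bp (0-based half-open)
#'   and optionally an \code{id} column.
#' @param track Per-bin numeric track.
#' @param bin_size Track bin size in bp.
#' @return Data frame: id, raw, rpm.
#' @export
quantify_signal <- function(intervals, track, bin_size) {
  n <- length(track)
  chrom_end <- n * bin_size
  if (nrow(intervals) == 0L) {
    return(data.frame(id = character(0), raw = numeric(0), rpm = numeric(0)))
  }
  if (any(intervals$start < 0 | intervals$end > chrom_end |
            intervals$start >= intervals$end)) {
    stop("interval outside the chromosome extent", call. = FALSE)
  }
  total <- sum(track)
  raw <- vapply(seq_len(nrow(intervals)), function(k) {
    b0 <- floor(intervals$start[k] / bin_size) + 1L
    b1 <- ceiling(intervals$end[k] / bin_size)
    sum(track[b0:b1])
  }, numeric(1))
  rpm <- if (total > 0) raw * 1e6 / total else rep(0, length(raw))
  data.frame(
    id = intervals$id %||% paste0("iv", seq_len(nrow(intervals))),
    raw = raw, rpm = rpm
  )
}

#' Length-matched shuffled control intervals
#'
#' For every query interval, places an interval of identical length uniformly
#' at random inside a randomly chosen container that can hold it. Queries with
#' no feasible container are skipped with a warning. Placements never extend
#' outside their container.
#'
#' @param query,containers Interval data frames (\code{start,end} bp).
#' @param seed Integer seed.
#' @return Data frame of shuffled intervals (\code{start,end,container}) in
#'   query order (skipped queries omitted).
#' @export
shuffle_within <- function(query, containers, seed = 1L) {
  stopifnot(nrow(containers) > 0)
  clen <- containers$end - containers$start
  with_seed(child_seed(seed, 5L), {
    rows <- lapply(seq_len(nrow(query)), function(k) {
      L <- query$end[k] - query$start[k]
      feas <- which(clen >= L)
      if (length(feas) == 0L) {
        warning("no container fits query of length ", L, "; skipped")
        return(NULL)
      }
      ci <- resample(feas, 1L)
      slack <- clen[ci] - L
      start <- containers$start[ci] +
        (if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L)
      data.frame(start = start, end = start + L, container = ci)
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
}

#' Stratify intervals into low / medium / high signal tertiles
#'
#' Zero-signal intervals are labelled \code{"none"}; the nonzero values are
#' split into rank-based tertiles (L/M/H). Ranks use average tie handling, so
#' the split is invariant to monotone transforms of the signal; a fully tied
#' set of nonzero values is assigned M.
#'
#' @param rpm Numeric signal values (e.g. RPM from \code{\link{quantify_signal}}).
#' @return A list with \code{labels} (factor with levels L, M, H, none) and
#'   \code{cutpoints} (value-scale tertile boundaries of the nonzero values).
#' @export
stratify_levels <- function(rpm) {
  labels <- rep("none", length(rpm))
  nz <- which(rpm > 0)
  if (length(nz) < 3L) {
    warning("fewer than 3 nonzero values; all labelled 'none'")
    return(list(labels = factor(labels, levels = c("L", "M", "H", "none")),
                cutpoints = c(NA_real_, NA_real_)))
  }
  v <- rpm[nz]
  r <- rank(v, ties.method = "average")
  nn <- length(v)
  lab <- ifelse(r <= nn / 3, "L", ifelse(r > 2 * nn / 3, "H", "M"))
  labels[nz] <- lab
  cut <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE)
  list(labels = factor(labels, levels = c("L", "M", "H", "none")),
       cutpoints = cut)
}

#' Compare a metric across groups (Wilcoxon, BH-adjusted)
#'
#' For every pair of group levels, a two-sided Wilcoxon rank-sum test on the
#' metric, BH-adjusted over all pairs, with the median difference and the fold
#' change of group means as effect summaries. Pairs where either group has
#' fewer than 3 values get NA.
#'
#' @param groups Factor (or coercible) of group labels, aligned with values.
#' @param values Numeric metric (IS, intra-TAD frequency, domain score, ...).
#' @return Data frame: group1, group2, n1, n2, median_diff (group1 - group2),
#'   fold_change_means (mean1/mean2), pvalue, qvalue.
#' @export
associate_groups <- function(groups, values) {
  stopifnot(length(groups) == length(values))
  g <- factor(groups)
  lev <- levels(droplevels(g[!is.na(values)]))
  if (length(lev) < 2L) stop("need at least two non-empty groups", call. = FALSE)
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    x <- values[g == pairs[1, j] & !is.na(values)]
    y <- values[g == pairs[2, j] & !is.na(values)]
    ok <- length(x) >= 3L && length(y) >= 3L
    p <- if (ok) suppressWarnings(stats::wilcox.test(x, y)$p.value) else NA_real_
    data.frame(
      group1 = pairs[1, j], group2 = pairs[2, j],
      n1 = length(x), n2 = length(y),
      median_diff = if (ok) stats::median(x) - stats::median(y) else NA_real_,
      fold_change_means = if (ok && mean(y) != 0) mean(x) / mean(y) else NA_real_,
      pvalue = p
    )
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, "BH")
  out
}
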