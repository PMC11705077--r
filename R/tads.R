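#' Window contact signal per bin (TopDom-style binSignal)
#'
#' For each bin \code{i}, the mean contact frequency of all pairs in the
#' \code{w x w} rectangle straddling the bin edge: rows \code{i-w+1..i}
#' (upstream) versus columns \code{i+1..i+w} (downstream). The curve dips at
#' insulating boundaries. Bins within \code{w} of a chromosome end are NA.
#'
#' @param cm Normalized contact matrix at TAD resolution.
#' @param w Window half-width in bins (>= 2, < n_bins/2).
#' @return A \code{bin_signal_track}: list with \code{signal} (length
#'   \code{n_bins}), \code{w} and \code{n_bins}.
#' @export
bin_signal <- function(cm, w = 5L) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  w <- as.integer(w)
  if (w < 2L) stop("'w' must be >= 2", call. = FALSE)
  if (w >= n / 2) stop("'w' must be smaller than n_bins/2", call. = FALSE)
  m <- cm$counts
  if (any(cm$mask)) {
    m[cm$mask, ] <- NA_real_
    m[, cm$mask] <- NA_real_
  }
  sig <- rep(NA_real_, n)
  for (i in w:(n - w)) {
    block <- m[(i - w + 1L):i, (i + 1L):(i + w), drop = FALSE]
    if (!all(is.na(block))) sig[i] <- mean(block, na.rm = TRUE)
  }
  structure(list(signal = sig, w = w, n_bins = n), class = "bin_signal_track")
}

# Candidate boundary dips: indices that attain the minimum of the signal in a
# +/- w neighborhood; ties broken by the leftmost index.
local_minima <- function(sig, w) {
  n <- length(sig)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(sig[i])) next
    win <- max(1L, i - w):min(n, i + w)
    vals <- sig[win]
    if (all(is.na(vals))) next
    mn <- min(vals, na.rm = TRUE)
    if (sig[i] == mn && i == win[which(vals == mn)[1L]]) out <- c(out, i)
  }
  out
}

#' Detect TAD boundaries and assemble TADs
#'
#' Candidate boundaries are local minima of the window signal within a
#' \code{+/-w} neighborhood. Each candidate is tested by a one-sided Wilcoxon
#' rank-sum comparing within-domain contacts (the two flanking \code{w x w}
#' triangles) against the cross-boundary rectangle; candidates whose
#' BH-adjusted q exceeds \code{alpha} are removed as lacking local interaction
#' aggregation. The test runs on the observed/expected transform of the
#' matrix (computed internally unless \code{cm} already is O/E): without
#' removing the distance-decay trend the flanking triangles sit at shorter
#' distances than the cross rectangle and the comparison would be biased
#' everywhere. Surviving boundaries tile the chromosome into TADs; TADs
#' shorter than \code{min_size} are merged into the neighbor across their
#' weaker (shallower-dip) boundary.
#'
#' A boundary bin index \code{b} (0-based) means the downstream TAD starts at
#' bin \code{b}.
#'
#' @param sig \code{\link{bin_signal}} track.
#' @param cm The contact matrix the signal was computed from.
#' @param alpha BH-adjusted q-value cutoff (default 0.05).
#' @param min_size Minimum TAD size in bins (default 3).
#' @return A \code{tad_set}: list with \code{boundaries} (data frame: bin,
#'   signal, pvalue, qvalue) and \code{tads} (data frame: start_bin, end_bin).
#'   With no surviving candidate, a single whole-chromosome TAD is returned
#'   with a warning.
#' @export
detect_boundaries <- function(sig, cm, alpha = 0.05, min_size = 3L) {
  stopifnot(inherits(sig, "bin_signal_track"), inherits(cm, "contact_matrix"))
  n <- sig$n_bins
  w <- sig$w
  m <- if (cm$state == "oe") cm$counts else observed_over_expected(cm)$counts
  cand <- local_minima(sig$signal, w)
  cand <- cand[cand - w + 1L >= 1L & cand + w <= n]
  pvals <- vapply(cand, function(i) {
    upidx <- (i - w + 1L):i
    dnidx <- (i + 1L):(i + w)
    a <- m[upidx, upidx]
    b <- m[dnidx, dnidx]
    within <- c(a[upper.tri(a)], b[upper.tri(b)])
    cross <- as.vector(m[upidx, dnidx])
    within <- within[!is.na(within)]
    cross <- cross[!is.na(cross)]
    if (length(within) < 2 || length(cross) < 2) return(1)
    suppressWarnings(
      stats::wilcox.test(within, cross, alternative = "greater",
                         exact = FALSE)$p.value
    )
  }, numeric(1))
  qvals <- stats::p.adjust(pvals, method = "BH")
  keep <- which(qvals <= alpha)
  if (length(keep) == 0L) {
    warning("no boundary passed filtering; returning a single TAD")
    return(structure(
      list(
        boundaries = data.frame(bin = integer(0), signal = numeric(0),
                                pvalue = numeric(0), qvalue = numeric(0)),
        tads = data.frame(start_bin = 0L, end_bin = n),
        n_bins = n, bin_size = cm$bin_size, chrom = cm$chrom, w = w
      ),
      class = "tad_set"
    ))
  }
  # localization refinement: the w-wide window blurs the dip, so re-localize
  # each surviving boundary to the edge minimizing a narrow (3-bin)
  # cross-edge mean within +/-2 bins of the coarse minimum
  wr <- 3L
  refine <- function(i) {
    js <- (i - 2L):(i + 2L)
    js <- js[js - wr + 1L >= 1L & js + wr <= n]
    if (length(js) == 0L) return(i)
    sc <- vapply(js, function(j) {
      mean(m[(j - wr + 1L):j, (j + 1L):(j + wr)], na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(sc))) i else js[which.min(sc)]
  }
  bins <- vapply(cand[keep], refine, integer(1))
  dup <- duplicated(bins)
  bdf <- data.frame(bin = bins[!dup], signal = sig$signal[cand[keep]][!dup],
                    pvalue = pvals[keep][!dup], qvalue = qvals[keep][!dup])
  bdf <- bdf[order(bdf$bin), ]

  # minimum-size merging: drop the weaker boundary (shallower dip, i.e.
  # larger signal) flanking any undersized TAD
  repeat {
    breaks <- bdf$bin
    starts <- c(0L, breaks)
    ends <- c(breaks, n)
    sizes <- ends - starts
    small <- which(sizes < min_size)
    if (length(small) == 0L || nrow(bdf) == 0L) break
    k <- small[1L]
    left_b <- if (k > 1L) k - 1L else NA_integer_         # boundary starting TAD k
    right_b <- if (k <= length(breaks)) k else NA_integer_ # boundary ending TAD k
    drop <- if (is.na(left_b)) right_b
            else if (is.na(right_b)) left_b
            else if (bdf$signal[left_b] >= bdf$signal[right_b]) left_b else right_b
    bdf <- bdf[-drop, , drop = FALSE]
  }
  breaks <- bdf$bin
  tads <- data.frame(start_bin = c(0L, breaks), end_bin = c(breaks, n))
  structure(
    list(boundaries = bdf, tads = tads, n_bins = n, bin_size = cm$bin_size,
         chrom = cm$chrom, w = w),
    class = "tad_set"
  )
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set: %s, %d TADs, %d boundaries (w=%d)\n",
              x$chrom, nrow(x$tads), nrow(x$boundaries), x$w))
  invisible(x)
}

#' Insulation score per boundary
#'
#' For each boundary, the local maximum of the window signal outside the dip
#' (within the two adjacent TADs, up to \code{w} bins from the boundary and
#' excluding the dip and its immediate shoulders) minus the local minimum
#' inside the dip window. A flat curve scores 0; a single dip of depth
#' \code{d} scores \code{d}. Larger IS therefore means a deeper dip and
#' stronger insulation under this package's sign convention; the complementary
#' \code{insulation_strength} column (rank of \code{-IS}) expresses the
#' opposite ordering used in some reports. Boundaries whose window reaches a
#' chromosome end get NA.
#'
#' @param sig \code{\link{bin_signal}} track.
#' @param tadset \code{\link{detect_boundaries}} result (or any tad_set with a
#'   \code{boundaries$bin} column and \code{tads}).
#' @return The \code{tad_set} with \code{IS} and \code{insulation_strength}
#'   columns added to \code{boundaries}.
#' @export
insulation_score <- function(sig, tadset) {
  stopifnot(inherits(sig, "bin_signal_track"), inherits(tadset, "tad_set"))
  w <- sig$w
  s <- sig$signal
  n <- sig$n_bins
  tads <- tadset$tads
  is_val <- vapply(tadset$boundaries$bin, function(b) {
    i0 <- b # 1-based signal index straddling the edge before 0-based bin b
    left <- tads[tads$end_bin == b, , drop = FALSE]
    right <- tads[tads$start_bin == b, , drop = FALSE]
    if (nrow(left) == 0L || nrow(right) == 0L) return(NA_real_)
    lo <- max(1L, i0 - w, left$start_bin + 1L)
    hi <- min(n, i0 + w, right$end_bin)
    if (i0 - w < 1L || i0 + w > n) return(NA_real_)
    inside <- s[lo:hi]
    out_idx <- setdiff(lo:hi, (i0 - 1L):(i0 + 1L))
    if (length(out_idx) == 0L || all(is.na(inside))) return(NA_real_)
    outside <- s[out_idx]
    max(outside, na.rm = TRUE) - min(inside, na.rm = TRUE)
  }, numeric(1))
  tadset$boundaries$IS <- is_val
  tadset$boundaries$insulation_strength <- rank(-is_val, na.last = "keep")
  tadset
}

#' Domain score of a TAD
#'
#' Fraction of all contacts involving the TAD that are intra-TAD: the sum of
#' unique within-TAD entries (diagonal counted once, symmetric pairs counted
#' once) over that sum plus all contacts between TAD bins and the rest of the
#' chromosome. Lies in [0, 1]; NA when the TAD has no contacts at all.
#'
#' @param cm Contact matrix at TAD resolution.
#' @param start_bin,end_bin Half-open 0-based bin interval of the TAD.
#' @return Scalar domain score.
#' @export
domain_score <- function(cm, start_bin, end_bin) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  if (start_bin < 0 || end_bin > n || start_bin >= end_bin) {
    stop("invalid TAD interval", call. = FALSE)
  }
  idx <- (start_bin + 1L):end_bin
  sub <- cm$counts[idx, idx, drop = FALSE]
  intra <- sum(sub[upper.tri(sub, diag = TRUE)], na.rm = TRUE)
  outer_idx <- setdiff(seq_len(n), idx)
  inter <- if (length(outer_idx)) sum(cm$counts[idx, outer_idx], na.rm = TRUE) else 0
  tot <- intra + inter
  if (tot == 0) return(NA_real_)
  intra / tot
}

#' Domain scores for every TAD in a set
#' @param cm Contact matrix.
#' @param tadset A \code{tad_set}.
#' @return The \code{tad_set} with a \code{domain_score} column on \code{tads}.
#' @export
domain_scores <- function(cm, tadset) {
  tadset$tads$domain_score <- mapply(
    function(a, b) domain_score(cm, a, b),
    tadset$tads$start_bin, tadset$tads$end_bin
  )
  tadset
}

#' Classify TADs and boundaries between two conditions
#'
#' A TAD of condition A is \emph{invariant} when some B TAD matches both of
#' its boundaries within \code{max_shift_bp} and overlaps it reciprocally by
#' more than \code{min_overlap}; otherwise it is \emph{merged} when it is
#' contained (> \code{min_overlap} of its length) in a B TAD that also
#' contains more than \code{min_overlap} of another A TAD, \emph{split} when
#' at least two B TADs are each > \code{min_overlap} contained in it,
#' \emph{disappeared} when its best overlap fraction with any B TAD is at most
#' \code{1 - min_overlap}, and \emph{rearranged} otherwise. A boundaries are
#' \emph{conserved} when within \code{max_shift_bp} of a B boundary, else
#' \emph{disappeared}.
#'
#' @param setA,setB \code{tad_set} objects at the same bin size.
#' @param max_shift_bp Boundary-distance tolerance in bp (default 10 kb).
#' @param min_overlap Reciprocal/containment overlap fraction (default 0.8).
#' @return A \code{tad_comparison}: list with \code{tads} (per-A-TAD class),
#'   \code{boundaries} (per-A-boundary label), and class count/percentage
#'   tables.
#' @export
compare_tad_sets <- function(setA, setB, max_shift_bp = 10000, min_overlap = 0.8) {
  stopifnot(inherits(setA, "tad_set"), inherits(setB, "tad_set"))
  if (setA$bin_size != setB$bin_size) stop("bin sizes differ", call. = FALSE)
  bs <- setA$bin_size
  tol_bins <- max_shift_bp / bs
  A <- setA$tads
  B <- setB$tads
  empty_b <- nrow(B) == 0L
  if (empty_b) warning("condition B has no TADs; everything is 'disappeared'")

  classify_one <- function(a_start, a_end, A_other) {
    if (empty_b) return("disappeared")
    lenA <- a_end - a_start
    ov <- pmax(0, pmin(a_end, B$end_bin) - pmax(a_start, B$start_bin))
    fracA <- ov / lenA
    fracB <- ov / (B$end_bin - B$start_bin)
    inv <- any(abs(B$start_bin - a_start) <= tol_bins &
                 abs(B$end_bin - a_end) <= tol_bins &
                 fracA > min_overlap & fracB > min_overlap)
    if (inv) return("invariant")
    # merged: contained in a B TAD that also swallows another A TAD
    for (t in which(fracA > min_overlap)) {
      ovo <- pmax(0, pmin(A_other$end_bin, B$end_bin[t]) -
                    pmax(A_other$start_bin, B$start_bin[t]))
      if (any(ovo / (A_other$end_bin - A_other$start_bin) > min_overlap)) {
        return("merged")
      }
    }
    if (sum(fracB > min_overlap) >= 2L) return("split")
    if (max(fracA) <= 1 - min_overlap) return("disappeared")
    "rearranged"
  }

  classes <- character(nrow(A))
  for (k in seq_len(nrow(A))) {
    classes[k] <- classify_one(A$start_bin[k], A$end_bin[k], A[-k, , drop = FALSE])
  }
  tab <- table(factor(classes, levels = c("invariant", "merged", "split",
                                          "disappeared", "rearranged")))

  bA <- setA$boundaries$bin
  bB <- setB$boundaries$bin
  blab <- if (length(bA) == 0L) {
    character(0)
  } else if (length(bB) == 0L) {
    rep("disappeared", length(bA))
  } else {
    ifelse(vapply(bA, function(b) min(abs(bB - b)), numeric(1)) <= tol_bins,
           "conserved", "disappeared")
  }
  structure(
    list(
      tads = data.frame(start_bin = A$start_bin, end_bin = A$end_bin,
                        class = classes),
      boundaries = data.frame(bin = bA, label = blab),
      class_counts = tab,
      class_percent = 100 * as.numeric(tab) / max(1L, nrow(A)),
      boundary_disappeared_percent =
        if (length(blab)) 100 * mean(blab == "disappeared") else NA_real_
    ),
    class = "tad_comparison"
  )
}

#' @export
print.tad_comparison <- function(x, ...) {
  cat("tad_comparison:\n")
  print(x$class_counts)
  cat(sprintf("boundaries disappeared: %.1f%%\n", x$boundary_disappeared_percent))
  invisible(x)
}

#' Build a tad_set from explicit boundary bins
#'
#' Convenience for annotation-only runs and simulations: tiles \code{n_bins}
#' into TADs split at the given internal boundaries.
#'
#' @param boundaries Strictly increasing 0-based internal boundary bins.
#' @param n_bins Chromosome length in bins.
#' @param bin_size,chrom Metadata.
#' @return A \code{tad_set} (no test statistics).
#' @export
tad_set_from_boundaries <- function(boundaries, n_bins, bin_size = 10000L,
                                    chrom = "chrS") {
  boundaries <- sort(unique(as.integer(boundaries)))
  if (length(boundaries) && (min(boundaries) <= 0L || max(boundaries) >= n_bins)) {
    stop("boundaries must be internal (0 < b < n_bins)", call. = FALSE)
  }
  structure(
    list(
      boundaries = data.frame(bin = boundaries,
                              signal = rep(NA_real_, length(boundaries)),
                              pvalue = rep(NA_real_, length(boundaries)),
                              qvalue = rep(NA_real_, length(boundaries))),
      tads = data.frame(start_bin = c(0L, boundaries),
                        end_bin = c(boundaries, as.integer(n_bins))),
      n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
      chrom = chrom, w = NA_integer_
    ),
    class = "tad_set"
  )
}

#' F1 score of boundary recovery against planted truth
#'
#' Matches each called boundary to an unused true boundary within
#' \code{tol_bins}; precision/recall/F1 follow from the match counts.
#'
#' @param called,truth Integer boundary bin vectors.
#' @param tol_bins Matching tolerance (default 1).
#' @return List with precision, recall, f1, n_called, n_true.
#' @export
boundary_f1 <- function(called, truth, tol_bins = 1L) {
  called <- sort(called)
  truth <- sort(truth)
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (b in called) {
    j <- which(!used & abs(truth - b) <= tol_bins)
    if (length(j)) {
      used[j[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  prec <- if (length(called)) tp / length(called) else NA_real_
  rec <- if (length(truth)) tp / length(truth) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else 0
  list(precision = prec, recall = rec, f1 = f1,
       n_called = length(called), n_true = length(truth))
}
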