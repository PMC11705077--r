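#' Construct a per-chromosome binned contact matrix
#'
#' @param counts Dense symmetric non-negative numeric matrix.
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param state One of \code{"raw"}, \code{"balanced"}, \code{"oe"}.
#' @param bias Per-bin bias vector (balanced state only).
#' @param mask Logical per-bin low-coverage mask (TRUE = masked).
#' @return A \code{contact_matrix} object.
#' @export
contact_matrix <- function(counts, chrom = "chrS", bin_size = 10000L,
                           state = "raw", bias = NULL, mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("counts must be symmetric", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  state <- match.arg(state, c("raw", "balanced", "oe"))
  if (state == "balanced" && is.null(bias)) {
    stop("balanced matrices must carry a bias vector", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(FALSE, nrow(counts))
  structure(
    list(counts = counts, chrom = chrom, bin_size = as.integer(bin_size),
         state = state, bias = bias, mask = mask,
         n_bins = nrow(counts)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %d bp, state=%s, %d masked\n",
              x$chrom, x$n_bins, x$bin_size, x$state, sum(x$mask)))
  invisible(x)
}

#' Low-coverage bin mask
#'
#' Masks bins whose marginal (row sum) is zero or below a quantile of the
#' nonzero marginals. Low-coverage bins destabilize balancing and compartment
#' correlation, so they are dropped from all downstream statistics.
#'
#' @param cm A contact matrix.
#' @param q Quantile of nonzero marginals below which bins are masked
#'   (default 0.02, i.e. the 2nd percentile).
#' @return Logical vector, TRUE for masked bins.
#' @export
coverage_mask <- function(cm, q = 0.02) {
  marg <- rowSums(cm$counts)
  nz <- marg[marg > 0]
  if (length(nz) == 0) return(rep(TRUE, cm$n_bins))
  thr <- stats::quantile(nz, q, names = FALSE)
  marg == 0 | marg < thr
}

#' ICE matrix balancing
#'
#' Iterative correction: each sweep divides the matrix by the outer product of
#' its (normalized) marginals, driving all unmasked row sums to a common
#' value. Converged when the coefficient of variation of the unmasked row sums
#' drops to \code{tol}. Masked rows/columns are zeroed and excluded.
#'
#' @param cm Raw \code{\link{contact_matrix}}.
#' @param tol Convergence tolerance on the row-sum CV (default 1e-5).
#' @param max_iter Maximum sweeps (default 200).
#' @param mask_quantile Passed to \code{\link{coverage_mask}} when the matrix
#'   carries no mask yet.
#' @return A balanced \code{contact_matrix} carrying the bias vector (NA at
#'   masked bins), the mask and a \code{converged} attribute. Non-convergence
#'   sets \code{converged = FALSE}; it is flagged, not raised.
#' @export
ice_balance <- function(cm, tol = 1e-5, max_iter = 200L, mask_quantile = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$state != "raw") stop("ice_balance expects a raw matrix", call. = FALSE)
  mask <- if (any(cm$mask)) cm$mask else coverage_mask(cm, mask_quantile)
  if (all(mask)) stop("all bins are masked; cannot balance", call. = FALSE)
  w <- cm$counts
  w[mask, ] <- 0
  w[, mask] <- 0
  bias <- rep(1, cm$n_bins)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    su <- s[!mask]
    cv <- stats::sd(su) / mean(su)
    if (is.na(cv)) cv <- 0
    if (cv <= tol) {
      converged <- TRUE
      break
    }
    # symmetric Sinkhorn step: dividing by sqrt of the normalized marginals
    # avoids the overshoot of a full-marginal division
    d <- sqrt(s / mean(su))
    d[mask | d == 0] <- 1
    w <- w / outer(d, d)
    bias <- bias * d
  }
  bias[mask] <- NA_real_
  out <- contact_matrix(w, chrom = cm$chrom, bin_size = cm$bin_size,
                        state = "balanced", bias = bias, mask = mask)
  attr(out, "converged") <- converged
  out
}

#' Mean contact value per genomic distance
#'
#' The expected profile used for observed/expected normalization: the value at
#' distance \code{s} bins is the mean over all unmasked \code{(i, i+s)}
#' entries.
#'
#' @param cm A contact matrix (raw or balanced).
#' @return An \code{expected_profile}: list with \code{values} (length
#'   \code{n_bins}, distance 0 first; NA where no unmasked pair exists) and
#'   \code{n_bins}.
#' @export
expected_by_distance <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  keep <- !cm$mask
  vals <- rep(NA_real_, n)
  m <- cm$counts
  for (s in 0:(n - 1L)) {
    i <- seq_len(n - s)
    ok <- keep[i] & keep[i + s]
    if (any(ok)) vals[s + 1L] <- mean(m[cbind(i[ok], i[ok] + s)])
  }
  structure(list(values = vals, n_bins = n), class = "expected_profile")
}

#' Observed/expected transform
#'
#' Divides every entry by the mean contact value at its distance, removing the
#' distance-decay trend; per-diagonal means of the result are exactly 1 on
#' unmasked entries.
#'
#' @param cm A contact matrix.
#' @param e Matching \code{\link{expected_by_distance}} profile (recomputed
#'   when omitted).
#' @return An O/E \code{contact_matrix} (state \code{"oe"}); NA at masked bins
#'   and where the expected value is 0.
#' @export
observed_over_expected <- function(cm, e = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(e)) e <- expected_by_distance(cm)
  if (e$n_bins != cm$n_bins) stop("expected profile shape mismatch", call. = FALSE)
  n <- cm$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ev <- e$values[d + 1L]
  ev[ev == 0] <- NA_real_
  oe <- cm$counts / ev
  oe[cm$mask, ] <- NA_real_
  oe[, cm$mask] <- NA_real_
  out <- contact_matrix(ifelse(is.na(oe), 0, oe), chrom = cm$chrom,
                        bin_size = cm$bin_size, state = "oe", mask = cm$mask)
  # keep NA pattern (constructor demands numeric symmetric; restore NAs after)
  out$counts[is.na(oe)] <- NA_real_
  out
}

#' Call A/B compartments from the correlation map
#'
#' Computes the Pearson correlation matrix of the O/E columns (masked bins
#' dropped), extracts its first principal component by eigendecomposition and
#' orients it so that PC1 correlates positively with gene density; bins with
#' positive PC1 are labelled A (gene-rich/active), negative B.
#'
#' @param oe O/E contact matrix (conventionally at 100-kb bins).
#' @param gene_density Per-bin gene density used as orientation reference.
#' @return A \code{compartment_track}: list with per-bin \code{pc1} (NA at
#'   masked bins), \code{label} ("A"/"B"/NA) and the orientation flip applied.
#' @export
call_compartments <- function(oe, gene_density) {
  stopifnot(inherits(oe, "contact_matrix"))
  if (length(gene_density) != oe$n_bins) {
    stop("gene_density length must equal n_bins", call. = FALSE)
  }
  keep <- !oe$mask
  if (sum(keep) < 10) stop("fewer than 10 unmasked bins", call. = FALSE)
  sub <- oe$counts[keep, keep, drop = FALSE]
  cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  pc1 <- eg$vectors[, 1L]
  flip <- FALSE
  ori <- suppressWarnings(stats::cor(pc1, gene_density[keep]))
  if (!is.na(ori) && ori < 0) {
    pc1 <- -pc1
    flip <- TRUE
  }
  full <- rep(NA_real_, oe$n_bins)
  full[keep] <- pc1
  label <- ifelse(is.na(full), NA_character_, ifelse(full > 0, "A", "B"))
  structure(
    list(pc1 = full, label = label, flipped = flip,
         orientation_reference = gene_density),
    class = "compartment_track"
  )
}

#' Coarsen a contact matrix by summing square blocks of bins
#'
#' Used to derive a compartment-resolution matrix (e.g. 100-kb) from the
#' TAD-resolution matrix (10-kb) by aggregating \code{factor} adjacent bins.
#' A trailing partial block is kept.
#'
#' @param cm Raw contact matrix.
#' @param factor Number of fine bins per coarse bin.
#' @return A raw \code{contact_matrix} at \code{bin_size * factor}.
#' @export
coarsen_matrix <- function(cm, factor = 10L) {
  stopifnot(inherits(cm, "contact_matrix"), factor >= 1)
  n <- cm$n_bins
  grp <- (seq_len(n) - 1L) %/% as.integer(factor)
  agg <- rowsum(cm$counts, grp)
  agg <- t(rowsum(t(agg), grp))
  contact_matrix(agg, chrom = cm$chrom, bin_size = cm$bin_size * as.integer(factor))
}

#' Aggregate a per-bin vector over coarse bins
#' @param x Per-bin numeric vector.
#' @param factor Fine bins per coarse bin.
#' @param fun Aggregation function (default sum).
#' @return Coarse per-bin vector.
#' @export
coarsen_track <- function(x, factor = 10L, fun = sum) {
  grp <- (seq_along(x) - 1L) %/% as.integer(factor)
  as.numeric(tapply(x, grp, fun))
}
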