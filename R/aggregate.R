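# Bilinear resize of a square matrix to n_out x n_out. Output pixel p maps to
# source coordinate 1 + (p-1)(n-1)/(n_out-1); when sizes match this is an
# exact copy. NA source corners propagate to NA output pixels.
bilinear_resize <- function(mat, n_out) {
  n <- nrow(mat)
  if (n == n_out) return(mat)
  if (n == 1L) return(matrix(mat[1, 1], n_out, n_out))
  x <- 1 + (seq_len(n_out) - 1) * (n - 1) / (n_out - 1)
  x0 <- pmin(floor(x), n - 1L)
  fx <- x - x0
  out <- matrix(NA_real_, n_out, n_out)
  for (i in seq_len(n_out)) {
    r0 <- x0[i]
    fr <- fx[i]
    a <- mat[r0, ] * (1 - fr) + mat[r0 + 1L, ] * fr
    out[i, ] <- a[x0] * (1 - fx) + a[x0 + 1L] * fx
  }
  out
}

#' Aggregate domain analysis (ADA)
#'
#' For each TAD, the O/E submatrix spanning the TAD extended by
#' \code{flank_frac} of its length on both sides is bilinearly rescaled to an
#' \code{n_pixels} square and the grids are averaged pixel-wise with NA-aware
#' means. TADs whose extended window runs off the chromosome are skipped.
#'
#' @param oe O/E contact matrix.
#' @param tads Data frame with \code{start_bin,end_bin} (0-based half-open).
#' @param flank_frac Flank as a fraction of TAD length (default 0.5).
#' @param n_pixels Output grid size (default 99).
#' @return A \code{pileup_grid}: list with \code{grid}, \code{n_anchors},
#'   \code{flank} specification.
#' @export
aggregate_domains <- function(oe, tads, flank_frac = 0.5, n_pixels = 99L) {
  stopifnot(inherits(oe, "contact_matrix"))
  n <- oe$n_bins
  acc <- matrix(0, n_pixels, n_pixels)
  cnt <- matrix(0, n_pixels, n_pixels)
  used <- 0L
  for (k in seq_len(nrow(tads))) {
    a <- tads$start_bin[k]
    b <- tads$end_bin[k]
    f <- round(flank_frac * (b - a))
    lo <- a - f + 1L
    hi <- b + f
    if (lo < 1L || hi > n) next
    sub <- oe$counts[lo:hi, lo:hi, drop = FALSE]
    g <- bilinear_resize(sub, n_pixels)
    ok <- !is.na(g)
    acc[ok] <- acc[ok] + g[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0L) stop("no usable TAD (all extended windows truncated)", call. = FALSE)
  grid <- acc / cnt
  grid[cnt == 0] <- NA_real_
  structure(
    list(grid = grid, n_anchors = used,
         flank = list(type = "fraction", value = flank_frac)),
    class = "pileup_grid"
  )
}

#' Fixed-window boundary pile-up with quadrant statistics
#'
#' Averages (2F+1)-bin square O/E windows centered on boundary bins (F =
#' \code{flank_bp / bin_size}), without rescaling; truncated windows are
#' dropped. Quadrant statistics are the NA-aware means of the two on-diagonal
#' blocks (upstream-intra, downstream-intra) and the off-diagonal block
#' (inter), excluding the one-bin center cross by construction.
#'
#' @param oe O/E contact matrix.
#' @param boundaries 0-based boundary bin indices.
#' @param flank_bp Window flank in bp; must be a multiple of the bin size.
#' @return A \code{pileup_grid} with an added \code{quadrants} element: means
#'   of the upstream-intra, downstream-intra and inter blocks plus the
#'   inter/intra ratio.
#' @export
boundary_pileup <- function(oe, boundaries, flank_bp = 500000) {
  stopifnot(inherits(oe, "contact_matrix"))
  bs <- oe$bin_size
  if (flank_bp %% bs != 0) stop("flank_bp must be a multiple of bin_size", call. = FALSE)
  F <- as.integer(flank_bp / bs)
  n <- oe$n_bins
  size <- 2L * F + 1L
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  used <- 0L
  for (b in boundaries) {
    c1 <- b + 1L # 1-based center
    lo <- c1 - F
    hi <- c1 + F
    if (lo < 1L || hi > n) next
    g <- oe$counts[lo:hi, lo:hi, drop = FALSE]
    ok <- !is.na(g)
    acc[ok] <- acc[ok] + g[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0L) stop("all boundary windows are truncated", call. = FALSE)
  grid <- acc / cnt
  grid[cnt == 0] <- NA_real_
  up <- grid[1:F, 1:F]
  dn <- grid[(F + 2L):size, (F + 2L):size]
  inter <- grid[1:F, (F + 2L):size]
  q <- list(
    upstream_intra = mean(up, na.rm = TRUE),
    downstream_intra = mean(dn, na.rm = TRUE),
    inter = mean(inter, na.rm = TRUE)
  )
  q$intra <- mean(c(up, dn), na.rm = TRUE)
  q$inter_intra_ratio <- q$inter / q$intra
  structure(
    list(grid = grid, n_anchors = used,
         flank = list(type = "bp", value = flank_bp), quadrants = q),
    class = "pileup_grid"
  )
}

#' @export
print.pileup_grid <- function(x, ...) {
  cat(sprintf("pileup_grid: %dx%d, %d anchors\n",
              nrow(x$grid), ncol(x$grid), x$n_anchors))
  if (!is.null(x$quadrants)) {
    cat(sprintf("  intra=%.3f inter=%.3f ratio=%.3f\n",
                x$quadrants$intra, x$quadrants$inter,
                x$quadrants$inter_intra_ratio))
  }
  invisible(x)
}
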