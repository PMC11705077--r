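# Plain-text readers/writers for the exchange formats used across the
# pipeline: triplet contact matrices, bin tables, BED peaks, bedGraph tracks
# and planted-truth TSVs. Paths ending in .gz are transparently gzipped.

open_out <- function(path) if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")

write_tsv <- function(df, path, col.names = TRUE) {
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
}

read_tsv <- function(path, header = TRUE, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = header, stringsAsFactors = FALSE,
                    colClasses = colClasses, comment.char = "")
}

#' Write a contact matrix as upper-triangle triplet text
#'
#' Format: \code{bin_i TAB bin_j TAB count}, 0-based bins, \code{bin_i <=
#' bin_j}, zero entries omitted.
#'
#' @param cm A \code{\link{contact_matrix}}.
#' @param path Output file (.gz supported).
#' @export
write_triplet_matrix <- function(cm, path) {
  m <- cm$counts
  up <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  cnt <- m[up]
  # %.17g round-trips doubles exactly, so reloading a balanced matrix
  # reproduces it bit for bit
  df <- data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
                   count = if (all(cnt == round(cnt))) cnt else
                     sprintf("%.17g", cnt))
  df <- df[order(df$bin_i, df$bin_j), ]
  write_tsv(df, path, col.names = FALSE)
  invisible(path)
}

#' Read a triplet contact matrix
#'
#' @param path Triplet file as written by \code{\link{write_triplet_matrix}}.
#' @param n_bins Number of bins (e.g. from the bin table).
#' @param chrom,bin_size Metadata attached to the returned matrix.
#' @return A raw \code{\link{contact_matrix}}.
#' @export
read_triplet_matrix <- function(path, n_bins, chrom = "chrS", bin_size = 10000L) {
  df <- read_tsv(path, header = FALSE)
  names(df) <- c("bin_i", "bin_j", "count")
  if (any(df$bin_i < 0 | df$bin_j >= n_bins)) {
    stop("triplet file contains bins outside [0, n_bins)", call. = FALSE)
  }
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$count
  m[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$count
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Write the bin table as BED
#' @param n_bins,bin_size,chrom Chromosome binning.
#' @param path Output BED path.
#' @export
write_bins_bed <- function(n_bins, bin_size, chrom, path) {
  i <- seq_len(n_bins) - 1L
  write_tsv(data.frame(chrom = chrom, start = i * bin_size,
                       end = (i + 1L) * bin_size, bin_id = i),
            path, col.names = FALSE)
  invisible(path)
}

#' Read a bin table BED
#' @param path BED path (chrom, start, end, bin_id).
#' @return Data frame with n_bins/bin_size attributes recoverable.
#' @export
read_bins_bed <- function(path) {
  df <- read_tsv(path, header = FALSE)
  names(df) <- c("chrom", "start", "end", "bin_id")[seq_len(ncol(df))]
  df
}

#' Write peaks as BED6 plus a summit-offset column
#' @param peaks Peak data frame with \code{chrom,start,end,name,score,strand,summit}.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- peaks
  df$summit_offset <- df$summit - df$start
  write_tsv(df[, c("chrom", "start", "end", "name", "score", "strand",
                   "summit_offset")], path, col.names = FALSE)
  invisible(path)
}

#' Read a peaks BED (6+ columns, optional summit offset in column 7)
#' @param path BED path.
#' @return Peak data frame with an absolute \code{summit} column (midpoint when
#'   no offset column is present).
#' @export
read_peaks_bed <- function(path) {
  df <- read_tsv(path, header = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(6L, ncol(df)))] <- base[seq_len(min(6L, ncol(df)))]
  if (ncol(df) >= 7L) {
    df$summit <- df$start + df[[7L]]
  } else {
    df$summit <- as.integer((df$start + df$end) %/% 2L)
  }
  df[, c(base[seq_len(min(6L, ncol(df)))], "summit")]
}

#' Write a per-bin track as bedGraph
#' @param track Numeric per-bin values.
#' @param bin_size,chrom Binning metadata.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, bin_size, chrom, path) {
  i <- seq_along(track) - 1L
  val <- if (all(is.na(track) | track == round(track))) track else
    sprintf("%.17g", track)
  write_tsv(data.frame(chrom = chrom, start = i * bin_size,
                       end = (i + 1L) * bin_size, value = val),
            path, col.names = FALSE)
  invisible(path)
}

#' Read a per-bin bedGraph back into a numeric vector
#' @param path bedGraph path with one row per bin, in order.
#' @return Numeric vector of values.
#' @export
read_bedgraph <- function(path) {
  df <- read_tsv(path, header = FALSE)
  df[[4L]][order(df[[2L]])]
}

#' Write planted-truth tables for an architecture
#'
#' Emits \code{truth_tads.tsv} (TAD intervals plus the insulation depth of the
#' boundary that starts each TAD after the first) and \code{truth_bins.tsv}
#' (per-bin compartment label and gene density). The pair reloads to an
#' identical architecture via \code{\link{read_architecture}}.
#'
#' @param arch Planted architecture.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_architecture <- function(arch, dir) {
  p1 <- file.path(dir, "truth_tads.tsv")
  p2 <- file.path(dir, "truth_bins.tsv")
  tads <- data.frame(
    chrom = arch$chrom,
    start_bin = arch$tads[, "start"], end_bin = arch$tads[, "end"],
    upstream_boundary_depth = c(NA, arch$boundary_depths)
  )
  write_tsv(tads, p1)
  bins <- data.frame(
    bin = seq_len(arch$n_bins) - 1L,
    compartment = ifelse(is.na(arch$compartment_label), ".", arch$compartment_label),
    gene_density = arch$gene_density,
    bin_size = arch$bin_size
  )
  write_tsv(bins, p2)
  invisible(c(truth_tads = p1, truth_bins = p2))
}

#' Reload a planted architecture from its truth tables
#' @param dir Directory containing \code{truth_tads.tsv} and \code{truth_bins.tsv}.
#' @return A \code{planted_architecture} equal to the one written.
#' @export
read_architecture <- function(dir) {
  tads <- read_tsv(file.path(dir, "truth_tads.tsv"))
  bins <- read_tsv(file.path(dir, "truth_bins.tsv"), colClasses = c(compartment = "character"))
  lab <- bins$compartment
  lab[lab == "."] <- NA_character_
  structure(
    list(
      n_bins = nrow(bins),
      bin_size = as.integer(bins$bin_size[1]),
      chrom = as.character(tads$chrom[1]),
      boundaries = as.integer(tads$start_bin[-1L]),
      tads = cbind(start = as.integer(tads$start_bin), end = as.integer(tads$end_bin)),
      boundary_depths = as.numeric(tads$upstream_boundary_depth[-1L]),
      compartment_label = lab,
      gene_density = as.numeric(bins$gene_density)
    ),
    class = "planted_architecture"
  )
}

#' Write TADs as BED with score columns
#' @param tads Data frame with \code{start_bin,end_bin} and optional score columns.
#' @param bin_size,chrom Binning metadata.
#' @param path Output path.
#' @export
write_tads_bed <- function(tads, bin_size, chrom, path) {
  df <- data.frame(chrom = chrom, start = tads$start_bin * bin_size,
                   end = tads$end_bin * bin_size)
  extra <- setdiff(names(tads), c("start_bin", "end_bin"))
  for (nm in extra) df[[nm]] <- tads[[nm]]
  write_tsv(df, path)
  invisible(path)
}

#' Write boundaries as BED with IS / p / q columns
#' @param boundaries Data frame with a \code{bin} column and score columns.
#' @param bin_size,chrom Binning metadata.
#' @param path Output path.
#' @export
write_boundaries_bed <- function(boundaries, bin_size, chrom, path) {
  df <- data.frame(chrom = chrom, start = boundaries$bin * bin_size,
                   end = (boundaries$bin + 1L) * bin_size)
  extra <- setdiff(names(boundaries), "bin")
  for (nm in extra) df[[nm]] <- boundaries[[nm]]
  write_tsv(df, path)
  invisible(path)
}
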