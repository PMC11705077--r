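#' Default pipeline configuration
#'
#' Returns the full nested parameter list driving \code{\link{run_pipeline}}:
#' simulation settings (chromosome size, depth, planted TADs, factors, a
#' transcription-like track), and per-stage parameters (window width, test
#' alpha, metagene flanks, NMF rank range/restarts, pile-up flanks). The
#' defaults describe a 1000-bin chromosome at 10-kb bins with 2 million read
#' pairs, boundary insulation depth 0.3, a 50-bin compartment checkerboard and
#' five factors with planted co-occupancy groups.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A named list (class \code{tadbound_config}).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_bins = 1000L, bin_size = 10000L, decay_exponent = 1, depth = 2e6,
      tad_min = 30L, tad_max = 60L, insulation_depth = 0.3,
      compartment_block_bins = 50L,
      factors = list(
        list(name = "CTCF", n_peaks = 60L, boundary_fraction = 0.3, group_id = 0L),
        list(name = "RBP_A", n_peaks = 60L, boundary_fraction = 0.2, group_id = 1L),
        list(name = "RBP_B", n_peaks = 60L, boundary_fraction = 0.2, group_id = 1L),
        list(name = "RBP_C", n_peaks = 60L, boundary_fraction = 0.2, group_id = 2L),
        list(name = "RBP_D", n_peaks = 60L, boundary_fraction = 0.2, group_id = 2L),
        list(name = "RBP_E", n_peaks = 60L, boundary_fraction = 0, group_id = 0L)
      ),
      peak_dropout = 0.2,
      gro = list(amplitude = 10, background = 1)
    ),
    tads = list(w = 5L, alpha = 0.05, min_size = 3L),
    compartments = list(coarsen = 10L),
    peaks = list(flank = 0, metagene_flank_bins = 25L, ba_threshold = 1.2,
                 anchor_factor = "CTCF"),
    nmf = list(rank_range = c(2L, 4L), n_restarts = 10L),
    pileup = list(flank_bp = 200000, ada_flank_frac = 0.5, ada_pixels = 99L),
    resume = TRUE
  ), class = "tadbound_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For \code{read_run_config}, a \code{tadbound_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config(cfg$seed %||% 1L))
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
            !is.null(names(over[[nm]]))) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_cfg(base, cfg), class = "tadbound_config")
}

#' @rdname read_run_config
#' @param config A \code{tadbound_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_done <- function(files) all(file.exists(files))

log_stage <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Generate and write the default synthetic dataset
#'
#' Runs the simulator under the configuration: plants the architecture,
#' simulates the contact matrix, the factor peak sets and a boundary-targeted
#' transcription-like track, and writes everything (plus truth tables) to
#' \code{dir}.
#'
#' @param config A \code{tadbound_config}.
#' @param dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory objects (arch, cm, peaks,
#'   tracks) and the file paths.
#' @export
simulate_dataset <- function(config = default_config(), dir, quiet = FALSE) {
  sc <- config$simulate
  cfg <- sim_config(
    n_bins = sc$n_bins, bin_size = sc$bin_size,
    decay_exponent = sc$decay_exponent, depth = sc$depth,
    tad_size_range = c(sc$tad_min, sc$tad_max),
    insulation_depths = sc$insulation_depth,
    compartment_block_bins = sc$compartment_block_bins,
    seed = config$seed
  )
  arch <- plant_architecture(cfg)
  log_stage("simulate", sprintf("planted %d TADs / %d boundaries",
                                nrow(arch$tads), length(arch$boundaries)), quiet)
  cm <- simulate_contact_map(arch, cfg)
  specs <- lapply(sc$factors, function(f) {
    factor_spec(f$name, f$n_peaks, f$boundary_fraction, f$group_id,
                f$peak_width %||% 200L)
  })
  peaks <- simulate_peaks(arch, specs, seed = config$seed,
                          dropout = sc$peak_dropout %||% 0.2)
  bs <- arch$bin_size
  gro_targets <- cbind(arch$boundaries * bs, (arch$boundaries + 1L) * bs)
  gro <- simulate_signal_track(arch, gro_targets, sc$gro$amplitude,
                               sc$gro$background, seed = config$seed)
  paths <- write_synthetic_dataset(arch, cm, peaks, list(gro = gro), dir)
  invisible(list(arch = arch, cm = cm, peaks = peaks,
                 tracks = list(gro = gro), paths = paths))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> ICE balancing -> compartments ->
#' TAD/boundary calling with insulation and domain scores -> peak annotation,
#' boundary-associated-factor calling and CTCF-stratified boundary groups ->
#' NMF co-occupancy clustering -> aggregate pile-ups -> transcription-boundary
#' association. Every stage writes flat TSV outputs under \code{outdir} and is
#' skipped (reloaded from disk) when its outputs already exist and
#' \code{config$resume} is TRUE. A JSON manifest with per-file checksums is
#' written at the end.
#'
#' @param config A \code{tadbound_config}.
#' @param outdir Output directory (created).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the principal in-memory results.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ddir <- file.path(outdir, "dataset")
  bs <- config$simulate$bin_size
  n_bins <- config$simulate$n_bins
  chrom <- "chrS"

  # -- stage: simulate ------------------------------------------------------
  dataset_files <- file.path(ddir, c("matrix.triplet.tsv", "bins.bed",
                                     "truth_tads.tsv", "truth_bins.tsv"))
  if (isTRUE(config$resume) && stage_done(dataset_files)) {
    log_stage("simulate", "outputs present; loading", quiet)
    arch <- read_architecture(ddir)
    cm <- read_triplet_matrix(dataset_files[1], arch$n_bins, arch$chrom,
                              arch$bin_size)
    peaks <- lapply(stats::setNames(nm = vapply(config$simulate$factors,
                                                `[[`, character(1), "name")),
                    function(nm) read_peaks_bed(file.path(ddir, paste0("peaks_", nm, ".bed"))))
    gro <- read_bedgraph(file.path(ddir, "track_gro.bedgraph"))
  } else {
    sim <- simulate_dataset(config, ddir, quiet)
    arch <- sim$arch
    cm <- sim$cm
    peaks <- sim$peaks
    gro <- sim$tracks$gro
  }

  # -- stage: balance -------------------------------------------------------
  bal_files <- file.path(outdir, c("balanced.triplet.tsv", "bias.bedgraph"))
  if (isTRUE(config$resume) && stage_done(bal_files)) {
    log_stage("balance", "outputs present; loading", quiet)
    bal <- read_triplet_matrix(bal_files[1], arch$n_bins, arch$chrom, arch$bin_size)
    bias <- read_bedgraph(bal_files[2])
    bias[bias < 0] <- NA_real_
    bal <- contact_matrix(bal$counts, arch$chrom, arch$bin_size,
                          state = "balanced", bias = bias,
                          mask = is.na(bias))
  } else {
    log_stage("balance", "ICE balancing", quiet)
    bal <- ice_balance(cm)
    write_triplet_matrix(bal, bal_files[1])
    write_bedgraph(ifelse(is.na(bal$bias), -1, bal$bias), arch$bin_size,
                   arch$chrom, bal_files[2])
  }

  # -- stage: compartments --------------------------------------------------
  comp_file <- file.path(outdir, "compartments.tsv")
  coarse <- coarsen_matrix(cm, config$compartments$coarsen)
  coarse_bal <- ice_balance(coarse)
  coarse_oe <- observed_over_expected(coarse_bal)
  gd_coarse <- coarsen_track(arch$gene_density, config$compartments$coarsen)
  comp <- call_compartments(coarse_oe, gd_coarse)
  if (!(isTRUE(config$resume) && stage_done(comp_file))) {
    log_stage("compartments", "PC1 of correlation map", quiet)
    write_tsv(data.frame(bin = seq_along(comp$pc1) - 1L, pc1 = comp$pc1,
                         label = ifelse(is.na(comp$label), ".", comp$label)),
              comp_file)
  }

  # -- stage: TAD calling ---------------------------------------------------
  tad_files <- file.path(outdir, c("tads.tsv", "boundaries.tsv"))
  sig <- bin_signal(bal, config$tads$w)
  tset <- detect_boundaries(sig, bal, alpha = config$tads$alpha,
                            min_size = config$tads$min_size)
  tset <- insulation_score(sig, tset)
  tset <- domain_scores(bal, tset)
  if (!(isTRUE(config$resume) && stage_done(tad_files))) {
    log_stage("tads", sprintf("%d boundaries, %d TADs",
                              nrow(tset$boundaries), nrow(tset$tads)), quiet)
    write_tsv(tset$tads, tad_files[1])
    write_tsv(tset$boundaries, tad_files[2])
  }

  # -- stage: peak annotation ----------------------------------------------
  ann_files <- file.path(outdir, c("factor_stats.tsv", "boundary_annotation.tsv",
                                   "barbp.tsv", "factor_ranking.tsv",
                                   "boundary_groups.tsv"))
  log_stage("annotate", "peak/boundary overlap and metagene", quiet)
  stats_list <- lapply(peaks, assign_peaks, tadset = tset,
                       flank = config$peaks$flank)
  fb <- config$peaks$metagene_flank_bins
  profiles <- lapply(peaks, function(p) {
    cov <- peak_coverage_track(p, n_bins, bs)
    metagene_profile(cov, tset$boundaries$bin, fb)
  })
  ba <- classify_ba(profiles, config$peaks$ba_threshold)
  ranking <- rank_factors(profiles)
  anchor <- config$peaks$anchor_factor
  test_factors <- setdiff(names(peaks), anchor)
  adj_ds <- adjacent_domain_score(tset)
  grp_rows <- lapply(test_factors, function(f) {
    g <- boundary_groups(stats_list[[anchor]]$boundary_flag,
                         stats_list[[f]]$boundary_flag,
                         IS = tset$boundaries$IS,
                         domain_scores_adjacent = adj_ds,
                         anchor_name = anchor, test_name = f)
    data.frame(factor = f, group = names(g$sizes),
               n = as.integer(g$sizes), proportion = g$proportions)
  })
  if (!(isTRUE(config$resume) && stage_done(ann_files))) {
    fs <- do.call(rbind, lapply(names(stats_list), function(nm) {
      s <- stats_list[[nm]]
      data.frame(factor = nm, n_peaks = s$n_peaks,
                 frac_boundary = s$fractions[["boundary"]],
                 frac_intra = s$fractions[["intra"]],
                 frac_gap = s$fractions[["gap"]])
    }))
    write_tsv(fs, ann_files[1])
    bann <- data.frame(bin = tset$boundaries$bin)
    for (nm in names(stats_list)) bann[[nm]] <- stats_list[[nm]]$boundary_flag
    write_tsv(bann, ann_files[2])
    write_tsv(ba, ann_files[3])
    write_tsv(ranking, ann_files[4])
    write_tsv(do.call(rbind, grp_rows), ann_files[5])
  }

  # -- stage: NMF -----------------------------------------------------------
  nmf_files <- file.path(outdir, c("nmf_rank_stats.tsv", "nmf_groups.tsv",
                                   "occupancy_matrix.tsv"))
  log_stage("nmf", "CRE construction and consensus rank selection", quiet)
  cre <- build_cres(peaks)
  rr <- config$nmf$rank_range
  rs <- rank_selection(cre$V, seq(rr[1], rr[2]),
                       n_restarts = config$nmf$n_restarts, seed = config$seed)
  fit <- nmf_factorize(cre$V, rs$chosen_rank,
                       n_restarts = config$nmf$n_restarts, seed = config$seed)
  grp <- assign_groups(fit)
  if (!(isTRUE(config$resume) && stage_done(nmf_files))) {
    write_tsv(rs$stats, nmf_files[1])
    write_tsv(data.frame(factor = names(grp), group = as.integer(grp)),
              nmf_files[2])
    write_tsv(as.data.frame(cre$V), nmf_files[3])
  }

  # -- stage: pile-ups ------------------------------------------------------
  pile_files <- file.path(outdir, c("ada_grid.tsv", "boundary_pileup.tsv",
                                    "pileup_quadrants.tsv"))
  log_stage("pileup", "aggregate domain analysis and boundary pile-up", quiet)
  oe <- observed_over_expected(bal)
  ada <- aggregate_domains(oe, tset$tads, config$pileup$ada_flank_frac,
                           config$pileup$ada_pixels)
  pu <- boundary_pileup(oe, tset$boundaries$bin, config$pileup$flank_bp)
  if (!(isTRUE(config$resume) && stage_done(pile_files))) {
    write_tsv(as.data.frame(ada$grid), pile_files[1], col.names = FALSE)
    write_tsv(as.data.frame(pu$grid), pile_files[2], col.names = FALSE)
    write_tsv(data.frame(block = c("upstream_intra", "downstream_intra",
                                   "inter", "intra", "inter_intra_ratio"),
                         value = c(pu$quadrants$upstream_intra,
                                   pu$quadrants$downstream_intra,
                                   pu$quadrants$inter, pu$quadrants$intra,
                                   pu$quadrants$inter_intra_ratio)),
              pile_files[3])
  }

  # -- stage: transcription link -------------------------------------------
  tr_files <- file.path(outdir, c("boundary_transcription.tsv",
                                  "transcription_strata.tsv",
                                  "transcription_association.tsv"))
  log_stage("transcription", "boundary signal quantification", quiet)
  bint <- data.frame(start = tset$boundaries$bin * bs,
                     end = (tset$boundaries$bin + 1L) * bs,
                     id = paste0("b", tset$boundaries$bin))
  quants <- quantify_signal(bint, gro, bs)
  strata <- stratify_levels(quants$rpm)
  shuf <- shuffle_within(bint, data.frame(start = 0, end = n_bins * bs),
                         seed = config$seed)
  shuf_q <- quantify_signal(shuf, gro, bs)
  has_groups <- sum(table(strata$labels) >= 3) >= 2
  assoc <- if (has_groups && any(!is.na(tset$boundaries$IS))) {
    associate_groups(strata$labels, tset$boundaries$IS)
  } else NULL
  if (!(isTRUE(config$resume) && stage_done(tr_files))) {
    write_tsv(cbind(quants,
                    level = as.character(strata$labels),
                    shuffled_rpm_mean = mean(shuf_q$rpm)), tr_files[1])
    write_tsv(data.frame(level = levels(strata$labels),
                         n = as.integer(table(strata$labels))), tr_files[2])
    if (!is.null(assoc)) write_tsv(assoc, tr_files[3]) else
      write_tsv(data.frame(note = "insufficient strata"), tr_files[3])
  }

  # -- manifest -------------------------------------------------------------
  all_out <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  all_out <- setdiff(all_out, file.path(outdir, "manifest.json"))
  manifest <- list(
    tool = "tadbound",
    version = as.character(utils::packageVersion("tadbound")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(tools::md5sum(sort(all_out)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(arch = arch, balanced = bal, compartments = comp,
                 tads = tset, factor_stats = stats_list, profiles = profiles,
                 barbp = ba, ranking = ranking, nmf = list(rank = rs, fit = fit,
                                                           groups = grp),
                 ada = ada, pileup = pu,
                 transcription = list(quants = quants, strata = strata,
                                      shuffled = shuf_q, association = assoc)))
}

# Mean domain score of the two TADs flanking each boundary.
adjacent_domain_score <- function(tset) {
  ds <- tset$tads$domain_score
  if (is.null(ds)) return(rep(NA_real_, nrow(tset$boundaries)))
  vapply(tset$boundaries$bin, function(b) {
    l <- which(tset$tads$end_bin == b)
    r <- which(tset$tads$start_bin == b)
    mean(c(ds[l], ds[r]), na.rm = TRUE)
  }, numeric(1))
}

#' Per-bin peak coverage track
#'
#' Number of peaks overlapping each bin; used to turn peak sets into a
#' metagene-compatible density track.
#'
#' @param peaks Peak data frame.
#' @param n_bins,bin_size Chromosome binning.
#' @return Integer per-bin counts.
#' @export
peak_coverage_track <- function(peaks, n_bins, bin_size) {
  cov <- integer(n_bins)
  for (k in seq_len(nrow(peaks))) {
    b0 <- max(0L, floor(peaks$start[k] / bin_size))
    b1 <- min(n_bins, ceiling(peaks$end[k] / bin_size))
    if (b1 > b0) cov[(b0 + 1L):b1] <- cov[(b0 + 1L):b1] + 1L
  }
  cov
}

#' Compare two pipeline bundles (TAD dynamics report)
#'
#' Reads the TAD and boundary tables of two completed \code{\link{run_pipeline}}
#' bundles, classifies condition-A TADs as invariant / merged / split /
#' disappeared / rearranged against condition B, labels A boundaries conserved
#' or disappeared, and writes a TSV report into \code{dirA}.
#'
#' @param dirA,dirB Bundle directories.
#' @param bin_size Bin size in bp (must match between bundles).
#' @param max_shift_bp,min_overlap Matching tolerances
#'   (see \code{\link{compare_tad_sets}}).
#' @return The \code{tad_comparison}, invisibly writing
#'   \code{tad_comparison.tsv} and \code{boundary_conservation.tsv} in dirA.
#' @export
compare_bundles <- function(dirA, dirB, bin_size = 10000L,
                            max_shift_bp = 10000, min_overlap = 0.8) {
  load_set <- function(d) {
    tads <- read_tsv(file.path(d, "tads.tsv"))
    bnd <- read_tsv(file.path(d, "boundaries.tsv"))
    ts <- tad_set_from_boundaries(bnd$bin, max(tads$end_bin), bin_size)
    ts
  }
  A <- load_set(dirA)
  B <- load_set(dirB)
  if (A$bin_size != B$bin_size) stop("bundle bin sizes differ", call. = FALSE)
  cmp <- compare_tad_sets(A, B, max_shift_bp, min_overlap)
  write_tsv(cmp$tads, file.path(dirA, "tad_comparison.tsv"))
  write_tsv(cmp$boundaries, file.path(dirA, "boundary_conservation.tsv"))
  cmp
}
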