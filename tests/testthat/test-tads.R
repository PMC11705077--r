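test_that("bin_signal equals the brute-force window mean everywhere", {
  m <- random_symmetric_matrix(50, 11)
  cm <- contact_matrix(m)
  sig <- bin_signal(cm, 5)
  expect_equal(sig$signal, brute_bin_signal(m, 5))
  # constant matrix -> constant interior signal
  csig <- bin_signal(contact_matrix(matrix(4, 30, 30)), 3)
  expect_true(all(csig$signal[3:27] == 4))
  expect_true(all(is.na(csig$signal[c(1, 2, 28, 29, 30)])))
  # two disjoint blocks meet at a zero junction
  blk <- matrix(0, 20, 20)
  blk[1:10, 1:10] <- 5
  blk[11:20, 11:20] <- 5
  jsig <- bin_signal(contact_matrix(blk), 3)
  expect_identical(jsig$signal[10], 0)
  expect_error(bin_signal(cm, 30), "n_bins/2")
})

test_that("boundary detection recovers planted architecture", {
  cfg <- sim_config(n_bins = 600, tad_size_range = c(60, 120),
                    insulation_depths = 0.1, depth = 2e6, seed = 21)
  arch <- plant_architecture(cfg)
  cm <- simulate_contact_map(arch, cfg)
  bal <- ice_balance(cm)
  ts <- detect_boundaries(bin_signal(bal, 5), bal)
  f1 <- boundary_f1(ts$boundaries$bin, arch$boundaries, 1)
  expect_gte(f1$recall, 0.99)
  expect_gte(f1$precision, 0.8)
  # TADs tile the chromosome
  expect_identical(ts$tads$start_bin[-1], ts$tads$end_bin[-nrow(ts$tads)])
  expect_identical(ts$tads$start_bin[1], 0L)
  expect_identical(ts$tads$end_bin[nrow(ts$tads)], 600L)
})

test_that("a uniform matrix yields no boundaries", {
  u <- contact_matrix(matrix(10, 60, 60))
  expect_warning(ts <- detect_boundaries(bin_signal(u, 5), u), "single TAD")
  expect_identical(nrow(ts$boundaries), 0L)
  expect_identical(ts$tads$end_bin, 60L)
})

test_that("recovery F1 improves monotonically with sequencing depth", {
  f1s <- sapply(c(2e5, 8e5, 3.2e6), function(d) {
    cfg <- sim_config(n_bins = 500, tad_size_range = c(40, 80),
                      insulation_depths = 0.5, depth = d, seed = 31)
    arch <- plant_architecture(cfg)
    cm <- simulate_contact_map(arch, cfg)
    bal <- ice_balance(cm)
    ts <- detect_boundaries(bin_signal(bal, 5), bal)
    boundary_f1(ts$boundaries$bin, arch$boundaries, 1)$f1
  })
  expect_true(all(diff(f1s) >= 0))
})

test_that("insulation score reflects dip depth and handles edges", {
  ts <- tad_set_from_boundaries(c(20), 40)
  flat <- structure(list(signal = rep(3, 40), w = 5L, n_bins = 40L),
                    class = "bin_signal_track")
  expect_equal(insulation_score(flat, ts)$boundaries$IS, 0)
  dip <- flat
  dip$signal[20] <- 3 - 1.25
  expect_equal(insulation_score(dip, ts)$boundaries$IS, 1.25)
  # boundary whose window reaches the chromosome end gets NA
  edge <- tad_set_from_boundaries(c(3), 40)
  expect_true(is.na(insulation_score(flat, edge)$boundaries$IS))
})

test_that("insulation score recovers the planted depth ordering", {
  depths <- seq(0.1, 0.9, 0.1)
  med_is <- sapply(seq_along(depths), function(k) {
    cfg <- sim_config(n_bins = 500, tad_size_range = c(50, 100),
                      insulation_depths = depths[k], depth = 1e6,
                      seed = 40 + k)
    arch <- plant_architecture(cfg)
    bal <- ice_balance(simulate_contact_map(arch, cfg))
    sig <- bin_signal(bal, 5)
    ts <- insulation_score(sig, tad_set_from_boundaries(arch$boundaries, 500))
    median(ts$boundaries$IS, na.rm = TRUE)
  })
  expect_gte(abs(cor(1 - depths, med_is, method = "spearman")), 0.8)
})

test_that("domain score equals the brute-force contact ratio on all intervals", {
  m <- random_symmetric_matrix(30, 13)
  cm <- contact_matrix(m)
  set.seed(99)
  for (rep in 1:40) {
    a <- sample(0:27, 1)
    b <- sample((a + 2):30, 1)
    expect_equal(domain_score(cm, a, b), brute_domain_score(m, a, b))
  }
  # isolated block -> 1; empty interior -> 0
  iso <- matrix(0, 20, 20)
  iso[1:8, 1:8] <- 3
  iso[9:20, 9:20] <- 2
  expect_equal(domain_score(contact_matrix(iso), 0, 8), 1)
  hollow <- matrix(0, 10, 10)
  hollow[1:4, 5:10] <- 1
  hollow[5:10, 1:4] <- 1
  expect_equal(domain_score(contact_matrix(hollow), 0, 4), 0)
  expect_true(is.na(domain_score(contact_matrix(matrix(0, 10, 10)), 2, 6)))
})

test_that("TAD comparison matches the dual classifier on random perturbations", {
  set.seed(7)
  for (case in 1:200) {
    # random condition A tiling
    n <- 200
    breaks <- sort(sample(5:195, sample(3:8, 1)))
    breaks <- breaks[c(TRUE, diff(breaks) >= 5)]
    A <- tad_set_from_boundaries(breaks, n)
    # random perturbation: jitter / fusion / fission / deletion
    b2 <- breaks
    op <- sample(c("jitter", "fuse", "split", "delete", "mixed"), 1)
    if (op %in% c("jitter", "mixed")) {
      b2 <- b2 + sample(-2:2, length(b2), replace = TRUE)
    }
    if (op %in% c("fuse", "delete", "mixed") && length(b2) > 1) {
      b2 <- b2[-sample(seq_along(b2), 1)]
    }
    if (op %in% c("split", "mixed")) {
      b2 <- c(b2, sample(5:195, 1))
    }
    b2 <- sort(unique(pmin(pmax(b2, 1), n - 1)))
    b2 <- b2[c(TRUE, diff(b2) >= 2)]
    B <- tad_set_from_boundaries(b2, n)
    got <- compare_tad_sets(A, B)$tads$class
    want <- brute_classify_tads(A$tads, B$tads, tol_bins = 1)
    expect_identical(got, want)
  }
})

test_that("identity and forced merge cases classify as published rules demand", {
  A <- tad_set_from_boundaries(c(50, 120), 200)
  self <- compare_tad_sets(A, A)
  expect_true(all(self$tads$class == "invariant"))
  expect_true(all(self$boundaries$label == "conserved"))
  A2 <- tad_set_from_boundaries(50, 100)
  B2 <- tad_set_from_boundaries(integer(0), 100)
  cmp <- compare_tad_sets(A2, B2)
  expect_identical(cmp$tads$class, c("merged", "merged"))
  expect_identical(cmp$boundaries$label, "disappeared")
  expect_warning(compare_tad_sets(A2, structure(list(
    boundaries = data.frame(bin = integer(0)), tads = data.frame(
      start_bin = integer(0), end_bin = integer(0)),
    n_bins = 100L, bin_size = 10000L, chrom = "chrS", w = 5L),
    class = "tad_set")), "disappeared")
})
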