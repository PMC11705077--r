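make_tadset <- function(boundaries = c(10, 20), n_bins = 30, bin_size = 10000) {
  tad_set_from_boundaries(boundaries, n_bins, bin_size)
}

random_peaks <- function(n, max_pos, seed, width = 300) {
  set.seed(seed)
  start <- sample.int(max_pos - width, n)
  data.frame(chrom = "chrS", start = start, end = start + width,
             name = paste0("p", 1:n), score = 0L, strand = ".",
             summit = start + width %/% 2)
}

test_that("peak category assignment equals the quadratic-scan oracle", {
  ts <- make_tadset()
  peaks <- random_peaks(500, 30 * 10000, seed = 5)
  got <- assign_peaks(peaks, ts)
  want <- brute_assign_categories(peaks, c(10, 20), 10000, 30)
  expect_identical(got$category, want)
  expect_equal(sum(got$fractions), 1)
  # boundary flags match a direct scan
  for (k in 1:2) {
    b <- c(10, 20)[k]
    expect_identical(
      got$boundary_flag[k],
      any(peaks$start < (b + 1) * 10000 & b * 10000 < peaks$end)
    )
  }
  # with flank, the oracle still agrees
  got_f <- assign_peaks(peaks, ts, flank = 5000)
  want_f <- brute_assign_categories(peaks, c(10, 20), 10000, 30, flank = 5000)
  expect_identical(got_f$category, want_f)
})

test_that("degenerate peak inputs behave per contract", {
  ts <- make_tadset()
  none <- assign_peaks(random_peaks(5, 1e6, 1)[0, ], ts)
  expect_identical(none$fractions[["boundary"]], 0)
  expect_true(all(!none$boundary_flag))
  inside <- data.frame(chrom = "chrS", start = 100001, end = 100500,
                       name = "q", score = 0L, strand = ".", summit = 100250)
  one <- assign_peaks(inside, ts)
  expect_equal(one$fractions[["boundary"]], 1)
  bad <- inside
  bad$chrom <- "chrX"
  expect_error(assign_peaks(bad, ts), "chrX")
})

test_that("metagene profiles are RPM-scaled window averages", {
  track <- rep(3, 100)
  prof <- metagene_profile(track, anchors = c(30, 60), flank_bins = 5)
  expect_equal(as.numeric(prof), rep(3 * 1e6 / 300, 11))
  # a single anchor reproduces its window exactly (up to RPM scale)
  set.seed(3)
  tr <- rpois(100, 5)
  p1 <- metagene_profile(tr, anchors = 50, flank_bins = 4)
  expect_equal(as.numeric(p1), tr[47:55] * 1e6 / sum(tr))
  expect_error(metagene_profile(tr, anchors = 1, flank_bins = 10), "truncated")
  # n_out interpolation preserves endpoints
  p2 <- metagene_profile(tr, anchors = 50, flank_bins = 4, n_out = 5)
  expect_length(p2, 5)
  expect_equal(p2[1], p1[1])
})

test_that("boundary-associated factors are called by central/flank enrichment", {
  # planted separation: 3x boundary enrichment vs flat
  arch <- plant_architecture(sim_config(n_bins = 3000, tad_size_range = c(30, 60),
                                        seed = 17))
  bs <- arch$bin_size
  targets <- cbind(arch$boundaries * bs, (arch$boundaries + 1) * bs)
  enriched <- simulate_signal_track(arch, targets, amplitude = 9, background = 3,
                                    seed = 5)
  flat <- simulate_signal_track(arch, NULL, amplitude = 3, background = 3,
                                seed = 6)
  profs <- list(
    hot = metagene_profile(enriched, arch$boundaries, 25),
    cold = metagene_profile(flat, arch$boundaries, 25)
  )
  ba <- classify_ba(profs, ratio_threshold = 1.2)
  expect_true(ba$barbp[ba$factor == "hot"])
  expect_false(ba$barbp[ba$factor == "cold"])
  # uniform signal has ratio ~1, never above a threshold > 1
  expect_lt(abs(ba$ratio[ba$factor == "cold"] - 1), 0.15)
  # zero flank -> NA with warning
  spike <- rep(0, 51)
  spike[26] <- 10
  expect_warning(ba0 <- classify_ba(list(s = spike)), "flank")
  expect_true(is.na(ba0$ratio))
})

test_that("baRBP calling is monotone in planted boundary placement", {
  arch <- plant_architecture(sim_config(n_bins = 3000, tad_size_range = c(30, 60),
                                        seed = 18))
  fracs <- c(0, 0.1, 0.25, 0.5)
  ratios <- sapply(seq_along(fracs), function(k) {
    p <- simulate_peaks(arch, list(factor_spec("f", 100, fracs[k])), seed = 7)$f
    cov <- peak_coverage_track(p, arch$n_bins, arch$bin_size)
    prof <- metagene_profile(cov, arch$boundaries, 25)
    classify_ba(list(f = prof))$ratio
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("four-way boundary groups partition and count correctly", {
  ctcf <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  f <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  g <- boundary_groups(ctcf, f, anchor_name = "CTCF", test_name = "f")
  expect_equal(as.integer(g$sizes), c(1, 2, 2, 1))
  expect_equal(sum(g$proportions), 1)
  # factor everywhere, anchor nowhere
  g2 <- boundary_groups(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(unname(g2$proportions), c(0, 0, 1, 0))
})

test_that("interval overlap fractions agree with the brute-force scan", {
  a <- random_peaks(300, 1e6, seed = 21)
  b <- random_peaks(300, 1e6, seed = 22)
  got <- interval_overlap_fraction(a, b)
  expect_equal(got$a_in_b, mean(brute_overlaps_any(a, b)))
  expect_equal(got$b_in_a, mean(brute_overlaps_any(b, a)))
  expect_equal(interval_overlap_fraction(a, a)$a_in_b, 1)
  far <- a
  far$start <- far$start + 2e6
  far$end <- far$end + 2e6
  expect_equal(interval_overlap_fraction(a, far)$a_in_b, 0)
})

test_that("factor ranking orders by central signal with alphabetical ties", {
  mk <- function(center) {
    p <- rep(1, 21)
    p[10:12] <- center
    p
  }
  r <- rank_factors(list(b5 = mk(5), a3 = mk(3), c1 = mk(1)))
  expect_identical(r$factor, c("b5", "a3", "c1"))
  tied <- rank_factors(list(zed = mk(2), abe = mk(2)))
  expect_identical(tied$factor, c("abe", "zed"))
})
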