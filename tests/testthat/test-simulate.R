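test_that("forced tiling yields the single expected boundary", {
  cfg <- sim_config(n_bins = 100, tad_size_range = c(50, 50), seed = 3)
  arch <- plant_architecture(cfg)
  expect_identical(arch$boundaries, 50L)
  expect_equal(arch$tads, cbind(start = c(0L, 50L), end = c(50L, 100L)))
})

test_that("architecture generation is deterministic and respects size bounds", {
  cfg <- sim_config(n_bins = 1000, tad_size_range = c(20, 100), seed = 1)
  a1 <- plant_architecture(cfg)
  a2 <- plant_architecture(cfg)
  expect_identical(a1, a2)
  # brute-force scan of emitted interval lengths
  lens <- a1$tads[, "end"] - a1$tads[, "start"]
  expect_true(all(lens >= 20 & lens <= 100))
  expect_true(all(diff(a1$boundaries) > 0))
  # TADs tile: consecutive intervals abut, covering [0, n_bins)
  expect_identical(a1$tads[-1, "start"], a1$tads[-nrow(a1$tads), "end"])
  expect_identical(a1$tads[1, "start"][[1]], 0L)
  expect_identical(a1$tads[nrow(a1$tads), "end"][[1]], 1000L)
})

test_that("infeasible TAD size range is rejected", {
  expect_error(sim_config(n_bins = 80, tad_size_range = c(50, 50)),
               "twice the maximum")
  expect_error(sim_config(n_bins = 100, tad_size_range = c(30, 50),
                          insulation_depths = 0), "insulation")
  expect_error(sim_config(n_bins = 100, tad_size_range = c(30, 50),
                          insulation_depths = 1.2), "insulation")
})

test_that("contact map matches the closed-form decay expectation", {
  # no insulation, no compartments: E depends on |i - j| only
  cfg <- sim_config(n_bins = 300, tad_size_range = c(50, 100),
                    insulation_depths = 1, depth = 1e6, decay_exponent = 1,
                    seed = 5)
  arch <- plant_architecture(cfg)
  cm <- simulate_contact_map(arch, cfg)
  e <- (1 + abs(outer(0:299, 0:299, "-")))^(-1)
  scale <- 1e6 / sum(e[upper.tri(e, diag = TRUE)])
  for (s in c(0, 1, 5, 20)) {
    obs <- mean(cm$counts[cbind(1:(300 - s), (1 + s):300)])
    expected <- scale * (1 + s)^(-1)
    se <- sqrt(expected / (300 - s))
    expect_lt(abs(obs - expected), 3.5 * se)
  }
})

test_that("simulated totals and symmetry honour the configured depth", {
  s <- small_sim(seed = 2)
  tot <- sum(s$cm$counts[upper.tri(s$cm$counts, diag = TRUE)])
  expect_lt(abs(tot - s$cfg$depth), 3 * sqrt(s$cfg$depth))
  expect_identical(s$cm$counts, t(s$cm$counts))
  # depth = 0 gives the empty matrix
  cfg0 <- sim_config(n_bins = 120, tad_size_range = c(30, 60), depth = 0, seed = 1)
  arch0 <- plant_architecture(cfg0)
  expect_true(all(simulate_contact_map(arch0, cfg0)$counts == 0))
})

test_that("cross-boundary attenuation matches the planted insulation depth", {
  cfg <- sim_config(n_bins = 200, tad_size_range = c(100, 100),
                    insulation_depths = 0.2, depth = 4e6, seed = 7)
  arch <- plant_architecture(cfg)
  cm <- simulate_contact_map(arch, cfg)
  b <- arch$boundaries[1]
  # same-distance pairs: cross-boundary vs within-TAD, distances 5..30
  ratios <- sapply(5:30, function(s) {
    i <- seq_len(200 - s)
    j <- i + s
    cross <- i <= b & j > b
    within <- (i <= b & j <= b) | (i > b & j > b)
    mean(cm$counts[cbind(i[cross], j[cross])]) /
      mean(cm$counts[cbind(i[within], j[within])])
  })
  expect_lt(abs(mean(ratios) - 0.2), 0.03)
})

test_that("peak placement honours boundary fractions and shared pools", {
  cfg <- sim_config(n_bins = 5000, tad_size_range = c(20, 60), seed = 11)
  arch <- plant_architecture(cfg)
  # boundary_fraction = 0: no peak touches a boundary bin
  p0 <- simulate_peaks(arch, list(factor_spec("x", 200, 0)), seed = 1)$x
  bin0 <- p0$summit %/% arch$bin_size
  expect_false(any(bin0 %in% arch$boundaries))
  # shared pool without dropout: identical summits
  sp <- list(factor_spec("a", 150, 0.25, group_id = 1),
             factor_spec("b", 150, 0.25, group_id = 1))
  pp <- simulate_peaks(arch, sp, seed = 2, dropout = 0)
  expect_identical(pp$a$summit, pp$b$summit)
  # binomial regime: ~25% of 400 peaks on boundaries
  p4 <- simulate_peaks(arch, list(factor_spec("y", 400, 0.25)), seed = 3)$y
  n_bound <- sum((p4$summit %/% arch$bin_size) %in% arch$boundaries)
  expect_gt(n_bound, qbinom(0.005, 400, 0.25))
  expect_lt(n_bound, qbinom(0.995, 400, 0.25))
  # infeasible boundary demand errors
  small <- plant_architecture(sim_config(n_bins = 100, tad_size_range = c(50, 50)))
  expect_error(simulate_peaks(small, list(factor_spec("z", 100, 0.5))),
               "boundary")
})

test_that("signal tracks follow the planted on/off Poisson rates", {
  arch <- plant_architecture(sim_config(n_bins = 2000, tad_size_range = c(50, 100),
                                        seed = 4))
  bs <- arch$bin_size
  targets <- cbind(arch$boundaries * bs, (arch$boundaries + 1) * bs)
  tr <- simulate_signal_track(arch, targets, amplitude = 10, background = 1,
                              seed = 9)
  on <- (seq_len(arch$n_bins) - 1L) %in% arch$boundaries
  expect_lt(abs(mean(tr[on]) / mean(tr[!on]) - 10), 1.5)
  # background = 0: silence off-target
  tr0 <- simulate_signal_track(arch, targets, amplitude = 5, background = 0,
                               seed = 9)
  expect_true(all(tr0[!on] == 0))
  # stationary when amplitude == background
  trs <- simulate_signal_track(arch, targets, amplitude = 2, background = 2,
                               seed = 9)
  # stationary up to Poisson noise (on-target set is only ~30 bins)
  expect_lt(abs(mean(trs[on]) - mean(trs[!on])), 3 * sqrt(2 / sum(on)))
})

test_that("truth tables round-trip through disk", {
  s <- small_sim(seed = 6, compartments = 40)
  d <- withr::local_tempdir()
  write_synthetic_dataset(s$arch, s$cm, dir = d)
  back <- read_architecture(d)
  expect_equal(back, s$arch)
  cm2 <- read_triplet_matrix(file.path(d, "matrix.triplet.tsv"),
                             s$arch$n_bins, s$arch$chrom, s$arch$bin_size)
  expect_equal(cm2$counts, s$cm$counts)
})

test_that("ablation removes boundaries and re-tiles TADs", {
  arch <- plant_architecture(sim_config(n_bins = 600, tad_size_range = c(50, 100),
                                        seed = 8))
  abl <- ablate_architecture(arch, c(1, 3))
  expect_identical(abl$boundaries, arch$boundaries[-c(1, 3)])
  expect_identical(abl$tads[-1, "start"], abl$tads[-nrow(abl$tads), "end"])
  expect_identical(abl$tads[nrow(abl$tads), "end"][[1]], arch$n_bins)
})
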