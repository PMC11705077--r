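test_that("signal quantification equals brute-force per-bin summation", {
  set.seed(12)
  track <- rpois(100, 4)
  iv <- data.frame(start = sample(0:900000, 50), id = paste0("q", 1:50))
  iv$end <- iv$start + sample(c(5000, 10000, 35000), 50, replace = TRUE)
  got <- quantify_signal(iv, track, 10000)
  want <- vapply(seq_len(50), function(k) {
    brute_quantify(iv$start[k], iv$end[k], track, 10000)
  }, numeric(1))
  expect_equal(got$raw, want)
  expect_equal(got$rpm, want * 1e6 / sum(track))
  # whole-chromosome interval returns the full library as 1e6 RPM
  whole <- quantify_signal(data.frame(start = 0, end = 1e6), track, 10000)
  expect_equal(whole$rpm, 1e6)
  # zero track
  z <- quantify_signal(iv, rep(0, 100), 10000)
  expect_true(all(z$rpm == 0))
  expect_error(quantify_signal(data.frame(start = -5, end = 100), track, 10000),
               "extent")
  # RPM is scale-free
  scaled <- quantify_signal(iv, track * 7, 10000)
  expect_equal(scaled$rpm, got$rpm)
})

test_that("shuffled intervals stay inside containers and cover them uniformly", {
  q <- data.frame(start = 100, end = 600)
  cont <- data.frame(start = 0, end = 10600)
  starts <- vapply(1:1000, function(k) {
    shuffle_within(q, cont, seed = k)$start
  }, numeric(1))
  expect_true(all(starts >= 0 & starts + 500 <= 10600))
  # chi-square goodness of fit against uniform starts
  h <- table(cut(starts, breaks = seq(0, 10100, length.out = 11)))
  p <- chisq.test(h)$p.value
  expect_gt(p, 0.01)
  # container equal to the query forces identity
  same <- shuffle_within(q, data.frame(start = 100, end = 600), seed = 1)
  expect_equal(same$start, 100)
  expect_warning(shuffle_within(data.frame(start = 0, end = 5000),
                                data.frame(start = 0, end = 100), seed = 1),
                 "skipped")
  # determinism
  s1 <- shuffle_within(q, cont, seed = 5)
  s2 <- shuffle_within(q, cont, seed = 5)
  expect_identical(s1, s2)
})

test_that("shuffled controls score below planted sites on an enriched track", {
  arch <- plant_architecture(sim_config(n_bins = 2000, tad_size_range = c(40, 80),
                                        seed = 19))
  bs <- arch$bin_size
  sites <- data.frame(start = arch$boundaries * bs,
                      end = (arch$boundaries + 1) * bs)
  track <- simulate_signal_track(arch, as.matrix(sites), amplitude = 10,
                                 background = 1, seed = 3)
  planted <- quantify_signal(sites, track, bs)
  shuf <- shuffle_within(sites, data.frame(start = 0, end = arch$n_bins * bs),
                         seed = 4)
  control <- quantify_signal(shuf, track, bs)
  expect_gt(mean(planted$rpm), mean(control$rpm))
})

test_that("tertile stratification matches sorted tertiles and tie rules", {
  s <- stratify_levels(c(1, 2, 3))
  expect_identical(as.character(s$labels), c("L", "M", "H"))
  tied <- stratify_levels(rep(4, 10))
  expect_true(all(tied$labels == "M"))
  expect_warning(few <- stratify_levels(c(0, 0, 1, 2)), "none")
  expect_true(all(few$labels == "none"))
  set.seed(21)
  v <- rexp(300)
  s3 <- stratify_levels(v)
  sizes <- table(s3$labels)[c("L", "M", "H")]
  expect_true(all(abs(sizes - 100) <= 1))
  # cutpoints equal brute-force sorted tertiles
  expect_equal(s3$cutpoints, quantile(v, c(1 / 3, 2 / 3), names = FALSE))
  # invariance to monotone transforms
  s4 <- stratify_levels(log1p(v))
  expect_identical(s3$labels, s4$labels)
  # zeros are 'none', never a tertile
  vz <- c(v, rep(0, 10))
  sz <- stratify_levels(vz)
  expect_true(all(sz$labels[301:310] == "none"))
})

test_that("group association reports Wilcoxon contrasts with effect sizes", {
  set.seed(33)
  same <- associate_groups(rep(c("a", "b"), each = 30), rep(rnorm(30), 2))
  expect_gt(same$pvalue, 0.9)
  expect_equal(same$fold_change_means, 1)
  shifted <- associate_groups(rep(c("a", "b"), each = 30),
                              c(rnorm(30, 10), rnorm(30, 20)))
  expect_lt(shifted$pvalue, 1e-6)
  expect_lt(shifted$median_diff, 0)
  tiny <- associate_groups(c("a", "a", "b", "b", "b"), c(1, 2, 5, 6, 7))
  expect_true(is.na(tiny$pvalue))
})

test_that("transcription-coupled insulation yields the planted L<M<H ordering", {
  # boundaries with higher transcription amplitude get deeper insulation
  n <- 900
  set.seed(44)
  n_tads <- 12
  sizes <- rep(n / n_tads, n_tads)
  breaks <- cumsum(sizes)[-n_tads]
  amp <- seq(2, 30, length.out = length(breaks))
  depth_map <- 0.65 - 0.6 * (amp - min(amp)) / diff(range(amp))
  cfg <- sim_config(n_bins = n, tad_size_range = c(75, 75),
                    insulation_depths = depth_map, depth = 2.4e6, seed = 9)
  arch <- plant_architecture(cfg)
  stopifnot(identical(arch$boundaries, as.integer(breaks)))
  bal <- ice_balance(simulate_contact_map(arch, cfg))
  sig <- bin_signal(bal, 5)
  ts <- insulation_score(sig, tad_set_from_boundaries(arch$boundaries, n))
  bs <- arch$bin_size
  track <- rep(1, n)
  for (k in seq_along(breaks)) {
    track[breaks[k] + 1] <- track[breaks[k] + 1] + rpois(1, amp[k])
  }
  q <- quantify_signal(data.frame(start = breaks * bs, end = (breaks + 1) * bs),
                       track, bs)
  strata <- stratify_levels(q$rpm)
  med <- tapply(ts$boundaries$IS, strata$labels, median)
  expect_true(med[["L"]] < med[["M"]] && med[["M"]] < med[["H"]])
})
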