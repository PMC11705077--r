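# Independent brute-force oracles. Each reimplements a contract with plain
# loops, deliberately ignoring the package's vectorized/interval-tree code
# paths, so tests compare two independent routes to the same number.

random_symmetric_matrix <- function(n, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# mean of the w x w rectangle straddling each bin edge, nested loops
brute_bin_signal <- function(m, w) {
  n <- nrow(m)
  sig <- rep(NA_real_, n)
  for (i in w:(n - w)) {
    acc <- 0
    cnt <- 0
    for (r in (i - w + 1):i) {
      for (cc in (i + 1):(i + w)) {
        acc <- acc + m[r, cc]
        cnt <- cnt + 1
      }
    }
    sig[i] <- acc / cnt
  }
  sig
}

# intra / (intra + inter) with explicit pair enumeration, diagonal once
brute_domain_score <- function(m, start_bin, end_bin) {
  n <- nrow(m)
  idx <- (start_bin + 1):end_bin
  intra <- 0
  for (i in idx) for (j in idx) if (j >= i) intra <- intra + m[i, j]
  inter <- 0
  for (i in idx) for (j in seq_len(n)) if (!(j %in% idx)) inter <- inter + m[i, j]
  if (intra + inter == 0) return(NA_real_)
  intra / (intra + inter)
}

# quadratic-scan overlap of 0-based half-open intervals
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

# per-peak category given boundary bins (0-based) and a flank, boundary first
brute_assign_categories <- function(peaks, boundary_bins, bin_size, n_bins,
                                    flank = 0) {
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$start[i]
    e <- peaks$end[i]
    on_boundary <- FALSE
    for (b in boundary_bins) {
      bs <- b * bin_size - flank
      be <- (b + 1) * bin_size + flank
      if (s < be && bs < e) on_boundary <- TRUE
    }
    if (on_boundary) "boundary"
    else if (e <= 0 || s >= n_bins * bin_size) "gap"
    else "intra"
  }, character(1))
}

# sorted-chain single-linkage merge of summits at <= max_gap
brute_cre_partition <- function(summits, max_gap = 1000) {
  s <- sort(summits)
  grp <- integer(length(s))
  g <- 1L
  grp[1] <- g
  for (i in seq_along(s)[-1]) {
    if (s[i] - s[i - 1] > max_gap) g <- g + 1L
    grp[i] <- g
  }
  split(s, grp)
}

# per-bin summation over an interval, full bin value on >= 1 bp overlap
brute_quantify <- function(start, end, track, bin_size) {
  acc <- 0
  for (b in seq_along(track)) {
    bs <- (b - 1) * bin_size
    be <- b * bin_size
    if (bs < end && start < be) acc <- acc + track[b]
  }
  acc
}

# independently coded TAD classifier applying the published rules
brute_classify_tads <- function(A, B, tol_bins, min_ov = 0.8) {
  ov_len <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
  out <- character(nrow(A))
  for (i in seq_len(nrow(A))) {
    a1 <- A$start_bin[i]; a2 <- A$end_bin[i]; lenA <- a2 - a1
    if (nrow(B) == 0) { out[i] <- "disappeared"; next }
    fracA <- fracB <- numeric(nrow(B))
    inv <- FALSE
    for (j in seq_len(nrow(B))) {
      ov <- ov_len(a1, a2, B$start_bin[j], B$end_bin[j])
      fracA[j] <- ov / lenA
      fracB[j] <- ov / (B$end_bin[j] - B$start_bin[j])
      if (abs(B$start_bin[j] - a1) <= tol_bins &&
            abs(B$end_bin[j] - a2) <= tol_bins &&
            fracA[j] > min_ov && fracB[j] > min_ov) inv <- TRUE
    }
    if (inv) { out[i] <- "invariant"; next }
    merged <- FALSE
    for (j in which(fracA > min_ov)) {
      for (k in seq_len(nrow(A))) {
        if (k == i) next
        ovo <- ov_len(A$start_bin[k], A$end_bin[k], B$start_bin[j], B$end_bin[j])
        if (ovo / (A$end_bin[k] - A$start_bin[k]) > min_ov) merged <- TRUE
      }
    }
    if (merged) { out[i] <- "merged"; next }
    if (sum(fracB > min_ov) >= 2) { out[i] <- "split"; next }
    if (max(fracA) <= 1 - min_ov) { out[i] <- "disappeared"; next }
    out[i] <- "rearranged"
  }
  out
}

# small standard simulation used by several recovery tests
small_sim <- function(seed, n_bins = 400, tad_range = c(40, 80), depth = 8e5,
                      insulation = 0.3, compartments = NULL) {
  cfg <- sim_config(n_bins = n_bins, tad_size_range = tad_range,
                    insulation_depths = insulation, depth = depth,
                    compartment_block_bins = compartments, seed = seed)
  arch <- plant_architecture(cfg)
  list(cfg = cfg, arch = arch, cm = simulate_contact_map(arch, cfg))
}

adjusted_rand <- function(a, b) {
  # contingency-based ARI (Hubert & Arabie); small and self-contained
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# planted binary occupancy matrix: 4 factor groups of 3, CREs pick one group
planted_occupancy <- function(n_cre = 200, noise = 0, seed = 1) {
  set.seed(seed)
  grp <- rep(1:4, each = 3)
  cre_grp <- sample(1:4, n_cre, replace = TRUE)
  V <- matrix(0L, n_cre, 12, dimnames = list(NULL, paste0("F", 1:12)))
  for (c in seq_len(n_cre)) V[c, grp == cre_grp[c]] <- 1L
  if (noise > 0) {
    flip <- matrix(runif(n_cre * 12) < noise, n_cre, 12)
    V[flip] <- 1L - V[flip]
  }
  list(V = V[rowSums(V) >= 2, , drop = FALSE], factor_groups = grp)
}
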