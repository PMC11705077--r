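#' Build cis-regulatory elements and the binary occupancy matrix
#'
#' All factors' peak summits are pooled and merged by single linkage: summits
#' whose consecutive sorted distance is at most \code{max_gap} bp chain into
#' one CRE. The occupancy matrix V has a row per CRE and a column per factor,
#' with V[c, f] = 1 when factor f contributed at least one summit to CRE c.
#' Rows occupied by fewer than two factors are dropped (only multi-factor
#' CREs inform co-occupancy).
#'
#' @param peak_sets Named list of peak data frames, each with a \code{summit}
#'   column (absolute bp).
#' @param max_gap Single-linkage merge distance in bp (default 1000).
#' @return A list with \code{cres} (data frame: cre id, start, end, n_summits),
#'   \code{V} (binary CRE x factor matrix over the kept rows) and
#'   \code{n_dropped} (single-factor CREs removed). An empty V after filtering
#'   raises a warning.
#' @export
build_cres <- function(peak_sets, max_gap = 1000) {
  stopifnot(length(peak_sets) > 0, !is.null(names(peak_sets)))
  for (nm in names(peak_sets)) {
    if (is.null(peak_sets[[nm]]$summit) || anyNA(peak_sets[[nm]]$summit)) {
      stop("peak set '", nm, "' is missing summit positions", call. = FALSE)
    }
  }
  df <- do.call(rbind, lapply(names(peak_sets), function(nm) {
    data.frame(summit = peak_sets[[nm]]$summit, factor = nm,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$summit, df$factor), ]
  if (nrow(df) == 0L) stop("no summits supplied", call. = FALSE)
  cre_id <- cumsum(c(1L, as.integer(diff(df$summit) > max_gap)))
  cres <- data.frame(
    cre = unique(cre_id),
    start = as.integer(tapply(df$summit, cre_id, min)),
    end = as.integer(tapply(df$summit, cre_id, max) + 1L),
    n_summits = as.integer(tapply(df$summit, cre_id, length))
  )
  fac <- names(peak_sets)
  V <- matrix(0L, nrow(cres), length(fac), dimnames = list(cres$cre, fac))
  occ <- unique(data.frame(cre = cre_id, factor = df$factor))
  V[cbind(match(occ$cre, cres$cre), match(occ$factor, fac))] <- 1L
  keep <- rowSums(V) >= 2L
  if (!any(keep)) warning("no CRE is occupied by multiple factors; V is empty")
  list(cres = cres, V = V[keep, , drop = FALSE], n_dropped = sum(!keep))
}

# One multiplicative-update NMF run from a seeded random start.
nmf_run <- function(V, k, seed, max_iter = 500L, tol = 1e-6) {
  n <- nrow(V)
  m <- ncol(V)
  eps <- 1e-10
  with_seed(seed, {
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  })
  err_prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sum((V - W %*% H)^2)
    trace <- c(trace, err)
    if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps)) break
    err_prev <- err
  }
  list(W = W, H = H, error = err, trace = trace)
}

#' Non-negative matrix factorization of the occupancy matrix
#'
#' Minimizes the squared Frobenius reconstruction error with the classical
#' multiplicative updates, restarted from \code{n_restarts} seeded random
#' initializations; the best restart (lowest error) is returned. The error
#' trace of every restart is checked to be non-increasing.
#'
#' @param V Binary (or non-negative) CRE x factor matrix.
#' @param k Factorization rank (1 <= k < n_factors).
#' @param n_restarts Number of random restarts (default 30).
#' @param seed Master seed; restart r uses a seed derived from it.
#' @param max_iter,tol Update iteration cap and relative error tolerance.
#' @return An \code{nmf_result}: W (CRE x k), H (k x factor), rank, error,
#'   error trace of the winning restart, n_restarts, seed.
#' @export
nmf_factorize <- function(V, k, n_restarts = 30L, seed = 1L,
                          max_iter = 500L, tol = 1e-6) {
  V <- as.matrix(V)
  if (nrow(V) == 0L || ncol(V) == 0L) stop("V is empty", call. = FALSE)
  if (k >= ncol(V)) stop("rank k must be smaller than the number of factors",
                         call. = FALSE)
  if (k < 1) stop("rank k must be >= 1", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_run(V, k, child_seed(seed, 100L + r), max_iter, tol)
    if (any(diff(fit$trace) > 1e-8 * pmax(fit$trace[-length(fit$trace)], 1))) {
      warning("NMF error trace increased; numerical issue in restart ", r)
    }
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  structure(
    list(W = best$W, H = best$H, rank = as.integer(k), error = best$error,
         error_trace = best$trace, n_restarts = as.integer(n_restarts),
         seed = as.integer(seed)),
    class = "nmf_result"
  )
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("nmf_result: rank %d, error %.4g, %d restarts\n",
              x$rank, x$error, x$n_restarts))
  invisible(x)
}

#' Assign factors to co-occupancy groups
#'
#' Each factor (column of H) goes to the component with its maximal
#' coefficient; ties break to the lower component index. An all-zero column is
#' left unassigned (NA) with a warning.
#'
#' @param fit An \code{nmf_result} (or a bare H matrix).
#' @return Named integer vector of group ids (NA = unassigned), with the
#'   coefficient matrix attached as attribute \code{H}.
#' @export
assign_groups <- function(fit) {
  H <- if (inherits(fit, "nmf_result")) fit$H else as.matrix(fit)
  g <- apply(H, 2L, function(col) {
    if (all(col == 0)) NA_integer_ else which.max(col)
  })
  if (anyNA(g)) warning("unassigned factors (all-zero H column): ",
                        paste(names(g)[is.na(g)], collapse = ", "))
  names(g) <- colnames(H)
  attr(g, "H") <- H
  g
}

#' Consensus-based NMF rank selection
#'
#' For every rank in \code{rank_range} and every restart, the factors are
#' assigned to their argmax component, giving a factor x factor connectivity
#' matrix; averaging over restarts gives the consensus matrix C. The
#' cophenetic coefficient is the Pearson correlation between the 1-C distances
#' and the cophenetic distances of their average-linkage dendrogram; the
#' dispersion coefficient is mean(4(C-1/2)^2). The chosen rank maximizes the
#' cophenetic coefficient, with dispersion as tie-breaker (then the smaller
#' rank).
#'
#' @param V Occupancy matrix.
#' @param rank_range Candidate ranks (each < n_factors).
#' @param n_restarts Restarts per rank (>= 2; consensus is undefined below).
#' @param seed Master seed.
#' @param max_iter,tol Passed to the per-restart solver.
#' @return A \code{consensus_stats}: data frame \code{stats} (rank,
#'   cophenetic, dispersion), list \code{consensus} of C matrices, and
#'   \code{chosen_rank}.
#' @export
rank_selection <- function(V, rank_range = 2:6, n_restarts = 30L, seed = 1L,
                           max_iter = 500L, tol = 1e-6) {
  V <- as.matrix(V)
  if (n_restarts < 2L) stop("consensus needs at least 2 restarts", call. = FALSE)
  if (any(rank_range >= ncol(V)) || any(rank_range < 2L)) {
    stop("rank_range must lie within [2, n_factors)", call. = FALSE)
  }
  m <- ncol(V)
  stats_rows <- list()
  consensus <- list()
  for (k in rank_range) {
    conn_sum <- matrix(0, m, m)
    for (r in seq_len(n_restarts)) {
      fit <- nmf_run(V, k, child_seed(seed, k * 1000L + r), max_iter, tol)
      g <- apply(fit$H, 2L, which.max)
      conn_sum <- conn_sum + outer(g, g, "==")
    }
    C <- conn_sum / n_restarts
    dimnames(C) <- list(colnames(V), colnames(V))
    d <- stats::as.dist(1 - C)
    coph <- if (stats::sd(d) == 0) {
      NA_real_  # degenerate: all pairs identical; no dendrogram structure
    } else {
      stats::cor(d, stats::cophenetic(stats::hclust(d, method = "average")))
    }
    disp <- mean(4 * (C - 0.5)^2)
    stats_rows[[as.character(k)]] <- data.frame(rank = k, cophenetic = coph,
                                                dispersion = disp)
    consensus[[as.character(k)]] <- C
  }
  st <- do.call(rbind, stats_rows)
  score <- ifelse(is.na(st$cophenetic), -Inf, st$cophenetic)
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[st$dispersion[best] == max(st$dispersion[best])]
  # residual ties (several ranks perfectly reproducible on both statistics)
  # resolve to the largest rank: merging below the true rank can be exactly
  # stable, while splitting beyond it loses reproducibility, so the finest
  # fully-stable clustering is the informative one
  structure(
    list(stats = st, consensus = consensus,
         chosen_rank = st$rank[best[length(best)]]),
    class = "consensus_stats"
  )
}

#' @export
print.consensus_stats <- function(x, ...) {
  cat("consensus_stats (chosen rank:", x$chosen_rank, ")\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}
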