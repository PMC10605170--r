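# Shared fixtures and independent oracles. Oracles are deliberately naive
# (closed forms, quadratic loops, exhaustive enumeration) and never call the
# code paths they check.

# Closed-form Spearman for tie-free vectors: 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearman_closed_form <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force BH step-up: padj_(i) = min(1, min_{j >= i} n/j * p_(j)).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min((n / seq(i, n)) * ps[seq(i, n)]))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Quadratic all-pairs overlap count: bins hit by >= 1 interval (half-open).
overlap_oracle <- function(bins, peaks) {
  hit <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(bins))) {
    for (j in seq_len(nrow(peaks))) {
      if (bins$chrom[i] == peaks$chrom[j] &&
          bins$start[i] < peaks$end[j] && peaks$start[j] < bins$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

# Direct running-sum GSEA enrichment statistic (weighted KS), O(N) sweep.
gsea_es_oracle <- function(ranked_scores, hit_ranks, weight = 1) {
  N <- length(ranked_scores)
  in_set <- seq_len(N) %in% hit_ranks
  w <- abs(ranked_scores)^weight
  nr <- sum(w[in_set])
  if (nr == 0) {
    w[] <- 1
    nr <- sum(in_set)
  }
  run <- 0
  best_pos <- -Inf
  best_neg <- Inf
  for (i in seq_len(N)) {
    run <- run + if (in_set[i]) w[i] / nr else -1 / (N - sum(in_set))
    best_pos <- max(best_pos, run)
    best_neg <- min(best_neg, run)
  }
  if (best_pos > -best_neg) best_pos else best_neg
}

# A tiny expression tibble: genes x samples from a matrix.
expr_tbl <- function(m, genes = rownames(m)) {
  colnames(m) <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  tibble::as_tibble(m) |>
    dplyr::mutate(gene = genes, .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulation config used by several suites; any field can be overridden.
small_config <- function(seed = 1, ...) {
  args <- list(
    n_cohorts = 3, samples_per_cohort = 30, n_genes = 200,
    window = "chrS:1000000-1100000", bin_size = 100, n_atac_samples = 60,
    planted_bins = tibble::tibble(bin = 495:504, rho = 0.8),
    n_factors = 6, experiments_per_factor = 3, peaks_per_experiment = 60,
    target_set_size = 40, n_loops = 10, seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
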