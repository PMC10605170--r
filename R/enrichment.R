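# Permutation overlap enrichment: per-experiment observed vs expected overlap
# of peak sets with significant bins, aggregated per factor as the sum of
# "observation beyond expectation" values and tested against a permutation
# null drawn from the pooled per-experiment values.

#' Observed overlap between one experiment's peaks and a bin set
#'
#' The number of (non-overlapping) query bins intersected by at least one
#' peak, under half-open interval arithmetic (any overlap >= 1 bp counts; the
#' unit of analysis is the bin, not the peak).
#'
#' @param peaks Interval tibble of one experiment's peaks.
#' @param bins Interval tibble of non-overlapping query bins.
#' @return Integer count of bins overlapped.
#' @export
#' @examples
#' bins <- tibble::tibble(chrom = "c", start = c(0, 200), end = c(100, 300))
#' peak <- tibble::tibble(chrom = "c", start = 50, end = 60)
#' observed_overlap(peak, bins) # 1
observed_overlap <- function(peaks, bins) {
  check_intervals(bins, "bins")
  if (nrow(peaks) == 0) return(0L)
  check_intervals(peaks, "peaks")
  hits <- GenomicRanges::countOverlaps(as_granges0(bins), as_granges0(peaks))
  sum(hits > 0)
}

#' Permutation-expected overlap for one experiment
#'
#' Relocates the query bin set uniformly at random within a background region
#' (bin widths preserved; overlaps among relocated bins allowed), `n_perm`
#' times, and returns the mean observed overlap against the experiment's
#' (fixed) peaks.
#'
#' @param peaks Interval tibble of one experiment's peaks.
#' @param bins Interval tibble of query bins.
#' @param background Interval tibble (>= 1 row) containing the bins; when
#'   several rows are given, placements land in a row with probability
#'   proportional to its length.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed for reproducible placements.
#' @return The mean overlap count over permutations.
#' @export
expected_overlap <- function(peaks, bins, background, n_perm = 100, seed = NULL) {
  check_intervals(bins, "bins")
  check_intervals(background, "background")
  stopifnot(n_perm >= 1)
  widths <- bins$end - bins$start
  bg_len <- background$end - background$start
  if (max(bg_len) < max(widths)) {
    rlang::abort("background is shorter than the widest bin")
  }
  if (nrow(peaks) == 0) return(0)
  # merged peak intervals per background chromosome, for the fast membership test
  merged <- lapply(unique(background$chrom), function(ch) {
    sel <- peaks$chrom == ch
    merge_intervals(peaks$start[sel], peaks$end[sel])
  })
  names(merged) <- unique(background$chrom)

  nb <- length(widths)
  with_seed(seed, {
    row <- if (nrow(background) == 1) {
      rep(1L, n_perm * nb)
    } else {
      sample.int(nrow(background), n_perm * nb, replace = TRUE, prob = bg_len)
    }
    w <- rep(widths, n_perm)
    avail <- bg_len[row] - w
    if (any(avail < 0)) {
      # a bin wider than the sampled background row: resample onto fitting rows
      for (i in which(avail < 0)) {
        ok <- which(bg_len >= w[i])
        row[i] <- ok[sample.int(length(ok), 1)]
        avail[i] <- bg_len[row[i]] - w[i]
      }
    }
    s <- background$start[row] + floor(stats::runif(n_perm * nb) * (avail + 1))
    hit <- logical(n_perm * nb)
    for (ch in names(merged)) {
      sel <- background$chrom[row] == ch
      m <- merged[[ch]]
      hit[sel] <- overlaps_merged(s[sel], s[sel] + w[sel], m$start, m$end)
    }
    mean(rowSums(matrix(hit, nrow = n_perm, byrow = TRUE)))
  })
}

#' Observed and expected overlap for every experiment in a peak collection
#'
#' Convenience wrapper running [observed_overlap()] and [expected_overlap()]
#' per experiment of a manifest-style peak tibble.
#'
#' @param peaks Peak tibble with `experiment` and `factor` columns (see
#'   [read_peak_experiments()]).
#' @param bins Query bins (significant bins from the chromatin survey).
#' @param background Background region(s) for permutation placement
#'   (typically the survey window).
#' @param n_perm Permutations per experiment.
#' @param seed Optional seed; each experiment gets a deterministic substream.
#' @return Tibble `experiment`, `factor`, `n_peaks`, `observed`, `expected`,
#'   `n_perm`.
#' @export
overlap_results <- function(peaks, bins, background, n_perm = 100, seed = NULL) {
  stopifnot(all(c("experiment", "factor") %in% names(peaks)))
  peaks |>
    dplyr::group_by(.data$experiment, .data$factor) |>
    dplyr::group_modify(function(d, key) {
      sub_seed <- if (is.null(seed)) NULL else {
        substream_seed(seed, paste0("overlap_", key$experiment))
      }
      tibble::tibble(
        n_peaks = nrow(d),
        observed = observed_overlap(d, bins),
        expected = expected_overlap(d, bins, background, n_perm, sub_seed),
        n_perm = n_perm
      )
    }) |>
    dplyr::ungroup()
}

#' Overlap enrichment score
#'
#' `log2(sum(observed) / sum(expected)) * -log10(padj)`; the score's sign
#' matches the sign of the log2 ratio.
#'
#' @param sum_obs,sum_exp Summed observed and expected overlap frequencies.
#' @param padj BH-adjusted permutation p-value.
#' @return Numeric score.
#' @export
#' @examples
#' overlap_enrichment_score(20, 5, 0.01) # 4
overlap_enrichment_score <- function(sum_obs, sum_exp, padj) {
  log2(sum_obs / sum_exp) * -log10(padj)
}

#' Factor-level permutation enrichment
#'
#' Aggregates per-experiment observation-beyond-expectation values
#' (`observed - expected`) per factor and compares each factor's aggregate to
#' a permutation null that controls for the number of experiments: `n_null`
#' sums of `k` values drawn without replacement from the pool of *all*
#' experiments' values, where `k` is the factor's experiment count. When all
#' `choose(pool, k)` draws number at most `n_null`, the null is enumerated
#' exhaustively instead of sampled. The permutation p uses the add-one
#' estimator (never 0, never > 1), is BH-adjusted across factors, and each
#' factor also gets the null z-score and the enrichment score of
#' [overlap_enrichment_score()].
#'
#' @param results Tibble from [overlap_results()].
#' @param n_null Null draws per factor (>= 100).
#' @param seed Optional seed.
#' @return A `factor_enrichment` tibble: `factor`, `n_experiments`,
#'   `sum_obs`, `sum_exp`, `aggregate`, `p`, `padj`, `z`, `score`, sorted by
#'   score.
#' @export
factor_enrichment <- function(results, n_null = 10000, seed = NULL) {
  stopifnot(all(c("factor", "observed", "expected") %in% names(results)))
  if (n_null < 100) rlang::abort("n_null must be >= 100")
  results <- dplyr::filter(results, !is.na(.data$observed))
  pool <- results$observed - results$expected
  n_pool <- length(pool)

  per_factor <- results |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      sum_obs = sum(.data$observed),
      sum_exp = sum(.data$expected),
      aggregate = sum(.data$observed - .data$expected),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_experiments > 0)

  # one null distribution per unique experiment count (identically
  # distributed across factors with the same k)
  nulls <- lapply(unique(per_factor$n_experiments), function(k) {
    if (k > n_pool) rlang::abort("factor has more experiments than the pool")
    exhaustive <- lchoose(n_pool, k) <= log(n_null)
    sums <- if (exhaustive) {
      utils::combn(pool, k, sum)
    } else {
      with_seed(if (is.null(seed)) NULL else substream_seed(seed, paste0("null_k", k)),
                vapply(seq_len(n_null),
                       function(i) sum(pool[sample.int(n_pool, k)]),
                       numeric(1)))
    }
    list(k = k, sums = sums)
  })
  names(nulls) <- as.character(vapply(nulls, `[[`, numeric(1), "k"))

  stat <- purrr::pmap(per_factor, function(factor, n_experiments, sum_obs,
                                           sum_exp, aggregate, ...) {
    ns <- nulls[[as.character(n_experiments)]]$sums
    p <- (1 + sum(ns >= aggregate)) / (length(ns) + 1)
    nsd <- stats::sd(ns)
    z <- if (is.na(nsd) || nsd == 0) NA_real_ else (aggregate - mean(ns)) / nsd
    tibble::tibble(p = p, z = z)
  }) |> dplyr::bind_rows()

  out <- dplyr::bind_cols(per_factor, stat) |>
    dplyr::mutate(
      padj = stats::p.adjust(.data$p, method = "BH"),
      score = overlap_enrichment_score(.data$sum_obs, .data$sum_exp, .data$padj)
    ) |>
    dplyr::arrange(dplyr::desc(.data$score))
  class(out) <- c("factor_enrichment", class(out))
  out
}

#' Flag bins intersecting chromatin-loop anchors
#'
#' A bin is flagged if it overlaps either anchor of any loop (half-open
#' arithmetic), the basis for coloring negative-correlate bins by loop-anchor
#' intersection.
#'
#' @param bins Interval tibble of bins.
#' @param loops BEDPE tibble from [read_bedpe()].
#' @return `bins` with a logical `loop_anchor` column.
#' @export
loop_intersect <- function(bins, loops) {
  anchors <- dplyr::bind_rows(
    tibble::tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1),
    tibble::tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  )
  dplyr::mutate(tibble::as_tibble(bins),
                loop_anchor = flag_overlaps(bins, anchors))
}
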