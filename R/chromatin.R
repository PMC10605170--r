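# Chromatin survey: tile the window into fixed-width bins, quantile-normalize
# per-sample bin counts, correlate each bin's accessibility with focal-gene
# expression across matched samples, and BH-select significant bins.

#' Tile a genomic window into fixed-width bins
#'
#' Produces contiguous, non-overlapping, equal-width half-open bins covering
#' the window. A final partial bin (when `bin_size` does not divide the
#' window length) is truncated with a warning.
#'
#' @param window Window string or interval tibble (see [parse_window()]).
#' @param bin_size Bin width in bp (> 0); must not exceed the window length.
#' @return A tibble `chrom`, `start`, `end`, `bin` (1-based index).
#' @export
#' @examples
#' nrow(make_bins("chr5:89970000-91020000", 100)) # 10500
make_bins <- function(window, bin_size) {
  window <- parse_window(window)
  stopifnot(bin_size > 0)
  len <- window$end - window$start
  if (len < bin_size) {
    rlang::abort(sprintf("window length %s is shorter than bin_size %s",
                         format_bp(len), format_bp(bin_size)))
  }
  n <- len %/% bin_size
  if (len %% bin_size != 0) {
    rlang::warn(sprintf("window length %s is not a multiple of %s; final %s bp dropped",
                        format_bp(len), format_bp(bin_size),
                        format_bp(len %% bin_size)))
  }
  tibble::tibble(
    chrom = window$chrom,
    start = window$start + (seq_len(n) - 1) * bin_size,
    end = window$start + seq_len(n) * bin_size,
    bin = seq_len(n)
  )
}

#' Quantile-normalize a bin count matrix across samples
#'
#' Classic quantile normalization: within each sample, values are replaced by
#' the across-sample mean of the order statistics at that value's rank (ties
#' receive interpolated means), so every sample ends up with an identical
#' value distribution while within-sample rank order is preserved. An
#' optional block of reference rows (e.g. genome-wide coordinates used for
#' global normalization) participates in the rank computation and is dropped
#' from the output.
#'
#' @param counts Tibble with coordinate columns (`chrom`, `start`, `end`,
#'   optionally `bin`) followed by one numeric column per sample (>= 2
#'   samples; a single sample is returned unchanged with a warning).
#' @param reference Optional tibble with the same sample columns, rows added
#'   for normalization only.
#' @return `counts` with the sample columns normalized.
#' @export
quantile_normalize <- function(counts, reference = NULL) {
  coord_cols <- intersect(c("chrom", "start", "end", "bin"), names(counts))
  sample_cols <- setdiff(names(counts), coord_cols)
  if (length(sample_cols) < 1) rlang::abort("no sample columns found")
  if (length(sample_cols) == 1) {
    rlang::warn("single sample: quantile normalization is the identity")
    return(counts)
  }
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  n_query <- nrow(m)
  if (!is.null(reference)) {
    if (!all(sample_cols %in% names(reference))) {
      rlang::abort("reference rows must carry the same sample columns")
    }
    m <- rbind(m, as.matrix(reference[, sample_cols, drop = FALSE]))
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  counts[, sample_cols] <- tibble::as_tibble(qn[seq_len(n_query), , drop = FALSE])
  counts
}

#' Correlate per-bin accessibility with focal-gene expression
#'
#' For each bin, the Spearman rank correlation between its (normalized)
#' counts and the focal gene's expression across matched samples, with a
#' two-sided p-value (t approximation on the rank correlation),
#' Benjamini-Hochberg adjustment across *all* bins in the window, and the
#' signed score `sign(rho) * -log10(padj)`. Samples are joined by ID and must
#' match exactly between the count matrix and the expression table. Constant
#' bins have an undefined correlation: `rho` is missing and `p = 1` by
#' convention (the bin stays in the grid and in the BH family).
#'
#' @param counts Bin count tibble (coordinates + sample columns), usually
#'   from [quantile_normalize()].
#' @param focal_expression Tibble with columns `sample`, `expression`.
#' @return A `bin_track` tibble: `chrom`, `start`, `end`, `bin`, `rho`, `p`,
#'   `padj`, `score`.
#' @export
correlate_bins <- function(counts, focal_expression) {
  stopifnot(all(c("sample", "expression") %in% names(focal_expression)))
  coord_cols <- intersect(c("chrom", "start", "end", "bin"), names(counts))
  sample_cols <- setdiff(names(counts), coord_cols)
  if (anyDuplicated(focal_expression$sample)) {
    rlang::abort("duplicate sample IDs in focal expression")
  }
  if (!setequal(sample_cols, focal_expression$sample)) {
    rlang::abort("sample IDs do not match between counts and focal expression")
  }
  if (length(sample_cols) < 4) rlang::abort("need >= 4 matched samples")
  x <- focal_expression$expression[match(sample_cols, focal_expression$sample)]
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  n <- length(x)

  rho <- spearman_rows_vs(m, x)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(rho)] <- 1
  p[!is.na(rho) & abs(rho) == 1] <- 0
  padj <- stats::p.adjust(p, method = "BH")
  score <- ifelse(is.na(rho), NA_real_, sign(rho) * -log10(padj))

  out <- dplyr::bind_cols(
    counts[, coord_cols, drop = FALSE],
    tibble::tibble(rho = rho, p = p, padj = padj, score = score)
  )
  attr(out, "n_samples") <- n
  class(out) <- c("bin_track", class(out))
  out
}

#' Select significant bins from a correlation track
#'
#' Bins with `padj < alpha`, split by correlation sign. The survey's default
#' threshold is `1e-4`; a relaxed cutoff of `5e-3` is conventional for
#' loop-anchor views.
#'
#' @param track A `bin_track` from [correlate_bins()].
#' @param alpha Adjusted-p threshold in `(0, 1)`.
#' @return The significant rows of `track` with a `direction` column
#'   (`"positive"`/`"negative"`).
#' @export
select_significant <- function(track, alpha = 1e-4) {
  if (!(alpha > 0 && alpha < 1)) rlang::abort("alpha must lie in (0, 1)")
  track |>
    dplyr::filter(!is.na(.data$rho), .data$padj < alpha) |>
    dplyr::mutate(direction = ifelse(.data$rho > 0, "positive", "negative")) |>
    tibble::as_tibble()
}

#' Upper-quartile composite of signal tracks
#'
#' Collapses several per-position signal tracks on a common grid into one
#' composite by taking the 75th percentile across tracks at each position
#' (linear-interpolation quantile convention).
#'
#' @param signal Matrix or data frame, positions x tracks (>= 1 track).
#' @param prob Quantile to take across tracks (default 0.75).
#' @return Numeric vector, one composite value per position.
#' @export
#' @examples
#' composite_track(matrix(c(0, 10, 20, 30), nrow = 1)) # 22.5
composite_track <- function(signal, prob = 0.75) {
  m <- as.matrix(signal)
  if (ncol(m) < 1 || nrow(m) < 1) rlang::abort("no signal tracks supplied")
  if (ncol(m) == 1) return(as.vector(m))
  unname(apply(m, 1, stats::quantile, probs = prob, type = 7))
}
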