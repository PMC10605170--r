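# Internal helpers shared across stages: deterministic seed substreams,
# interval arithmetic on 0-based half-open coordinates, and input checks.

# Deterministic 31-bit hash of a character label (used to derive per-stage
# RNG substreams from one user-facing seed).
hash_label <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a per-stage seed from a global seed
#'
#' One user-facing integer seed is expanded into independent substreams, one
#' per pipeline stage, so that each stage is reproducible in isolation and
#' inserting a new stage does not perturb the others.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "cohorts")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + hash_label(label)) %%
               2147483647)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# --- interval helpers (all coordinates 0-based half-open, BED convention) ---

check_intervals <- function(tbl, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    rlang::abort(sprintf("%s must have columns chrom, start, end", what))
  }
  if (nrow(tbl) > 0 && any(tbl$start >= tbl$end)) {
    rlang::abort(sprintf("%s contain ranges with start >= end", what))
  }
  if (nrow(tbl) > 0 && any(tbl$start < 0)) {
    rlang::abort(sprintf("%s contain negative coordinates", what))
  }
  invisible(tbl)
}

# Convert a half-open interval tibble to GRanges (1-based closed internally).
as_granges0 <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = as.character(tbl$chrom),
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

# Merge (reduce) intervals on a single chromosome; returns sorted disjoint
# start/end vectors. Used by the fast membership test below.
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# Vectorised test: does each half-open query [qs, qe) intersect any of a set
# of *sorted disjoint* intervals [ms, me)? O(log n) per query via findInterval.
# This is the hot path inside overlap permutations; correctness is checked
# against a quadratic oracle in the test suite.
overlaps_merged <- function(qs, qe, ms, me) {
  n <- length(ms)
  if (n == 0) return(rep(FALSE, length(qs)))
  idx <- findInterval(qs, ms)
  hit_cur <- idx >= 1 & me[pmax(idx, 1)] > qs
  nxt <- idx + 1
  hit_nxt <- nxt <= n & ms[pmin(nxt, n)] < qe
  hit_cur | hit_nxt
}

# Flag each query interval that intersects >= 1 subject interval (multi-chrom).
flag_overlaps <- function(query, subject) {
  check_intervals(query, "query intervals")
  check_intervals(subject, "subject intervals")
  flags <- rep(FALSE, nrow(query))
  if (nrow(subject) == 0 || nrow(query) == 0) return(flags)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- subject$chrom == ch
    if (!any(si)) next
    m <- merge_intervals(subject$start[si], subject$end[si])
    flags[qi] <- overlaps_merged(query$start[qi], query$end[qi], m$start, m$end)
  }
  flags
}

format_bp <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)
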