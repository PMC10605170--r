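# Plain-text I/O. All genomic files are BED-style TSVs with 0-based half-open
# coordinates; expression matrices are genes x samples TSVs with a header row
# of sample IDs and gene identifiers in the first column.

#' Parse a genomic window string
#'
#' Accepts `"chr5:89970000-91020000"` (commas in coordinates tolerated) or a
#' tibble that already has `chrom`, `start`, `end` columns, and returns a
#' one-row tibble of the half-open window.
#'
#' @param window Window string or interval tibble.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' parse_window("chr5:89,970,000-91,020,000")
parse_window <- function(window) {
  if (is.data.frame(window)) {
    check_intervals(window, "window")
    return(tibble::as_tibble(window[1, c("chrom", "start", "end")]))
  }
  stopifnot(is.character(window), length(window) == 1)
  m <- regmatches(window, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", window))[[1]]
  if (length(m) != 4) {
    rlang::abort("window must look like 'chr5:89970000-91020000'")
  }
  out <- tibble::tibble(
    chrom = m[2],
    start = as.numeric(gsub(",", "", m[3])),
    end = as.numeric(gsub(",", "", m[4]))
  )
  check_intervals(out, "window")
  out
}

#' Read and write cohort expression matrices
#'
#' A cohort file is a TSV with gene identifiers in the first column (`gene`)
#' and one numeric column per sample. The cohort label defaults to the file
#' name without extension.
#'
#' @param path File path.
#' @param cohort Optional cohort label; stored as the `"cohort"` attribute.
#' @return A tibble with a `gene` column and one column per sample.
#' @export
read_cohort <- function(path, cohort = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  attr(x, "cohort") <- cohort %||% sub("\\.[^.]*$", "", basename(path))
  x
}

#' @param expr Expression tibble (`gene` + sample columns).
#' @rdname read_cohort
#' @export
write_cohort <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read and write BED-style interval files
#'
#' `read_bed()` reads a headerless BED TSV; columns beyond the first three are
#' named from `extra_cols`. `write_bed()` writes the named columns (in BED
#' order) without a header.
#'
#' @param path File path.
#' @param extra_cols Names for columns after `chrom`, `start`, `end`
#'   (e.g. `c("name", "score")` for BED5).
#' @return A tibble of intervals.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  nm <- c("chrom", "start", "end", extra_cols)
  names(x)[seq_len(min(ncol(x), length(nm)))] <- nm[seq_len(min(ncol(x), length(nm)))]
  check_intervals(x, basename(path))
  x
}

#' @param intervals Interval tibble; written columns are
#'   `chrom`,`start`,`end` plus any in `extra_cols` that are present.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path, extra_cols = intersect(c("name", "score"), names(intervals))) {
  check_intervals(intervals, "intervals")
  cols <- c("chrom", "start", "end", extra_cols)
  readr::write_tsv(intervals[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write BEDPE loop files
#'
#' Chromatin loops as anchor pairs: `chrom1 start1 end1 chrom2 start2 end2`
#' plus optional `name` and `context` columns.
#'
#' @param path File path.
#' @return A tibble of anchor pairs.
#' @export
read_bedpe <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "context")
  names(x)[seq_len(min(ncol(x), length(nm)))] <- nm[seq_len(min(ncol(x), length(nm)))]
  for (side in 1:2) {
    iv <- tibble::tibble(chrom = x[[paste0("chrom", side)]],
                         start = x[[paste0("start", side)]],
                         end = x[[paste0("end", side)]])
    check_intervals(iv, sprintf("%s anchor %d", basename(path), side))
  }
  x
}

#' @param loops Loop tibble as returned by [read_bedpe()].
#' @rdname read_bedpe
#' @export
write_bedpe <- function(loops, path) {
  cols <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "context"), names(loops))
  readr::write_tsv(loops[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Reading is delegated to [fgsea::gmtPathways()] when fgsea is installed and
#' falls back to a minimal line parser otherwise; writing emits the standard
#' `name <tab> description <tab> gene...` lines.
#'
#' @param path File path.
#' @return A named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1))
}

#' @param sets Named list of character gene vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak-experiment manifest and its BED files
#'
#' The manifest is a TSV with columns `experiment`, `factor`, `context`,
#' `path` (paths relative to the manifest's directory). Each BED5 file holds
#' one experiment's scored peaks. Experiments can be score-filtered at import
#' (the upstream peak-inclusion filter).
#'
#' @param manifest Path to the manifest TSV.
#' @param min_score Optional minimum peak score retained at import.
#' @return A tibble of peaks with columns `experiment`, `factor`, `context`,
#'   `chrom`, `start`, `end`, `score`.
#' @export
read_peak_experiments <- function(manifest, min_score = NULL) {
  man <- readr::read_tsv(manifest, show_col_types = FALSE, progress = FALSE)
  need <- c("experiment", "factor", "context", "path")
  if (!all(need %in% names(man))) {
    rlang::abort("manifest must have columns experiment, factor, context, path")
  }
  base <- dirname(manifest)
  peaks <- purrr::pmap(man, function(experiment, factor, context, path, ...) {
    bed <- read_bed(file.path(base, path), extra_cols = c("name", "score"))
    dplyr::mutate(bed, experiment = experiment, factor = factor,
                  context = context)
  })
  out <- dplyr::bind_rows(peaks)
  if (!is.null(min_score)) out <- dplyr::filter(out, .data$score >= min_score)
  dplyr::select(out, "experiment", "factor", "context", "chrom", "start",
                "end", "score")
}

#' Serialize and restore the planted truth of a simulation
#'
#' The truth records every planted entity (regulators with target rank
#' correlations, bins with target rank correlations, factors with fold
#' enrichments) plus the seed, as JSON, and round-trips exactly.
#'
#' @param truth A `synthetic_truth` object from [simulate_cohorts()] etc.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$regulators <- tibble::as_tibble(x$regulators)
  x$bins <- tibble::as_tibble(x$bins)
  x$factors <- tibble::as_tibble(x$factors)
  structure(x, class = "synthetic_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
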