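# Pan-cancer co-expression survey: per-cohort Spearman correlation of every
# gene to the focal gene, z-transformation within cohort, and a per-gene
# median z across cohorts as the pan-cancer summary.

#' Spearman correlation of every gene to a focal gene within one cohort
#'
#' Computes, for each non-focal gene, the Spearman rank correlation between
#' its expression and the focal gene's expression across the cohort's
#' samples. Ties are handled by average ranks. Genes constant across samples
#' have an undefined rank correlation and are recorded as missing (`NA`),
#' never as zero.
#'
#' @param expr Expression tibble: a `gene` identifier column plus one numeric
#'   column per sample (>= 4 samples). No missing values: impute or drop rows
#'   upstream.
#' @param focal Focal gene identifier (must be present in `expr$gene`).
#' @param cohort Cohort label; defaults to the tibble's `"cohort"` attribute.
#' @return A tibble with columns `cohort`, `gene`, `rho` (focal gene
#'   excluded), one row per non-focal gene.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = c("F", "A"), s1 = c(1, 2), s2 = c(2, 1),
#'                        s3 = c(3, 4), s4 = c(4, 3))
#' spearman_to_focal(expr, "F") # rho = 0.6
spearman_to_focal <- function(expr, focal, cohort = NULL) {
  stopifnot(is.data.frame(expr))
  gene_col <- names(expr)[1]
  if (gene_col != "gene") names(expr)[1] <- "gene"
  if (anyDuplicated(expr$gene)) rlang::abort("gene identifiers must be unique")
  if (!focal %in% expr$gene) {
    rlang::abort(sprintf("focal gene '%s' not found in cohort", focal))
  }
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (ncol(m) < 4) rlang::abort("a cohort needs >= 4 samples")
  if (anyNA(m)) rlang::abort("expression matrix contains missing values")
  rownames(m) <- expr$gene
  cohort <- cohort %||% attr(expr, "cohort") %||% "cohort"

  rho <- spearman_rows_vs(m, m[focal, ])
  out <- tibble::tibble(cohort = cohort, gene = rownames(m), rho = rho)
  dplyr::filter(out, .data$gene != focal)
}

# Row-wise Spearman of a matrix against one vector: Pearson on average ranks.
# Zero-variance rows (or a zero-variance reference) yield NA.
spearman_rows_vs <- function(m, y) {
  n <- ncol(m)
  ry <- rank(y, ties.method = "average")
  rm <- t(apply(m, 1, rank, ties.method = "average"))
  ryc <- ry - mean(ry)
  rmc <- rm - rowMeans(rm)
  denom <- sqrt(rowSums(rmc^2) * sum(ryc^2))
  num <- as.vector(rmc %*% ryc)
  out <- ifelse(denom > 0, num / denom, NA_real_)
  unname(out)
}

#' Z-transform a cohort's correlation vector
#'
#' Standardizes the per-gene correlations within each cohort: the difference
#' between the observed and the mean correlation, divided by the standard
#' deviation (sample sd, `n - 1` denominator), with mean and sd taken over
#' all non-missing genes in that cohort. Missing correlations (constant
#' genes) are excluded from the mean/sd and stay missing in the output.
#'
#' @param cor_tbl Tibble from [spearman_to_focal()] (columns `cohort`,
#'   `gene`, `rho`); may hold several cohorts stacked.
#' @return The input with a `z` column appended.
#' @export
z_transform <- function(cor_tbl) {
  stopifnot(all(c("cohort", "gene", "rho") %in% names(cor_tbl)))
  cor_tbl |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_modify(function(d, key) {
      ok <- !is.na(d$rho)
      if (sum(ok) < 2) {
        rlang::abort(sprintf("cohort '%s' has < 2 non-missing correlations",
                             key$cohort))
      }
      s <- stats::sd(d$rho[ok])
      if (s == 0) {
        rlang::abort(sprintf(
          "cohort '%s' is degenerate: correlation sd is 0", key$cohort))
      }
      d$z <- (d$rho - mean(d$rho[ok])) / s
      d
    }) |>
    dplyr::ungroup()
}

#' Pan-cancer median z-score per gene
#'
#' Summarizes z-transformed correlations across cohorts as the per-gene
#' median of the available (non-missing) values, with the number of
#' contributing cohorts recorded and genes ranked by median z. Genes present
#' in fewer than `min_cohorts` cohorts are kept but flagged. Set
#' `use_raw_rho = TRUE` to take medians of the raw correlations instead of
#' the z-scores.
#'
#' @param z_tbl Stacked tibble from [z_transform()] across cohorts.
#' @param min_cohorts Minimum contributing cohorts for the flag (default 3).
#' @param use_raw_rho Median raw `rho` instead of median `z`.
#' @return A `pan_cancer_score` tibble: `gene`, `median_z`, `n_cohorts`,
#'   `pass_min_cohorts`, `rank` (1 = highest median z).
#' @export
pan_cancer_median <- function(z_tbl, min_cohorts = 3, use_raw_rho = FALSE) {
  value_col <- if (use_raw_rho) "rho" else "z"
  stopifnot(all(c("gene", value_col) %in% names(z_tbl)))
  out <- z_tbl |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      median_z = stats::median(.data[[value_col]], na.rm = TRUE),
      n_cohorts = sum(!is.na(.data[[value_col]])),
      .groups = "drop"
    )
  absent <- out$n_cohorts == 0
  if (any(absent)) {
    rlang::warn(sprintf("%d gene(s) missing from every cohort were excluded",
                        sum(absent)))
    out <- out[!absent, , drop = FALSE]
  }
  out <- out |>
    dplyr::mutate(pass_min_cohorts = .data$n_cohorts >= min_cohorts) |>
    dplyr::arrange(dplyr::desc(.data$median_z)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("pan_cancer_score", class(out))
  out
}

#' Signed response-rank score
#'
#' Ranks perturbation responses as `-log10(padj) * log2FC` (signed): large
#' positive for strongly up-regulated, large negative for strongly
#' down-regulated responses.
#'
#' @param log2fc Log2 fold change (signed).
#' @param padj Adjusted p-value in `(0, 1]`; a zero must be floored by the
#'   caller, otherwise the score is infinite and an error is raised.
#' @return Numeric score(s).
#' @export
#' @examples
#' response_rank_score(2, 0.01) # 4
response_rank_score <- function(log2fc, padj) {
  if (any(padj <= 0) || any(padj > 1)) {
    rlang::abort("padj must lie in (0, 1]; floor zeros before scoring")
  }
  -log10(padj) * log2fc
}
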