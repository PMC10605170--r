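# broom-style tidiers for the survey's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for survey results
#'
#' `tidy()` returns the per-unit table of a result object as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A result object (`bin_track`, `pan_cancer_score`,
#'   `factor_enrichment`, `gsea_result`, `gsea_integration`).
#' @param alpha Significance threshold used by summaries.
#' @param ... Unused.
#' @name regscan-tidiers
NULL

#' @rdname regscan-tidiers
#' @export
tidy.bin_track <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname regscan-tidiers
#' @export
glance.bin_track <- function(x, alpha = 1e-4, ...) {
  ok <- !is.na(x$rho)
  tibble::tibble(
    n_bins = nrow(x),
    n_samples = attr(x, "n_samples"),
    n_sig_positive = sum(ok & x$padj < alpha & x$rho > 0),
    n_sig_negative = sum(ok & x$padj < alpha & x$rho < 0),
    alpha = alpha
  )
}

#' @rdname regscan-tidiers
#' @export
tidy.pan_cancer_score <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname regscan-tidiers
#' @export
glance.pan_cancer_score <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 median_of_medians = stats::median(x$median_z),
                 max_cohorts = max(x$n_cohorts))
}

#' @rdname regscan-tidiers
#' @export
tidy.factor_enrichment <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname regscan-tidiers
#' @export
glance.factor_enrichment <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_factors = nrow(x),
                 n_significant = sum(x$padj < alpha),
                 top_factor = x$factor[which.max(x$score)],
                 alpha = alpha)
}

#' @rdname regscan-tidiers
#' @export
tidy.gsea_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname regscan-tidiers
#' @export
glance.gsea_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_sets = nrow(x),
                 n_significant = sum(x$padj < alpha, na.rm = TRUE),
                 n_perm = attr(x, "n_perm"),
                 weight = attr(x, "weight"),
                 alpha = alpha)
}

#' @rdname regscan-tidiers
#' @export
tidy.gsea_integration <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname regscan-tidiers
#' @export
glance.gsea_integration <- function(x, ...) {
  tibble::tibble(rho = attr(x, "rho"), p = attr(x, "p"),
                 n_factors = nrow(x), score_type = attr(x, "score_type"))
}
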