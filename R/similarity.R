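# Regulatory similarity and set enrichment: promoter-proximal target-set
# construction, binary occupancy matrix, Euclidean regulatory distances and
# PCA, preranked GSEA of target sets against the pan-cancer ranking, GO-style
# overrepresentation, and integration of GSEA scores with promoter signal.

#' Build TF target gene sets from promoter-proximal occupancy
#'
#' A gene is a target of a factor iff at least one of the factor's peaks
#' (across all its experiments) overlaps the promoter window
#' `[TSS - width, TSS + width)` and the mean score of those overlapping peaks
#' exceeds `min_score`. Missing strand information is treated as `'+'` with a
#' warning (the window is symmetric, so strand affects nothing but
#' provenance).
#'
#' @param peaks Peak tibble with `factor`, `chrom`, `start`, `end`, `score`.
#' @param tss TSS table: `gene`, `chrom`, `tss`, optional `strand` (one
#'   representative TSS per gene).
#' @param promoter_width Half-width of the promoter window in bp (default
#'   1000).
#' @param min_score Mean-score threshold (strict `>`, default 50).
#' @return Tibble `factor`, `gene`, `n_peaks`, `mean_score`, one row per
#'   factor-target pair passing the filter.
#' @export
build_target_sets <- function(peaks, tss, promoter_width = 1000, min_score = 50) {
  stopifnot(all(c("factor", "chrom", "start", "end", "score") %in% names(peaks)))
  stopifnot(all(c("gene", "chrom", "tss") %in% names(tss)))
  if (anyDuplicated(tss$gene)) rlang::abort("tss must have one row per gene")
  if (!"strand" %in% names(tss) || anyNA(tss$strand)) {
    rlang::warn("missing strand treated as '+' (promoter window is symmetric)")
  }
  promoters <- tibble::tibble(
    gene = tss$gene, chrom = tss$chrom,
    start = pmax(0, tss$tss - promoter_width),
    end = tss$tss + promoter_width
  )
  hits <- GenomicRanges::findOverlaps(as_granges0(peaks), as_granges0(promoters))
  if (length(hits) == 0) {
    return(tibble::tibble(factor = character(), gene = character(),
                          n_peaks = integer(), mean_score = numeric()))
  }
  tibble::tibble(
    factor = peaks$factor[S4Vectors::queryHits(hits)],
    gene = promoters$gene[S4Vectors::subjectHits(hits)],
    score = peaks$score[S4Vectors::queryHits(hits)]
  ) |>
    dplyr::group_by(.data$factor, .data$gene) |>
    dplyr::summarise(n_peaks = dplyr::n(), mean_score = mean(.data$score),
                     .groups = "drop") |>
    dplyr::filter(.data$mean_score > min_score)
}

#' Binary gene-by-factor occupancy matrix
#'
#' Converts target-set membership (long tibble from [build_target_sets()] or
#' a named list of gene sets) into a genes x factors 0/1 matrix over a gene
#' universe. Genes with zero variance across factors (all 0 or all 1) are
#' flagged in the `"zero_variance"` attribute.
#'
#' @param targets Long tibble with `factor`, `gene`, or a named list of gene
#'   vectors.
#' @param universe Optional character vector fixing the gene rows (defaults
#'   to all genes seen).
#' @return Tibble with a `gene` column and one 0/1 column per factor.
#' @export
regulatory_matrix <- function(targets, universe = NULL) {
  if (is.list(targets) && !is.data.frame(targets)) {
    targets <- purrr::imap(targets, ~ tibble::tibble(factor = .y, gene = .x)) |>
      dplyr::bind_rows()
  }
  stopifnot(all(c("factor", "gene") %in% names(targets)))
  universe <- universe %||% sort(unique(targets$gene))
  factors <- sort(unique(targets$factor))
  m <- matrix(0L, nrow = length(universe), ncol = length(factors),
              dimnames = list(universe, factors))
  keep <- targets$gene %in% universe
  m[cbind(match(targets$gene[keep], universe),
          match(targets$factor[keep], factors))] <- 1L
  out <- tibble::as_tibble(m, rownames = "gene")
  rs <- rowSums(m)
  attr(out, "zero_variance") <- universe[rs == 0 | rs == ncol(m)]
  out
}

#' Euclidean regulatory distance to the focal gene
#'
#' Distance between each gene's binary factor-occupancy row and the focal
#' gene's row; genes are ranked ascending by distance and assigned to
#' consecutive fixed-size distance bins (40 genes per bin by default). The
#' focal gene itself (distance 0) is excluded from the ranking unless
#' `include_focal = TRUE`.
#'
#' @param mat Binary occupancy tibble from [regulatory_matrix()].
#' @param focal Focal gene identifier (must be a row of `mat`).
#' @param bin_width Genes per distance bin (default 40).
#' @param include_focal Keep the focal gene in the ranking.
#' @return Tibble `gene`, `distance`, `rank`, `dist_bin`, ascending by
#'   distance (ties broken by gene name for determinism).
#' @export
gene_distance <- function(mat, focal, bin_width = 40, include_focal = FALSE) {
  stopifnot("gene" %in% names(mat))
  if (!focal %in% mat$gene) rlang::abort("focal gene not in the matrix")
  m <- as.matrix(mat[, setdiff(names(mat), "gene"), drop = FALSE])
  rownames(m) <- mat$gene
  fr <- m[focal, ]
  d <- sqrt(rowSums(sweep(m, 2, fr)^2))
  out <- tibble::tibble(gene = mat$gene, distance = unname(d))
  if (!include_focal) out <- dplyr::filter(out, .data$gene != focal)
  out |>
    dplyr::arrange(.data$distance, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  dist_bin = ceiling(.data$rank / bin_width))
}

#' Project genes onto the leading principal components of occupancy
#'
#' Removes zero-variance genes, centers the factor columns, and projects the
#' remaining genes onto PC1/PC2 of the covariance eigen-decomposition. Each
#' component's sign is fixed deterministically by making its
#' largest-magnitude loading positive. A rank-deficient matrix (rank < 2)
#' yields PC2 = 0 with a warning. Set `on_factors = TRUE` to project factors
#' on the basis of gene membership instead (the transposed analysis).
#'
#' @param mat Binary occupancy tibble from [regulatory_matrix()].
#' @param on_factors Project factors rather than genes.
#' @return Tibble `gene` (or `factor`), `PC1`, `PC2`; fraction of variance
#'   explained in the `"var_explained"` attribute.
#' @export
pca_project <- function(mat, on_factors = FALSE) {
  stopifnot("gene" %in% names(mat))
  m <- as.matrix(mat[, setdiff(names(mat), "gene"), drop = FALSE])
  rownames(m) <- mat$gene
  if (on_factors) m <- t(m)
  keep <- apply(m, 1, stats::var) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3) rlang::abort("need >= 3 rows after zero-variance removal")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- ncol(pc$rotation)
  scores <- pc$x
  for (j in seq_len(min(2, k))) {
    load <- pc$rotation[, j]
    # deterministic orientation: the first loading within tolerance of the
    # maximum magnitude is made positive (tolerance guards numeric ties)
    anchor <- which(abs(load) > max(abs(load)) - 1e-8)[1]
    if (load[anchor] < 0) scores[, j] <- -scores[, j]
  }
  pc2 <- if (k < 2 || pc$sdev[2] < 1e-12) {
    rlang::warn("occupancy matrix has rank < 2: PC2 reported as zero")
    rep(0, nrow(m))
  } else {
    scores[, 2]
  }
  out <- tibble::tibble(gene = rownames(m), PC1 = unname(scores[, 1]),
                        PC2 = unname(pc2))
  if (on_factors) names(out)[1] <- "factor"
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:min(2, k)]
  out
}

# Running-sum enrichment statistic for one hit set. `w_all` are the per-gene
# weights (|score|^exponent) in ranking order; `hit_idx` the (sorted) ranks of
# the set members; N the universe size. Max-deviation convention: hits climb
# by their normalized weight, misses fall uniformly.
gsea_es <- function(w_all, hit_idx, N) {
  k <- length(hit_idx)
  if (k == 0 || k >= N) return(NA_real_)
  w <- w_all[hit_idx]
  NR <- sum(w)
  if (NR == 0) { # all-zero scores in the set: fall back to equal weights
    w <- rep(1, k); NR <- k
  }
  miss_pen <- 1 / (N - k)
  cumw <- cumsum(w) / NR
  at_hit <- cumw - (hit_idx - seq_len(k)) * miss_pen
  before_hit <- at_hit - w / NR
  es_pos <- max(at_hit)
  es_neg <- min(before_hit)
  if (es_pos > -es_neg) es_pos else es_neg
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov-style GSEA against a ranked gene list:
#' the running sum climbs by `|score|^weight` (normalized to the in-set
#' total) at set members and falls uniformly at non-members; the enrichment
#' score (ES) is the maximum deviation. The null is `n_perm` random gene sets
#' of the same size (enumerated exhaustively when there are at most `n_perm`
#' distinct sets); NES divides ES by the mean magnitude of same-sign null
#' scores, the permutation p uses the same-sign null with the add-one
#' estimator, and FDR is BH across the supplied sets. Null distributions are
#' computed once per distinct set size. `weight = 0` gives the unweighted
#' statistic, which is invariant to monotone rescaling of the scores.
#'
#' @param scores Ranking scores: a tibble with `gene` and a score column
#'   (e.g. a [pan_cancer_median()] result, ranked by `median_z`), or a named
#'   numeric vector. Scores must be finite.
#' @param sets Named list of character gene vectors (see [read_gmt()]).
#' @param n_perm Null sets per set size (default 10000).
#' @param seed Optional seed.
#' @param weight Weighting exponent on `|score|` (default 1).
#' @return A `gsea_result` tibble: `set`, `size`, `ES`, `NES`, `p`, `padj`,
#'   `leading_edge` (list column).
#' @export
preranked_gsea <- function(scores, sets, n_perm = 10000, seed = NULL,
                           weight = 1) {
  if (is.data.frame(scores)) {
    score_col <- if ("median_z" %in% names(scores)) "median_z" else
      setdiff(names(scores), "gene")[1]
    v <- stats::setNames(scores[[score_col]], scores$gene)
  } else {
    v <- scores
  }
  if (anyNA(v) || any(!is.finite(v))) rlang::abort("ranking scores must be finite")
  stopifnot(is.list(sets), !is.null(names(sets)))
  # rank decreasing; ties broken by gene name for determinism
  o <- order(-v, names(v))
  v <- v[o]
  N <- length(v)
  w_all <- abs(v)^weight
  gene_rank <- stats::setNames(seq_len(N), names(v))

  hit_sets <- lapply(sets, function(s) sort(unname(gene_rank[intersect(s, names(v))])))
  sizes <- vapply(hit_sets, length, integer(1))
  if (any(sizes == 0)) {
    rlang::abort(sprintf("set(s) fully outside the ranked universe: %s",
                         paste(names(sets)[sizes == 0], collapse = ", ")))
  }
  if (any(sizes == N)) {
    rlang::warn("set spanning the whole universe: degenerate, ES reported NA")
  }

  # null ES values, one batch per distinct (non-degenerate) set size
  null_es <- lapply(unique(sizes[sizes < N]), function(k) {
    exhaustive <- lchoose(N, k) <= log(n_perm)
    es <- if (exhaustive) {
      utils::combn(N, k, function(ix) gsea_es(w_all, ix, N))
    } else {
      with_seed(if (is.null(seed)) NULL else substream_seed(seed, paste0("gsea_k", k)),
                vapply(seq_len(n_perm), function(i) {
                  gsea_es(w_all, sort(sample.int(N, k)), N)
                }, numeric(1)))
    }
    es
  })
  names(null_es) <- as.character(unique(sizes[sizes < N]))

  rows <- purrr::map2(names(sets), hit_sets, function(nm, hits) {
    k <- length(hits)
    if (k == N) {
      return(tibble::tibble(set = nm, size = k, ES = NA_real_, NES = NA_real_,
                            p = NA_real_, leading_edge = list(character())))
    }
    es <- gsea_es(w_all, hits, N)
    ns <- null_es[[as.character(k)]]
    same <- ns[sign(ns) == sign(es)]
    nes <- if (length(same) == 0) NA_real_ else es / mean(abs(same))
    # null values tied with the observed ES (up to float noise) count as >=
    p <- (1 + sum(abs(same) >= abs(es) - 1e-12)) / (length(same) + 1)
    # leading edge: members up to the extremum (positive ES) or after it
    w <- w_all[hits]; NR <- sum(w); if (NR == 0) { w <- rep(1, k); NR <- k }
    run <- cumsum(w) / NR - (hits - seq_len(k)) / (N - k)
    le <- if (es >= 0) hits[seq_len(which.max(run))] else
      hits[seq(which.min(run - w / NR), k)]
    tibble::tibble(set = nm, size = k, ES = es, NES = nes, p = p,
                   leading_edge = list(names(v)[le]))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(padj = stats::p.adjust(.data$p, method = "BH"),
                  .after = "p")
  attr(out, "n_perm") <- n_perm
  attr(out, "weight") <- weight
  class(out) <- c("gsea_result", class(out))
  out
}

#' Hypergeometric overrepresentation of annotation terms
#'
#' One-sided hypergeometric tail `P(X >= overlap)` of a gene set against each
#' annotation term, both intersected with a gene universe, BH-adjusted across
#' terms.
#'
#' @param genes Character vector, the query gene set.
#' @param annotations Named list of term gene vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of background genes (non-empty; query
#'   genes outside it are dropped).
#' @return Tibble `term`, `overlap`, `term_size`, `set_size`,
#'   `universe_size`, `p`, `padj`.
#' @export
overrepresentation <- function(genes, annotations, universe) {
  if (length(universe) == 0) rlang::abort("empty gene universe")
  universe <- unique(universe)
  genes <- intersect(genes, universe)
  U <- length(universe); k <- length(genes)
  rows <- purrr::imap(annotations, function(term_genes, nm) {
    m <- length(intersect(term_genes, universe))
    ov <- length(intersect(intersect(term_genes, universe), genes))
    p <- stats::phyper(ov - 1, m, U - m, k, lower.tail = FALSE)
    tibble::tibble(term = nm, overlap = ov, term_size = m, set_size = k,
                   universe_size = U, p = p)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(padj = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::arrange(.data$p)
}

#' Compare target-set overlaps and their score distributions
#'
#' Pairwise and full-intersection membership counts across target sets, plus
#' a two-sided rank-sum comparison of the pan-cancer score distribution of a
#' designated gene group (default: the full intersection) against all other
#' scored genes.
#'
#' @param sets Named list of >= 2 character gene vectors.
#' @param scores A [pan_cancer_median()] tibble (`gene`, `median_z`).
#' @param group Optional character vector of genes to compare; defaults to
#'   the intersection of all sets.
#' @return List with `pairwise` (tibble `set1`, `set2`, `overlap`),
#'   `intersection` (character vector), and `comparison` (one-row tibble with
#'   the rank-sum test, or `NULL` when skipped).
#' @export
set_overlap_compare <- function(sets, scores, group = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2)
  prs <- utils::combn(names(sets), 2)
  pairwise <- tibble::tibble(
    set1 = prs[1, ], set2 = prs[2, ],
    overlap = apply(prs, 2, function(p) length(intersect(sets[[p[1]]], sets[[p[2]]])))
  )
  full <- Reduce(intersect, sets)
  group <- group %||% full
  comparison <- NULL
  in_group <- scores$gene %in% group
  if (length(group) == 0 || !any(in_group)) {
    # nothing to compare
  } else if (all(in_group)) {
    rlang::warn("group covers all scored genes: comparison skipped")
  } else {
    wt <- stats::wilcox.test(scores$median_z[in_group],
                             scores$median_z[!in_group],
                             alternative = "two.sided", exact = FALSE)
    comparison <- tibble::tibble(
      n_group = sum(in_group), n_rest = sum(!in_group),
      median_group = stats::median(scores$median_z[in_group]),
      median_rest = stats::median(scores$median_z[!in_group]),
      statistic = unname(wt$statistic), p = wt$p.value
    )
  }
  list(pairwise = pairwise, intersection = full, comparison = comparison)
}

#' Correlate GSEA scores with promoter-proximal signal
#'
#' Combines each factor's GSEA result into `NES * -log10(FDR)` (the combined
#' score; `NES` or `ES` are selectable) and computes the Spearman rank
#' correlation against per-factor promoter signal, after an inner join on
#' factor names (dropped factors are listed in a warning; fewer than 4 shared
#' factors is an error).
#'
#' @param gsea A `gsea_result` tibble whose set names are factor labels.
#' @param promoter_signal Tibble `factor`, `signal`.
#' @param score_type `"combined"` (default), `"nes"`, or `"es"`.
#' @return A `gsea_integration` tibble `factor`, `gsea_score`, `signal`,
#'   `rank` (by gsea score); Spearman `rho`, `p` and `n` as attributes (see
#'   [glance.gsea_integration()]).
#' @export
gsea_signal_integration <- function(gsea, promoter_signal,
                                    score_type = c("combined", "nes", "es")) {
  score_type <- match.arg(score_type)
  stopifnot(all(c("factor", "signal") %in% names(promoter_signal)))
  g <- tibble::tibble(
    factor = gsea$set,
    gsea_score = switch(score_type,
                        combined = gsea$NES * -log10(gsea$padj),
                        nes = gsea$NES,
                        es = gsea$ES)
  )
  dropped <- c(setdiff(g$factor, promoter_signal$factor),
               setdiff(promoter_signal$factor, g$factor))
  if (length(dropped) > 0) {
    rlang::warn(sprintf("factors dropped by the join: %s",
                        paste(sort(dropped), collapse = ", ")))
  }
  joined <- dplyr::inner_join(g, promoter_signal, by = "factor") |>
    dplyr::filter(is.finite(.data$gsea_score), is.finite(.data$signal))
  if (nrow(joined) < 4) rlang::abort("fewer than 4 shared factors")
  ct <- stats::cor.test(joined$gsea_score, joined$signal, method = "spearman",
                        exact = FALSE)
  out <- joined |>
    dplyr::arrange(dplyr::desc(.data$gsea_score)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "rho") <- unname(ct$estimate)
  attr(out, "p") <- ct$p.value
  attr(out, "score_type") <- score_type
  class(out) <- c("gsea_integration", class(out))
  out
}
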