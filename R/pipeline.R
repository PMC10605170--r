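# End-to-end pipeline: declarative config, input validation, stage
# orchestration in dependency order, deterministic per-stage seeding, and a
# run manifest with file hashes.

#' Pipeline run configuration
#'
#' Collects every input path and tunable of the survey. Numeric defaults are
#' the survey's conventions: significance threshold `1e-4` (relaxed `5e-3`),
#' 100 overlap permutations per experiment, 10,000 draws for the factor-level
#' permutation test, 10,000 GSEA permutations.
#'
#' @param focal Focal gene identifier.
#' @param cohort_dir Directory of per-cohort expression TSVs.
#' @param atac_counts Bin count TSV (coordinates + sample columns).
#' @param atac_expression Focal-expression TSV (`sample`, `expression`).
#' @param peak_manifest Peak manifest TSV (see [read_peak_experiments()]).
#' @param loops BEDPE loop file.
#' @param target_sets GMT file of factor target sets.
#' @param tss TSS table TSV (`gene`, `chrom`, `tss`, `strand`).
#' @param outdir Output directory.
#' @param window Survey window (string or tibble).
#' @param bin_size Bin width in bp.
#' @param alpha,alpha_relaxed Adjusted-p thresholds in (0, 1).
#' @param n_perm Overlap permutations per experiment.
#' @param n_null Factor-level null draws.
#' @param gsea_n_perm GSEA permutations.
#' @param min_cohorts Minimum cohorts for the pan-cancer flag.
#' @param promoter_width Promoter half-width in bp.
#' @param seed Integer seed; stages use deterministic substreams.
#' @return A `run_config` list.
#' @export
run_config <- function(focal, cohort_dir, atac_counts, atac_expression,
                       peak_manifest, loops, target_sets, tss, outdir,
                       window = "chr5:89970000-91020000", bin_size = 100,
                       alpha = 1e-4, alpha_relaxed = 5e-3,
                       n_perm = 100, n_null = 10000, gsea_n_perm = 10000,
                       min_cohorts = 3, promoter_width = 1000, seed = 1) {
  for (a in c(alpha, alpha_relaxed)) {
    if (!(is.numeric(a) && a > 0 && a < 1)) {
      rlang::abort("alpha thresholds must lie in (0, 1)", class = "regscan_validation_error")
    }
  }
  if (!(is.numeric(seed) && seed == round(seed))) {
    rlang::abort("seed must be an integer", class = "regscan_validation_error")
  }
  structure(list(
    focal = focal, cohort_dir = cohort_dir, atac_counts = atac_counts,
    atac_expression = atac_expression, peak_manifest = peak_manifest,
    loops = loops, target_sets = target_sets, tss = tss, outdir = outdir,
    window = parse_window(window), bin_size = bin_size,
    alpha = alpha, alpha_relaxed = alpha_relaxed,
    n_perm = n_perm, n_null = n_null, gsea_n_perm = gsea_n_perm,
    min_cohorts = min_cohorts, promoter_width = promoter_width,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Validate pipeline input files
#'
#' Per-file format checks (existence, BED coordinate sanity, TSV headers and
#' sample-ID consistency between the count matrix and the expression table,
#' GMT structure, BEDPE anchor validity). Failures are reported, not raised.
#'
#' @param config A [run_config()].
#' @return Tibble `file`, `check`, `ok`, `message`, one row per check.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  add <- function(file, check, ok, message = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      file = file, check = check, ok = ok, message = message)
  }
  try_check <- function(file, check, expr) {
    res <- tryCatch({ force(expr); list(TRUE, "") },
                    error = function(e) list(FALSE, conditionMessage(e)),
                    warning = function(w) list(TRUE, conditionMessage(w)))
    add(file, check, res[[1]], res[[2]])
  }

  cohort_files <- if (dir.exists(config$cohort_dir)) {
    list.files(config$cohort_dir, pattern = "\\.tsv$", full.names = TRUE)
  } else character(0)
  add(config$cohort_dir, "cohort directory", length(cohort_files) > 0,
      if (length(cohort_files) == 0) "no cohort TSVs found" else "")
  for (f in cohort_files) {
    try_check(f, "cohort matrix", {
      x <- read_cohort(f)
      if (!config$focal %in% x$gene) stop("focal gene missing")
      if (ncol(x) < 5) stop("fewer than 4 samples")
      if (anyNA(x)) stop("missing values")
    })
  }
  try_check(config$atac_counts, "bin count matrix", {
    x <- readr::read_tsv(config$atac_counts, n_max = 5, show_col_types = FALSE,
                         progress = FALSE)
    if (!all(c("chrom", "start", "end") %in% names(x))) stop("missing coordinate columns")
    check_intervals(x, basename(config$atac_counts))
  })
  try_check(config$atac_expression, "focal expression", {
    x <- readr::read_tsv(config$atac_expression, show_col_types = FALSE,
                         progress = FALSE)
    if (!all(c("sample", "expression") %in% names(x))) stop("missing columns")
    hdr <- names(readr::read_tsv(config$atac_counts, n_max = 1,
                                 show_col_types = FALSE, progress = FALSE))
    samples <- setdiff(hdr, c("chrom", "start", "end", "bin"))
    if (!setequal(samples, x$sample)) {
      warning("sample IDs mismatch between count matrix and expression table")
    }
  })
  try_check(config$peak_manifest, "peak manifest", {
    invisible(read_peak_experiments(config$peak_manifest))
  })
  try_check(config$loops, "loops BEDPE", invisible(read_bedpe(config$loops)))
  try_check(config$target_sets, "GMT sets", {
    s <- read_gmt(config$target_sets)
    if (length(s) == 0 || is.null(names(s))) stop("no named sets")
  })
  try_check(config$tss, "TSS table", {
    x <- readr::read_tsv(config$tss, show_col_types = FALSE, progress = FALSE)
    if (!all(c("gene", "chrom", "tss") %in% names(x))) stop("missing columns")
  })
  dplyr::bind_rows(rows)
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "regscan_stage_error", stage = stage)
  })
}

#' Run the full survey pipeline
#'
#' Executes the stages in dependency order — co-expression survey and
#' chromatin survey, then overlap enrichment and loop intersection on the
#' significant bins, then regulatory distance / PCA / preranked GSEA on the
#' target sets, then GSEA-promoter-signal integration — writing each stage's
#' outputs before dependents run. Identical config and seed reproduce
#' byte-identical outputs. Failures abort naming the failing stage.
#'
#' @param config A [run_config()].
#' @return The run manifest: tibble `stage`, `output`, `md5`, `seed`, also
#'   written to `manifest.tsv` (with a `params.json` parameter snapshot)
#'   in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rep_ok <- validate_inputs(config)
  if (!all(rep_ok$ok)) {
    bad <- rep_ok[!rep_ok$ok, ]
    rlang::abort(sprintf("input validation failed: %s",
                         paste(bad$file, bad$message, sep = ": ", collapse = "; ")),
                 class = "regscan_validation_error")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, path, seed = NA_integer_) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, output = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed)
  }
  out <- function(name) file.path(config$outdir, name)

  # --- stage: co-expression survey ---
  scores <- run_stage("coexpr", {
    files <- list.files(config$cohort_dir, pattern = "\\.tsv$", full.names = TRUE)
    zs <- purrr::map(files, function(f) {
      read_cohort(f) |>
        spearman_to_focal(config$focal) |>
        z_transform()
    }) |> dplyr::bind_rows()
    sc <- pan_cancer_median(zs, min_cohorts = config$min_cohorts)
    wide <- tidyr::pivot_wider(zs, id_cols = "gene", names_from = "cohort",
                               names_prefix = "z_", values_from = "z")
    tab <- dplyr::left_join(sc, wide, by = "gene")
    readr::write_tsv(tab, out("pan_cancer_scores.tsv"), progress = FALSE)
    sc
  })
  note("coexpr", out("pan_cancer_scores.tsv"))

  # --- stage: chromatin survey ---
  sig <- run_stage("chromatin", {
    counts <- readr::read_tsv(config$atac_counts, show_col_types = FALSE,
                              progress = FALSE)
    fx <- readr::read_tsv(config$atac_expression, show_col_types = FALSE,
                          progress = FALSE)
    track <- counts |>
      quantile_normalize() |>
      correlate_bins(fx)
    readr::write_tsv(track, out("bin_track.tsv"), progress = FALSE)
    sig <- select_significant(track, config$alpha)
    sig_rel <- select_significant(track, config$alpha_relaxed)
    for (dir_ in c("positive", "negative")) {
      write_bed(dplyr::filter(sig, .data$direction == dir_),
                out(sprintf("sig_bins_%s.bed", dir_)), extra_cols = NULL)
    }
    write_bed(sig_rel, out("sig_bins_relaxed.bed"), extra_cols = NULL)
    sig
  })
  for (f in c("bin_track.tsv", "sig_bins_positive.bed", "sig_bins_negative.bed",
              "sig_bins_relaxed.bed")) note("chromatin", out(f))

  # --- stage: overlap enrichment + loop intersection ---
  enr_seed <- substream_seed(config$seed, "enrich")
  run_stage("enrich", {
    peaks <- read_peak_experiments(config$peak_manifest)
    loops <- read_bedpe(config$loops)
    for (dir_ in c("positive", "negative")) {
      bins <- dplyr::filter(sig, .data$direction == dir_)
      path <- out(sprintf("factor_enrichment_%s.tsv", dir_))
      if (nrow(bins) == 0) {
        rlang::inform(sprintf("no %s significant bins: enrichment skipped", dir_))
        readr::write_tsv(factor_enrichment_empty(), path, progress = FALSE)
        next
      }
      res <- overlap_results(peaks, bins, config$window,
                             n_perm = config$n_perm, seed = enr_seed)
      fe <- factor_enrichment(res, n_null = config$n_null, seed = enr_seed)
      readr::write_tsv(fe, path, progress = FALSE)
    }
    flagged <- loop_intersect(
      dplyr::select(sig, "chrom", "start", "end", "bin", "rho", "padj",
                    "direction"), loops)
    readr::write_tsv(flagged, out("sig_bins_loop_anchors.tsv"), progress = FALSE)
  })
  for (f in c("factor_enrichment_positive.tsv", "factor_enrichment_negative.tsv",
              "sig_bins_loop_anchors.tsv")) note("enrich", out(f), enr_seed)

  # --- stage: regulatory distance / PCA / GSEA ---
  gsea_seed <- substream_seed(config$seed, "gsea")
  gsea <- run_stage("distance_gsea", {
    sets <- read_gmt(config$target_sets)
    mat <- regulatory_matrix(sets, universe = union(scores$gene, config$focal))
    dist_tbl <- gene_distance(mat, config$focal)
    dist_tbl <- dplyr::left_join(
      dist_tbl, dplyr::select(scores, "gene", "median_z"), by = "gene")
    readr::write_tsv(dist_tbl, out("regulatory_distance.tsv"), progress = FALSE)
    pcs <- pca_project(mat)
    readr::write_tsv(pcs, out("regulatory_pca.tsv"), progress = FALSE)
    gsea <- preranked_gsea(scores, sets, n_perm = config$gsea_n_perm,
                           seed = gsea_seed)
    flat <- dplyr::mutate(gsea, leading_edge = vapply(
      .data$leading_edge, paste, "", collapse = ","))
    readr::write_tsv(flat, out("gsea_results.tsv"), progress = FALSE)
    gsea
  })
  for (f in c("regulatory_distance.tsv", "regulatory_pca.tsv",
              "gsea_results.tsv")) note("distance_gsea", out(f), gsea_seed)

  # --- stage: GSEA x promoter-signal integration ---
  run_stage("integrate", {
    peaks <- read_peak_experiments(config$peak_manifest)
    tss <- readr::read_tsv(config$tss, show_col_types = FALSE, progress = FALSE)
    ft <- tss[tss$gene == config$focal, ]
    if (nrow(ft) != 1) stop("focal gene missing from the TSS table")
    prom <- tibble::tibble(chrom = ft$chrom,
                           start = max(0, ft$tss - config$promoter_width),
                           end = ft$tss + config$promoter_width)
    at_prom <- flag_overlaps(peaks[, c("chrom", "start", "end")], prom)
    signal <- peaks[at_prom, ] |>
      dplyr::group_by(.data$factor) |>
      dplyr::summarise(signal = mean(.data$score), .groups = "drop")
    # factors with no promoter-proximal peak carry zero signal
    signal <- tibble::tibble(factor = unique(peaks$factor)) |>
      dplyr::left_join(signal, by = "factor") |>
      dplyr::mutate(signal = dplyr::coalesce(.data$signal, 0))
    integ <- suppressWarnings(gsea_signal_integration(gsea, signal))
    readr::write_tsv(integ, out("integration.tsv"), progress = FALSE)
    readr::write_tsv(tibble::tibble(rho = attr(integ, "rho"),
                                    p = attr(integ, "p"),
                                    n_factors = nrow(integ)),
                     out("integration_summary.tsv"), progress = FALSE)
  })
  note("integrate", out("integration.tsv"))
  note("integrate", out("integration_summary.tsv"))

  params <- config
  params$window <- sprintf("%s:%d-%d", config$window$chrom,
                           config$window$start, config$window$end)
  jsonlite::write_json(
    c(unclass(params), list(package_version = as.character(utils::packageVersion("regscan")))),
    out("params.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  man <- dplyr::bind_rows(manifest)
  readr::write_tsv(man, out("manifest.tsv"), progress = FALSE)
  class(man) <- c("run_manifest", class(man))
  man
}

factor_enrichment_empty <- function() {
  tibble::tibble(factor = character(), n_experiments = integer(),
                 sum_obs = numeric(), sum_exp = numeric(),
                 aggregate = numeric(), p = numeric(), padj = numeric(),
                 z = numeric(), score = numeric())
}
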