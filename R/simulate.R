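# Synthetic-data generator. Every downstream stage is tested against data
# with planted structure: regulator genes at specified rank correlations with
# the focal gene, accessibility bins whose counts track focal expression,
# peak-experiment collections with planted overlap enrichment, and target
# gene sets with planted co-membership. Rank correlations are planted through
# a Gaussian copula: a latent bivariate normal is drawn with the Pearson
# correlation whose Spearman image matches the target
# (rho_pearson = 2 sin(pi * rho_spearman / 6)), then pushed through monotone
# transforms, which leave Spearman correlations untouched.

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: multiple tumor
#' cohorts with a focal gene and planted regulators, a 1 Mb survey window
#' tiled into 100 bp bins with planted accessibility-correlated bins, and
#' factor-labelled peak experiments with planted overlap enrichment.
#'
#' Defaults mirror the scale of the real survey: a 1 Mb window
#' (`chr5:89970000-91020000`) at 100 bp (10,500 bins), 409 accessibility
#' samples, cohorts of 100 tumors, and a contiguous 20-bin planted element at
#' the window center (a gene-internal regulatory element whose accessibility
#' tracks focal expression at rank correlation 0.8).
#'
#' @param n_cohorts Number of expression cohorts.
#' @param samples_per_cohort Samples per cohort (>= 4).
#' @param n_genes Genes per cohort (including the focal gene).
#' @param focal_gene Identifier of the focal gene.
#' @param planted_regulators Tibble or data frame with columns `gene`,
#'   `rho` (target Spearman correlation with the focal gene, in `[-1, 1]`).
#' @param window Survey window (string or interval tibble, half-open).
#' @param bin_size Bin width in bp; must divide the window length.
#' @param n_atac_samples Number of accessibility samples.
#' @param planted_bins Tibble with columns `bin` (1-based index into the bin
#'   grid) and `rho` (target Spearman correlation with focal expression).
#' @param n_factors Number of peak-experiment factors.
#' @param experiments_per_factor Experiments per factor.
#' @param planted_factors Tibble with columns `factor` (label) and `fold`
#'   (overlap fold enrichment, >= 1).
#' @param peaks_per_experiment Peaks placed per experiment.
#' @param peak_width Peak width in bp.
#' @param target_set_size Genes per simulated target set.
#' @param co_membership Fraction of the focal neighborhood (planted
#'   regulators + focal gene) shared by planted factors' target sets.
#' @param n_loops Number of simulated chromatin loops.
#' @param measurement_noise Extra Gaussian noise (sd, latent scale) added to
#'   planted regulator genes; incompatible with `|rho| = 1`.
#' @param seed Integer seed; expanded into per-component substreams.
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_cohorts = 2, samples_per_cohort = 30, n_genes = 100,
#'                   window = "chrS:0-100000", n_atac_samples = 40, seed = 1)
sim_config <- function(n_cohorts = 8,
                       samples_per_cohort = 100,
                       n_genes = 2000,
                       focal_gene = "FOCAL",
                       planted_regulators = default_regulators(),
                       window = "chr5:89970000-91020000",
                       bin_size = 100,
                       n_atac_samples = 409,
                       planted_bins = NULL,
                       n_factors = 20,
                       experiments_per_factor = 10,
                       planted_factors = tibble::tibble(factor = "TF_PLANTED",
                                                        fold = 3),
                       peaks_per_experiment = 300,
                       peak_width = 300,
                       target_set_size = 100,
                       co_membership = 0.8,
                       n_loops = 50,
                       measurement_noise = 0,
                       seed = 1) {
  window <- parse_window(window)
  win_len <- window$end - window$start
  n_bins <- floor(win_len / bin_size)
  if (is.null(planted_bins)) {
    center <- floor(n_bins / 2)
    planted_bins <- tibble::tibble(bin = center + seq_len(20) - 10, rho = 0.8)
  }
  planted_regulators <- tibble::as_tibble(planted_regulators)
  planted_bins <- tibble::as_tibble(planted_bins)
  planted_factors <- tibble::as_tibble(planted_factors)

  cfg <- structure(list(
    n_cohorts = n_cohorts, samples_per_cohort = samples_per_cohort,
    n_genes = n_genes, focal_gene = focal_gene,
    planted_regulators = planted_regulators,
    window = window, bin_size = bin_size, n_atac_samples = n_atac_samples,
    planted_bins = planted_bins,
    n_factors = n_factors, experiments_per_factor = experiments_per_factor,
    planted_factors = planted_factors,
    peaks_per_experiment = peaks_per_experiment, peak_width = peak_width,
    target_set_size = target_set_size, co_membership = co_membership,
    n_loops = n_loops, measurement_noise = measurement_noise,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

default_regulators <- function() {
  tibble::tibble(
    gene = sprintf("REG_%02d", 1:10),
    rho = rep(c(0.6, -0.6), each = 5)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$samples_per_cohort < 4) {
    rlang::abort("samples_per_cohort must be >= 4")
  }
  if (nrow(cfg$planted_regulators) > 0) {
    if (!all(c("gene", "rho") %in% names(cfg$planted_regulators))) {
      rlang::abort("planted_regulators needs columns gene, rho")
    }
    if (any(abs(cfg$planted_regulators$rho) > 1)) {
      rlang::abort("planted regulator target rho must lie in [-1, 1]")
    }
    if (cfg$measurement_noise > 0 &&
        any(abs(cfg$planted_regulators$rho) == 1)) {
      rlang::abort(paste("|target_rho| = 1 with added measurement noise is",
                         "unsatisfiable"))
    }
  }
  win_len <- cfg$window$end - cfg$window$start
  if (win_len %% cfg$bin_size != 0) {
    rlang::abort("bin_size must divide the window length")
  }
  n_bins <- win_len / cfg$bin_size
  if (nrow(cfg$planted_bins) > 0) {
    if (any(abs(cfg$planted_bins$rho) > 1)) {
      rlang::abort("planted bin target rho must lie in [-1, 1]")
    }
    if (any(cfg$planted_bins$bin < 1 | cfg$planted_bins$bin > n_bins)) {
      rlang::abort("planted bin index outside the bin grid")
    }
  }
  if (nrow(cfg$planted_factors) > 0 && any(cfg$planted_factors$fold < 1)) {
    rlang::abort("fold_enrichment must be >= 1")
  }
  if (cfg$target_set_size > cfg$n_genes) {
    rlang::abort("requested target set size exceeds the gene universe")
  }
  cfg
}

# Spearman target -> latent Pearson correlation for a bivariate Gaussian.
copula_r <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Latent values correlated with z at Spearman target rho_s. |rho_s| = 1 maps
# the latent exactly (perfect monotone copy), so the empirical Spearman
# correlation is exactly +/-1.
correlated_latent <- function(z, rho_s) {
  if (abs(rho_s) == 1) return(sign(rho_s) * z)
  r <- copula_r(rho_s)
  r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
}

#' Simulate expression cohorts with planted regulators
#'
#' Per cohort, draws a latent standard-normal focal signal per sample, plants
#' each regulator's latent at the copula correlation matching its target
#' Spearman rho, leaves all other genes independent, and exponentiates to a
#' positive expression scale (monotone, so rank correlations are preserved).
#'
#' @param config A [sim_config()].
#' @return A list with `cohorts` (named list of expression tibbles, `gene` +
#'   sample columns) and `truth` (a `synthetic_truth`).
#' @export
simulate_cohorts <- function(config) {
  cfg <- validate_sim_config(config)
  genes <- union(cfg$focal_gene, cfg$planted_regulators$gene)
  n_null <- cfg$n_genes - length(genes)
  if (n_null < 0) rlang::abort("n_genes smaller than focal + planted genes")
  genes <- c(genes, sprintf("NULL_%04d", seq_len(n_null)))

  cohorts <- lapply(seq_len(cfg$n_cohorts), function(ci) {
    with_seed(substream_seed(cfg$seed, paste0("cohort_", ci)), {
      n <- cfg$samples_per_cohort
      zf <- stats::rnorm(n)
      mu <- stats::runif(length(genes), 1, 6)
      names(mu) <- genes
      m <- matrix(0, nrow = length(genes), ncol = n,
                  dimnames = list(genes, sprintf("S%03d_%02d", seq_len(n), ci)))
      m[cfg$focal_gene, ] <- zf
      for (i in seq_len(nrow(cfg$planted_regulators))) {
        g <- cfg$planted_regulators$gene[i]
        lat <- correlated_latent(zf, cfg$planted_regulators$rho[i])
        if (cfg$measurement_noise > 0) {
          lat <- lat + stats::rnorm(n, sd = cfg$measurement_noise)
        }
        m[g, ] <- lat
      }
      null_genes <- setdiff(genes, c(cfg$focal_gene, cfg$planted_regulators$gene))
      if (length(null_genes) > 0) {
        m[null_genes, ] <- stats::rnorm(length(null_genes) * n)
      }
      expr <- exp(1.5 * m + mu)
      tibble::as_tibble(expr, rownames = "gene")
    })
  })
  names(cohorts) <- sprintf("cohort_%02d", seq_len(cfg$n_cohorts))
  for (i in seq_along(cohorts)) attr(cohorts[[i]], "cohort") <- names(cohorts)[i]

  truth <- structure(list(
    regulators = cfg$planted_regulators,
    bins = cfg$planted_bins,
    factors = cfg$planted_factors,
    seed = cfg$seed
  ), class = "synthetic_truth")
  list(cohorts = cohorts, truth = truth)
}

#' Simulate binned accessibility counts tracking focal expression
#'
#' Produces a bins x samples matrix of non-negative integer counts over the
#' configured window. Planted bins' latent signal is copula-correlated with
#' the *normal scores of the ranks* of the supplied focal expression, so the
#' planted Spearman correlation holds for whatever expression values are
#' passed in; counts are `round(exp(latent))` (positive, overdispersed,
#' monotone in the latent). Null bins are independent lognormal counts.
#'
#' Because rounding to integer counts perturbs ranks, planting `|rho| = 1` is
#' unsatisfiable here and is rejected.
#'
#' @param config A [sim_config()].
#' @param focal_expression Tibble with columns `sample`, `expression` (one row
#'   per accessibility sample).
#' @return A tibble: `chrom`, `start`, `end`, `bin`, then one count column per
#'   sample.
#' @export
simulate_atac <- function(config, focal_expression) {
  cfg <- validate_sim_config(config)
  stopifnot(all(c("sample", "expression") %in% names(focal_expression)))
  if (nrow(cfg$planted_bins) > 0 && any(abs(cfg$planted_bins$rho) == 1)) {
    rlang::abort(paste("planted bin |target_rho| = 1 is unsatisfiable:",
                       "integer rounding of counts adds noise"))
  }
  grid <- make_bins(cfg$window, cfg$bin_size)
  n_bins <- nrow(grid)
  x <- focal_expression$expression
  n <- length(x)
  if (stats::sd(x) == 0) {
    zf <- rep(0, n) # degenerate: correlations undefined downstream
  } else {
    zf <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  }
  with_seed(substream_seed(cfg$seed, "atac"), {
    mu <- stats::runif(n_bins, log(20), log(300))
    lat <- matrix(stats::rnorm(n_bins * n), nrow = n_bins)
    for (i in seq_len(nrow(cfg$planted_bins))) {
      b <- cfg$planted_bins$bin[i]
      lat[b, ] <- correlated_latent(zf, cfg$planted_bins$rho[i])
    }
    counts <- round(exp(0.6 * lat + mu))
    dimnames(counts) <- list(NULL, focal_expression$sample)
    dplyr::bind_cols(grid, tibble::as_tibble(counts))
  })
}

#' Simulate factor-labelled peak experiments with planted overlap enrichment
#'
#' Per factor, draws `experiments_per_factor` scored peak sets over the
#' window. Each peak's midpoint falls inside the union of `significant_bins`
#' with probability `min(1, fold * f)` where `f` is the fraction of the
#' window covered by those bins (fold 1 reproduces uniform placement), and
#' uniformly over the complement otherwise. Scores are lognormal,
#' MACS2-like.
#'
#' @param config A [sim_config()].
#' @param significant_bins Interval tibble of bins the planted factors should
#'   be enriched in (non-empty).
#' @return Peak tibble with columns `experiment`, `factor`, `context`,
#'   `chrom`, `start`, `end`, `score`.
#' @export
simulate_peak_experiments <- function(config, significant_bins) {
  cfg <- validate_sim_config(config)
  check_intervals(significant_bins, "significant_bins")
  if (nrow(significant_bins) == 0) rlang::abort("significant_bins is empty")
  win <- cfg$window
  sig <- merge_intervals(significant_bins$start, significant_bins$end)
  sig_len <- sum(sig$end - sig$start)
  f0 <- sig_len / (win$end - win$start)

  factors <- sprintf("TF_%03d", seq_len(cfg$n_factors))
  if (nrow(cfg$planted_factors) > 0) {
    factors[seq_len(nrow(cfg$planted_factors))] <- cfg$planted_factors$factor
  }
  folds <- stats::setNames(rep(1, length(factors)), factors)
  if (nrow(cfg$planted_factors) > 0) {
    folds[cfg$planted_factors$factor] <- cfg$planted_factors$fold
  }

  with_seed(substream_seed(cfg$seed, "peaks"), {
    out <- purrr::map(factors, function(fac) {
      q <- folds[[fac]] * f0
      if (q > 1) {
        rlang::warn(sprintf(
          "fold %.2f for %s exceeds full coverage of significant bins; clamped",
          folds[[fac]], fac))
        q <- 1
      }
      purrr::map(seq_len(cfg$experiments_per_factor), function(ei) {
        k <- cfg$peaks_per_experiment
        in_sig <- stats::runif(k) < q
        mid <- numeric(k)
        if (any(in_sig)) {
          # uniform over the union of significant intervals
          widths <- sig$end - sig$start
          iv <- sample.int(length(widths), sum(in_sig), replace = TRUE,
                           prob = widths)
          mid[in_sig] <- sig$start[iv] + stats::runif(sum(in_sig)) * widths[iv]
        }
        if (any(!in_sig)) {
          # rejection-sample the complement of the significant union
          need <- sum(!in_sig)
          got <- numeric(0)
          while (length(got) < need) {
            cand <- stats::runif(2 * need + 10, win$start, win$end)
            keep <- !overlaps_merged(cand, cand + 1e-9, sig$start, sig$end)
            got <- c(got, cand[keep])
          }
          mid[!in_sig] <- got[seq_len(need)]
        }
        start <- pmax(win$start, floor(mid - cfg$peak_width / 2))
        end <- pmin(win$end, start + cfg$peak_width)
        tibble::tibble(
          experiment = sprintf("%s_exp%02d", fac, ei),
          factor = fac, context = "synthetic",
          chrom = win$chrom, start = start, end = end,
          score = round(stats::rlnorm(k, log(80), 0.7), 1)
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    out
  })
}

#' Simulate TF target gene sets, a gene universe, and chromatin loops
#'
#' Planted factors share a `co_membership` fraction of the focal gene's
#' neighborhood (the planted regulators plus the focal gene); all remaining
#' members, and all members of null factors' sets, are drawn uniformly from
#' the universe. Loops are emitted as BEDPE anchor pairs within the window;
#' when bins are planted, the first loop's second anchor is placed exactly on
#' the first planted bin, so loop-anchor intersection has a known positive.
#'
#' @param config A [sim_config()].
#' @return A list with `sets` (named list of gene vectors), `universe`
#'   (character), `loops` (BEDPE tibble), and `tss` (gene TSS table used by
#'   promoter-based stages; the focal gene's TSS sits at the window center).
#' @export
simulate_target_sets <- function(config) {
  cfg <- validate_sim_config(config)
  genes <- union(cfg$focal_gene, cfg$planted_regulators$gene)
  n_null <- cfg$n_genes - length(genes)
  universe <- c(genes, sprintf("NULL_%04d", seq_len(max(0, n_null))))
  neighborhood <- union(cfg$focal_gene, cfg$planted_regulators$gene)

  factors <- sprintf("TF_%03d", seq_len(cfg$n_factors))
  if (nrow(cfg$planted_factors) > 0) {
    factors[seq_len(nrow(cfg$planted_factors))] <- cfg$planted_factors$factor
  }
  planted <- factors %in% cfg$planted_factors$factor

  with_seed(substream_seed(cfg$seed, "target_sets"), {
    size <- cfg$target_set_size
    # Planted factors share a common core: the focal neighborhood first,
    # padded with random genes up to co_membership * set size. At
    # co_membership = 1 planted sets are identical; at 0 they are independent
    # uniform draws.
    core_size <- min(size, ceiling(cfg$co_membership * size))
    core <- utils::head(neighborhood, core_size)
    if (length(core) < core_size) {
      core <- c(core, sample(setdiff(universe, core), core_size - length(core)))
    }
    sets <- stats::setNames(lapply(seq_along(factors), function(i) {
      if (planted[i] && core_size > 0) {
        fill <- sample(setdiff(universe, core), size - length(core))
        sort(c(core, fill))
      } else {
        sort(sample(universe, size))
      }
    }), factors)

    win <- cfg$window
    grid <- make_bins(win, cfg$bin_size)
    anchor_w <- 5000
    a1 <- stats::runif(cfg$n_loops, win$start, win$end - anchor_w)
    a2 <- stats::runif(cfg$n_loops, win$start, win$end - anchor_w)
    loops <- tibble::tibble(
      chrom1 = win$chrom, start1 = floor(a1), end1 = floor(a1) + anchor_w,
      chrom2 = win$chrom, start2 = floor(a2), end2 = floor(a2) + anchor_w,
      name = sprintf("loop_%03d", seq_len(cfg$n_loops)),
      context = "synthetic"
    )
    if (nrow(cfg$planted_bins) > 0 && cfg$n_loops > 0) {
      b <- cfg$planted_bins$bin[1]
      loops$start2[1] <- grid$start[b]
      loops$end2[1] <- grid$end[b]
    }

    # TSS table: focal gene at the window center (its promoter sits inside
    # the planted element), other genes spread over a flanking region.
    tss_pos <- floor(stats::runif(length(universe), win$start, win$end))
    tss <- tibble::tibble(
      gene = universe, chrom = win$chrom, tss = tss_pos,
      strand = sample(c("+", "-"), length(universe), replace = TRUE)
    )
    tss$tss[tss$gene == cfg$focal_gene] <-
      floor((win$start + win$end) / 2)
    list(sets = sets, universe = universe, loops = loops, tss = tss)
  })
}

#' Write a full synthetic study to disk
#'
#' Runs all simulators under the configuration's seed and writes the file
#' layout the pipeline consumes: `cohorts/*.tsv`, `atac_counts.tsv`,
#' `atac_expression.tsv`, `peaks/*.bed` with `peak_manifest.tsv`,
#' `loops.bedpe`, `target_sets.gmt`, `tss.tsv`, and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written plus the truth.
#' @export
write_simulation <- function(config, outdir) {
  cfg <- validate_sim_config(config)
  dir.create(file.path(outdir, "cohorts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)

  sim <- simulate_cohorts(cfg)
  for (nm in names(sim$cohorts)) {
    write_cohort(sim$cohorts[[nm]], file.path(outdir, "cohorts", paste0(nm, ".tsv")))
  }

  # accessibility samples have their own focal-expression values (matched IDs)
  focal_expr <- with_seed(substream_seed(cfg$seed, "atac_expression"), {
    tibble::tibble(
      sample = sprintf("T%04d", seq_len(cfg$n_atac_samples)),
      expression = exp(1.5 * stats::rnorm(cfg$n_atac_samples) + 3)
    )
  })
  readr::write_tsv(focal_expr, file.path(outdir, "atac_expression.tsv"),
                   progress = FALSE)

  counts <- simulate_atac(cfg, focal_expr)
  readr::write_tsv(counts, file.path(outdir, "atac_counts.tsv"), progress = FALSE)

  grid <- make_bins(cfg$window, cfg$bin_size)
  sig_bins <- grid[cfg$planted_bins$bin, , drop = FALSE]
  peaks <- simulate_peak_experiments(cfg, sig_bins)
  man <- peaks |>
    dplyr::distinct(.data$experiment, .data$factor, .data$context) |>
    dplyr::mutate(path = file.path("peaks", paste0(.data$experiment, ".bed")))
  for (i in seq_len(nrow(man))) {
    exp_peaks <- dplyr::filter(peaks, .data$experiment == man$experiment[i])
    exp_peaks$name <- exp_peaks$experiment
    write_bed(exp_peaks, file.path(outdir, man$path[i]),
              extra_cols = c("name", "score"))
  }
  readr::write_tsv(man, file.path(outdir, "peak_manifest.tsv"), progress = FALSE)

  ts <- simulate_target_sets(cfg)
  write_gmt(ts$sets, file.path(outdir, "target_sets.gmt"))
  write_bedpe(ts$loops, file.path(outdir, "loops.bedpe"))
  readr::write_tsv(ts$tss, file.path(outdir, "tss.tsv"), progress = FALSE)
  write_truth(sim$truth, file.path(outdir, "truth.json"))

  invisible(list(
    outdir = outdir,
    cohort_dir = file.path(outdir, "cohorts"),
    atac_counts = file.path(outdir, "atac_counts.tsv"),
    atac_expression = file.path(outdir, "atac_expression.tsv"),
    peak_manifest = file.path(outdir, "peak_manifest.tsv"),
    loops = file.path(outdir, "loops.bedpe"),
    target_sets = file.path(outdir, "target_sets.gmt"),
    tss = file.path(outdir, "tss.tsv"),
    truth = sim$truth
  ))
}
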