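# Synthetic-data generator: planted rank correlations, null behaviour,
# reproducibility, truth round-trips.

test_that("planted regulators hit their target Spearman correlation", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 500, n_genes = 20,
                    planted_regulators = tibble::tibble(gene = "geneA",
                                                        rho = 0.6),
                    window = "c:0-10000", bin_size = 100,
                    target_set_size = 10, seed = 2)
  sim <- simulate_cohorts(cfg)
  expr <- sim$cohorts[[1]]
  m <- as.matrix(expr[, -1])
  rownames(m) <- expr$gene
  emp <- cor(m["geneA", ], m["FOCAL", ], method = "spearman")
  expect_lt(abs(emp - 0.6), 0.1)
})

test_that("null genes stay uncorrelated with the focal gene", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 200, n_genes = 1001,
                    planted_regulators = tibble::tibble(gene = character(),
                                                        rho = numeric()),
                    window = "c:0-10000", bin_size = 100,
                    target_set_size = 10, seed = 3)
  sim <- simulate_cohorts(cfg)
  ct <- spearman_to_focal(sim$cohorts[[1]], "FOCAL")
  expect_equal(nrow(ct), 1000)
  expect_lt(max(abs(ct$rho)), 0.3)
})

test_that("a perfect anti-monotone regulator yields rho exactly -1", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 50, n_genes = 10,
                    planted_regulators = tibble::tibble(gene = "geneB",
                                                        rho = -1),
                    window = "c:0-10000", bin_size = 100,
                    target_set_size = 10, seed = 4)
  ct <- spearman_to_focal(simulate_cohorts(cfg)$cohorts[[1]], "FOCAL")
  expect_equal(ct$rho[ct$gene == "geneB"], -1)
})

test_that("|rho| = 1 with added noise is rejected as unsatisfiable", {
  expect_error(
    sim_config(planted_regulators = tibble::tibble(gene = "g", rho = 1),
               measurement_noise = 0.1),
    "unsatisfiable")
})

test_that("planted accessibility bins track focal expression at target rho", {
  cfg <- small_config(seed = 6, n_atac_samples = 409)
  fx <- tibble::tibble(sample = sprintf("T%03d", 1:409),
                       expression = exp(rnorm(409)))
  counts <- simulate_atac(cfg, fx)
  m <- as.matrix(counts[, fx$sample])
  for (b in cfg$planted_bins$bin) {
    emp <- cor(m[b, ], fx$expression, method = "spearman")
    expect_lt(abs(emp - 0.8), 0.1)
  }
})

test_that("null bins produce uniform p-values at the nominal rate", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 10, n_genes = 10,
                    window = "chr5:89970000-91020000", bin_size = 100,
                    n_atac_samples = 100,
                    planted_bins = tibble::tibble(bin = integer(),
                                                  rho = numeric()),
                    target_set_size = 10, seed = 8)
  fx <- tibble::tibble(sample = sprintf("T%03d", 1:100),
                       expression = exp(rnorm(100)))
  tr <- correlate_bins(simulate_atac(cfg, fx), fx)
  frac <- mean(tr$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 0.02) # 10,500 null bins
})

test_that("constant focal expression still emits a count matrix", {
  cfg <- small_config(seed = 9)
  fx <- tibble::tibble(sample = sprintf("T%02d", 1:60), expression = 5)
  counts <- simulate_atac(cfg, fx)
  expect_equal(nrow(counts), 1000)
  expect_true(all(as.matrix(counts[, fx$sample]) >= 0))
})

test_that("planted bins outside the grid and |rho| = 1 bins are rejected", {
  expect_error(small_config(planted_bins = tibble::tibble(bin = 2000,
                                                          rho = 0.5)),
               "outside the bin grid")
  cfg <- small_config(planted_bins = tibble::tibble(bin = 5, rho = 1))
  fx <- tibble::tibble(sample = "a", expression = 1)
  expect_error(simulate_atac(cfg, fx), "unsatisfiable")
})

test_that("peak placement reproduces the planted fold enrichment", {
  cfg <- small_config(seed = 10, n_factors = 2, experiments_per_factor = 20,
                      peaks_per_experiment = 200,
                      planted_factors = tibble::tibble(factor = "PLANTED",
                                                       fold = 3))
  grid <- make_bins(cfg$window, cfg$bin_size)
  sig <- grid[seq(5, 995, by = 20), ] # 50 bins -> f0 = 0.005 coverage
  peaks <- simulate_peak_experiments(cfg, sig)
  frac_in <- function(fac) {
    p <- dplyr::filter(peaks, factor == fac)
    mid <- (p$start + p$end) / 2
    mean(regscan:::overlaps_merged(mid, mid + 1e-9, sig$start, sig$end))
  }
  f0 <- sum(sig$end - sig$start) / 100000
  expect_lt(abs(frac_in("PLANTED") / f0 - 3), 0.75) # 4,000 peaks
  expect_lt(abs(frac_in("TF_002") / f0 - 1), 0.5)
})

test_that("fold-1 experiments center observed - expected on zero", {
  cfg <- small_config(seed = 12, n_factors = 6, experiments_per_factor = 5,
                      peaks_per_experiment = 100,
                      planted_factors = tibble::tibble(factor = character(),
                                                       fold = numeric()))
  grid <- make_bins(cfg$window, cfg$bin_size)
  sig <- grid[seq(10, 990, by = 10), ]
  peaks <- simulate_peak_experiments(cfg, sig)
  res <- overlap_results(peaks, sig, cfg$window, n_perm = 50, seed = 1)
  dev <- res$observed - res$expected
  expect_lt(abs(mean(dev)), 2 * sd(dev) / sqrt(length(dev)) + 0.5)
})

test_that("an experiment with zero peaks has zero observed overlap", {
  bins <- tibble::tibble(chrom = "c", start = 0, end = 100)
  none <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric())
  expect_equal(observed_overlap(none, bins), 0L)
})

test_that("overfull fold requests are clamped with a warning", {
  cfg <- small_config(seed = 13, n_factors = 1, experiments_per_factor = 1,
                      peaks_per_experiment = 20,
                      planted_factors = tibble::tibble(factor = "X",
                                                       fold = 1000))
  grid <- make_bins(cfg$window, cfg$bin_size)
  sig <- grid[1:100, ]
  expect_warning(simulate_peak_experiments(cfg, sig), "clamped")
})

test_that("full co-membership yields identical planted target sets", {
  cfg <- small_config(seed = 14, co_membership = 1,
                      planted_factors = tibble::tibble(factor = c("P1", "P2"),
                                                       fold = c(2, 2)))
  ts <- simulate_target_sets(cfg)
  expect_identical(ts$sets$P1, ts$sets$P2)
  # distance between identical binary rows is zero
  mat <- regulatory_matrix(ts$sets)
  d <- gene_distance(mat, ts$sets$P1[1], include_focal = TRUE)
  expect_true(all(c("P1", "P2") %in% names(mat)))
})

test_that("zero co-membership overlap matches the hypergeometric mean", {
  overlaps <- vapply(1:50, function(s) {
    cfg <- small_config(seed = s, co_membership = 0, n_genes = 200,
                        target_set_size = 40,
                        planted_factors = tibble::tibble(
                          factor = c("P1", "P2"), fold = c(2, 2)))
    ts <- simulate_target_sets(cfg)
    length(intersect(ts$sets$P1, ts$sets$P2))
  }, numeric(1))
  expected <- 40 * 40 / 200 # hypergeometric mean k*m/N
  se <- sqrt(40 * (40 / 200) * (1 - 40 / 200) * (200 - 40) / 199 / 50)
  expect_lt(abs(mean(overlaps) - expected), 4 * se)
})

test_that("requested set size beyond the universe errors", {
  expect_error(small_config(n_genes = 20, target_set_size = 30),
               "exceeds the gene universe")
})

test_that("a loop anchored on a planted bin is flagged downstream", {
  cfg <- small_config(seed = 15)
  ts <- simulate_target_sets(cfg)
  grid <- make_bins(cfg$window, cfg$bin_size)
  planted_bin <- grid[cfg$planted_bins$bin[1], ]
  out <- loop_intersect(planted_bin, ts$loops)
  expect_true(out$loop_anchor)
})

test_that("same seed reproduces byte-identical simulation outputs", {
  cfg <- small_config(seed = 16)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("truth files round-trip through JSON", {
  cfg <- small_config(seed = 17)
  truth <- simulate_cohorts(cfg)$truth
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$regulators, truth$regulators)
  expect_equal(back$bins, truth$bins)
  expect_equal(back$factors, truth$factors)
  expect_equal(back$seed, truth$seed)
})
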