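# Regulatory similarity: target-set construction, distances, PCA, GSEA,
# overrepresentation, integration.

test_that("build_target_sets applies the promoter window and mean-score filter", {
  tss <- tibble::tibble(gene = "g1", chrom = "c", tss = 5000, strand = "+")
  peak <- function(score, factor = "TF1", start = 4500, end = 4700) {
    tibble::tibble(factor = factor, chrom = "c", start = start, end = end,
                   score = score)
  }
  expect_equal(build_target_sets(peak(60), tss)$gene, "g1")
  expect_equal(nrow(build_target_sets(peak(40), tss)), 0) # filter boundary
  # mean-then-threshold: scores (40, 80) across two experiments -> mean 60
  two <- dplyr::bind_rows(peak(40), peak(80))
  out <- build_target_sets(two, tss)
  expect_equal(out$mean_score, 60)
  expect_equal(out$n_peaks, 2L)
  # a peak outside [TSS-1000, TSS+1000) is not promoter-proximal
  expect_equal(nrow(build_target_sets(peak(90, start = 6100, end = 6300), tss)),
               0)
})

test_that("missing strand is tolerated with a warning", {
  tss <- tibble::tibble(gene = "g1", chrom = "c", tss = 5000)
  pk <- tibble::tibble(factor = "TF1", chrom = "c", start = 4500, end = 4700,
                       score = 60)
  expect_warning(out <- build_target_sets(pk, tss), "strand")
  expect_equal(out$gene, "g1")
})

test_that("regulatory_matrix builds 0/1 occupancy and flags zero variance", {
  sets <- list(TF1 = c("a", "b"), TF2 = c("b", "c"))
  m <- regulatory_matrix(sets, universe = c("a", "b", "c", "d"))
  expect_equal(m$TF1, c(1, 1, 0, 0))
  expect_equal(m$TF2, c(0, 1, 1, 0))
  expect_true("d" %in% attr(m, "zero_variance")) # all-zero row
  expect_true("b" %in% attr(m, "zero_variance")) # all-one row
})

test_that("gene_distance matches hand values and the brute-force oracle", {
  mat <- tibble::tibble(gene = c("f", "g", "h"),
                        TF1 = c(1, 1, 1), TF2 = c(1, 0, 1), TF3 = c(0, 0, 0))
  d <- gene_distance(mat, "f", include_focal = TRUE)
  expect_equal(d$distance[d$gene == "g"], 1) # rows (1,1,0) vs (1,0,0)
  expect_equal(d$distance[d$gene == "h"], 0) # identical rows
  expect_equal(d$distance[d$gene == "f"], 0)

  set.seed(20)
  big <- tibble::as_tibble(matrix(rbinom(50 * 12, 1, 0.4), 50,
                                  dimnames = list(NULL, paste0("TF", 1:12)))) |>
    dplyr::mutate(gene = sprintf("g%02d", 1:50), .before = 1)
  dd <- gene_distance(big, "g01", include_focal = TRUE)
  m <- as.matrix(big[, -1])
  for (i in seq_len(50)) {
    oracle <- sqrt(sum((m[i, ] - m[1, ])^2))
    expect_equal(dd$distance[dd$gene == big$gene[i]], oracle)
  }
  # focal excluded by default; 40-gene bins consecutive
  dx <- gene_distance(big, "g01", bin_width = 10)
  expect_false("g01" %in% dx$gene)
  expect_equal(dx$dist_bin, ceiling(seq_len(49) / 10))
  expect_true(all(diff(dx$distance) >= 0))
})

test_that("pca_project matches a hand eigen-decomposition on a 3-point toy", {
  mat <- tibble::tibble(gene = c("a", "b", "c"),
                        TF1 = c(0, 1, 1), TF2 = c(0, 0, 1), TF3 = c(1, 0, 0))
  p <- pca_project(mat)
  x <- cbind(c(0, 1, 1), c(0, 0, 1), c(1, 0, 0))
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(x)) # covariance eigen-decomposition as the oracle
  scores <- xc %*% ev$vectors
  for (j in 1:2) { # same sign convention: largest-|loading| positive
    v <- ev$vectors[, j]
    anchor <- which(abs(v) > max(abs(v)) - 1e-8)[1]
    if (v[anchor] < 0) scores[, j] <- -scores[, j]
  }
  expect_equal(p$PC1, scores[, 1], tolerance = 1e-10)
  expect_equal(p$PC2, scores[, 2], tolerance = 1e-10)
})

test_that("pca_project handles collinear and duplicated configurations", {
  line <- tibble::tibble(gene = letters[1:4],
                         TF1 = c(1, 2, 3, 4), TF2 = c(2, 4, 6, 8))
  expect_warning(p <- pca_project(line), "rank < 2")
  expect_equal(p$PC2, rep(0, 4))
  expect_equal(attr(p, "var_explained")[1], 1)

  dup <- tibble::tibble(gene = c("a", "b", "c", "a2", "b2", "c2"),
                        TF1 = rep(c(0, 1, 1), 2), TF2 = rep(c(1, 0, 1), 2),
                        TF3 = rep(c(1, 1, 0), 2))
  pd <- pca_project(dup)
  expect_equal(pd$PC1[1:3], pd$PC1[4:6])
  expect_equal(pd$PC2[1:3], pd$PC2[4:6])
})

test_that("GSEA enrichment statistic matches the direct running-sum oracle", {
  set.seed(30)
  v <- sort(rnorm(40), decreasing = TRUE)
  names(v) <- sprintf("g%02d", 1:40)
  for (k in c(3, 8)) {
    hits <- sort(sample.int(40, k))
    mine <- regscan:::gsea_es(abs(v)^1, hits, 40)
    expect_equal(mine, gsea_es_oracle(v, hits, weight = 1))
  }
  # singleton set at the very top of the ranking peaks at ES = 1
  g <- preranked_gsea(v, list(top = names(v)[1]), n_perm = 50, seed = 1)
  expect_equal(g$ES, 1)
})

test_that("GSEA agrees with the reference implementation's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  v <- sort(rnorm(100), decreasing = TRUE)
  names(v) <- sprintf("g%03d", 1:100)
  hits <- sort(sample.int(100, 10))
  mine <- regscan:::gsea_es(abs(v), hits, 100)
  ref <- fgsea::calcGseaStat(v, selectedStats = hits, gseaParam = 1)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("GSEA p-value matches exhaustive enumeration on a tiny universe", {
  v <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1, g6 = -1, g7 = -2, g8 = -3)
  set <- c("g1", "g2", "g4")
  res <- preranked_gsea(v, list(s = set), n_perm = 100, seed = 7) # 56 combos
  combos <- combn(8, 3)
  null_es <- apply(combos, 2, function(ix) gsea_es_oracle(v, sort(ix)))
  es <- gsea_es_oracle(v, match(set, names(v)))
  same <- null_es[sign(null_es) == sign(es)]
  p_oracle <- (1 + sum(abs(same) >= abs(es) - 1e-12)) / (length(same) + 1)
  expect_equal(res$ES, es)
  expect_equal(res$p, p_oracle)
  expect_equal(sign(res$NES), sign(res$ES))
})

test_that("degenerate GSEA inputs are rejected or warned", {
  v <- c(a = 3, b = 2, c = 1, d = -1)
  expect_error(preranked_gsea(v, list(s = c("x", "y")), n_perm = 10),
               "outside the ranked universe")
  expect_warning(res <- preranked_gsea(v, list(s = names(v)), n_perm = 10),
                 "degenerate")
  expect_true(is.na(res$ES))
  expect_error(preranked_gsea(c(a = 1, b = Inf), list(s = "a"), 10), "finite")
})

test_that("the unweighted statistic is invariant to monotone rescaling", {
  set.seed(32)
  v <- sort(rexp(30), decreasing = TRUE)
  names(v) <- sprintf("g%02d", 1:30)
  set <- list(s = names(v)[c(2, 5, 11, 20)])
  a <- preranked_gsea(v, set, n_perm = 200, seed = 3, weight = 0)
  b <- preranked_gsea(v^3 + 1, set, n_perm = 200, seed = 3, weight = 0)
  expect_equal(a$ES, b$ES)
  expect_equal(a$p, b$p)
})

test_that("overrepresentation matches the hypergeometric tail", {
  universe <- paste0("u", 1:10)
  term <- universe[1:4]
  genes <- c(universe[1:4], "u9")
  out <- overrepresentation(genes, list(t = term), universe)
  expect_equal(out$p, 6 / 252) # C(4,4) C(6,1) / C(10,5)
  # zero overlap with nonzero expectation: tail includes X >= 0
  out0 <- overrepresentation(universe[8:10], list(t = universe[1:2]), universe)
  expect_equal(out0$p, 1)
  # term covering the universe forces overlap = set size
  outU <- overrepresentation(genes, list(t = universe), universe)
  expect_equal(outU$overlap, 5)
  expect_equal(outU$p, 1)
  expect_error(overrepresentation(genes, list(t = term), character(0)),
               "empty")
})

test_that("set_overlap_compare counts overlaps and tests distributions", {
  sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"))
  expect_equal(set_overlap_compare(
    sets, pan_cancer_median(tibble::tibble(
      cohort = "c", gene = LETTERS[1:8], rho = 0, z = rnorm(8)),
      min_cohorts = 1))$pairwise$overlap, 2)

  # a group planted with high scores separates from the rest
  set.seed(50)
  shared <- sprintf("T%02d", 1:10)
  big_sets <- list(s1 = c(shared, "X1"), s2 = c(shared, "X2"))
  scores <- pan_cancer_median(
    tibble::tibble(cohort = "c", gene = c(shared, sprintf("n%02d", 1:40)),
                   rho = 0, z = c(rnorm(10, 2), rnorm(40))),
    min_cohorts = 1)
  out <- set_overlap_compare(big_sets, scores)
  expect_setequal(out$intersection, shared)
  expect_s3_class(out$comparison, "tbl_df")
  expect_lt(out$comparison$p, 0.05)
  expect_gt(out$comparison$median_group, out$comparison$median_rest)
  # group covering every scored gene is skipped with a warning
  expect_warning(
    all_g <- set_overlap_compare(big_sets, scores, group = scores$gene),
    "skipped")
  expect_null(all_g$comparison)
})

test_that("rank-sum p-values are calibrated under the null", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:100)
  ps <- vapply(1:40, function(i) {
    scores <- pan_cancer_median(
      tibble::tibble(cohort = "c", gene = genes, rho = 0,
                     z = rnorm(100)), min_cohorts = 1)
    out <- set_overlap_compare(list(s1 = genes[1:20], s2 = genes[11:30]),
                               scores, group = genes[1:15])
    out$comparison$p
  }, numeric(1))
  # the rank statistic is discrete, so KS tie warnings are expected
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("gsea_signal_integration recovers monotone coupling and errors", {
  g <- tibble::tibble(set = paste0("TF", 1:6), size = 10,
                      ES = c(0.8, 0.6, 0.5, 0.3, -0.2, -0.5),
                      NES = c(2.4, 1.9, 1.6, 1.1, -0.8, -1.7),
                      p = c(.001, .002, .01, .2, .5, .03),
                      padj = c(.006, .006, .02, .24, .5, .045))
  class(g) <- c("gsea_result", class(g))
  combined <- g$NES * -log10(g$padj)
  sig <- tibble::tibble(factor = paste0("TF", 1:6),
                        signal = exp(combined) + 1) # monotone in the score
  out <- gsea_signal_integration(g, sig)
  expect_equal(attr(out, "rho"), 1)
  expect_equal(out$rank, 1:6)
  expect_equal(glance(out)$n_factors, 6)
  short <- sig[1:3, ]
  expect_warning(expect_error(gsea_signal_integration(g, short), "fewer than 4"),
                 "dropped")
})

test_that("integration correlation is null-calibrated for independent tables", {
  set.seed(34)
  rhos <- vapply(1:30, function(i) {
    g <- tibble::tibble(set = paste0("TF", 1:20), size = 10,
                        ES = runif(20, -1, 1), NES = rnorm(20),
                        p = runif(20), padj = runif(20))
    class(g) <- c("gsea_result", class(g))
    sig <- tibble::tibble(factor = paste0("TF", 1:20), signal = rlnorm(20))
    attr(gsea_signal_integration(g, sig), "rho")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})
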