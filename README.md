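# regscan

**regscan** discovers candidate regulators of a focal gene — the
transcription factors and regulatory DNA elements likely to drive its
expression — from multi-cohort tumor expression and chromatin accessibility
data. It is aimed at computational biologists who have per-cohort RNA-seq
matrices, binned ATAC-seq counts with matched expression, and collections of
factor-labelled peak files, and who want a tested, deterministic pipeline
from those inputs to a ranked list of candidate factors and elements.

## The method

Four stages, each exposed as data-frame-in / tibble-out functions that chain
with the pipe:

1. **Pan-cancer co-expression.** Within each cohort, the Spearman rank
   correlation ρ<sub>g</sub> of every gene *g* with the focal gene is
   standardized, *z*<sub>g</sub> = (ρ<sub>g</sub> − ρ̄)/s<sub>ρ</sub>, and
   genes are summarized pan-cancer by the median *z* across cohorts
   (`spearman_to_focal() |> z_transform() |> pan_cancer_median()`).
2. **Chromatin scan.** A survey window (default 1 Mb,
   `chr5:89970000-91020000`) is tiled into 100 bp bins (10,500 bins);
   quantile-normalized bin counts are Spearman-correlated with focal
   expression across matched sample IDs; p-values are Benjamini–Hochberg
   adjusted across the window, bins scored sign(ρ)·(−log₁₀ p<sub>adj</sub>)
   and selected at p<sub>adj</sub> < 10⁻⁴
   (`make_bins()`, `quantile_normalize()`, `correlate_bins()`,
   `select_significant()`).
3. **Overlap enrichment.** Each peak experiment's observed overlap with the
   significant bins is compared with the mean overlap after relocating the
   bins uniformly in a background (100 permutations); per factor, the
   aggregate Σ(obs − exp) is tested against 10,000 sums of equally many
   values drawn from the pooled experiments, and factors are scored
   log₂(Σobs/Σexp) × −log₁₀(p<sub>adj</sub>)
   (`overlap_results()`, `factor_enrichment()`, `loop_intersect()`).
4. **Regulatory similarity and GSEA.** Promoter-proximal target sets (peak
   within ±1 kb of the TSS, mean score > 50) become a binary gene × factor
   matrix; genes are ranked by Euclidean distance to the focal gene's row
   and projected by PCA; each factor's target set is tested by preranked
   GSEA (10,000 permutations) against the median-z ranking, and NES ×
   −log₁₀(FDR) is correlated with promoter-proximal signal
   (`build_target_sets()`, `gene_distance()`, `pca_project()`,
   `preranked_gsea()`, `gsea_signal_integration()`).

A synthetic-data generator (`sim_config()`, `write_simulation()`) plants
known rank correlations (Gaussian copula), overlap folds, and set
co-membership so that every stage has a parameter-recovery test, and
`run_pipeline()` drives everything end to end, byte-deterministically under
a fixed seed.

## Worked example

Simulate a small study (3 cohorts × 30 tumors × 200 genes, ten regulators
planted at |ρ| = 0.6; a 1,000-bin window with ten bins planted at ρ = 0.8;
six factors with one planted at fold 3) and run the first three stages:

```r
library(regscan)

cfg <- sim_config(n_cohorts = 3, samples_per_cohort = 30, n_genes = 200,
                  window = "chrS:1000000-1100000", n_atac_samples = 60,
                  planted_bins = tibble::tibble(bin = 495:504, rho = 0.8),
                  n_factors = 6, experiments_per_factor = 3,
                  peaks_per_experiment = 60, target_set_size = 40, seed = 11)

sim <- simulate_cohorts(cfg)
zs <- dplyr::bind_rows(lapply(sim$cohorts, function(co)
  z_transform(spearman_to_focal(co, "FOCAL"))))
scores <- pan_cancer_median(zs, min_cohorts = 2)
head(scores, 5)
#>   gene   median_z n_cohorts pass_min_cohorts  rank
#> 1 REG_05     2.69         3 TRUE                 1
#> 2 REG_04     2.53         3 TRUE                 2
#> 3 REG_03     2.48         3 TRUE                 3
#> 4 REG_02     2.43         3 TRUE                 4
#> 5 REG_01     2.41         3 TRUE                 5
```

The five planted positive regulators top the pan-cancer ranking: their
median z-scores (≈ 2.4–2.7) sit far above the null genes' (centered on 0).

```r
fx <- withr::with_seed(1, tibble::tibble(sample = sprintf("T%03d", 1:60),
                                         expression = exp(rnorm(60))))
track <- simulate_atac(cfg, fx) |> quantile_normalize() |> correlate_bins(fx)
glance(track)
#>   n_bins n_samples n_sig_positive n_sig_negative  alpha
#> 1   1000        60             10              0 0.0001
```

Exactly the ten planted bins pass the default threshold; no null bin does.

```r
sig <- select_significant(track, 1e-4)
peaks <- simulate_peak_experiments(cfg, sig)
fe <- factor_enrichment(
  overlap_results(peaks, sig, cfg$window, n_perm = 50, seed = 2),
  n_null = 2000, seed = 2)
head(fe, 3)
#>   factor     n_experiments sum_obs sum_exp aggregate      p     z  padj score
#> 1 TF_PLANTED             3      17    6.36     10.6  0.0196 2.26  0.118 1.32
#> 2 TF_003                 3      10    6.54      3.46 0.261  0.634 0.602 0.135
#> 3 TF_002                 3       9    6.30      2.70 0.301  0.463 0.602 0.113
```

The planted factor overlaps the significant bins 17 times against 6.4
expected (≈ fold 3, as planted), ranks first by enrichment score, and is
the only factor with a small permutation p. At this miniature scale (3
experiments per factor) the BH-adjusted p stays above 0.05 — the full-scale
recovery tests in `tests/testthat/` show the planted factor reaching
significance with 5–10 experiments.

`write_simulation()` + `run_pipeline()` run all stages (including GSEA,
regulatory distance/PCA, and promoter-signal integration) from files on
disk and write per-stage TSV/BED outputs with an md5 manifest; see the
vignette `vignettes/regulator-survey.Rmd` for the model details and design
choices.

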