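---
title: "An integrated survey of candidate gene regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated survey of candidate gene regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscan)
library(dplyr)
```

## The problem

A gene of interest — the *focal gene* — is upregulated across many tumor
types, and we want to know which transcription factors and which regulatory
DNA elements drive that expression. Direct perturbation data rarely exist at
this breadth, but two large observational resources do: per-cohort tumor
RNA-seq (expression of all genes in hundreds of samples per cancer subtype)
and tumor chromatin accessibility (ATAC-seq) with matched expression.
`regscan` implements an integrated survey over such data with four
analytical stages, plus a synthetic-data generator that plants known
structure so every stage has a parameter-recovery test.

## Stage 1: pan-cancer co-expression

Within each cohort, every gene's Spearman rank correlation with the focal
gene is computed across samples (`spearman_to_focal()`). Rank correlation is
used because expression is heavy-tailed and cohort pipelines differ in
scale; any monotone transformation of a gene's expression leaves its
coefficient untouched (a tested invariant). Correlations are then
standardized *within cohort*:

$$z_g = \frac{\rho_g - \bar\rho}{s_\rho}$$

with the mean and sample standard deviation (denominator $n-1$) taken over
all genes with a defined coefficient in that cohort (`z_transform()`). The
z-transform makes cohorts with different correlation spreads comparable.
Genes constant across samples have no defined rank correlation; they are
recorded as missing and excluded from the mean/sd rather than imputed,
because any imputed value would be arbitrary. A cohort whose correlations
have zero spread is degenerate and rejected outright rather than silently
zeroed.

The pan-cancer summary is the per-gene **median z across cohorts**
(`pan_cancer_median()`), robust to a single outlying cohort. The number of
contributing cohorts is recorded per gene and a reporting flag defaults to
three cohorts; medians of raw correlations are available behind
`use_raw_rho = TRUE` for comparison, since "median correlation" and "median
z-score" denote subtly different summaries and we expose both rather than
claim one exclusively.

## Stage 2: the chromatin scan

A survey window (1 Mb around the focal gene; the default is
`chr5:89970000-91020000`) is tiled into contiguous half-open 100 bp bins —
10,500 bins for the default window (`make_bins()`). All coordinates in the
package are 0-based half-open, BED convention; a single stated convention
beats silent mixing, and the printed window is interpreted under it.

Per-sample bin counts are quantile normalized (`quantile_normalize()`,
classic rank-mean normalization via limma): after normalization every
sample has an identical value distribution while within-sample rank order is
preserved. A block of reference rows (e.g. a genome-wide coordinate list)
can participate in the rank computation and be dropped from the output; the
reference list itself is user-supplied, since no canonical list ships with
the package.

Each bin's normalized counts are then Spearman-correlated with focal-gene
expression across **matched sample IDs** (`correlate_bins()`); a shuffled or
partial ID set is an error, never a silent inner join. Two-sided p-values
use the t approximation on the rank correlation (exact at the sample sizes
this survey targets), and are Benjamini–Hochberg adjusted across *all bins
in the window* — the window is the family, not the genome. Constant bins
stay in the grid with a missing coefficient and p = 1 by convention so that
downstream overlap analyses keep grid alignment. Bins are reported with the
signed score $\mathrm{sign}(\rho) \cdot (-\log_{10} p_{adj})$ and selected
at `padj < 1e-4` by default (a relaxed `5e-3` cutoff is conventional for
loop-anchor views); both thresholds are plain arguments
(`select_significant()`).

Composite views of external signal tracks use the per-position 75th
percentile across tracks (`composite_track()`), with the
linear-interpolation quantile convention (R type 7) — the quantile
convention is unstated in most track-hub pipelines, so we fix one and test
it.

## Stage 3: overlap enrichment

Factor-labelled peak experiments (ChIP-seq-style scored intervals, one BED
per experiment with a manifest) are scored against the significant bins.
Per experiment, the **observed** overlap is the number of query bins
intersected by at least one peak — the unit of analysis is the bin, not the
peak — and the **expected** overlap is the mean observed overlap after
relocating the bin set uniformly at random within a declared background
(default: the survey window), preserving bin widths, 100 permutations by
default (`expected_overlap()`). The upstream tool this stage re-specifies
performs its permutation server-side without publishing internals; our
local re-specification (relocate query bins over a user-declared
background) is documented as a design choice, not asserted as identical.

Per factor with $k$ experiments, the aggregate statistic is
$\sum_k (\mathrm{obs}_k - \mathrm{exp}_k)$ — "observation beyond
expectation" — compared against a null of sums of $k$ values drawn without
replacement from the pool of all experiments' values, which controls for
the number of experiments a factor has (`factor_enrichment()`). Two
implementation details matter:

* The permutation p uses the add-one estimator
  $p = (1 + \#\{null \ge obs\}) / (n_{null} + 1)$: never zero, never above
  one, slightly conservative.
* The null is computed once per distinct $k$ (factors with equal experiment
  counts face identically distributed nulls), and when
  $\binom{|pool|}{k} \le n_{null}$ the null is **enumerated exhaustively**
  instead of sampled, so small problems get exact p-values.

Factors are BH-adjusted across the family and reported with the z-score
(standard deviations beyond the null mean) and the enrichment score
$\log_2(\sum obs / \sum exp) \times -\log_{10}(p_{adj})$. A factor with zero
observed overlap has a $-\infty$ score by this formula; it is reported as
such rather than floored. An upstream per-peak score cutoff (the import
filter in `read_peak_experiments(min_score = )`) reproduces the q-value
inclusion filter of the original peak resource. Bins are also flagged for
intersection with chromatin-loop anchors (`loop_intersect()`), either anchor
of a BEDPE pair counting.

## Stage 4: regulatory similarity and set enrichment

Target gene sets per factor are built from promoter-proximal occupancy
(`build_target_sets()`): a gene is a target iff at least one of the
factor's peaks overlaps $[\mathrm{TSS} - 1\,\mathrm{kb},
\mathrm{TSS} + 1\,\mathrm{kb})$ and the *mean* score of those peaks across
the factor's experiments exceeds 50. We read "minimum average score" as
mean-then-threshold; the alternative (per-experiment minimum) would make a
single weak replicate veto a target, which contradicts averaging. One
representative TSS per gene is used — the analysis is about genes, not
transcripts — and a missing strand is tolerated with a warning because the
window is symmetric.

Membership becomes a binary genes × factors matrix
(`regulatory_matrix()`). Regulatory similarity between genes is the
Euclidean distance between binary rows (`gene_distance()`), ranked
ascending and cut into consecutive 40-gene bins; the focal gene (distance
0) is excluded from its own ranking by default, with a flag to include it.
`pca_project()` centers the factor columns, removes zero-variance genes,
and projects genes on the two leading principal axes; each component's sign
is fixed deterministically (first loading within numeric tolerance of the
maximum magnitude made positive) so projections are reproducible across
platforms and eigen-solvers.

Preranked GSEA (`preranked_gsea()`) tests each factor's target set against
the median-z ranking: the classic weighted running-sum statistic with
weight exponent 1 on |score| (exponent 0, the unweighted variant invariant
to monotone rescaling, is behind a flag), a gene-set permutation null of
`n_perm = 10000` same-size random sets, NES normalized by the mean
magnitude of same-sign null scores, add-one permutation p with exhaustive
enumeration on tiny universes, and BH FDR across sets. The reference
implementation this emulates uses an adaptive multilevel p-value refinement
that we deliberately do not replicate — the simple permutation null is
transparent, testable against exhaustive enumeration, and sufficient at the
set counts this survey handles; its statistic agrees with the reference
implementation's to machine precision in the test suite. Null ES values
tied with the observed value (up to float noise) count toward the p-value.

Hypergeometric overrepresentation against flat annotation sets
(`overrepresentation()`), rank-sum comparisons of score distributions
between target groups (`set_overlap_compare()`; the test is a two-sided
Wilcoxon, chosen for its distribution-freeness since no parametric family
is defensible for median-z values), and the final integration — per-factor
combined score $NES \times -\log_{10}(FDR)$ Spearman-correlated with
promoter-proximal signal (`gsea_signal_integration()`) — complete the
survey. Whether "GSEA score" means NES, the combined score, or raw ES is
genuinely ambiguous in this kind of figure; the combined score is the
default and all three are selectable.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the generator is not a tuning
dial. Defaults mirror the real survey's scale: 8 cohorts × 100 tumors ×
2,000 genes with ten regulators planted at $|\rho| = 0.6$; the 1 Mb window
at 100 bp (10,500 bins) with a contiguous 20-bin element planted at the
window center at $\rho = 0.8$ across 409 accessibility samples; 20 factors
× 10 experiments with one factor planted at fold 3. Cohort sizes, effect
sizes, and fold are the scales at which the corresponding real analyses
report clear signal; where no value is stated by the source material we
chose what a practitioner would call realistic once, and did not revisit.

Rank correlations are planted by a Gaussian copula: the latent bivariate
normal uses the Pearson correlation whose Spearman image equals the target,
$r = 2\sin(\pi \rho_s / 6)$, and all outputs are monotone transforms of the
latent (exponentiation for expression; `round(exp(·))` for counts, which
keeps counts positive and overdispersed). Monotone maps preserve Spearman
correlation exactly, so the planted value is the population value — except
that rounding to integer counts perturbs ranks slightly, which is why
planting $|\rho| = 1$ in the accessibility simulator is rejected as
unsatisfiable while the cohort simulator honors it exactly. Planted peak
enrichment places each peak's midpoint inside the significant-bin union
with probability $\min(1, \mathrm{fold} \times f)$ where $f$ is the bins'
coverage fraction (fold 1 reproduces uniform placement exactly); target-set
co-membership shares a common core between planted factors that scales from
independent draws (0) to identical sets (1). One global seed expands into
per-component substreams (`substream_seed()`) so each stage is reproducible
in isolation.

What the generator does **not** emulate: RSEM- or ATAC-specific noise
families, GC or mappability bias, cohort batch structure, spatial
autocorrelation of accessibility along the chromosome, or correlated TF
modules beyond the planted co-membership. Passing recovery tests therefore
demonstrates that the statistics recover the structure they are designed to
detect at realistic scale and nominal error rates — not that the pipeline
is robust to every artifact of real sequencing data.

## Numerical choices and degenerate inputs

* Half-open 0-based coordinates everywhere; any `start >= end` is an error
  at parse time.
* A final partial bin is truncated with a warning; a window shorter than
  one bin is an error.
* Constant bins: p = 1, kept in the grid. Constant genes: missing, dropped
  from the z-transform's moments.
* Permutation p-values never reach 0 (add-one) and exhaustive enumeration
  replaces sampling whenever it is cheaper than `n_null`/`n_perm` draws.
* Distance ties are broken by gene name; PCA signs by the
  largest-magnitude-loading rule with a `1e-8` tie tolerance.
* The pipeline writes every stage's outputs before dependents run, aborts
  naming the failing stage, and is byte-deterministic under a fixed seed
  (hashes recorded in `manifest.tsv`).

## Problem sizes used in the test suite

The recovery tests run at the survey's native scale where that is cheap
(the full 10,500-bin window with 409 samples; 8 × 100 × 2,000 cohorts) and
at reduced scale elsewhere (a 1,000-bin window for enrichment recovery with
10 factors × 5 experiments; GSEA at universe 2,000 with 10,000
permutations; the packaged end-to-end fixture at 3 cohorts × 30 samples ×
200 genes). Null calibration of the factor-level test pools 300 simulated
null factors. These sizes were chosen so each property is tested with
comfortable statistical margin.

## Known limitations

* The chromatin stage consumes bin counts, not alignments; read extraction
  from BAM files is out of scope by design.
* No gene-ontology DAG traversal: annotation sets are flat GMT inputs.
* The overlap-permutation background is a user declaration; results are
  conditional on that choice.
* Survival modelling, differential expression, motif discovery, and
  super-enhancer calling are out of scope; their outputs enter, if at all,
  as ordinary interval or score inputs.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_cohorts = 3, samples_per_cohort = 30, n_genes = 200,
                  window = "chrS:1000000-1100000", n_atac_samples = 60,
                  planted_bins = tibble::tibble(bin = 495:504, rho = 0.8),
                  n_factors = 6, experiments_per_factor = 3,
                  peaks_per_experiment = 60, target_set_size = 40, seed = 11)
paths <- write_simulation(cfg, "study/data")
manifest <- run_pipeline(run_config(
  focal = "FOCAL", cohort_dir = paths$cohort_dir,
  atac_counts = paths$atac_counts, atac_expression = paths$atac_expression,
  peak_manifest = paths$peak_manifest, loops = paths$loops,
  target_sets = paths$target_sets, tss = paths$tss,
  outdir = "study/out", window = "chrS:1000000-1100000",
  n_perm = 20, n_null = 500, gsea_n_perm = 500, min_cohorts = 2, seed = 5))
```
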