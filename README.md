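# icitools

Single-cell and bulk-cohort analytics for neoadjuvant immune-checkpoint-
inhibitor (ICI) studies.

Tumors treated with neoadjuvant ICI (e.g. anti-PD-L1 durvalumab with or
without anti-CTLA-4 tremelimumab) are profiled with scRNA-seq, scTCR-seq and
bulk RNA cohorts, and several of the decisive computations in such studies
are bespoke rather than off-the-shelf. icitools packages those computations
as tested, reusable functions with a tidyverse-native surface (tibbles in and
out, `tidy()`/`glance()` on fitted objects, `autoplot()` for result types):

- **Meta-program discovery.** Per-sample consensus non-negative matrix
  factorization (restart pooling, density-based outlier filtering, consensus
  clustering, refit), module extraction by the above-mean / argmax rank rule,
  a Jaccard consensus filter across samples, hypergeometric overlap
  statistics, and a gene co-occurrence network with edge weight
  w(g,h) = co(g,h) / (occ(g) + occ(h)) ∈ [0, 0.5], partitioned into
  non-overlapping meta-programs by weighted Louvain clustering.
- **Bin-matched signature scoring.** Cell scores as mean(signature) −
  mean(expression-bin-matched control pool), dominant-program assignment,
  Pearson correlation of program proportions with tumor regression, and
  Brown–Forsythe variance tests.
- **Composition shifts.** Pearson residuals r<sub>ij</sub> =
  (O<sub>ij</sub> − E<sub>ij</sub>)/√E<sub>ij</sub> with
  E<sub>ij</sub> = T<sub>i</sub>T<sub>j</sub>/T<sub>tot</sub>, chi-square
  goodness of fit, and augmentation/depletion calls at |r| > 3.5.
- **Strict TCR clonotypes.** Same V gene + normalized Levenshtein CDR3
  similarity strictly above 0.85, single-linkage within V-gene blocks;
  expansion classes (1 / 2–4 / ≥5 cells), tumor-reactive cell extraction by
  clonotype sharing with the CXCL13+ exhausted subset, and clonotype fate
  across timepoints.
- **Transition densities.** Aggregation of cell-to-cell transition
  probabilities into per-start-cell subset-to-subset densities (zeros
  excluded after summation) compared by two-sided Kolmogorov–Smirnov tests.
- **Network hub statistics.** Binary node-profile Euclidean similarity of
  patient-specific gene networks, t / Fligner–Killeen group tests,
  percentile-rank degree centrality, Louvain subcommunities, and
  differential-hub signature extraction.
- **Response prediction.** A leave-one-study-out ensemble of depth-5
  probability random forests over signature scores, probability averaging,
  midrank AUROC, and a with/without comparison quantifying what a candidate
  predictor (e.g. a senescence-module score) adds.
- **Synthetic data.** Generators for every input above with planted ground
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(icitools)

# a synthetic cohort with 3 shared planted programs
coh <- generate_program_cohort(cohort_config(
  n_samples = 4, cells_per_sample = 150, n_genes = 600,
  n_shared_programs = 3, program_size = 50, signal_strength = 5, seed = 7))

res <- discover_metaprograms(coh$counts, coh$cells, k = 3, n_iter = 8,
                             n_top_genes = 600, min_partners = 3,
                             top_n = 50, seed = 7)
glance(res$metaprograms)
#> # A tibble: 3 × 3
#>   program_id n_genes top_gene
#>   <chr>        <int> <chr>
#> 1 MP1             50 g0001
#> 2 MP2             50 g0051
#> 3 MP3             50 g0101
```

The three planted 50-gene programs come back as three meta-programs, and the
top-centrality gene of each sits in the corresponding planted block
(`g0001–g0050`, `g0051–g0100`, `g0101–g0150`).

```r
# composition shift: 2 arms x 2 subsets, counts (20,10) vs (10,20)
r <- pearson_residuals(matrix(c(20, 10, 10, 20), 2))
glance(r)
#> # A tibble: 1 × 4
#>   statistic    df p.value n_cells
#>       <dbl> <int>   <dbl>   <dbl>
#> 1      6.67     1 0.00982      60

# strict clonotyping of a planted repertoire
contigs <- generate_tcr_contigs(40, c(big = 12, mid = 7, sm = 3,
                                      setNames(rep(1, 18), paste0("s", 1:18))),
                                seed = 7)
glance(classify_expansion(call_clonotypes(contigs)))
#> # A tibble: 1 × 4
#>   n_cells n_clonotypes expanded_fraction largest_clone
#>     <int>        <int>             <dbl>         <int>
#> 1      40           21             0.143            12

# does a senescence-module score add predictive value across 8 bulk cohorts?
bk <- generate_bulk_cohorts(effect_of_senescence = 2, seed = 7)
ft <- assemble_features(bk$cohorts, bk$gene_sets)
compare_with_without(ft, c("immune_score", "stromal_score", "tumor_purity"),
                     "senescence_score", seed = 7)
#> LOSO ensemble comparison: AUROC 0.701 (base) vs 0.936 (+senescence_score)
#> mean TPR difference on FPR in [0.40, 0.60]: +0.187
```

The 2×2 chi-square (6.67, p ≈ 0.01) is the classical Pearson statistic; the
repertoire resolves into 21 clonotypes of which the three planted expanded
clones are the only non-singletons; and with a 2-SD planted senescence
effect, adding the senescence score lifts the pooled held-out AUROC of the
leave-one-study-out ensemble from 0.70 to 0.94, with the largest
true-positive-rate gain in the ambiguous mid-FPR band.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, their
assumptions, every tunable parameter with its default and rationale, what the
synthetic generators do and do not emulate, and the package's numerical and
design choices.
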