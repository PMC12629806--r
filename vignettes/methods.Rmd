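---
title: "Models and methods behind icitools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icitools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

icitools implements the bespoke computational procedures used in single-cell
studies of neoadjuvant immune-checkpoint-inhibitor (ICI) therapy: discovery of
recurrent malignant-cell gene programs, cell-level signature scoring,
compositional shift testing, strict TCR clonotype analysis, transition-density
comparison, gene-network hub statistics, and a cross-cohort ensemble test of a
signature's predictive value. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
procedure left room for interpretation. Every empirical statement here is
backed by a computation in the test suite or `scripts/acceptance.R`; nothing
is quoted from external results.

## Synthetic cohorts with planted ground truth

All stages are testable without downloads because the package ships a
generator for every input it consumes.

**Single-cell cohorts** (`generate_program_cohort()`). Counts are
`Poisson(noise_rate)` background plus `Poisson(signal_strength)` on the genes
of a cell's assigned program. The additive two-Poisson model is deliberately
simple: it is sufficient for non-negative factorization to recover planted
programs, and it avoids guessing negative-binomial dispersion parameters that
would add nothing to the contracts under test. Programs are disjoint gene
blocks — a configurable number shared by all samples plus per-sample private
blocks — and every cell is dominated by exactly one program of its sample.
`active_fraction` controls the share of a sample's cells given to each
program; the default spreads cells evenly, and configured values are capped
with leftover cells cycled round-robin so the assignment stays total.
Phenotypes (response R/NR, timepoint pre/post, arm D vs D+T) alternate at the
sample level, mirroring sample-level clinical labels. The defaults
(6 samples x 200 cells x 1,000 genes, 3 shared programs of 50 genes,
`signal_strength = 5`, `noise_rate = 0.2`) are the desk-scale study
conditions used throughout the tests.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, library-size variation, gene-gene correlation beyond program
membership. Passing tests therefore demonstrate the correctness and
calibration of the algorithms, not robustness to every artifact of real
scRNA-seq data.

**TCR repertoires** (`generate_tcr_contigs()`). Each clone receives a V gene
and a length-14 CDR3 ancestor over the 20-amino-acid alphabet; length 14 is a
typical CDR3 length and keeps the normalized-distance arithmetic transparent
(one substitution = 1/14). Members mutate at most one position (probability
`mutation_rate` per position, capped at one per sequence), which bounds
within-clone pairwise similarity below by 1 - 2/14 ~ 0.857, safely above the
0.85 clonotype threshold; ancestors sharing a V gene are rejection-sampled to
stay below 0.7 similarity so planted clones remain separable.

**Transition matrices** (`generate_transition_matrix()`). Row entries are
independent Gamma(1) draws scaled by a per-subset-pair bias, then
row-normalized. Expected mass from subset a to b is proportional to
`bias[a, b]` times the size of b, so planted directional biases are exactly
the kind of signal the aggregation step is meant to expose. Velocity
estimation itself is out of scope: the matrix is an input.

**Bulk cohorts** (`generate_bulk_cohorts()`). Gene expression is Gaussian
around per-gene baselines; the planted immune and senescence signatures share
a sample-level latent activity that is shifted in responders by
`effect_of_immune` (default 0.8 SD — a moderately predictive baseline
signature) and `effect_of_senescence` (the experimental knob). Because the
latent dominates the set-level score variance, a shift of `e` latent SDs is a
shift of ~`e` pooled score SDs, which is the parameterization the ensemble
experiments are phrased in. Stromal score and tumor purity are uninformative
standard normals: they give the base model realistic nuisance predictors.
Defaults (8 cohorts x 60 samples x 12,000 genes, 40% responders) clear the
downstream cohort filters (>= 10,000 genes, >= 30 labeled samples) by design.

## Consensus NMF and meta-program discovery

`fit_sample_nmf()` factorizes one sample's cells x genes matrix with
multiplicative-update NMF (Frobenius loss) restarted `n_iter` times from
random initializations. The gene spectra of all restarts are L2-normalized
and pooled; spectra whose mean Euclidean distance to their nearest neighbors
(30% of `n_iter`) exceeds `density_threshold` are dropped as outliers; the
survivors are k-means-clustered into `k` consensus spectra (cluster medians);
usages are refit against the fixed consensus. The density threshold default
is 0.01 — strict, keeping only highly reproducible spectra. When the filter
would leave fewer than `k` spectra (typical when `k` exceeds the true rank,
because restarts stop agreeing), the `k` densest are kept with a warning;
this degradation is informative and is exactly what drives rank selection.

Gene scores are reported in Z-score units: per-gene z-scored expression is
regressed on row-normalized usages, so a score is the standardized expression
change associated with one unit of program usage. This makes scores
comparable across factors and samples and gives the module rule below a
well-defined scale.

**Module rule.** A gene joins factor f's module iff (1) its score in f is
strictly above f's mean score across genes, and (2) f is the argmax of the
gene's scores (ties to the lowest-index factor). The rule is stated in the
literature in terms of "rank above the average", which is ambiguous when
scores are per-factor rather than per-cell; the reading adopted here — factor
score strictly above the factor's gene-mean — is the only one that yields
gene modules, and rule (2) guarantees that modules within a sample are
disjoint. The strict inequality matters at the boundary and is pinned by
tests against a brute-force rule evaluator.

**Rank selection** (`select_k()`). For each candidate k two diagnostics are
computed from the same pooled restarts: stability (mean silhouette of the
surviving spectra under consensus clustering) and relative Frobenius
reconstruction error. The selected rank is the largest k with stability
within `tolerance = 0.025` of the maximum; if stability is exactly flat over
the whole range the smallest k wins. The flat-stability tie-break prefers the
simplest model; the "largest within tolerance" rule prefers resolution when
the data support it. On planted 3-program samples at signal 5 this selects
k = 3 in the large majority of seeds (tested).

**Consensus filter** (`filter_consensus_modules()`). A module is retained iff
it has Jaccard >= `min_jaccard` (default 0.05) with at least `min_partners`
other modules. Partner counts are always computed within the supplied set —
re-applying the filter to its own output can therefore remove further modules;
that is the documented semantics, not a bug. The compendium default of 50
partners presumes a corpus of hundreds of modules; at desk scale the floor
should scale with the corpus (the tests use `n_samples - 1`, i.e. "recurs in
every sample", which is the same ~25% tail the large-corpus default targets).

**Co-occurrence network** (`build_cooccurrence_network()`). Modules are first
truncated to their `top_n` strongest genes so that modules of different sizes
contribute equally. For genes g, h: `occ` counts truncated modules containing
the gene, `co` counts modules containing both, and the edge weight is
`co / (occ_g + occ_h)`, which lives in [0, 0.5] and attains 0.5 exactly when
the two genes' module memberships coincide. The default `top_n = 100` is the
compendium-scale setting; at desk scale the tests truncate to the planted
program size (50), for the same reason the paper-scale analysis truncates at
all — keeping each module's contribution to the network at comparable size
and composition. Truncation is the main guard against background genes: genes
that clear the above-mean module rule by chance have low weights and fall out
here, which is what makes community recovery clean.

**Meta-programs** (`detect_metaprograms()`). Weighted Louvain community
detection (resolution default 1.2) partitions the network; communities are
numbered by decreasing size and genes are ranked within each community by
weighted degree (strength) in the community-induced subgraph, ties broken
alphabetically so ranks are a bijection. The Louvain seed is explicit.
`derive_core_module()` generalizes the manual "seed gene + direct network
neighbors" derivation of a compact program (e.g. a senescence module from a
tumor-suppressor seed): it returns the seeds plus their in-program neighbors
ordered by summed edge weight to the seed set.

## Bin-matched signature scoring

`score_signature()` implements control-gene scoring: genes are placed into
`n_bins = 25` equal-frequency bins by mean expression; each signature gene
contributes `n_ctrl` same-bin control genes to a pooled control multiset; the
cell score is mean(signature) - mean(control pool). Controls are sampled
without replacement within a bin, falling back to with-replacement (with a
warning) when the bin is smaller than `n_ctrl` — the degenerate case where a
bin holds only the signature gene itself then yields a score of exactly 0,
which is the correct self-control limit. Bins are computed on all scored
cells jointly; ties in aggregate expression fall to the lower bin via rank
order. The construction's purpose is calibration: a random gene set with the
signature's expression profile scores ~0, and the score is invariant to
cell-constant expression offsets (both properties are tested). The default
`n_ctrl = 100` presumes transcriptome-scale matrices (~25 bins x hundreds of
genes); on the 1,000-gene synthetic cohorts the tests use `n_ctrl = 30` so
bins are not exhausted.

`assign_dominant()` labels each cell with its highest-scoring program (ties
to the first program in declared order), under the modeling assumption that
each malignant cell is driven by one representative program.
`program_response_correlation()` is a plain Pearson correlation with its
two-sided p value on per-sample proportions vs a response measure — zero
variance is an explicit error, not an NA. `score_variance_test()` is the
Brown-Forsythe variant of Levene's test (absolute deviations from group
medians), matching the default of the standard implementation.

`single_sample_enrichment()` is a transparent rank-mean z-score: per sample,
mean expression rank of the set genes, z-scaled across samples. It stands in
for heavier single-sample enrichment machinery (GSVA-style kernels) because
everything downstream only needs a monotone, cohort-standardized set-level
score; the substitution is deliberate and the ensemble results are read as
relative model improvement, not absolute enrichment values.

## Pearson-residual composition analysis

For a groups x subsets count table, `E_ij = T_i T_j / T_tot` and
`r_ij = (O_ij - E_ij) / sqrt(E_ij)`. The sign of `r` gives the direction
(augmentation vs depletion), the sum of `r^2` is the chi-square statistic
with `(rows-1)(cols-1)` degrees of freedom (standard contingency choice, no
continuity correction), and `classify_shifts()` applies the conservative
|r| > 3.5 bar for follow-up calls while also annotating the nominal
|r| > 2 ~ p < 0.05 band. Residuals are only approximately standard normal:
with estimated margins their variance is deflated by
`(1 - p_i)(1 - p_j)`, so the +/-2 band is slightly conservative for small
tables — the calibration test uses 20 x 20 homogeneous tables, where the
deflation is ~5%. Cells with expected count below 5 are flagged, not
excluded; empty rows/columns are excluded with a warning.

## Strict clonotype analysis

`normalized_similarity()` is `1 - levenshtein / max(length)`. The strict
clonotype definition combines the V gene with CDR3 similarity **strictly
above** 0.85; the figure is quoted in the field as a "distance", which only
parses as similarity, and the strict inequality is pinned by a boundary test
(similarity exactly 0.85 does not link). Within each V-gene block, cells are
linked single-linkage (connected components of the similarity graph) — the
linkage is not stated in the original description, and single linkage is what
connected components of a threshold graph give. Clonotype IDs are canonical
(V gene + lexicographically smallest member CDR3), so results are invariant
to row order. Raising the threshold can only refine the partition (tested).
Multi-contig cells collapse to their first row with a warning; paired-chain
logic is out of scope.

Expansion classes: `single` (1 cell), `expanded_small` (2-4),
`expanded_large` (>= 5). `extract_tumor_reactive()` returns the reference
exhausted subset (e.g. CXCL13+ Tex) plus every cell sharing a clonotype with
it — clonal linkage to the exhausted pool read as evidence of tumor-antigen
encounter. `clonotype_fate()` compares clonotype inventories across
timepoints (persistent / emergent / lost).

## Transition-density aggregation

Given a row-stochastic cell-to-cell transition matrix, the per-start-cell
density into a target subset is the sum of transition probabilities over the
subset's cells, which corrects for subset abundance. Start cells with zero
total mass into the target are excluded **after** summation — a start cell
with some zero entries but positive total is kept; this is the reading
adopted for the stated zero-exclusion and it is the one under which densities
over a partition of targets sum to exactly 1. Self-transitions are included
when start and target coincide (the persistence readout). Distributions are
compared with the two-sided two-sample Kolmogorov-Smirnov test; its type-I
rate is verified at the nominal 5% under the null.

## Gene-network comparison

Patient- or group-level cell-type-specific networks are inputs (their
construction is reference-interactome-guided inference, external to this
package). `node_profiles()` turns each network into a binary membership
vector over the union node space; `pairwise_profile_distance()` is the
Euclidean distance between those vectors (= sqrt(Hamming)), with an optional
adjacency mode that vectorizes the weighted upper triangle instead — the two
readings of "distance from the adjacency matrix of a union gene set" — with
node membership as the default. `group_similarity_tests()` contrasts pooled
within-group distances with a two-sided t test (location) and
Fligner-Killeen (spread). Centrality is weighted degree converted to a
percentile rank (average rank for ties, divided by node count) to normalize
for node-set size; it is invariant under uniform edge-weight scaling.
`differential_hub_signature()` keeps the genes of a chosen subcommunity that
are modeled in both networks and strictly hubbier in the reference network,
ranked by reference centrality, truncated to `top_n = 30` — the procedure
that turns "hubbier in responders" into a compact signature. Comparing a
network to itself yields an empty signature by construction.

## Leave-one-study-out ensemble

`assemble_features()` applies the compendium filters (>= 10,000 genes, known
binary labels only, >= 30 labeled samples), projects every cohort onto a
fixed gene space with absent genes at 0, computes immune and senescence
scores by rank-mean enrichment, and attaches supplied stromal/purity values.
`train_loso_ensemble()` fits one probability random forest per cohort on all
other cohorts (maximum tree depth 5; 500 trees and sqrt(p) features per
split — the depth is the stated constraint, the rest are unstated and set to
common defaults, all configurable) and records each sample's single held-out
probability; the ensemble prediction for new data is the mean of member
probabilities. Feature importance is impurity (Gini) importance. Training is
deterministic given the seed (single-threaded member fits with derived
seeds), and held-out predictions provably ignore the held-out cohort (the
test corrupts a held-out cohort's labels and asserts unchanged predictions).
AUROC is computed from the midrank (Mann-Whitney) statistic with midrank tie
handling, cross-checked against pairwise counting and an independent ROC
library. `compare_with_without()` trains base and base+candidate ensembles
under identical seeds and reports both pooled AUROCs plus the mean TPR
difference over the FPR band [0.4, 0.6], where ambiguous samples
concentrate. The optional filter that drops cohorts with no predictive power
for any signature is a data-dependent manual step in the original workflow
and is off by default here.

## Numerical choices and degenerate inputs

- NMF updates run up to 120 iterations with a relative-error stopping rule
  (1e-5, checked every 20); epsilon 1e-12 guards divisions.
- k-means consensus uses 10 restarts from a derived seed; a pool of exactly
  k spectra maps to the identity clustering (the `n_iter = 1` no-op case).
- Rank-deficient usage crossproducts fall back to a pseudoinverse.
- All-zero factors produce empty modules and are logged, not errors.
- Hypergeometric tail probabilities are floored at the smallest positive
  double before `-log10`.
- Every stochastic entry point takes an explicit integer seed; child seeds
  are derived arithmetically and stay below 2^31.

## Problem sizes used in the checks

The acceptance-style checks run at desk scale, chosen so the full suite
completes on a single CPU while leaving the contracts sharp: discovery on
6 x 200 x 1,000 cohorts with `n_iter = 8` restarts over 20 seeds; clonotype
oracle equivalence on 100 repertoires of up to 500 contigs; 10,000
multinomial tables for residual calibration; 1,000-cell transition matrices;
8 x 60 bulk cohorts with 50 ensemble replicates per planted-effect level;
100 random signatures for scoring calibration. Larger `n_iter` (the
compendium-scale default is 100) sharpens consensus spectra but does not
change any tested contract.

## Known limitations

- The Poisson cohort generator cannot probe robustness to overdispersion,
  batch effects, or ambient contamination.
- Consensus NMF quality is assessed by planted-truth recovery, not by
  bit-compatibility with any particular external implementation.
- Rank-mean enrichment is a monotone stand-in for kernel-based single-sample
  enrichment; absolute score values are not comparable across methods.
- Single-chain clonotyping only; paired alpha/beta logic is out of scope.
- Network construction and velocity estimation are inputs, not outputs.
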