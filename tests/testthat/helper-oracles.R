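# Independent brute-force oracles used to cross-check the implementations.

# O(n^2) union-find clonotyper: same V gene AND similarity strictly > threshold.
# All n^2 pairs are evaluated (no V-gene blocking, no canonicalization);
# the pairwise edit distances come from one vectorized utils::adist call.
oracle_clonotypes <- function(contigs, threshold = 0.85) {
  n <- nrow(contigs)
  d <- utils::adist(contigs$cdr3)
  len <- nchar(contigs$cdr3)
  sim <- 1 - d / outer(len, len, pmax)
  same_v <- outer(contigs$v_gene, contigs$v_gene, `==`)
  link <- which(sim > threshold & same_v & upper.tri(sim), arr.ind = TRUE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(link))) {
    ri <- find(link[r, 1]); rj <- find(link[r, 2])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}

# partition equality up to label names
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, integer(1)))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, integer(1)))]))
}

# literal evaluation of the two module-inclusion rules
oracle_modules <- function(scores) {
  k <- ncol(scores)
  means <- colMeans(scores)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    genes <- character(0)
    for (g in rownames(scores)) {
      row <- scores[g, ]
      best <- which(row == max(row))[1]      # ties -> lowest factor index
      if (best == f && row[f] > means[f]) genes <- c(genes, g)
    }
    out[[f]] <- genes
  }
  out
}

# pairwise-comparison AUROC with half credit for ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# upper-tail hypergeometric by explicit enumeration (small universes)
oracle_hyper_tail <- function(overlap, size_a, size_b, universe) {
  js <- overlap:min(size_a, size_b)
  sum(choose(size_a, js) * choose(universe - size_a, size_b - js)) /
    choose(universe, size_b)
}

# random contig table with planted clusters and loose singletons
random_contigs <- function(n, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_anc <- max(2L, rpois(1, n / 8))
  anc <- replicate(n_anc, paste(sample(aa, sample(10:16, 1), replace = TRUE),
                                collapse = ""))
  vs <- sample(paste0("TRBV", 1:3), n_anc, replace = TRUE)
  pick <- sample(n_anc, n, replace = TRUE)
  cdr3 <- vapply(pick, function(i) {
    s <- strsplit(anc[i], "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      pos <- sample(length(s), nmut)
      s[pos] <- sample(aa, nmut, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  tibble::tibble(barcode = sprintf("bc%04d", seq_len(n)),
                 v_gene = vs[pick], cdr3 = cdr3)
}

# best-match Jaccard of each detected community against planted gene sets
best_match_jaccard <- function(metaprograms, planted) {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  vapply(split(metaprograms$gene, metaprograms$program_id),
         function(g) max(vapply(planted, jac, numeric(1), a = g)),
         numeric(1))
}

# desk-scale meta-program discovery chain used across tests
run_discovery <- function(seed, signal_strength = 5, n_samples = 6,
                          cells_per_sample = 200, n_genes = 1000,
                          n_iter = 8) {
  coh <- generate_program_cohort(cohort_config(
    n_samples = n_samples, cells_per_sample = cells_per_sample,
    n_genes = n_genes, n_shared_programs = 3, program_size = 50,
    signal_strength = signal_strength, noise_rate = 0.2, seed = seed))
  res <- suppressWarnings(discover_metaprograms(
    coh$counts, coh$cells, k = 3, n_iter = n_iter, n_top_genes = n_genes,
    min_jaccard = 0.05, min_partners = n_samples - 1, top_n = 50,
    resolution = 1.2, seed = seed + 1000))
  list(result = res, truth = coh$truth)
}
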