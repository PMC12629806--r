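test_that("module extraction applies both inclusion rules exactly", {
  scores <- matrix(c(3, 0, 0, 1, 0, 3, 1, 0), 4,
                   dimnames = list(paste0("g", 1:4), c("f1", "f2")))
  mods <- extract_modules(scores, sample_id = "s")
  # means are 1.0; g4 (score 1.0) fails the strict inequality, g3 likewise
  expect_equal(mods$gene[mods$module_id == "s_m1"], "g1")
  expect_equal(mods$gene[mods$module_id == "s_m2"], "g2")

  # exhaustive agreement with the brute-force rule evaluator
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(rnorm(8), 4, dimnames = list(paste0("g", 1:4), NULL))
    got <- extract_modules(m, sample_id = "x")
    want <- oracle_modules(m)
    for (f in 1:2) {
      expect_setequal(got$gene[got$module_id == paste0("x_m", f)],
                      want[[f]])
    }
    # modules within a sample are disjoint
    expect_equal(anyDuplicated(got$gene), 0L)
  }
})

test_that("tied genes land in the lowest-index factor only", {
  scores <- matrix(c(2, 0, 2, 0), 2, dimnames = list(c("g1", "g2"), NULL))
  mods <- extract_modules(scores, sample_id = "t")
  expect_equal(mods$module_id[mods$gene == "g1"], "t_m1")
  expect_equal(sum(mods$gene == "g1"), 1L)
})

test_that("consensus NMF recovers planted programs and is deterministic", {
  coh <- generate_program_cohort(cohort_config(
    n_samples = 1, cells_per_sample = 150, n_genes = 300,
    n_shared_programs = 2, program_size = 40, signal_strength = 5, seed = 21))
  fit <- suppressWarnings(fit_sample_nmf(coh$counts, k = 2, n_iter = 8,
                                         n_top_genes = 300, seed = 5))
  mods <- extract_modules(fit)
  planted <- coh$truth$shared_program_genes
  recall <- vapply(split(mods$gene, mods$module_id), function(g)
    max(vapply(planted, function(p) mean(p %in% g), numeric(1))), numeric(1))
  expect_true(all(recall >= 0.9))
  # precision of each module's top genes against its planted set
  top40 <- dplyr::slice_max(dplyr::group_by(mods, module_id),
                            order_by = weight, n = 40, with_ties = FALSE)
  prec <- vapply(split(top40$gene, top40$module_id), function(g)
    max(vapply(planted, function(p) mean(g %in% p), numeric(1))), numeric(1))
  expect_true(all(prec >= 0.8))

  fit2 <- suppressWarnings(fit_sample_nmf(coh$counts, k = 2, n_iter = 8,
                                          n_top_genes = 300, seed = 5))
  expect_identical(fit$gene_scores, fit2$gene_scores)
  expect_error(fit_sample_nmf(coh$counts, k = 1), "k must be")
})

test_that("a single restart degenerates to one factorization", {
  coh <- generate_program_cohort(cohort_config(
    n_samples = 1, cells_per_sample = 60, n_genes = 150,
    n_shared_programs = 2, program_size = 30, seed = 3))
  fit <- suppressWarnings(fit_sample_nmf(coh$counts, k = 2, n_iter = 1,
                                         n_top_genes = 150, seed = 9))
  expect_equal(fit$n_spectra_kept, 2)
  expect_equal(dim(fit$usage), c(60, 2))
})

test_that("rank selection finds the planted number of programs", {
  hits <- 0
  for (s in 1:8) {
    coh <- generate_program_cohort(cohort_config(
      n_samples = 1, cells_per_sample = 150, n_genes = 400,
      n_shared_programs = 3, program_size = 40, signal_strength = 5,
      seed = s))
    k <- suppressWarnings(select_k(coh$counts, k_range = 2:5, n_iter = 8,
                                   n_top_genes = 400, seed = s + 50))
    hits <- hits + (k == 3L)
  }
  expect_gte(hits, 6)
  expect_error(select_k(matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                        k_range = integer(0)), "empty")
  # diagnostics travel with the selection
  coh <- generate_program_cohort(cohort_config(
    n_samples = 1, cells_per_sample = 80, n_genes = 200,
    n_shared_programs = 2, program_size = 30, seed = 70))
  k <- suppressWarnings(select_k(coh$counts, k_range = c(2, 3), n_iter = 5,
                                 n_top_genes = 200, seed = 4))
  expect_s3_class(attr(k, "diagnostics"), "tbl_df")
})

test_that("the consensus filter counts partners within the input set", {
  mk <- function(id, genes) tibble::tibble(module_id = id, sample_id = id,
                                           gene = genes,
                                           weight = rev(seq_along(genes)))
  # five identical modules: each has 4 partners at J = 1
  five <- as_module_set(dplyr::bind_rows(lapply(paste0("m", 1:5), mk,
                                                genes = paste0("g", 1:10))))
  kept <- filter_consensus_modules(five, min_jaccard = 0.05, min_partners = 3)
  expect_equal(length(unique(kept$module_id)), 5)
  # pairwise-disjoint modules: none retained for positive thresholds
  disj <- as_module_set(dplyr::bind_rows(
    lapply(1:4, function(i) mk(paste0("d", i), paste0("g", i * 100 + 1:5)))))
  expect_equal(nrow(filter_consensus_modules(disj, 0.05, 1)), 0)
  # J({a,b,c},{b,c,d}) = 0.5 counts as a partner
  two <- as_module_set(dplyr::bind_rows(mk("x", c("a", "b", "c")),
                                        mk("y", c("b", "c", "d"))))
  expect_equal(length(unique(filter_consensus_modules(two, 0.05, 1)$module_id)), 2)
  expect_warning(filter_consensus_modules(two, 0.05, 5), "no module")
})

test_that("overlap significance matches closed-form and enumerated hypergeometrics", {
  mk <- function(id, genes) tibble::tibble(module_id = id, sample_id = id,
                                           gene = genes, weight = 1)
  universe <- paste0("u", 1:100)
  ms <- as_module_set(dplyr::bind_rows(mk("a", universe[1:10]),
                                       mk("b", universe[1:10]),
                                       mk("c", universe[90:95])),
                      universe = universe)
  sig <- overlap_significance(ms)
  expect_equal(sig["a", "b"], -log10(1 / choose(100, 10)), tolerance = 1e-9)
  expect_equal(sig["a", "c"], 0)          # zero overlap: P(X >= 0) = 1
  expect_equal(sig, t(sig))
  # brute-force enumeration agreement on small universes
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    u <- paste0("g", seq_len(n))
    s1 <- sample(u, sample(2:6, 1)); s2 <- sample(u, sample(2:6, 1))
    ms2 <- as_module_set(dplyr::bind_rows(mk("p", s1), mk("q", s2)),
                         universe = u)
    got <- overlap_significance(ms2)["p", "q"]
    want <- -log10(oracle_hyper_tail(length(intersect(s1, s2)),
                                     length(s1), length(s2), n))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("co-occurrence weights count truncated-module memberships", {
  mk <- function(id, genes, w = rev(seq_along(genes)))
    tibble::tibble(module_id = id, sample_id = id, gene = genes, weight = w)
  ms <- as_module_set(dplyr::bind_rows(
    mk("m1", c("g", "x1")), mk("m2", c("g", "h")), mk("m3", c("g", "h")),
    mk("m4", c("h", "x2"))))
  net <- build_cooccurrence_network(ms, top_n = 10)
  e <- net$edges
  gh <- e[(e$gene_a == "g" & e$gene_b == "h") |
            (e$gene_a == "h" & e$gene_b == "g"), ]
  expect_equal(gh$weight, 2 / (3 + 3))    # co=2, occ 3 and 3
  # perfectly coupled genes attain the 0.5 maximum
  ms2 <- as_module_set(dplyr::bind_rows(mk("m1", c("p", "q")),
                                        mk("m2", c("p", "q"))))
  expect_equal(build_cooccurrence_network(ms2)$edges$weight[1], 0.5)
  # never-co-occurring genes get no edge
  expect_false(any((e$gene_a == "x1" & e$gene_b == "x2") |
                     (e$gene_a == "x2" & e$gene_b == "x1")))
  expect_true(all(e$weight > 0 & e$weight <= 0.5))
  # truncation drops low-weight genes from the occurrence counts
  ms3 <- as_module_set(mk("big", paste0("z", 1:20), w = 20:1))
  net3 <- build_cooccurrence_network(ms3, top_n = 5)
  expect_equal(nrow(net3$occurrence), 5)
})

test_that("meta-program detection partitions the network and ranks by centrality", {
  mk <- function(id, genes) tibble::tibble(module_id = id, sample_id = id,
                                           gene = genes,
                                           weight = rev(seq_along(genes)))
  # two gene blocks recurring in separate module groups
  blockA <- paste0("a", 1:6); blockB <- paste0("b", 1:6)
  ms <- as_module_set(dplyr::bind_rows(
    lapply(1:4, function(i) mk(paste0("mA", i), blockA)),
    lapply(1:4, function(i) mk(paste0("mB", i), blockB))))
  net <- build_cooccurrence_network(ms)
  mp <- detect_metaprograms(net, resolution = 1.2, seed = 2)
  expect_equal(length(unique(mp$program_id)), 2)
  expect_setequal(mp$gene, c(blockA, blockB))
  expect_equal(anyDuplicated(mp$gene), 0L)
  # centrality ranks are a bijection onto 1..n within each program
  for (p in unique(mp$program_id)) {
    expect_equal(sort(mp$centrality_rank[mp$program_id == p]),
                 seq_len(sum(mp$program_id == p)))
  }
  expect_s3_class(autoplot(mp), "ggplot")
})

test_that("core-module derivation collects in-program neighbors of the seeds", {
  edges <- tibble::tibble(
    gene_a = c("s", "s", "s", "s", "s", "out"),
    gene_b = c("l1", "l2", "l3", "l4", "l5", "s"),
    weight = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.45), co = 1)
  net <- structure(list(edges = edges,
                        occurrence = tibble::tibble(
                          gene = c("s", paste0("l", 1:5), "out"), occ = 1L)),
                   class = "cooc_network")
  program <- c("s", paste0("l", 1:5))
  core <- derive_core_module(net, program, "s")
  expect_equal(core$gene, c("s", paste0("l", 1:5)))   # star recovered, sorted by weight
  expect_false("out" %in% core$gene)
  expect_error(derive_core_module(net, program, c("s", "zz")), "outside")
  # seeds with no neighbors return just the seeds
  lonely <- structure(list(edges = edges[0, ],
                           occurrence = tibble::tibble(gene = "s", occ = 1L)),
                      class = "cooc_network")
  expect_equal(derive_core_module(lonely, "s", "s")$gene, "s")
})

test_that("planted meta-program recovery improves with signal strength", {
  mean_best <- vapply(c(1, 5), function(sig) {
    vals <- vapply(1:3, function(s) {
      run <- run_discovery(s + 200, signal_strength = sig, n_samples = 3,
                           cells_per_sample = 100, n_genes = 300, n_iter = 5)
      mean(best_match_jaccard(run$result$metaprograms,
                              run$truth$shared_program_genes))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gte(mean_best[2], mean_best[1])
})
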