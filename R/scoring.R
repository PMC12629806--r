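#' Score cells for a gene signature against bin-matched controls
#'
#' Classic control-gene module scoring: all analyzed genes are placed into
#' `n_bins` equal-frequency bins by their aggregate (mean across cells)
#' expression; for every signature gene, `n_ctrl` genes are drawn from its
#' bin to form a pooled control set. The cell score is the mean expression of
#' the signature genes minus the mean expression of the pooled control set,
#' so a random gene set with the same expression profile scores ~0.
#'
#' Control genes are drawn without replacement within a bin; when a bin holds
#' fewer than `n_ctrl` candidates, sampling falls back to with-replacement
#' with a warning. Signature genes missing from the matrix are dropped with a
#' warning.
#'
#' @param expr Normalized expression matrix, cells x genes (dense or sparse),
#'   with dimnames.
#' @param genes Character vector: the gene signature.
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes per signature gene (default 100).
#' @param seed Integer seed for control sampling.
#' @return A tibble with columns `cell`, `score`; the signature size and
#'   parameters are attached as attributes.
#' @export
score_signature <- function(expr, genes, n_bins = 25, n_ctrl = 100,
                            seed = 1L) {
  expr <- as_expr_matrix(expr, "expr")
  present <- intersect(genes, colnames(expr))
  if (length(present) == 0L) abort("no signature gene is present in the matrix")
  if (length(present) < length(genes)) {
    warn(sprintf("%d signature gene(s) absent from the matrix; dropped",
                 length(genes) - length(present)))
  }
  aggregate <- Matrix::colMeans(expr)
  bins <- equal_freq_bins(aggregate, n_bins)
  names(bins) <- colnames(expr)

  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- colnames(expr)[bins == bins[g]]
    if (length(pool) >= n_ctrl) {
      sample(pool, n_ctrl)
    } else {
      warn(sprintf("bin of gene %s holds %d < %d genes; sampling with replacement",
                   g, length(pool), n_ctrl))
      sample(pool, n_ctrl, replace = TRUE)
    }
  }), use.names = FALSE)

  sig_mean <- Matrix::rowMeans(expr[, present, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(expr[, ctrl, drop = FALSE])
  out <- tibble::tibble(cell = rownames(expr),
                        score = as.numeric(sig_mean - ctrl_mean))
  attr(out, "n_genes") <- length(present)
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  out
}

#' Score cells for each meta-program
#'
#' Convenience wrapper: scores every meta-program with [score_signature()]
#' using its top `top_n_genes` genes ranked by degree centrality.
#'
#' @param expr Normalized expression matrix, cells x genes.
#' @param metaprograms A `metaprogram_set` from [detect_metaprograms()].
#' @param top_n_genes Genes per program used for scoring (default 50).
#' @inheritParams score_signature
#' @return Named list of score tibbles, one per program.
#' @export
score_metaprograms <- function(expr, metaprograms, top_n_genes = 50,
                               n_bins = 25, n_ctrl = 100, seed = 1L) {
  split_mp <- split(metaprograms, metaprograms$program_id)
  lapply(split_mp, function(mp) {
    top <- mp$gene[order(mp$centrality_rank)][seq_len(min(top_n_genes, nrow(mp)))]
    score_signature(expr, top, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  })
}

#' Assign each cell to its dominant program
#'
#' Each cell is labeled with the program of its highest score; exact ties go
#' to the first program in list order (documented, deterministic).
#'
#' @param scores Named list of score tibbles (`cell`, `score`), one per
#'   program, all covering the same cells.
#' @return Tibble with columns `cell`, `program`.
#' @export
assign_dominant <- function(scores) {
  stopifnot(is.list(scores), length(scores) >= 1L, !is.null(names(scores)))
  cells <- scores[[1]]$cell
  mat <- vapply(scores, function(s) {
    if (!setequal(s$cell, cells) || nrow(s) != length(cells)) {
      abort("all score vectors must cover the same cells")
    }
    s$score[match(cells, s$cell)]
  }, numeric(length(cells)))
  idx <- max.col(mat, ties.method = "first")
  tibble::tibble(cell = cells, program = names(scores)[idx])
}

#' Correlate per-sample program proportions with tumor regression
#'
#' Pearson correlation between the per-sample proportion of cells dominated
#' by a program and a per-sample response measure (e.g. pathological tumor
#' regression), with its two-sided p value.
#'
#' @param proportions,regression Numeric vectors paired by sample (names, if
#'   present on both, are used for alignment).
#' @return Tibble with `estimate` (r), `statistic`, `p.value`, `n`.
#' @export
program_response_correlation <- function(proportions, regression) {
  if (!is.null(names(proportions)) && !is.null(names(regression))) {
    regression <- regression[names(proportions)]
  }
  if (length(proportions) != length(regression) || length(proportions) < 3L) {
    abort("need >= 3 paired samples")
  }
  if (sd(proportions) == 0 || sd(regression) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- cor.test(proportions, regression, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value, n = length(proportions))
}

#' Test for a variance shift in signature scores between two groups
#'
#' Brown-Forsythe/Levene test (absolute deviations from the group medians)
#' for a difference in score dispersion, e.g. pre- vs post-treatment
#' senescence-program enrichment.
#'
#' @param scores Score tibble (`cell`, `score`) from [score_signature()].
#' @param groups Named vector mapping cells to two group labels.
#' @return Tibble with `statistic`, `p.value` and the two group variances
#'   (`var_<label>` columns).
#' @export
score_variance_test <- function(scores, groups) {
  g <- factor(groups[scores$cell])
  if (anyNA(g)) abort("every scored cell needs a group label")
  if (nlevels(g) != 2L) abort("exactly two groups required")
  if (any(table(g) < 2L)) abort("each group needs >= 2 cells")
  lt <- car::leveneTest(scores$score, g)   # center = median (Brown-Forsythe)
  vars <- tapply(scores$score, g, var)
  out <- tibble::tibble(statistic = lt[1, "F value"],
                        p.value = lt[1, "Pr(>F)"])
  out[paste0("var_", levels(g))] <- as.list(unname(vars))
  out
}

#' Single-sample gene-set enrichment by rank-mean z-score
#'
#' A transparent single-sample enrichment score for bulk cohorts: per sample,
#' genes are ranked by expression (average rank for ties), the mean rank of
#' the set genes is taken, and the per-sample means are z-scaled across the
#' cohort. Monotone in the set genes' relative expression; a set comprising
#' all genes scores 0 everywhere.
#'
#' @param bulk Expression matrix, genes x samples, with dimnames.
#' @param genes Character vector of set genes.
#' @return Tibble with columns `sample`, `score`.
#' @export
single_sample_enrichment <- function(bulk, genes) {
  bulk <- as_expr_matrix(bulk, "bulk")
  multi_set_enrichment(bulk, list(set = genes))[[1]]
}

# shared workhorse: rank each sample once, score several sets from it
multi_set_enrichment <- function(bulk, gene_sets) {
  present <- lapply(gene_sets, intersect, x = rownames(bulk))
  if (any(lengths(present) == 0L)) {
    abort("gene set does not intersect the matrix")
  }
  ranks <- apply(as.matrix(bulk), 2, rank, ties.method = "average")
  lapply(present, function(g) {
    raw <- base::colMeans(ranks[g, , drop = FALSE])
    s <- sd(raw)
    score <- if (s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
    tibble::tibble(sample = colnames(bulk), score = as.numeric(score))
  })
}
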