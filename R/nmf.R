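#' Consensus non-negative matrix factorization of one sample
#'
#' Decomposes a sample's cells-x-genes count matrix into `k` additive gene
#' expression programs by consensus NMF: the factorization is restarted
#' `n_iter` times from random initializations, the gene spectra of all
#' restarts are pooled, spectra in low-density regions (mean Euclidean
#' distance to their nearest neighbors above `density_threshold`) are dropped
#' as outliers, the survivors are clustered into `k` consensus spectra
#' (cluster medians), and cell usages are refit against the consensus.
#' Gene scores are returned in Z-score units: per-gene z-scored expression is
#' regressed on the normalized usages, so a score is the standardized
#' expression change associated with one unit of program usage.
#'
#' Cells and genes with zero total counts are removed, genes may be
#' restricted to a coding-gene `universe`, and the factorization runs on the
#' `n_top_genes` most over-dispersed genes (variance/mean ratio).
#'
#' @param counts Count matrix for one sample, cells x genes, dimnames
#'   required.
#' @param k Number of programs (>= 2).
#' @param n_iter Number of random restarts (default 100).
#' @param n_top_genes Over-dispersed genes used for the factorization
#'   (default 4000; all genes, with a warning, when fewer are available).
#' @param density_threshold Mean nearest-neighbor distance above which a
#'   pooled spectrum is discarded as an outlier (default 0.01). If the filter
#'   would leave fewer than `k` spectra, the `k` densest are kept, with a
#'   warning.
#' @param universe Optional character vector restricting the gene space
#'   (e.g. a coding-gene list).
#' @param sample_id Identifier stored on the result.
#' @param seed Integer seed; all restarts derive from it.
#' @return A `sample_nmf` object: list with `sample_id`, `k`, `gene_scores`
#'   (genes x k, Z-score units), `usage` (cells x k), `consensus_spectra`,
#'   `stability` (mean silhouette of the pooled spectra), `recon_error`
#'   (relative Frobenius error) and `n_spectra_kept`.
#' @export
fit_sample_nmf <- function(counts, k, n_iter = 100, n_top_genes = 4000,
                           density_threshold = 0.01, universe = NULL,
                           sample_id = "sample", seed = 1L) {
  if (k < 2L) abort("k must be >= 2")
  x <- prepare_nmf_matrix(counts, n_top_genes, universe)
  pool <- pool_nmf_restarts(x, k, n_iter, seed)
  cons <- consensus_from_pool(x, pool, k, n_iter, density_threshold, seed)

  # gene scores in Z units: regress per-gene z-scored expression on usage
  u <- cons$usage / pmax(rowSums(cons$usage), 1e-12)
  z <- scale(as.matrix(x))
  z[is.na(z)] <- 0
  coefs <- tryCatch(solve(crossprod(u), crossprod(u, z)),
                    error = function(e) MASS_ginv(crossprod(u)) %*% crossprod(u, z))
  gene_scores <- t(coefs)
  colnames(gene_scores) <- paste0("factor", seq_len(k))

  structure(list(
    sample_id = sample_id, k = k,
    gene_scores = gene_scores,
    usage = cons$usage,
    consensus_spectra = cons$spectra,
    stability = cons$stability,
    recon_error = cons$recon_error,
    n_spectra_kept = cons$n_kept),
    class = "sample_nmf")
}

# minimal Moore-Penrose fallback for rank-deficient usage crossproducts
MASS_ginv <- function(m) {
  s <- svd(m)
  pos <- s$d > max(s$d) * 1e-10
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# filter, restrict to universe, pick over-dispersed genes, normalize
prepare_nmf_matrix <- function(counts, n_top_genes, universe) {
  counts <- as_expr_matrix(counts, "counts")
  if (!is.null(universe)) {
    keep <- colnames(counts) %in% universe
    if (!any(keep)) abort("no gene of the matrix is in the supplied universe")
    counts <- counts[, keep, drop = FALSE]
  }
  counts <- counts[Matrix::rowSums(counts) > 0, , drop = FALSE]
  counts <- counts[, Matrix::colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    abort("no cells or genes left after zero filtering")
  }
  mu <- Matrix::colMeans(counts)
  v <- Matrix::colMeans(counts^2) - mu^2
  disp <- v / pmax(mu, 1e-12)
  if (ncol(counts) > n_top_genes) {
    keep <- order(disp, decreasing = TRUE)[seq_len(n_top_genes)]
    counts <- counts[, sort(keep), drop = FALSE]
  } else if (ncol(counts) < n_top_genes) {
    warn(sprintf("only %d variable genes available (< %d); using all",
                 ncol(counts), n_top_genes))
  }
  # depth-normalize cells, unit-variance genes (kept nonnegative)
  depth <- Matrix::rowSums(counts)
  x <- counts / depth * stats::median(depth)
  sds <- sqrt(pmax(Matrix::colMeans(x^2) - Matrix::colMeans(x)^2, 1e-12))
  as.matrix(x) %*% diag(1 / sds, ncol(x)) -> xs
  dimnames(xs) <- dimnames(x)
  xs
}

# one multiplicative-update NMF run (Frobenius loss)
nmf_once <- function(x, k, seed, n_updates = 120, tol = 1e-5) {
  set.seed(seed)
  n <- nrow(x); g <- ncol(x)
  w <- matrix(runif(n * k, 0.1, 1), n, k)
  h <- matrix(runif(k * g, 0.1, 1), k, g)
  err_old <- Inf
  for (it in seq_len(n_updates)) {
    h <- h * crossprod(w, x) / (crossprod(w) %*% h + 1e-12)
    w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + 1e-12)
    if (it %% 20L == 0L) {
      err <- sum((x - w %*% h)^2)
      if (abs(err_old - err) < tol * abs(err_old)) break
      err_old <- err
    }
  }
  list(w = w, h = h)
}

# run restarts and pool L2-normalized gene spectra
pool_nmf_restarts <- function(x, k, n_iter, seed) {
  spectra <- vector("list", n_iter)
  for (r in seq_len(n_iter)) {
    fit <- nmf_once(x, k, child_seed(seed, r))
    h <- fit$h / pmax(sqrt(rowSums(fit$h^2)), 1e-12)
    spectra[[r]] <- h
  }
  do.call(rbind, spectra)
}

# density-filter pooled spectra, cluster to k medians, refit usage
consensus_from_pool <- function(x, pool, k, n_iter, density_threshold, seed) {
  n_neighbors <- max(1L, as.integer(round(0.3 * n_iter)))
  d <- as.matrix(stats::dist(pool))
  density <- apply(d, 1, function(row)
    mean(sort(row[-which.min(row)])[seq_len(min(n_neighbors, length(row) - 1L))]))
  keep <- density <= density_threshold
  if (sum(keep) < k) {
    warn(sprintf(
      "density filter at %.3g keeps %d < k spectra; keeping the %d densest",
      density_threshold, sum(keep), k))
    keep <- rank(density, ties.method = "first") <= k
  }
  pool_kept <- pool[keep, , drop = FALSE]

  set.seed(child_seed(seed, 999983L))
  if (nrow(pool_kept) == k) {
    cl <- list(cluster = seq_len(k))
  } else {
    cl <- kmeans(pool_kept, centers = k, nstart = 10, iter.max = 50)
  }
  stability <- mean_silhouette(stats::dist(pool_kept), cl$cluster)
  spectra <- t(vapply(seq_len(k), function(j) {
    members <- pool_kept[cl$cluster == j, , drop = FALSE]
    apply(members, 2, median)
  }, numeric(ncol(pool_kept))))
  spectra <- spectra / pmax(sqrt(rowSums(spectra^2)), 1e-12)
  dimnames(spectra) <- list(paste0("factor", seq_len(k)), colnames(x))

  # refit usage against fixed consensus spectra
  usage <- matrix(runif(nrow(x) * k, 0.1, 1), nrow(x), k,
                  dimnames = list(rownames(x), rownames(spectra)))
  for (it in 1:60) {
    usage <- usage * (x %*% t(spectra)) /
      (usage %*% tcrossprod(spectra) + 1e-12)
  }
  recon <- usage %*% spectra
  list(spectra = spectra, usage = usage, stability = stability,
       recon_error = sqrt(sum((x - recon)^2)) / sqrt(sum(x^2)),
       n_kept = nrow(pool_kept))
}

#' @export
print.sample_nmf <- function(x, ...) {
  cat(sprintf(
    "Consensus NMF of sample '%s': k = %d, %d genes, %d cells\n",
    x$sample_id, x$k, nrow(x$gene_scores), nrow(x$usage)))
  cat(sprintf("stability %.3f | relative error %.3f | %d pooled spectra kept\n",
              x$stability, x$recon_error, x$n_spectra_kept))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sample_nmf <- function(x, ...) {
  out <- tibble::as_tibble(x$gene_scores, rownames = "gene")
  tidyr::pivot_longer(out, -"gene", names_to = "factor", values_to = "score")
}

#' @exportS3Method generics::glance
glance.sample_nmf <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, k = x$k,
                 stability = x$stability, recon_error = x$recon_error,
                 n_spectra_kept = x$n_spectra_kept)
}

#' Choose the factorization rank by stability and error diagnostics
#'
#' For each candidate `k`, restarts are pooled as in [fit_sample_nmf()] and
#' two diagnostics are computed: stability (mean silhouette of the pooled
#' spectra under consensus clustering) and the relative Frobenius
#' reconstruction error of the consensus refit. The selected rank is the
#' largest `k` whose stability is within `tolerance` of the maximum; when
#' stability is flat across the whole range (exact ties) the smallest `k` is
#' returned.
#'
#' @inheritParams fit_sample_nmf
#' @param k_range Integer vector of candidate ranks (default `2:10`).
#' @param tolerance Stability slack defining near-maximal candidates
#'   (default 0.025).
#' @return The chosen `k` (integer) with the diagnostic tibble
#'   (`k`, `stability`, `error`) attached as attribute `"diagnostics"`.
#' @export
select_k <- function(counts, k_range = 2:10, n_iter = 30, n_top_genes = 4000,
                     density_threshold = 0.01, universe = NULL,
                     tolerance = 0.025, seed = 1L) {
  if (length(k_range) == 0L) abort("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) abort("all candidate k must be >= 2")
  x <- prepare_nmf_matrix(counts, n_top_genes, universe)
  diag_tbl <- purrr::map_dfr(k_range, function(k) {
    pool <- pool_nmf_restarts(x, k, n_iter, child_seed(seed, k))
    cons <- consensus_from_pool(x, pool, k, n_iter, density_threshold,
                                child_seed(seed, k))
    tibble::tibble(k = k, stability = cons$stability,
                   error = cons$recon_error)
  })
  if (length(k_range) == 1L) {
    best <- k_range
  } else if (max(diag_tbl$stability) - min(diag_tbl$stability) < 1e-12) {
    best <- min(k_range)   # flat stability: prefer the simplest model
  } else {
    cand <- diag_tbl$k[diag_tbl$stability >= max(diag_tbl$stability) - tolerance]
    best <- max(cand)
  }
  structure(as.integer(best), diagnostics = diag_tbl)
}

#' Extract gene modules from a sample factorization
#'
#' A gene joins the module of factor `f` iff (1) its Z-score in `f` is
#' strictly above that factor's mean score across genes, and (2) `f` is the
#' argmax of the gene's score across the `k` factors (ties to the
#' lowest-index factor). Rule (2) makes modules within a sample disjoint.
#' All-zero factors produce empty modules and are dropped with a message.
#'
#' @param fact A `sample_nmf` object, or a plain genes x factors score
#'   matrix with dimnames.
#' @param sample_id Used when `fact` is a bare matrix.
#' @return A `module_set`: tibble with columns `module_id`, `sample_id`,
#'   `gene`, `weight` (the factor Z-score), ordered by decreasing weight
#'   within each module.
#' @export
extract_modules <- function(fact, sample_id = NULL) {
  if (inherits(fact, "sample_nmf")) {
    scores <- fact$gene_scores
    sample_id <- sample_id %||% fact$sample_id
  } else {
    scores <- as.matrix(fact)
    sample_id <- sample_id %||% "sample"
  }
  if (any(!is.finite(scores))) abort("gene scores must be finite")
  k <- ncol(scores)
  col_means <- base::colMeans(scores)
  top_factor <- max.col(scores, ties.method = "first")
  rows <- lapply(seq_len(k), function(f) {
    in_module <- top_factor == f & scores[, f] > col_means[f]
    if (!any(in_module)) return(NULL)
    g <- rownames(scores)[in_module]
    w <- scores[in_module, f]
    ord <- order(-w, g)
    tibble::tibble(module_id = paste0(sample_id, "_m", f),
                   sample_id = sample_id, gene = g[ord], weight = w[ord])
  })
  empty <- sum(vapply(rows, is.null, logical(1)))
  if (empty > 0) inform(sprintf("%d factor(s) yielded empty modules", empty))
  out <- dplyr::bind_rows(rows)
  as_module_set(out)
}

#' Bundle gene modules into a module set
#'
#' @param modules Tibble with columns `module_id`, `sample_id`, `gene`,
#'   `weight`.
#' @param universe Optional gene universe attached for overlap statistics.
#' @return A `module_set` tibble.
#' @export
as_module_set <- function(modules, universe = NULL) {
  stopifnot(all(c("module_id", "sample_id", "gene", "weight") %in%
                  names(modules)))
  out <- tibble::as_tibble(modules)
  if (!inherits(out, "module_set")) class(out) <- c("module_set", class(out))
  attr(out, "universe") <- universe
  out
}

#' @exportS3Method generics::glance
glance.module_set <- function(x, ...) {
  tibble::tibble(n_modules = length(unique(x$module_id)),
                 n_samples = length(unique(x$sample_id)),
                 n_genes = length(unique(x$gene)),
                 median_module_size = median(table(x$module_id)))
}

module_gene_list <- function(ms) {
  split(ms$gene, ms$module_id)
}

#' Retain modules that recur across samples
#'
#' A module is kept iff it has a Jaccard index of at least `min_jaccard`
#' with at least `min_partners` other modules of the input set -- the
#' consensus filter that removes patient-private programs. Partner counts are
#' always computed within the supplied set.
#'
#' @param ms A `module_set`.
#' @param min_jaccard Minimum Jaccard index to count a partner
#'   (default 0.05).
#' @param min_partners Minimum number of qualifying partners (default 50).
#' @return Filtered `module_set` (possibly empty, with a warning when
#'   `min_partners` exceeds the attainable partner count).
#' @export
filter_consensus_modules <- function(ms, min_jaccard = 0.05,
                                     min_partners = 50) {
  sets <- module_gene_list(ms)
  if (length(sets) < 2L) abort("need at least 2 modules")
  if (min_partners >= length(sets)) {
    warn(sprintf(
      "min_partners = %d >= %d modules: no module can qualify",
      min_partners, length(sets)))
  }
  jac <- module_jaccard(sets)
  partners <- rowSums(jac >= min_jaccard) - 1L  # exclude self (J = 1)
  keep <- names(sets)[partners >= min_partners]
  as_module_set(ms[ms$module_id %in% keep, ],
                universe = attr(ms, "universe"))
}

module_jaccard <- function(sets) {
  genes <- unique(unlist(sets))
  inc <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  inter <- crossprod(inc)          # |A n B|
  sizes <- base::colSums(inc)
  uni <- outer(sizes, sizes, "+") - inter
  inter / pmax(uni, 1)
}

#' Hypergeometric overlap significance between modules
#'
#' For every module pair, the upper-tail hypergeometric probability of
#' observing at least the actual gene overlap given the two module sizes and
#' the coding-gene universe, returned as `-log10(p)`.
#'
#' @param ms A `module_set` whose `universe` attribute (or `universe`
#'   argument) defines the total gene space.
#' @param universe Optional character vector overriding the attached
#'   universe.
#' @return Symmetric matrix of `-log10` p values (diagonal included).
#' @export
overlap_significance <- function(ms, universe = NULL) {
  universe <- universe %||% attr(ms, "universe")
  if (is.null(universe)) abort("a gene universe is required")
  sets <- module_gene_list(ms)
  outside <- setdiff(unique(ms$gene), universe)
  if (length(outside)) {
    abort(paste0("module genes outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  n <- length(universe)
  m <- length(sets)
  sizes <- lengths(sets)
  out <- matrix(0, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m)) {
    for (j in i:m) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      p <- phyper(ov - 1L, sizes[i], n - sizes[i], sizes[j],
                  lower.tail = FALSE)
      out[i, j] <- out[j, i] <- -log10(max(p, .Machine$double.xmin))
    }
  }
  out
}

#' Build the gene co-occurrence network of a module set
#'
#' Each module is truncated to its `top_n` genes by weight (equalizing the
#' contribution of modules of different sizes); for genes g and h,
#' `occ(g)` counts truncated modules containing g, `co(g, h)` modules
#' containing both, and the edge weight is `co / (occ_g + occ_h)`, which
#' lies in `[0, 0.5]` and attains 0.5 only when the two genes' module
#' memberships coincide exactly. Pairs that never co-occur get no edge.
#'
#' @param ms A `module_set` (typically after
#'   [filter_consensus_modules()]).
#' @param top_n Genes kept per module (default 100).
#' @return A `cooc_network`: list with `edges` (tibble `gene_a`, `gene_b`,
#'   `weight`, `co`) and `occurrence` (tibble `gene`, `occ`).
#' @export
build_cooccurrence_network <- function(ms, top_n = 100) {
  trunc <- dplyr::slice_max(dplyr::group_by(ms, .data$module_id),
                            order_by = .data$weight, n = top_n,
                            with_ties = FALSE)
  sets <- split(trunc$gene, trunc$module_id)
  genes <- sort(unique(unlist(sets)))
  inc <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  co <- tcrossprod(inc)           # genes x genes co-occurrence counts
  occ <- base::rowSums(inc)
  idx <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
  co_counts <- co[idx]
  edges <- tibble::tibble(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    co = co_counts,
    weight = co_counts / (occ[idx[, 1]] + occ[idx[, 2]]))
  structure(list(edges = edges,
                 occurrence = tibble::tibble(gene = genes,
                                             occ = as.integer(occ))),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("Gene co-occurrence network: %d genes, %d edges\n",
              nrow(x$occurrence), nrow(x$edges)))
  invisible(x)
}

cooc_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$gene_a, to = net$edges$gene_b,
               weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = net$occurrence$gene))
}

#' Detect meta-programs as communities of the co-occurrence network
#'
#' Weighted Louvain community detection partitions the co-occurrence network
#' into non-overlapping gene communities -- the meta-programs. Communities
#' are numbered by decreasing size; within each program, genes are ranked by
#' weighted degree centrality inside the community (ties broken
#' alphabetically), giving the centrality ranking used for top-gene scoring.
#' Size-1 communities (disconnected singleton genes) are kept but flagged.
#'
#' @param net A `cooc_network` from [build_cooccurrence_network()].
#' @param resolution Louvain resolution parameter (default 1.2).
#' @param seed Integer seed.
#' @return A `metaprogram_set` tibble: `program_id`, `gene`,
#'   `centrality_rank`, `strength`.
#' @export
detect_metaprograms <- function(net, resolution = 1.2, seed = 1L) {
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$occurrence) == 0L) abort("empty network")
  g <- cooc_igraph(net)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  if (any(sizes == 1L)) {
    inform(sprintf("%d singleton communit(y/ies) detected", sum(sizes == 1L)))
  }
  ord <- names(sort(sizes, decreasing = TRUE))
  relabel <- setNames(sprintf("MP%d", seq_along(ord)), ord)
  out <- purrr::map_dfr(ord, function(cid) {
    nodes <- names(memb)[memb == as.integer(cid)]
    sub <- igraph::induced_subgraph(g, nodes)
    s <- igraph::strength(sub)
    o <- order(-s, names(s))
    tibble::tibble(program_id = unname(relabel[cid]),
                   gene = names(s)[o],
                   centrality_rank = seq_along(o),
                   strength = unname(s[o]))
  })
  class(out) <- c("metaprogram_set", class(out))
  out
}

#' @exportS3Method generics::glance
glance.metaprogram_set <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$program_id),
                   n_genes = dplyr::n(),
                   top_gene = .data$gene[.data$centrality_rank == 1],
                   .groups = "drop")
}

#' @exportS3Method ggplot2::autoplot
autoplot.metaprogram_set <- function(object, ...) {
  d <- glance(object)
  d$program_id <- factor(d$program_id, levels = d$program_id)
  ggplot2::ggplot(d, ggplot2::aes(.data$program_id, .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes in meta-program") +
    ggplot2::theme_minimal()
}

#' Derive a core module from seed genes and their network neighbors
#'
#' Given seed genes inside a meta-program, returns the seeds plus their
#' direct co-occurrence-network neighbors restricted to the program's genes,
#' ordered by total edge weight to the seed set. This generalizes the
#' derivation of a compact senescence module from tumor-suppressor seed
#' genes and their immune-regulatory neighbors.
#'
#' @param net A `cooc_network`.
#' @param program_genes Character vector: the meta-program's genes.
#' @param seed_genes Character vector, subset of `program_genes`.
#' @return Tibble with `gene`, `is_seed`, `weight_to_seed`, seeds first.
#' @export
derive_core_module <- function(net, program_genes, seed_genes) {
  offenders <- setdiff(seed_genes, program_genes)
  if (length(offenders)) {
    abort(paste0("seed genes outside the program: ",
                 paste(offenders, collapse = ", ")))
  }
  e <- net$edges
  touching <- e[e$gene_a %in% seed_genes | e$gene_b %in% seed_genes, ]
  partner <- ifelse(touching$gene_a %in% seed_genes,
                    touching$gene_b, touching$gene_a)
  w <- if (nrow(touching)) c(tapply(touching$weight, partner, sum)) else numeric(0)
  neighbors <- setdiff(intersect(names(w), program_genes), seed_genes)
  ord <- if (length(neighbors)) order(-unname(w[neighbors]), neighbors) else integer(0)
  out <- tibble::tibble(
    gene = c(seed_genes, neighbors[ord]),
    is_seed = c(rep(TRUE, length(seed_genes)),
                rep(FALSE, length(neighbors))))
  out$weight_to_seed <- ifelse(out$gene %in% names(w),
                               as.numeric(w[out$gene]), 0)
  out
}

#' Run the full meta-program discovery chain on a multi-sample cohort
#'
#' Convenience pipeline: per-sample consensus NMF, module extraction,
#' consensus filtering, co-occurrence network construction and Louvain
#' community detection, returning the meta-programs together with the
#' intermediate artifacts.
#'
#' @param counts Count matrix, cells x genes, all samples.
#' @param cells Data frame with columns `cell`, `sample` covering the rows
#'   of `counts`.
#' @param k Factorization rank per sample (a single value, or a named vector
#'   by sample; see [select_k()] for choosing it).
#' @param n_iter Restarts per sample factorization.
#' @param min_jaccard,min_partners Consensus-filter parameters; the partner
#'   floor should scale with the number of modules (the compendium default
#'   of 50 presumes hundreds of modules).
#' @param top_n Genes kept per module for the co-occurrence network.
#' @param resolution Louvain resolution.
#' @inheritParams fit_sample_nmf
#' @return List with `metaprograms`, `network`, `modules` (post-filter),
#'   `all_modules`, and `fits`.
#' @export
discover_metaprograms <- function(counts, cells, k = 3, n_iter = 30,
                                  n_top_genes = 4000,
                                  density_threshold = 0.01, universe = NULL,
                                  min_jaccard = 0.05, min_partners = 50,
                                  top_n = 100, resolution = 1.2, seed = 1L) {
  stopifnot(all(c("cell", "sample") %in% names(cells)))
  samples <- unique(cells$sample)
  ks <- if (length(k) == 1L) setNames(rep(k, length(samples)), samples) else k
  fits <- lapply(seq_along(samples), function(i) {
    s <- samples[i]
    fit_sample_nmf(counts[cells$cell[cells$sample == s], , drop = FALSE],
                   k = ks[[s]], n_iter = n_iter, n_top_genes = n_top_genes,
                   density_threshold = density_threshold, universe = universe,
                   sample_id = s, seed = child_seed(seed, i))
  })
  all_modules <- as_module_set(dplyr::bind_rows(lapply(fits, extract_modules)),
                               universe = universe %||% colnames(counts))
  modules <- filter_consensus_modules(all_modules, min_jaccard = min_jaccard,
                                      min_partners = min_partners)
  network <- build_cooccurrence_network(modules, top_n = top_n)
  metaprograms <- detect_metaprograms(network, resolution = resolution,
                                      seed = seed)
  list(metaprograms = metaprograms, network = network, modules = modules,
       all_modules = all_modules, fits = setNames(fits, samples))
}
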