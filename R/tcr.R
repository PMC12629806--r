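#' Normalized CDR3 similarity
#'
#' Similarity between two CDR3 amino-acid sequences, defined as
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`. Vectorized over pairs.
#'
#' @param a,b Character vectors of CDR3 sequences (recycled to equal length).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' normalized_similarity("CASSLG", "CASSLA")   # 1 - 1/6
#' @export
normalized_similarity <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    abort("CDR3 sequences must be non-empty")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  d <- vapply(seq_len(n), function(i) adist(a[i], b[i])[1, 1], numeric(1))
  1 - d / pmax(nchar(a), nchar(b))
}

#' Strict clonotype calling from TCR contigs
#'
#' Implements a strict clonotype definition: cells share a clonotype when they
#' use the same V gene and their CDR3 amino-acid sequences exceed an 85%
#' normalized Levenshtein similarity. Within each V-gene block, cells are
#' linked whenever pairwise similarity is strictly greater than `threshold`
#' and clonotypes are the connected components of that graph (single linkage).
#' Clonotype IDs are canonical -- V gene plus the lexicographically smallest
#' member CDR3 -- so the result is invariant to input row order.
#'
#' Cells with multiple contig rows collapse to their first row, with a
#' warning; paired-chain logic is out of scope.
#'
#' @param contigs Data frame with columns `barcode`, `v_gene`, `cdr3`.
#' @param threshold Similarity threshold; linkage requires similarity
#'   strictly above it (default 0.85).
#' @return A `clonotype_table`: tibble with columns `barcode`, `v_gene`,
#'   `cdr3`, `clonotype_id`, `clone_size`.
#' @export
call_clonotypes <- function(contigs, threshold = 0.85) {
  stopifnot(all(c("barcode", "v_gene", "cdr3") %in% names(contigs)))
  contigs <- tibble::as_tibble(contigs)[, c("barcode", "v_gene", "cdr3")]
  if (any(!nzchar(contigs$cdr3)) || anyNA(contigs$cdr3)) {
    abort("CDR3 sequences must be non-empty")
  }
  if (anyDuplicated(contigs$barcode)) {
    warn(sprintf("%d barcode(s) with multiple contigs; keeping first row each",
                 sum(duplicated(contigs$barcode))))
    contigs <- contigs[!duplicated(contigs$barcode), ]
  }
  # cluster unique CDR3s per V-gene block, then map cells back
  blocks <- split(seq_len(nrow(contigs)), contigs$v_gene)
  contigs$clonotype_id <- NA_character_
  for (idx in blocks) {
    cdr3s <- sort(unique(contigs$cdr3[idx]))
    comp <- cluster_cdr3_block(cdr3s, threshold)
    ids <- vapply(split(cdr3s, comp), min, character(1))[as.character(comp)]
    names(ids) <- cdr3s
    contigs$clonotype_id[idx] <-
      paste0(contigs$v_gene[idx], ":", ids[contigs$cdr3[idx]])
  }
  sizes <- table(contigs$clonotype_id)
  contigs$clone_size <- as.integer(sizes[contigs$clonotype_id])
  contigs <- dplyr::arrange(contigs, .data$clonotype_id, .data$barcode)
  class(contigs) <- c("clonotype_table", class(contigs))
  contigs
}

# connected components over the similarity graph of one V-gene block
cluster_cdr3_block <- function(cdr3s, threshold) {
  n <- length(cdr3s)
  if (n == 1L) return(1L)
  d <- adist(cdr3s)
  len <- nchar(cdr3s)
  sim <- 1 - d / outer(len, len, pmax)
  adj <- sim > threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Classify clonotype expansion
#'
#' Clonotypes are `single` (one cell), `expanded_small` (2-4 cells) or
#' `expanded_large` (5 or more cells).
#'
#' @param ct A `clonotype_table` from [call_clonotypes()].
#' @return The table with an added `expansion_class` column.
#' @export
classify_expansion <- function(ct) {
  stopifnot("clone_size" %in% names(ct))
  ct$expansion_class <- dplyr::case_when(
    ct$clone_size >= 5 ~ "expanded_large",
    ct$clone_size >= 2 ~ "expanded_small",
    TRUE ~ "single")
  ct
}

#' Extract tumor-reactive T cells by clonotype sharing
#'
#' Tumor-reactive cells are taken to be every cell of a reference exhausted
#' subset (e.g. CXCL13+ Tex) plus every cell sharing a clonotype with at
#' least one reference-subset cell -- clonal linkage to the exhausted pool is
#' read as evidence of tumor-antigen encounter.
#'
#' @param cells Data frame with columns `barcode` and `subset`.
#' @param ct A `clonotype_table`; cells without TCR data simply cannot be
#'   recruited by sharing.
#' @param reference_subset Subset label defining the anchor population.
#' @return Character vector of tumor-reactive barcodes (sorted).
#' @export
extract_tumor_reactive <- function(cells, ct, reference_subset) {
  stopifnot(all(c("barcode", "subset") %in% names(cells)))
  ref_cells <- cells$barcode[cells$subset == reference_subset]
  if (length(ref_cells) == 0L) {
    abort(sprintf("reference subset '%s' has no cells", reference_subset))
  }
  ref_clones <- unique(ct$clonotype_id[ct$barcode %in% ref_cells])
  shared <- ct$barcode[ct$clonotype_id %in% ref_clones]
  sort(unique(c(ref_cells, shared)))
}

#' Clonotype fate across treatment timepoints
#'
#' Compares clonotype inventories before and after treatment: `persistent`
#' clonotypes appear at both timepoints, `emergent` only after, `lost` only
#' before. Requires both tables to come from [call_clonotypes()] so IDs are
#' comparable.
#'
#' @param pre,post `clonotype_table`s for the two timepoints.
#' @return Tibble with columns `clonotype_id`, `fate`.
#' @export
clonotype_fate <- function(pre, post) {
  a <- unique(pre$clonotype_id)
  b <- unique(post$clonotype_id)
  ids <- sort(union(a, b))
  tibble::tibble(
    clonotype_id = ids,
    fate = dplyr::case_when(
      ids %in% a & ids %in% b ~ "persistent",
      ids %in% b ~ "emergent",
      TRUE ~ "lost"))
}

#' @exportS3Method generics::tidy
tidy.clonotype_table <- function(x, ...) {
  out <- dplyr::summarise(dplyr::group_by(x, .data$clonotype_id),
                          v_gene = .data$v_gene[1],
                          size = dplyr::n(), .groups = "drop")
  out$expansion_class <- dplyr::case_when(
    out$size >= 5 ~ "expanded_large",
    out$size >= 2 ~ "expanded_small",
    TRUE ~ "single")
  out
}

#' @exportS3Method generics::glance
glance.clonotype_table <- function(x, ...) {
  cl <- tidy(x)
  tibble::tibble(
    n_cells = nrow(x),
    n_clonotypes = nrow(cl),
    expanded_fraction = mean(cl$size > 1),
    largest_clone = max(cl$size))
}
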