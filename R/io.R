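#' Read and write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format used by MSigDB and most
#' enrichment tools: one set per line, `name<TAB>description<TAB>gene...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) abort("malformed GMT line: fewer than 3 fields")
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @param sets Named list of character vectors (gene sets).
#' @param description Optional per-set description column; recycled.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write weighted edge lists
#'
#' Tab-separated with header `gene_a  gene_b  weight`; the format used for
#' co-occurrence and cell-type-specific gene networks throughout the package.
#'
#' @param path File path.
#' @return A tibble with columns `gene_a`, `gene_b`, `weight`.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    weight = readr::col_double()
  ))
}

#' @param edges A data frame with columns `gene_a`, `gene_b`, `weight`.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  readr::write_tsv(edges[, c("gene_a", "gene_b", "weight")], path)
  invisible(path)
}

#' Read a 10x-style TCR contig table
#'
#' Accepts `filtered_contig_annotation.csv`-like files: any CSV with at least
#' `barcode`, `v_gene` and `cdr3` columns; extra columns are ignored. Rows
#' with empty CDR3 sequences are dropped with a warning.
#'
#' @param path CSV file path.
#' @return A tibble with columns `barcode`, `v_gene`, `cdr3`.
#' @export
read_contigs <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("barcode", "v_gene", "cdr3")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("contig file lacks required columns: ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl[, need]
  bad <- is.na(tbl$cdr3) | !nzchar(tbl$cdr3)
  if (any(bad)) {
    warn(sprintf("dropping %d contig rows with empty CDR3", sum(bad)))
    tbl <- tbl[!bad, ]
  }
  tbl
}

#' @param contigs A data frame with `barcode`, `v_gene`, `cdr3` columns.
#' @rdname read_contigs
#' @export
write_contigs <- function(contigs, path) {
  readr::write_csv(contigs[, c("barcode", "v_gene", "cdr3")], path)
  invisible(path)
}

#' Write / read a synthetic cohort as MTX + TSV sidecars
#'
#' Writes `matrix.mtx` (cells x genes), `genes.tsv`, `barcodes.tsv` and
#' `cell_metadata.tsv` into `dir`; planted truth, when present, goes to
#' `truth.json`.
#'
#' @param cohort A list as returned by [generate_program_cohort()].
#' @param dir Output directory (created if absent).
#' @return `read_cohort()` returns a list with `counts` and `cells`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix(cohort$counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(cohort$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(cohort$counts), file.path(dir, "barcodes.tsv"))
  readr::write_tsv(cohort$cells, file.path(dir, "cell_metadata.tsv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(
      list(shared_program_genes = cohort$truth$shared_program_genes,
           private_program_genes = cohort$truth$private_program_genes),
      file.path(dir, "truth.json"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "genes.tsv"))
  cells <- readr::read_tsv(file.path(dir, "cell_metadata.tsv"),
                           col_types = readr::cols())
  list(counts = counts, cells = cells)
}
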