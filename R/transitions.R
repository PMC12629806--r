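#' Row-normalize a cell-to-cell transition matrix
#'
#' Rescales each row of a nonnegative transition matrix to sum to 1.
#' Rows with no outgoing mass cannot be normalized; they are dropped with a
#' warning (the corresponding start cells carry no velocity information).
#'
#' @param m Square nonnegative matrix (dense or `Matrix`), rows = start
#'   cells, with row and column names.
#' @return Row-stochastic matrix; possibly fewer rows than input.
#' @export
normalize_rows <- function(m) {
  m <- as_expr_matrix(m, "m")
  if (any(m < 0)) abort("transition matrix has negative entries")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warn(sprintf("dropping %d start cell(s) with zero outgoing mass",
                 sum(rs == 0)))
    m <- m[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  m / rs
}

#' Aggregate transition probabilities into a subset-to-subset density sample
#'
#' For each start cell in `start_subset`, sums its transition probability
#' over every target cell in `target_subset`; the summation accounts for
#' differences in subset abundance. Start cells with zero total mass into the
#' target subset are excluded. Self-transitions are included when start and
#' target subsets coincide, giving the persistence readout for a subset.
#'
#' @param m Row-stochastic transition matrix with cell names.
#' @param cells Data frame with columns `cell`, `subset` and optionally
#'   `group`, covering the matrix cells.
#' @param start_subset,target_subset Subset labels.
#' @return A `density_sample` tibble: `cell`, `density`, plus constant
#'   columns `start_subset`, `target_subset` and (if present) per-cell `group`.
#' @export
aggregate_density <- function(m, cells, start_subset, target_subset) {
  stopifnot(all(c("cell", "subset") %in% names(cells)))
  subset_of <- setNames(as.character(cells$subset), cells$cell)
  starts <- rownames(m)[subset_of[rownames(m)] %in% start_subset]
  targets <- colnames(m)[subset_of[colnames(m)] %in% target_subset]
  if (length(starts) == 0L) abort(sprintf("no start cells in subset '%s'", start_subset))
  if (length(targets) == 0L) abort(sprintf("no target cells in subset '%s'", target_subset))
  dens <- rowSums(m[starts, targets, drop = FALSE])
  keep <- dens > 0
  out <- tibble::tibble(
    cell = starts[keep],
    density = as.numeric(dens[keep]),
    start_subset = paste(start_subset, collapse = "+"),
    target_subset = paste(target_subset, collapse = "+"))
  if ("group" %in% names(cells)) {
    out$group <- setNames(as.character(cells$group), cells$cell)[out$cell]
  }
  class(out) <- c("density_sample", class(out))
  out
}

#' Compare two transition-density distributions
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the aggregated density
#' values, as used to contrast subset-to-subset transition behavior between
#' response groups.
#'
#' @param a,b `density_sample` tibbles (or data frames with a `density`
#'   column).
#' @return Tibble with `statistic` (KS D), `p.value`, `n_a`, `n_b`.
#' @export
compare_densities <- function(a, b) {
  xa <- a$density; xb <- b$density
  if (length(xa) < 2L || length(xb) < 2L) {
    abort("need at least 2 density values per sample")
  }
  kt <- suppressWarnings(ks.test(xa, xb, alternative = "two.sided"))
  tibble::tibble(statistic = unname(kt$statistic),
                 p.value = kt$p.value,
                 n_a = length(xa), n_b = length(xb))
}

#' Density-comparison plot
#'
#' Overlaid kernel density estimates of two aggregated transition-density
#' samples, annotated with the KS test.
#'
#' @param a,b `density_sample` tibbles.
#' @param labels Length-2 character vector naming the two samples.
#' @return A ggplot.
#' @export
plot_density_comparison <- function(a, b, labels = c("a", "b")) {
  ks <- compare_densities(a, b)
  d <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(a), .sample = labels[1]),
    dplyr::mutate(tibble::as_tibble(b), .sample = labels[2]))
  ggplot2::ggplot(d, ggplot2::aes(.data$density, fill = .data$.sample)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(
      subtitle = sprintf("KS D = %.3f, p = %.3g", ks$statistic, ks$p.value),
      x = "summed transition probability", fill = NULL) +
    ggplot2::theme_minimal()
}
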