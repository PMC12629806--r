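#' Tabulate cell counts by group and subset
#'
#' Builds the group x subset contingency table that the Pearson-residual
#' composition analysis operates on. Accepts either per-cell metadata (one row
#' per cell) or an already-tabulated count matrix via [as_composition_table()].
#'
#' @param cells A data frame with one row per cell.
#' @param group,subset Columns of `cells` holding the group (e.g. treatment
#'   arm or response) and the cell-subset label; tidy-eval.
#' @return A `composition_table`: an integer matrix (groups x subsets) with a
#'   `composition_table` class attribute.
#' @examples
#' cells <- tibble::tibble(
#'   arm = rep(c("D", "D+T"), each = 50),
#'   celltype = rep(c("Tex", "Tmem"), times = 50))
#' composition_table(cells, arm, celltype)
#' @export
composition_table <- function(cells, group, subset) {
  g <- dplyr::pull(cells, {{ group }})
  s <- dplyr::pull(cells, {{ subset }})
  as_composition_table(unclass(table(g, s)))
}

#' @param counts A nonnegative integer matrix, groups in rows, subsets in
#'   columns.
#' @rdname composition_table
#' @export
as_composition_table <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || sum(counts) == 0) {
    abort("composition table is empty: no cells to tabulate")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("composition counts must be nonnegative integers")
  }
  storage.mode(counts) <- "double"
  structure(counts, class = c("composition_table", "matrix", "array"))
}

#' Expected counts under compositional homogeneity
#'
#' The expected count for group i and subset j is `E_ij = (T_i / T_tot) * T_j`
#' with `T_i`, `T_j` the group/subset margins and `T_tot` the grand total, i.e.
#' the usual independence expectation of a contingency table.
#'
#' @param tbl A [composition_table()].
#' @return Matrix of expected counts, same dimensions as `tbl`.
#' @export
expected_counts <- function(tbl) {
  m <- unclass(tbl)
  tot <- sum(m)
  if (tot <= 0) abort("composition table is empty")
  outer(rowSums(m), base::colSums(m)) / tot
}

#' Pearson residuals and chi-square goodness of fit for composition shifts
#'
#' For each cell of the group x subset table the Pearson residual
#' `r_ij = (O_ij - E_ij) / sqrt(E_ij)` measures how far the observed count
#' deviates from the homogeneity expectation; its sign gives the direction
#' (positive = augmentation, negative = depletion). The chi-square statistic
#' is the sum of squared residuals with `(rows - 1) * (cols - 1)` degrees of
#' freedom. Rows or columns with zero margin contribute no information and are
#' excluded with a warning; cells with expected count below 5 are flagged
#' (normal approximation caveat) but kept.
#'
#' @param tbl A [composition_table()] or plain count matrix.
#' @return An `ici_residuals` object: list with `observed`, `expected`,
#'   `residuals` matrices, `statistic`, `df`, `p.value`, and a logical
#'   `low_expected` matrix.
#' @seealso [classify_shifts()] for the +/-3.5 calling rule.
#' @export
pearson_residuals <- function(tbl) {
  if (!inherits(tbl, "composition_table")) tbl <- as_composition_table(tbl)
  m <- unclass(tbl)
  zero_rows <- rowSums(m) == 0
  zero_cols <- base::colSums(m) == 0
  if (any(zero_rows) || any(zero_cols)) {
    warn(sprintf("excluding %d empty group(s) and %d empty subset(s)",
                 sum(zero_rows), sum(zero_cols)))
    m <- m[!zero_rows, !zero_cols, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("need at least 2 non-empty groups and 2 non-empty subsets")
  }
  e <- outer(rowSums(m), base::colSums(m)) / sum(m)
  bad <- e == 0 & m > 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("zero expected count with observed cells at (%s, %s)",
                  rownames(m)[idx[1]] %||% idx[1],
                  colnames(m)[idx[2]] %||% idx[2]))
  }
  r <- (m - e) / sqrt(e)
  stat <- sum(r^2)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(
    list(observed = m, expected = e, residuals = r,
         statistic = stat, df = df,
         p.value = pchisq(stat, df, lower.tail = FALSE),
         low_expected = e < 5),
    class = "ici_residuals")
}

#' Call augmented / depleted subsets from Pearson residuals
#'
#' A group-subset cell is called `augmented` when its residual exceeds
#' `call_threshold` and `depleted` when it falls below `-call_threshold`
#' (default 3.5, a conservative bar for follow-up); `nominal_significant`
#' additionally marks the +/-2 band corresponding to p < 0.05 under the
#' normal approximation of the residual.
#'
#' @param res An `ici_residuals` object from [pearson_residuals()].
#' @param call_threshold Positive residual cutoff for calls (default 3.5).
#' @return A tibble with columns `group`, `subset`, `observed`, `expected`,
#'   `residual`, `call` (`augmented`/`depleted`/`none`), `nominal_significant`,
#'   `low_expected`.
#' @export
classify_shifts <- function(res, call_threshold = 3.5) {
  stopifnot(inherits(res, "ici_residuals"), call_threshold > 0)
  long <- tidy(res)
  long$call <- dplyr::case_when(
    long$residual >  call_threshold ~ "augmented",
    long$residual < -call_threshold ~ "depleted",
    TRUE ~ "none")
  long$nominal_significant <- abs(long$residual) > 2
  long
}

#' @exportS3Method generics::tidy
tidy.ici_residuals <- function(x, ...) {
  grid <- expand.grid(group = rownames(x$observed) %||% seq_len(nrow(x$observed)),
                      subset = colnames(x$observed) %||% seq_len(ncol(x$observed)),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    group = as.character(grid$group),
    subset = as.character(grid$subset),
    observed = as.vector(x$observed),
    expected = as.vector(x$expected),
    residual = as.vector(x$residuals),
    low_expected = as.vector(x$low_expected))
}

#' @exportS3Method generics::glance
glance.ici_residuals <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n_cells = sum(x$observed))
}

#' @export
print.ici_residuals <- function(x, ...) {
  cat(sprintf("Composition shift analysis: %d groups x %d subsets\n",
              nrow(x$observed), ncol(x$observed)))
  cat(sprintf("chi-square = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Mosaic-style residual heatmap
#'
#' @param object An `ici_residuals` object.
#' @param call_threshold Residual cutoff passed to [classify_shifts()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ici_residuals <- function(object, call_threshold = 3.5, ...) {
  d <- classify_shifts(object, call_threshold)
  ggplot2::ggplot(d, ggplot2::aes(.data$subset, .data$group)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$residual), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$call == "none", "", substr(.data$call, 1, 1)))) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "grey95",
                                  high = "#2166ac") +
    ggplot2::labs(x = "cell subset", y = "group", fill = "Pearson\nresidual") +
    ggplot2::theme_minimal()
}
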