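#' Assemble per-sample predictor features from bulk cohorts
#'
#' Applies the compendium inclusion filters -- at least `min_genes` measured
#' genes, only samples with a known binary response label, at least
#' `min_samples` labeled samples -- then maps every cohort onto a fixed gene
#' space (absent genes filled with 0), computes the immune and senescence
#' signature scores with [single_sample_enrichment()], and attaches the
#' supplied stromal score and tumor purity.
#'
#' @param cohorts Named list; each element a list with `expression`
#'   (genes x samples matrix) and `samples` (tibble with `sample`,
#'   `response`, `stromal_score`, `tumor_purity`). Response labels other
#'   than `"responder"` / `"non-responder"` (e.g. `"UNK"`) are dropped.
#' @param gene_sets List with character vectors `immune` and `senescence`.
#' @param gene_space Character vector fixing the total gene space; defaults
#'   to the union of all cohort genes.
#' @param min_genes,min_samples Cohort inclusion filters (defaults 10000 and
#'   30).
#' @return A `cohort_features` tibble: `cohort`, `sample`, `immune_score`,
#'   `senescence_score`, `stromal_score`, `tumor_purity`, `response`.
#'   Excluded cohorts are reported via messages.
#' @export
assemble_features <- function(cohorts, gene_sets, gene_space = NULL,
                              min_genes = 10000, min_samples = 30) {
  stopifnot(is.list(cohorts), all(c("immune", "senescence") %in% names(gene_sets)))
  gene_space <- gene_space %||%
    sort(unique(unlist(lapply(cohorts, function(co) rownames(co$expression)))))
  out <- purrr::imap(cohorts, function(co, nm) {
    expr <- co$expression
    meta <- tibble::as_tibble(co$samples)
    if (nrow(expr) < min_genes) {
      inform(sprintf("cohort %s excluded: %d < %d genes", nm, nrow(expr), min_genes))
      return(NULL)
    }
    keep <- meta$response %in% c("responder", "non-responder")
    if (any(!keep)) {
      inform(sprintf("cohort %s: dropping %d sample(s) with unknown response",
                     nm, sum(!keep)))
    }
    meta <- meta[keep, ]
    expr <- expr[, meta$sample, drop = FALSE]
    if (nrow(meta) < min_samples) {
      inform(sprintf("cohort %s excluded: %d < %d labeled samples",
                     nm, nrow(meta), min_samples))
      return(NULL)
    }
    # project onto the fixed gene space; absent genes contribute 0
    full <- matrix(0, length(gene_space), ncol(expr),
                   dimnames = list(gene_space, colnames(expr)))
    shared <- intersect(rownames(expr), gene_space)
    full[shared, ] <- as.matrix(expr[shared, , drop = FALSE])
    scores <- multi_set_enrichment(full, gene_sets[c("immune", "senescence")])
    imm <- scores$immune; sen <- scores$senescence
    tibble::tibble(
      cohort = nm, sample = meta$sample,
      immune_score = imm$score[match(meta$sample, imm$sample)],
      senescence_score = sen$score[match(meta$sample, sen$sample)],
      stromal_score = meta$stromal_score,
      tumor_purity = meta$tumor_purity,
      response = meta$response)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) abort("no cohort passed the inclusion filters")
  class(res) <- c("cohort_features", class(res))
  res
}

#' Train a leave-one-study-out ensemble of depth-limited random forests
#'
#' For every cohort, a probability random forest with maximum tree depth
#' `max_depth` is trained on all other cohorts and evaluated on the held-out
#' cohort, so each sample receives exactly one held-out probability. The
#' ensemble prediction for new data is the mean of the member probabilities
#' ([ensemble_predict()]). Feature importance is the impurity (Gini)
#' importance of each member.
#'
#' @param features A `cohort_features` tibble from [assemble_features()].
#' @param feature_names Character vector of predictor columns.
#' @param max_depth Maximum tree depth (default 5).
#' @param num_trees Trees per forest (default 500).
#' @param seed Integer seed; member forests derive theirs from it.
#' @return A `loso_ensemble`: list with `models`, `predictions` (tibble
#'   `cohort`, `sample`, `response`, `prob`), `importance` (tibble
#'   `held_out`, `feature`, `importance`), `feature_names`, `auroc` (pooled
#'   held-out AUROC).
#' @export
train_loso_ensemble <- function(features, feature_names, max_depth = 5,
                                num_trees = 500, seed = 1L) {
  stopifnot(all(feature_names %in% names(features)))
  cohort_ids <- unique(features$cohort)
  if (length(cohort_ids) < 2L) abort("need at least 2 cohorts")
  features$response <- factor(features$response,
                              levels = c("non-responder", "responder"))
  fits <- lapply(seq_along(cohort_ids), function(i) {
    co <- cohort_ids[i]
    train <- features[features$cohort != co, ]
    test <- features[features$cohort == co, ]
    if (length(unique(train$response)) < 2L) {
      abort(sprintf("training set for held-out cohort %s has a single class", co))
    }
    fit <- ranger::ranger(
      x = as.data.frame(train[, feature_names]),
      y = train$response,
      probability = TRUE, max.depth = max_depth, num.trees = num_trees,
      mtry = max(1L, floor(sqrt(length(feature_names)))),
      importance = "impurity", seed = child_seed(seed, i),
      num.threads = 1)
    prob <- stats::predict(fit,
      data = as.data.frame(test[, feature_names]),
      num.threads = 1)$predictions[, "responder"]
    list(model = fit, held_out = co,
         predictions = tibble::tibble(
           cohort = co, sample = test$sample,
           response = as.character(test$response), prob = prob),
         importance = tibble::tibble(
           held_out = co, feature = feature_names,
           importance = unname(fit$variable.importance[feature_names])))
  })
  predictions <- dplyr::bind_rows(lapply(fits, `[[`, "predictions"))
  structure(list(
    models = setNames(lapply(fits, `[[`, "model"), cohort_ids),
    predictions = predictions,
    importance = dplyr::bind_rows(lapply(fits, `[[`, "importance")),
    feature_names = feature_names,
    auroc = evaluate_auroc(predictions$prob,
                           predictions$response == "responder")),
    class = "loso_ensemble")
}

#' Ensemble probability prediction
#'
#' Arithmetic mean of the member forests' responder probabilities -- the
#' final ensemble classifier.
#'
#' @param model A `loso_ensemble`.
#' @param newdata Data frame containing the model's feature columns.
#' @return Numeric vector of responder probabilities.
#' @export
ensemble_predict <- function(model, newdata) {
  stopifnot(inherits(model, "loso_ensemble"))
  missing <- setdiff(model$feature_names, names(newdata))
  if (length(missing)) {
    abort(paste0("missing feature(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(newdata[, model$feature_names])
  probs <- vapply(model$models, function(m)
    stats::predict(m, data = x, num.threads = 1)$predictions[, "responder"],
    numeric(nrow(x)))
  if (nrow(x) == 1L) mean(probs) else base::rowMeans(probs)
}

#' Area under the ROC curve via the midrank statistic
#'
#' Computes AUROC as the normalized Mann-Whitney statistic: positives'
#' mean midrank among all scores, rescaled. Ties are handled by average
#' ranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or coercible) vector; `TRUE` = positive class.
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve points
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical vector; `TRUE` = positive.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered by increasing
#'   `fpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, scores[ord][keep]),
    fpr = c(0, fp[keep] / sum(!labels)),
    tpr = c(0, tp[keep] / sum(labels)))
}

# mean TPR over an FPR band via step-function interpolation of the ROC
band_tpr <- function(roc, fpr_lo, fpr_hi, grid_step = 0.005) {
  f <- stats::approxfun(roc$fpr, roc$tpr, method = "constant",
                        ties = max, rule = 2)
  mean(f(seq(fpr_lo, fpr_hi, by = grid_step)))
}

#' Compare ensembles with and without an added predictor
#'
#' Trains the leave-one-study-out ensemble twice with identical seeds -- on
#' the base feature set and on base plus `added_feature` -- and reports the
#' pooled held-out AUROCs, both importance tables, and the mean TPR
#' difference over an intermediate FPR band (default `[0.4, 0.6]`, where
#' hard-to-call samples live).
#'
#' @param features A `cohort_features` tibble.
#' @param base_features Character vector of base predictors.
#' @param added_feature Name of the candidate predictor.
#' @param fpr_band Length-2 numeric FPR window for the partial-ROC
#'   comparison.
#' @inheritParams train_loso_ensemble
#' @return An `ensemble_comparison`: list with `base`, `added` (the two
#'   `loso_ensemble`s), `auroc_base`, `auroc_added`, `tpr_band_difference`
#'   and `fpr_band`.
#' @export
compare_with_without <- function(features, base_features, added_feature,
                                 max_depth = 5, num_trees = 500,
                                 fpr_band = c(0.4, 0.6), seed = 1L) {
  if (!added_feature %in% names(features)) {
    abort(sprintf("added feature '%s' absent from the feature table",
                  added_feature))
  }
  base <- train_loso_ensemble(features, base_features,
                              max_depth = max_depth, num_trees = num_trees,
                              seed = seed)
  added <- train_loso_ensemble(features, c(base_features, added_feature),
                               max_depth = max_depth, num_trees = num_trees,
                               seed = seed)
  roc_b <- roc_points(base$predictions$prob,
                      base$predictions$response == "responder")
  roc_a <- roc_points(added$predictions$prob,
                      added$predictions$response == "responder")
  structure(list(
    base = base, added = added,
    auroc_base = base$auroc, auroc_added = added$auroc,
    tpr_band_difference = band_tpr(roc_a, fpr_band[1], fpr_band[2]) -
      band_tpr(roc_b, fpr_band[1], fpr_band[2]),
    fpr_band = fpr_band),
    class = "ensemble_comparison")
}

#' @exportS3Method generics::tidy
tidy.loso_ensemble <- function(x, ...) x$importance

#' @exportS3Method generics::glance
glance.loso_ensemble <- function(x, ...) {
  tibble::tibble(auroc = x$auroc,
                 n_models = length(x$models),
                 n_samples = nrow(x$predictions),
                 features = paste(x$feature_names, collapse = ","))
}

#' @exportS3Method generics::glance
glance.ensemble_comparison <- function(x, ...) {
  tibble::tibble(auroc_base = x$auroc_base, auroc_added = x$auroc_added,
                 auroc_gain = x$auroc_added - x$auroc_base,
                 tpr_band_difference = x$tpr_band_difference)
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat(sprintf("LOSO ensemble comparison: AUROC %.3f (base) vs %.3f (+%s)\n",
              x$auroc_base, x$auroc_added,
              setdiff(x$added$feature_names, x$base$feature_names)))
  cat(sprintf("mean TPR difference on FPR in [%.2f, %.2f]: %+.3f\n",
              x$fpr_band[1], x$fpr_band[2], x$tpr_band_difference))
  invisible(x)
}

#' ROC overlay for an ensemble comparison
#'
#' @param object An `ensemble_comparison`.
#' @param ... Unused.
#' @return A ggplot with both ROC curves and the compared FPR band shaded.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_comparison <- function(object, ...) {
  rb <- roc_points(object$base$predictions$prob,
                   object$base$predictions$response == "responder")
  ra <- roc_points(object$added$predictions$prob,
                   object$added$predictions$response == "responder")
  d <- dplyr::bind_rows(dplyr::mutate(rb, model = "base"),
                        dplyr::mutate(ra, model = "base + added"))
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::annotate("rect", xmin = object$fpr_band[1],
                      xmax = object$fpr_band[2], ymin = 0, ymax = 1,
                      alpha = 0.1) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
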