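# small hand-built feature table: 4 cohorts x 40 samples
toy_features <- function(effect = 0, seed = 1, n_cohorts = 4, n = 40) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_cohorts), function(ci) {
    resp <- rep(c("responder", "non-responder"), length.out = n)
    tibble::tibble(
      cohort = paste0("c", ci),
      sample = paste0("c", ci, "_s", seq_len(n)),
      immune_score = rnorm(n) + 0.8 * (resp == "responder"),
      senescence_score = rnorm(n) + effect * (resp == "responder"),
      stromal_score = rnorm(n),
      tumor_purity = rnorm(n),
      response = resp)
  })
}

test_that("cohort assembly applies the three inclusion filters", {
  bk <- generate_bulk_cohorts(n_cohorts = 3, samples_per_cohort = 35,
                              n_genes = 11000, seed = 2)
  # sabotage: cohort 1 too few genes, cohort 2 too few known labels
  bk$cohorts[[1]]$expression <- bk$cohorts[[1]]$expression[1:9000, ]
  bk$cohorts[[2]]$samples$response[1:10] <- "UNK"
  msgs <- capture.output(
    ft <- assemble_features(bk$cohorts, bk$gene_sets), type = "message")
  expect_setequal(unique(ft$cohort), "study3")
  expect_true(any(grepl("9000 < 10000 genes", msgs)))
  expect_true(any(grepl("unknown response", msgs)))
  expect_true(any(grepl("25 < 30 labeled samples", msgs)))
  expect_named(ft, c("cohort", "sample", "immune_score", "senescence_score",
                     "stromal_score", "tumor_purity", "response"))
  expect_false(anyNA(ft))
  # a gene missing from one cohort is read as zero over the fixed space
  bk2 <- generate_bulk_cohorts(n_cohorts = 2, samples_per_cohort = 30,
                               n_genes = 10500, seed = 3)
  space <- c(rownames(bk2$cohorts[[1]]$expression), "phantom_gene")
  expect_silent(suppressMessages(
    assemble_features(bk2$cohorts, bk2$gene_sets, gene_space = space)))
})

test_that("each sample gets exactly one held-out prediction and AUROC is pooled", {
  ft <- toy_features(effect = 2, seed = 5)
  mod <- train_loso_ensemble(ft, c("immune_score", "senescence_score"),
                             num_trees = 100, seed = 1)
  expect_length(mod$models, 4)
  expect_equal(nrow(mod$predictions), nrow(ft))
  expect_equal(anyDuplicated(mod$predictions$sample), 0L)
  expect_gt(mod$auroc, 0.7)
  expect_named(glance(mod), c("auroc", "n_models", "n_samples", "features"))
  expect_equal(nrow(tidy(mod)), 4 * 2)
  # deterministic under a fixed seed
  mod2 <- train_loso_ensemble(ft, c("immune_score", "senescence_score"),
                              num_trees = 100, seed = 1)
  expect_identical(mod$predictions$prob, mod2$predictions$prob)
})

test_that("held-out predictions never depend on the held-out cohort", {
  ft <- toy_features(effect = 1, seed = 9)
  mod <- train_loso_ensemble(ft, c("immune_score", "stromal_score"),
                             num_trees = 100, seed = 3)
  poisoned <- ft
  flip <- poisoned$cohort == "c2"
  poisoned$response[flip] <- ifelse(poisoned$response[flip] == "responder",
                                    "non-responder", "responder")
  mod_p <- train_loso_ensemble(poisoned, c("immune_score", "stromal_score"),
                               num_trees = 100, seed = 3)
  expect_identical(mod$predictions$prob[mod$predictions$cohort == "c2"],
                   mod_p$predictions$prob[mod_p$predictions$cohort == "c2"])
})

test_that("ensemble prediction averages member probabilities", {
  ft <- toy_features(effect = 2, seed = 13)
  mod <- train_loso_ensemble(ft, c("immune_score", "senescence_score"),
                             num_trees = 50, seed = 2)
  new <- ft[1:5, ]
  p <- ensemble_predict(mod, new)
  member <- vapply(mod$models, function(m)
    predict(m, data = as.data.frame(new[, mod$feature_names]),
            num.threads = 1)$predictions[, "responder"],
    numeric(5))
  expect_equal(p, rowMeans(member), ignore_attr = TRUE)
  expect_true(all(p >= apply(member, 1, min) - 1e-12 &
                    p <= apply(member, 1, max) + 1e-12))
  expect_error(ensemble_predict(mod, new[, "sample"]), "missing feature")
})

test_that("AUROC agrees with pairwise counting and behaves under symmetry", {
  expect_equal(evaluate_auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    scores <- sample(rnorm(40), n, replace = TRUE)  # deliberate ties
    labels <- rbinom(n, 1, 0.4) == 1
    if (!any(labels) || all(labels)) next
    a <- evaluate_auroc(scores, labels)
    expect_equal(a, oracle_auroc(scores, labels), tolerance = 1e-12)
    expect_equal(evaluate_auroc(-scores, labels), 1 - a, tolerance = 1e-12)
  }
  expect_error(evaluate_auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # independent cross-check against pROC on one draw
  scores <- rnorm(100); labels <- rbinom(100, 1, 0.5) == 1
  expect_equal(evaluate_auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(
                 labels, scores, levels = c(FALSE, TRUE), direction = "<",
                 quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("a separable feature yields near-perfect held-out AUROC, noise does not", {
  ft <- toy_features(effect = 0, seed = 21)
  ft$immune_score <- ifelse(ft$response == "responder", 1, 0) + rnorm(nrow(ft), sd = 0.05)
  mod <- train_loso_ensemble(ft, "immune_score", num_trees = 100, seed = 5)
  expect_gte(mod$auroc, 0.95)
  # label independent of features: AUROC hovers near 0.5
  set.seed(23)
  aucs <- vapply(1:10, function(s) {
    f <- toy_features(effect = 0, seed = 100 + s)
    f$immune_score <- rnorm(nrow(f))
    train_loso_ensemble(f, c("immune_score", "stromal_score"),
                        num_trees = 50, seed = s)$auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("constant features receive zero importance", {
  ft <- toy_features(effect = 2, seed = 31)
  ft$stromal_score <- 1
  mod <- train_loso_ensemble(ft, c("senescence_score", "stromal_score"),
                             num_trees = 100, seed = 7)
  imp <- tidy(mod)
  expect_true(all(imp$importance[imp$feature == "stromal_score"] == 0))
  expect_true(all(imp$importance >= 0))
})

test_that("with/without comparison reports AUROCs, band TPR and plots", {
  ft <- toy_features(effect = 2, seed = 41)
  cmp <- compare_with_without(ft, c("immune_score", "stromal_score"),
                              "senescence_score", num_trees = 100, seed = 2)
  gl <- glance(cmp)
  expect_named(gl, c("auroc_base", "auroc_added", "auroc_gain",
                     "tpr_band_difference"))
  expect_gt(gl$auroc_gain, 0)
  expect_error(compare_with_without(ft, "immune_score", "nope"), "absent")
  expect_s3_class(autoplot(cmp), "ggplot")
  # ROC points are monotone in both axes
  roc <- roc_points(cmp$base$predictions$prob,
                    cmp$base$predictions$response == "responder")
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})
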