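# A small synthetic feature table with mouse grouping and one informative
# feature, for exercising the CV machinery without the full pipeline.
planted_table <- function(n_per_geno = 8, sessions = 5, shift = 2, seed = 1,
                          n_noise = 5) {
  withr::with_seed(seed, {
    mice <- c(sprintf("A%02d", seq_len(n_per_geno)),
              sprintf("B%02d", seq_len(n_per_geno)))
    geno <- rep(c("WT", "KO"), each = n_per_geno)
    rows <- expand.grid(mouse = mice, session = seq_len(sessions),
                        stringsAsFactors = FALSE)
    rows <- rows[order(rows$mouse, rows$session), ]
    g <- geno[match(rows$mouse, mice)]
    tab <- data.frame(mouse_id = rows$mouse, session = rows$session,
                      genotype = g, stringsAsFactors = FALSE)
    tab$AUC_H <- stats::rnorm(nrow(tab)) + ifelse(g == "KO", -shift, 0)
    for (i in seq_len(n_noise)) {
      tab[[paste0("Cl_", c("SB", "SN", "H")[1 + (i %% 3)], i)]] <-
        stats::rnorm(nrow(tab))
    }
    names(tab) <- sub("^Cl_SB1$", "Cl_SB", names(tab))  # keep one real name
    tab
  })
}

test_that("outer folds exhaustively enumerate genotype-balanced pairs", {
  m11 <- sprintf("w%02d", 1:11)
  m9 <- sprintf("k%02d", 1:9)
  plan <- enumerate_outer_folds(list(k = m9, w = m11))
  expect_length(plan, choose(11, 2) * choose(9, 2))  # 1980
  f <- plan[[1]]
  expect_length(f$test, 4)
  expect_length(intersect(f$test, f$train), 0)
  expect_setequal(c(f$test, f$train), c(m11, m9))
  # 4 + 4 mice
  plan44 <- enumerate_outer_folds(list(a = letters[1:4], b = LETTERS[1:4]))
  expect_length(plan44, 36)
  # every fold holds exactly two mice per genotype in the test set
  for (fold in plan44) {
    expect_equal(sum(fold$test %in% letters[1:4]), 2)
    expect_equal(sum(fold$test %in% LETTERS[1:4]), 2)
  }
  expect_error(enumerate_outer_folds(list(a = letters[1:2], b = LETTERS[1:4])),
               "at least 3")
  # deterministic subsampling
  s1 <- enumerate_outer_folds(list(k = m9, w = m11), max_folds = 20, seed = 5)
  s2 <- enumerate_outer_folds(list(k = m9, w = m11), max_folds = 20, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1, 20)
})

test_that("inner folds enumerate all one-per-genotype validation pairs", {
  inner <- enumerate_inner_folds(list(a = letters[1:9], b = LETTERS[1:7]))
  expect_length(inner, 63)
  inner22 <- enumerate_inner_folds(list(a = letters[1:2], b = LETTERS[1:2]))
  expect_length(inner22, 4)
  for (fold in inner22) {
    expect_length(intersect(fold$validation, fold$train), 0)
    expect_setequal(c(fold$validation, fold$train),
                    c(letters[1:2], LETTERS[1:2]))
  }
  expect_error(enumerate_inner_folds(list(a = "x", b = LETTERS[1:3])),
               "at least 2")
})

test_that("confusion metrics are recoverable from printed matrices", {
  m1 <- confusion_metrics(61, 39, 15, 85)
  expect_equal(m1$sensitivity, 0.61)
  expect_equal(m1$specificity, 0.85)
  expect_equal(m1$ppv, 0.80, tolerance = 0.005)
  expect_equal(m1$npv, 0.69, tolerance = 0.01)  # 85/124 at printed precision
  m2 <- confusion_metrics(76, 24, 33, 67)
  expect_equal(m2$accuracy, 0.715)
})

test_that("the internal rank AUC agrees with pROC", {
  withr::with_seed(61, {
    for (rep in 1:10) {
      sc <- stats::runif(40)
      lab <- stats::runif(40) < 0.4
      if (length(unique(lab)) < 2) next
      expect_equal(miniconn:::auc_rank(sc, lab),
                   as.numeric(pROC::auc(pROC::roc(lab, sc,
                                                  levels = c(FALSE, TRUE),
                                                  direction = "<",
                                                  quiet = TRUE))))
    }
  })
})

test_that("RFE recovers a planted informative feature and is deterministic", {
  tab <- planted_table(shift = 2.5, seed = 3)
  ctrl <- ml_control(n_trees = 100, max_inner_folds = 4)
  hits <- vapply(1:5, function(s) {
    t2 <- planted_table(shift = 2.5, seed = s + 10)
    inner <- enumerate_inner_folds(t2[, c("mouse_id", "genotype")],
                                   max_folds = 4, seed = s)
    feat_cols <- setdiff(names(t2), c("mouse_id", "session", "genotype"))
    fit <- fit_rf_with_rfe(t2, feat_cols, "genotype", "KO", inner,
                           control = ctrl, seed = s)
    "AUC_H" %in% fit$features
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # mtry grid never exceeds ceil(sqrt(p))
  inner <- enumerate_inner_folds(tab[, c("mouse_id", "genotype")],
                                 max_folds = 4, seed = 1)
  feat_cols <- setdiff(names(tab), c("mouse_id", "session", "genotype"))
  fit1 <- fit_rf_with_rfe(tab, feat_cols, "genotype", "KO", inner,
                          control = ctrl, seed = 9)
  expect_lte(fit1$mtry, ceiling(sqrt(length(feat_cols))))
  fit2 <- fit_rf_with_rfe(tab, feat_cols, "genotype", "KO", inner,
                          control = ctrl, seed = 9)
  expect_identical(fit1$features, fit2$features)
  expect_equal(evaluate_fold(fit1, tab, "genotype", "KO")$score,
               evaluate_fold(fit2, tab, "genotype", "KO")$score)
})

test_that("fold evaluation scores probabilities with a low tie convention", {
  tab <- planted_table(shift = 3, seed = 5)
  inner <- enumerate_inner_folds(tab[, c("mouse_id", "genotype")],
                                 max_folds = 3, seed = 1)
  feat_cols <- setdiff(names(tab), c("mouse_id", "session", "genotype"))
  fit <- fit_rf_with_rfe(tab, feat_cols, "genotype", "KO", inner,
                         control = ml_control(n_trees = 80), seed = 2)
  ev <- evaluate_fold(fit, tab, "genotype", "KO")
  expect_true(all(ev$score >= 0 & ev$score <= 1))
  expect_identical(ev$predicted, ev$score > 0.5)  # 0.5 goes negative
  expect_error(evaluate_fold(fit, tab[, c("mouse_id", "genotype")],
                             "genotype", "KO"), "lacks feature")
})

test_that("report aggregation pools scores and normalizes the confusion matrix", {
  preds <- list(
    data.frame(mouse_id = "a", truth = c(TRUE, TRUE, FALSE),
               score = c(0.9, 0.4, 0.2), predicted = c(TRUE, FALSE, FALSE)),
    data.frame(mouse_id = "b", truth = c(TRUE, FALSE, FALSE),
               score = c(0.8, 0.6, 0.1), predicted = c(TRUE, TRUE, FALSE)))
  rep_ <- aggregate_reports(preds, list(c("f1", "f2"), "f1"),
                            all_features = c("f1", "f2", "f3"))
  expect_equal(unname(rep_$confusion_counts), c(2, 1, 1, 2))  # TP FN FP TN
  expect_equal(unname(rep_$confusion_normalized["TP"]), 100 * 2 / 3)
  expect_equal(unname(rep_$selection_frequency),
               c(1, 0.5, 0))
  expect_equal(rep_$metrics$sensitivity, 2 / 3)
  # all-perfect folds give AUC 1 and perfect metrics
  perfect <- list(data.frame(mouse_id = "a", truth = c(TRUE, FALSE),
                             score = c(1, 0), predicted = c(TRUE, FALSE)))
  rp <- aggregate_reports(perfect, list("f1"), "f1")
  expect_equal(rp$roc_auc, 1)
  expect_equal(rp$metrics$accuracy, 1)
})

test_that("model frameworks honor ablations and the leakage guard", {
  feats <- small_preprocessed()
  ctrl <- ml_control(n_trees = 60, max_outer_folds = 4, max_inner_folds = 3)
  rep3 <- run_model(3, feats, ablation = "both", control = ctrl, seed = 8)
  spec <- attr(rep3, "spec")
  expect_false(any(grepl("^(AUC_|s_)", spec$feature_cols)))
  expect_true("Genotype" %in% spec$feature_cols)
  expect_setequal(setdiff(spec$feature_cols, "Genotype"),
                  c("Lg_SB", "Cl_SB", "Cl_SN", "Cg_H", "Cg_SB", "Cg_SN"))
  # Model 1 has no genotype predictor
  rep1 <- run_model(1, feats, ablation = "none", control = ctrl, seed = 8)
  expect_false("Genotype" %in% attr(rep1, "spec")$feature_cols)
  # determinism of the full report
  rep1b <- run_model(1, feats, ablation = "none", control = ctrl, seed = 8)
  expect_equal(rep1$roc_auc, rep1b$roc_auc)
  expect_identical(attr(rep1, "fold_features"), attr(rep1b, "fold_features"))
})

test_that("the ablation suite shares one fold plan across its 12 reports", {
  feats <- small_preprocessed()
  ctrl <- ml_control(n_trees = 40, max_outer_folds = 2, max_inner_folds = 2,
                     rfe_sizes = c(3, 6))
  suite <- ablation_suite(feats, control = ctrl, seed = 4)
  expect_length(suite, 12)
  expect_named(suite, c(t(outer(paste0("model", 1:3),
                                c("none", "auc", "s", "both"),
                                paste, sep = "_"))))
  expect_true(all(vapply(suite, function(r) r$n_outer_folds, numeric(1)) == 2))
})
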