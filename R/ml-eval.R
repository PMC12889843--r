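#' Control parameters for the nested-CV models
#'
#' Collects the tunables of [run_model()]. The defaults are the faithful
#' full-scale settings (500 trees, exhaustive inner folds, RFE subset sizes
#' 1..p, mtry grid 1..ceil(sqrt(p))); the `max_*` caps exist for
#' desk-scale runs and subsample folds deterministically from the seed.
#'
#' @param n_trees trees per random forest (default 500).
#' @param max_outer_folds cap on outer folds (`NULL` = all, exhaustively
#'   enumerated).
#' @param max_inner_folds cap on inner validation pairs per outer fold.
#' @param rfe_sizes candidate feature-subset sizes (`NULL` = 1..p).
#' @param mtry_grid mtry candidates (`NULL` = 1..ceil(sqrt(p))).
#' @return list of class `ml_control`.
#' @export
ml_control <- function(n_trees = 500, max_outer_folds = NULL,
                       max_inner_folds = NULL, rfe_sizes = NULL,
                       mtry_grid = NULL) {
  structure(list(n_trees = n_trees, max_outer_folds = max_outer_folds,
                 max_inner_folds = max_inner_folds, rfe_sizes = rfe_sizes,
                 mtry_grid = mtry_grid),
            class = "ml_control")
}

## mice_by_genotype: named list of two character vectors of mouse ids.
mice_table_to_list <- function(x) {
  if (is.data.frame(x)) {
    x <- x[!duplicated(x$mouse_id), ]
    split(x$mouse_id, x$genotype)
  } else x
}

#' Enumerate genotype-balanced leave-two-pairs-out outer folds
#'
#' Every outer fold holds out two mice of each genotype (all their sessions
#' travel to the test side together); the folds exhaustively enumerate all
#' `C(n_A, 2) * C(n_B, 2)` combinations in deterministic lexicographic
#' order. With 11 and 9 mice this yields 55 * 36 = 1980 folds. An optional
#' seeded uniform subsample caps the count for desk-scale runs.
#'
#' @param mice_by_genotype named list of two character vectors of mouse
#'   ids, or a data.frame with `mouse_id` and `genotype`.
#' @param max_folds optional cap; folds are subsampled uniformly.
#' @param seed seed for the subsample (required when `max_folds` bites).
#' @return list of folds, each `list(test = <4 ids>, train = <rest>)`, of
#'   class `fold_plan`.
#' @export
enumerate_outer_folds <- function(mice_by_genotype, max_folds = NULL,
                                  seed = 1L) {
  ml <- mice_table_to_list(mice_by_genotype)
  if (length(ml) != 2) stopf("expected exactly two genotypes")
  if (any(lengths(ml) < 3))
    stopf("need at least 3 mice per genotype (got %s)",
          paste(lengths(ml), collapse = ", "))
  ml <- lapply(ml, sort)
  pairs_a <- utils::combn(ml[[1]], 2, simplify = FALSE)
  pairs_b <- utils::combn(ml[[2]], 2, simplify = FALSE)
  all_mice <- unlist(ml, use.names = FALSE)
  folds <- list()
  k <- 0
  for (pa in pairs_a) for (pb in pairs_b) {
    k <- k + 1
    test <- c(pa, pb)
    folds[[k]] <- list(test = test, train = setdiff(all_mice, test))
  }
  if (!is.null(max_folds) && max_folds < length(folds)) {
    idx <- withr::with_seed(seed,
      sort(sample.int(length(folds), max_folds)))
    folds <- folds[idx]
  }
  structure(folds, class = "fold_plan")
}

#' Enumerate leave-one-pair-out inner folds
#'
#' Within an outer-training set, every (one mouse of genotype A, one of
#' genotype B) pair serves once as the inner validation set, the remainder
#' as inner training data; all `n_A * n_B` pairs are enumerated, optionally
#' subsampled with a seed.
#'
#' @inheritParams enumerate_outer_folds
#' @param train_mice_by_genotype named list of two character vectors (the
#'   outer-training mice), or data.frame with `mouse_id`, `genotype`.
#' @return list of folds, each `list(validation = <2 ids>, train = <rest>)`.
#' @export
enumerate_inner_folds <- function(train_mice_by_genotype, max_folds = NULL,
                                  seed = 1L) {
  ml <- mice_table_to_list(train_mice_by_genotype)
  if (length(ml) != 2 || any(lengths(ml) < 2))
    stopf("need at least 2 training mice per genotype")
  ml <- lapply(ml, sort)
  all_mice <- unlist(ml, use.names = FALSE)
  folds <- list()
  k <- 0
  for (a in ml[[1]]) for (b in ml[[2]]) {
    k <- k + 1
    folds[[k]] <- list(validation = c(a, b),
                       train = setdiff(all_mice, c(a, b)))
  }
  if (!is.null(max_folds) && max_folds < length(folds)) {
    idx <- withr::with_seed(seed,
      sort(sample.int(length(folds), max_folds)))
    folds <- folds[idx]
  }
  folds
}

## Fit a probability forest; response must be a factor with the positive
## class as the second level.
fit_ranger <- function(data, feature_cols, y, mtry, n_trees, seed) {
  df <- data[, feature_cols, drop = FALSE]
  df$.y <- y
  ranger::ranger(.y ~ ., data = df, probability = TRUE,
                 num.trees = n_trees, mtry = min(mtry, length(feature_cols)),
                 seed = seed, num.threads = 1,
                 importance = "none")
}

rf_scores <- function(model, data, feature_cols, positive_class) {
  pr <- stats::predict(model, data = data[, feature_cols, drop = FALSE],
                       num.threads = 1)$predictions
  pr[, positive_class]
}

#' Random forest with recursive feature elimination on inner folds
#'
#' Ranks features by permutation importance averaged over inner-training
#' fits, then evaluates candidate subset sizes (top-k features) crossed
#' with the mtry grid by mean inner-validation ROC-AUC. The best
#' combination (ties broken toward fewer features, then smaller mtry) is
#' refit on the full outer-training set. All randomness derives from
#' `seed`.
#'
#' @param train_table outer-training feature rows (with `mouse_id` and the
#'   label column).
#' @param feature_cols predictor column names.
#' @param label_col name of the binary label column.
#' @param positive_class label value treated as positive.
#' @param inner_folds inner folds from [enumerate_inner_folds()].
#' @param control an [ml_control()].
#' @param seed integer seed.
#' @return list with `model` (ranger fit), `features` (selected subset),
#'   `mtry`, `inner_auc`.
#' @export
fit_rf_with_rfe <- function(train_table, feature_cols, label_col,
                            positive_class, inner_folds,
                            control = ml_control(), seed = 1L) {
  y_all <- factor(train_table[[label_col]] == positive_class,
                  levels = c(FALSE, TRUE), labels = c("neg", "pos"))
  if (length(unique(y_all)) < 2) stopf("training data has a single class")
  p <- length(feature_cols)
  mtry_grid <- control$mtry_grid %||% seq_len(ceiling(sqrt(p)))
  rfe_sizes <- control$rfe_sizes %||% seq_len(p)
  rfe_sizes <- sort(unique(pmin(rfe_sizes, p)))

  split_fold <- function(fold) {
    tr <- train_table$mouse_id %in% fold$train
    va <- train_table$mouse_id %in% fold$validation
    list(tr = which(tr), va = which(va))
  }
  splits <- lapply(inner_folds, split_fold)

  ## 1. feature ranking: permutation importance averaged over inner fits
  imp <- matrix(0, length(splits), p, dimnames = list(NULL, feature_cols))
  for (i in seq_along(splits)) {
    df <- train_table[splits[[i]]$tr, feature_cols, drop = FALSE]
    df$.y <- y_all[splits[[i]]$tr]
    fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                          num.trees = control$n_trees,
                          mtry = min(ceiling(sqrt(p)), p),
                          importance = "permutation",
                          seed = child_seed(seed, i), num.threads = 1)
    imp[i, names(fit$variable.importance)] <- fit$variable.importance
  }
  ranking <- feature_cols[order(colMeans(imp), decreasing = TRUE)]

  ## 2. choose subset size and mtry by mean inner-validation ROC-AUC
  best <- NULL
  for (k in rfe_sizes) {
    feats <- ranking[seq_len(k)]
    for (mtry in mtry_grid[mtry_grid <= k]) {
      aucs <- vapply(seq_along(splits), function(i) {
        sp <- splits[[i]]
        fit <- fit_ranger(train_table[sp$tr, , drop = FALSE], feats,
                          y_all[sp$tr], mtry, control$n_trees,
                          seed = child_seed(seed, 1000 + i))
        sc <- rf_scores(fit, train_table[sp$va, , drop = FALSE], feats, "pos")
        auc_rank(sc, y_all[sp$va] == "pos")
      }, numeric(1))
      mean_auc <- mean(aucs, na.rm = TRUE)
      if (!is.nan(mean_auc) &&
          (is.null(best) || mean_auc > best$auc + 1e-9)) {
        best <- list(auc = mean_auc, k = k, mtry = mtry, features = feats)
      }
    }
  }
  if (is.null(best)) {  # every validation pair single-class: keep everything
    best <- list(auc = NA_real_, k = p, mtry = max(1, floor(sqrt(p))),
                 features = ranking)
  }

  ## 3. refit on the full outer-training set
  model <- fit_ranger(train_table, best$features, y_all, best$mtry,
                      control$n_trees, seed = child_seed(seed, 999983))
  list(model = model, features = best$features, mtry = best$mtry,
       inner_auc = best$auc)
}

#' Evaluate a fitted fold model on its outer test set
#'
#' Produces class-probability scores and hard labels at the default 0.5
#' probability threshold (a score of exactly 0.5 goes to the negative
#' class).
#'
#' @param fit result of [fit_rf_with_rfe()].
#' @param test_table outer-test feature rows.
#' @param label_col,positive_class as in [fit_rf_with_rfe()].
#' @return data.frame with `mouse_id`, `truth`, `score`, `predicted`
#'   (logical: positive).
#' @export
evaluate_fold <- function(fit, test_table, label_col, positive_class) {
  missing_cols <- setdiff(fit$features, names(test_table))
  if (length(missing_cols))
    stopf("test table lacks feature columns: %s",
          paste(missing_cols, collapse = ", "))
  score <- rf_scores(fit$model, test_table, fit$features, "pos")
  data.frame(mouse_id = test_table$mouse_id,
             truth = test_table[[label_col]] == positive_class,
             score = score,
             predicted = score > 0.5,
             stringsAsFactors = FALSE)
}

#' Derived metrics from a (possibly normalized) confusion matrix
#'
#' Recovers sensitivity, specificity, PPV, NPV and accuracy from the four
#' confusion entries; valid for raw counts or row-normalized percentages
#' (the row scale cancels in sensitivity/specificity, and PPV/NPV/accuracy
#' are then the values for balanced true classes).
#'
#' @param tp,fn,fp,tn confusion entries (positives: tp + fn; negatives:
#'   fp + tn).
#' @return A one-row data.frame with `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`.
#' @examples
#' confusion_metrics(61, 39, 15, 85)  # sens .61 spec .85 ppv .80 npv .69
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  data.frame(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    accuracy = (tp + tn) / (tp + fn + fp + tn))
}

## TPR at a fixed FPR grid for one fold's scores (staircase interpolation).
roc_curve_points <- function(truth, score, fpr_grid) {
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    c(fpr = mean(score[!truth] >= t), tpr = mean(score[truth] >= t))
  }, numeric(2))
  fpr <- c(0, pts["fpr", ], 1)
  tpr <- c(0, pts["tpr", ], 1)
  vapply(fpr_grid, function(f) max(tpr[fpr <= f]), numeric(1))
}

#' Aggregate per-fold predictions into a model report
#'
#' Pools scores over all outer folds for the headline trapezoidal ROC-AUC,
#' vertically averages per-fold ROC curves on a fixed FPR grid for the
#' plotted mean curve, sums confusion counts at the 0.5 threshold and
#' row-normalizes them to percentages per true class, derives secondary
#' metrics from the normalized matrix, and reports each feature's
#' selection frequency (fraction of outer folds whose final model retained
#' it).
#'
#' @param fold_predictions list of data.frames from [evaluate_fold()].
#' @param fold_features list of selected-feature character vectors, one
#'   per fold.
#' @param all_features full candidate feature names (denominator columns
#'   for selection frequency).
#' @return list of class `model_report`: `roc_auc` (pooled),
#'   `roc_auc_fold_mean`, `mean_roc_curve` (data.frame `fpr`, `tpr`),
#'   `confusion_counts`, `confusion_normalized`, `metrics`,
#'   `selection_frequency`, `n_outer_folds`.
#' @export
aggregate_reports <- function(fold_predictions, fold_features, all_features) {
  stopifnot(length(fold_predictions) >= 1)
  pooled <- do.call(rbind, fold_predictions)
  roc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = pooled$truth, predictor = pooled$score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  fold_aucs <- vapply(fold_predictions, function(fp) {
    auc_rank(fp$score, fp$truth)
  }, numeric(1))
  fpr_grid <- seq(0, 1, by = 0.01)
  curves <- vapply(fold_predictions, function(fp) {
    if (length(unique(fp$truth)) < 2) return(rep(NA_real_, length(fpr_grid)))
    roc_curve_points(fp$truth, fp$score, fpr_grid)
  }, numeric(length(fpr_grid)))
  mean_curve <- data.frame(fpr = fpr_grid,
                           tpr = rowMeans(curves, na.rm = TRUE))
  tp <- sum(pooled$truth & pooled$predicted)
  fn <- sum(pooled$truth & !pooled$predicted)
  fp_ <- sum(!pooled$truth & pooled$predicted)
  tn <- sum(!pooled$truth & !pooled$predicted)
  norm <- c(TP = 100 * tp / max(tp + fn, 1), FN = 100 * fn / max(tp + fn, 1),
            FP = 100 * fp_ / max(fp_ + tn, 1), TN = 100 * tn / max(fp_ + tn, 1))
  sel <- vapply(all_features, function(f) {
    mean(vapply(fold_features, function(fs) f %in% fs, logical(1)))
  }, numeric(1))
  structure(
    list(roc_auc = roc_auc,
         roc_auc_fold_mean = mean(fold_aucs, na.rm = TRUE),
         mean_roc_curve = mean_curve,
         confusion_counts = c(TP = tp, FN = fn, FP = fp_, TN = tn),
         confusion_normalized = norm,
         metrics = confusion_metrics(norm["TP"], norm["FN"], norm["FP"],
                                     norm["TN"]),
         selection_frequency = sel,
         n_outer_folds = length(fold_predictions)),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %d outer folds | pooled ROC-AUC %.3f\n",
              x$n_outer_folds, x$roc_auc))
  cat(sprintf("  normalized confusion: TP %.1f FN %.1f FP %.1f TN %.1f\n",
              x$confusion_normalized["TP"], x$confusion_normalized["FN"],
              x$confusion_normalized["FP"], x$confusion_normalized["TN"]))
  m <- x$metrics
  cat(sprintf("  sens %.2f spec %.2f PPV %.2f NPV %.2f acc %.2f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy))
  top <- sort(x$selection_frequency, decreasing = TRUE)
  cat("  top selected:",
      paste(sprintf("%s (%.0f%%)", names(top)[seq_len(min(4, length(top)))],
                    100 * top[seq_len(min(4, length(top)))]),
            collapse = ", "), "\n")
  invisible(x)
}

## Resolve target/positive class and feature set for one of the three
## model frameworks + ablation condition.
resolve_model_spec <- function(model, features, ablation) {
  stopifnot(model %in% 1:3)
  ablation <- match.arg(ablation, c("none", "auc", "s", "both"))
  feature_cols <- intersect(c(candidate_columns(), predictor_columns()),
                            names(features))
  feature_cols <- unique(feature_cols)
  if (ablation %in% c("auc", "both"))
    feature_cols <- feature_cols[!grepl("^AUC_", feature_cols)]
  if (ablation %in% c("s", "both"))
    feature_cols <- feature_cols[!grepl("^s_", feature_cols)]
  if (model == 1) {
    target <- "genotype"
  } else {
    target <- "motivation_label"
    if (!"motivation_label" %in% names(features))
      stopf("features table lacks motivation_label (run label_motivation)")
  }
  if (model == 3) feature_cols <- c(feature_cols, "Genotype")
  if (!length(setdiff(feature_cols, "Genotype")))
    stopf("ablation leaves no predictors")
  ## positive class: affected genotype (lower mean composite score when
  ## available, else second sorted label) for genotype; "high" for behavior
  if (target == "genotype") {
    gl <- sort(unique(features$genotype))
    if ("S_avg" %in% names(features)) {
      means <- tapply(features$S_avg, features$genotype, mean)
      positive <- names(means)[which.min(means)]
    } else positive <- gl[2]
  } else {
    positive <- "high"
  }
  list(target = target, positive = positive, feature_cols = feature_cols,
       ablation = ablation)
}

#' Run one prediction model under nested leave-pairs-out cross-validation
#'
#' The three frameworks: Model 1 predicts genotype from the imaging-derived
#' indices; Model 2 predicts the high/low social-motivation label from the
#' same indices; Model 3 additionally includes genotype (as a binary
#' predictor named `Genotype`). For every outer fold (two held-out mice
#' per genotype, all sessions together) an inner leave-one-pair-out CV
#' performs RFE and mtry tuning, the tuned forest is refit on the outer
#' training set, and the untouched outer test set is scored. Ablations
#' remove the activity features (`auc`), the spectral-distance features
#' (`s`), or both before training. A runtime leakage guard asserts that no
#' mouse appears on both sides of any fold.
#'
#' @param model 1, 2 or 3.
#' @param features preprocessed feature table ([preprocess_features()]).
#' @param fold_plan outer folds from [enumerate_outer_folds()]; built from
#'   the table's mice when `NULL`.
#' @param ablation `"none"`, `"auc"`, `"s"` or `"both"`.
#' @param control an [ml_control()].
#' @param seed integer seed governing all randomness.
#' @return A `model_report` (see [aggregate_reports()]); the selected
#'   feature subsets per fold are attached as attribute `"fold_features"`.
#' @export
run_model <- function(model, features, fold_plan = NULL, ablation = "none",
                      control = ml_control(), seed = 1L) {
  spec <- resolve_model_spec(model, features, ablation)
  features <- as.data.frame(features)
  if (model == 3) {
    affected <- if (spec$target == "genotype") spec$positive else {
      means <- tapply(features$S_avg, features$genotype, mean)
      names(means)[which.min(means)]
    }
    features$Genotype <- as.numeric(features$genotype == affected)
  }
  if (is.null(fold_plan)) {
    fold_plan <- enumerate_outer_folds(
      features[, c("mouse_id", "genotype")],
      max_folds = control$max_outer_folds, seed = seed)
  }
  fold_predictions <- vector("list", length(fold_plan))
  fold_features <- vector("list", length(fold_plan))
  for (i in seq_along(fold_plan)) {
    fold <- fold_plan[[i]]
    if (length(intersect(fold$test, fold$train)))
      stopf("leakage: mice in both train and test of fold %d", i)
    train_tab <- features[features$mouse_id %in% fold$train, , drop = FALSE]
    test_tab <- features[features$mouse_id %in% fold$test, , drop = FALSE]
    inner <- enumerate_inner_folds(
      train_tab[, c("mouse_id", "genotype")],
      max_folds = control$max_inner_folds, seed = child_seed(seed, i))
    fit <- fit_rf_with_rfe(train_tab, spec$feature_cols, spec$target,
                           spec$positive, inner, control = control,
                           seed = child_seed(seed, 10000 + i))
    fold_features[[i]] <- fit$features
    fold_predictions[[i]] <- evaluate_fold(fit, test_tab, spec$target,
                                           spec$positive)
  }
  report <- aggregate_reports(fold_predictions, fold_features,
                              spec$feature_cols)
  attr(report, "fold_features") <- fold_features
  attr(report, "spec") <- spec
  report
}

#' In-silico ablation suite
#'
#' Runs Models 1-3 under each of the four feature conditions (full,
#' without activity features, without spectral distances, without both)
#' with identical fold plans and seeds, so that only the feature set
#' varies across the 12 reports.
#'
#' @inheritParams run_model
#' @return Named list of 12 `model_report`s,
#'   `"model<k>_<none|auc|s|both>"`.
#' @export
ablation_suite <- function(features, fold_plan = NULL,
                           control = ml_control(), seed = 1L) {
  if (is.null(fold_plan)) {
    fold_plan <- enumerate_outer_folds(
      features[, c("mouse_id", "genotype")],
      max_folds = control$max_outer_folds, seed = seed)
  }
  out <- list()
  for (model in 1:3) {
    for (ab in c("none", "auc", "s", "both")) {
      out[[sprintf("model%d_%s", model, ab)]] <-
        run_model(model, features, fold_plan = fold_plan, ablation = ab,
                  control = control, seed = seed)
    }
  }
  out
}
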