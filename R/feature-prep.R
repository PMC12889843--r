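## Canonical predictor column names. Stage-wise indices use suffixes _H,
## _SB, _SN; spectral distances name the stage pair.
predictor_columns <- function() {
  c(paste0("AUC_", c("H", "SB", "SN")),
    "s_H_SB", "s_H_SN", "s_SB_SN",
    paste0("Lg_", c("H", "SB", "SN")),
    paste0("Cl_", c("H", "SB", "SN")),
    paste0("Cg_", c("H", "SB", "SN")))
}

## The fixed 11-predictor candidate subset used by the prediction models.
candidate_columns <- function() {
  c("AUC_H", "AUC_SB", "AUC_SN", "s_H_SB", "s_H_SN",
    "Lg_SB", "Cl_SB", "Cl_SN", "Cg_H", "Cg_SB", "Cg_SN")
}

#' Assemble the per-session feature table
#'
#' Joins stage-wise graph indices, cross-stage spectral distances,
#' stage-mean activity and behavior labels into one row per mouse-session
#' with 15 raw predictors: `AUC_{H,SB,SN}`, `s_{H_SB,H_SN,SB_SN}`,
#' `Lg_{H,SB,SN}`, `Cl_{H,SB,SN}`, `Cg_{H,SB,SN}`. Any (mouse, session,
#' stage/pair) missing from an input is an error naming the key — the
#' table must be complete.
#'
#' @param indices data.frame `mouse_id`, `session`, `stage`, `L_g`, `C_l`,
#'   `C_g` (three stage rows per session).
#' @param spectral data.frame `mouse_id`, `session`, `pair` (one of
#'   `"H-SB"`, `"H-SN"`, `"SB-SN"`), `s`.
#' @param activity data.frame `mouse_id`, `session`, `stage`,
#'   `stage_mean_auc`.
#' @param behavior labeled behavior table from [label_motivation()].
#' @return data.frame with id columns `mouse_id`, `session`, `genotype`,
#'   `motivation_label`, `S_avg` followed by the 15 predictors in the fixed
#'   documented order of `predictor_columns()`.
#' @export
assemble_features <- function(indices, spectral, activity, behavior) {
  keys <- unique(behavior[, c("mouse_id", "session")])
  stages <- c("H", "SB", "SN")
  pairs <- c("H-SB", "H-SN", "SB-SN")
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    m <- keys$mouse_id[r]; s <- keys$session[r]
    pick <- function(df, extra_col, extra_val, what) {
      hit <- df[df$mouse_id == m & df$session == s &
                  df[[extra_col]] == extra_val, , drop = FALSE]
      if (nrow(hit) != 1)
        stopf("missing or duplicated %s for mouse %s session %s (%s)",
              what, m, s, extra_val)
      hit
    }
    out <- data.frame(mouse_id = m, session = s, stringsAsFactors = FALSE)
    beh <- behavior[behavior$mouse_id == m & behavior$session == s, ,
                    drop = FALSE]
    if (nrow(beh) != 1)
      stopf("missing behavior row for mouse %s session %s", m, s)
    out$genotype <- beh$genotype
    out$motivation_label <- beh$motivation_label
    out$S_avg <- beh$S_avg
    for (st in stages) {
      act <- pick(activity, "stage", st, "activity")
      out[[paste0("AUC_", st)]] <- act$stage_mean_auc
    }
    for (pr in pairs) {
      sp <- pick(spectral, "pair", pr, "spectral distance")
      out[[paste0("s_", gsub("-", "_", pr))]] <- sp$s
    }
    for (st in stages) {
      gi <- pick(indices, "stage", st, "graph indices")
      out[[paste0("Lg_", st)]] <- gi$L_g
      out[[paste0("Cl_", st)]] <- gi$C_l
      out[[paste0("Cg_", st)]] <- gi$C_g
    }
    out
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  id_cols <- c("mouse_id", "session", "genotype", "motivation_label", "S_avg")
  tab[, c(id_cols, predictor_columns())]
}

#' Variance-stabilizing transforms of the feature table
#'
#' Right-skewed spectral distances and local clustering are
#' log-transformed, `log(x + eps)`; the strongly skewed global clustering
#' uses the inverse transform `1 / (x + eps)`. AUC and path-length columns
#' are left unchanged. The `eps` offset keeps exact zeros (possible on
#' sparse graphs) finite.
#'
#' @param table feature table from [assemble_features()].
#' @param eps offset guarding zeros (default 1e-6).
#' @return The transformed table.
#' @export
transform_features <- function(table, eps = 1e-6) {
  for (col in names(table)) {
    if (grepl("^(s_|Cl_)", col)) table[[col]] <- log(table[[col]] + eps)
    if (grepl("^Cg_", col)) table[[col]] <- 1 / (table[[col]] + eps)
  }
  table
}

#' Winsorize a column at k median absolute deviations
#'
#' Values are clipped to `[median - k*MAD, median + k*MAD]` where
#' `MAD = median(|x - median(x)|)` — unscaled (no 1.4826 consistency
#' factor). A constant column (MAD 0) is returned unchanged with a warning.
#'
#' @param column numeric vector, length >= 2.
#' @param k clipping width in MADs (default 3).
#' @param mad_scale multiplicative consistency factor applied to the MAD
#'   (default 1 = unscaled).
#' @return The clipped vector.
#' @export
winsorize_mad <- function(column, k = 3, mad_scale = 1) {
  if (length(column) < 2) stopf("need at least 2 values")
  med <- stats::median(column)
  mad_ <- stats::median(abs(column - med)) * mad_scale
  if (mad_ == 0) {
    warnf("MAD is zero; column returned unchanged")
    return(column)
  }
  pmin(pmax(column, med - k * mad_), med + k * mad_)
}

#' Screen multivariate outliers by Mahalanobis distance
#'
#' Computes each row's squared Mahalanobis distance from the column means
#' under the sample covariance of the predictor columns, and flags rows
#' with `D^2` above the chi-square quantile `qchisq(quantile, p)` where p
#' is the number of predictors. Flagged rows are removed by default
#' (`action = "remove"`) or only reported (`action = "flag"`). A singular
#' covariance is ridge-regularized with a warning.
#'
#' @param table feature table.
#' @param columns predictor columns to use (default: all of
#'   `predictor_columns()` present in the table).
#' @param quantile chi-square probability cutoff (default 0.975).
#' @param action `"remove"` or `"flag"`.
#' @return A list with `kept` (table rows retained), `flagged` (rows over
#'   the cutoff), `d2` (all distances) and `cutoff`.
#' @export
mahalanobis_screen <- function(table, columns = NULL, quantile = 0.975,
                               action = c("remove", "flag")) {
  action <- match.arg(action)
  if (is.null(columns))
    columns <- intersect(predictor_columns(), names(table))
  x <- as.matrix(table[, columns, drop = FALSE])
  p <- ncol(x)
  if (nrow(x) <= p) stopf("need more rows than predictor columns")
  ctr <- colMeans(x)
  cv <- stats::cov(x)
  ok <- tryCatch({solve(cv); TRUE}, error = function(e) FALSE)
  if (!ok) {
    warnf("singular covariance; applying ridge regularization")
    cv <- cv + diag(1e-8 * max(diag(cv), 1), p)
  }
  d2 <- stats::mahalanobis(x, center = ctr, cov = cv)
  cutoff <- stats::qchisq(quantile, df = p)
  over <- d2 > cutoff
  list(kept = if (action == "remove") table[!over, , drop = FALSE] else table,
       flagged = table[over, , drop = FALSE],
       d2 = d2, cutoff = cutoff)
}

#' Prune highly correlated predictors
#'
#' Iteratively removes columns while any absolute pairwise correlation
#' exceeds `cutoff`: from the worst offending pair, the column with the
#' larger mean absolute correlation to all remaining columns is dropped
#' (ties broken toward the earlier column). Deterministic given column
#' order.
#'
#' @param table feature table.
#' @param cutoff absolute-correlation cutoff (default 0.8).
#' @param columns predictor columns considered (default: those of
#'   `predictor_columns()` present).
#' @return The table with pruned predictor columns removed; removed names
#'   in attribute `"pruned"`.
#' @export
prune_correlated <- function(table, cutoff = 0.8, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(predictor_columns(), names(table))
  if (length(columns) < 2) stopf("need at least 2 predictor columns")
  keep <- columns
  removed <- character(0)
  repeat {
    cc <- abs(suppressWarnings(stats::cor(table[, keep, drop = FALSE])))
    diag(cc) <- 0
    cc[is.na(cc)] <- 0
    if (max(cc) <= cutoff) break
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    mean_abs <- (rowSums(cc)) / (length(keep) - 1)
    pair <- sort(unname(worst))
    drop_idx <- if (mean_abs[pair[1]] >= mean_abs[pair[2]]) pair[1] else pair[2]
    removed <- c(removed, keep[drop_idx])
    keep <- keep[-drop_idx]
    if (length(keep) < 2) break
  }
  out <- table[, setdiff(names(table), removed), drop = FALSE]
  attr(out, "pruned") <- removed
  out
}

#' Restrict to the fixed 11-feature candidate subset
#'
#' Keeps the id columns plus the fixed candidate predictors
#' `AUC_H, AUC_SB, AUC_SN, s_H_SB, s_H_SN, Lg_SB, Cl_SB, Cl_SN, Cg_H,
#' Cg_SB, Cg_SN` — the default input to the prediction models. Subsets
#' derived from data-driven pruning remain available via
#' [prune_correlated()].
#'
#' @param table feature table containing all candidate columns.
#' @return The restricted table.
#' @export
candidate_subset <- function(table) {
  missing_cols <- setdiff(candidate_columns(), names(table))
  if (length(missing_cols))
    stopf("missing candidate columns: %s", paste(missing_cols, collapse = ", "))
  id_cols <- intersect(c("mouse_id", "session", "genotype",
                         "motivation_label", "S_avg"), names(table))
  table[, c(id_cols, candidate_columns())]
}

#' Default preprocessing ledger
#'
#' Applies, in order and once on the full table (a deliberate, logged
#' leakage trade-off that keeps the feature space identical across CV
#' folds): variance-stabilizing transforms, per-column 3-MAD
#' winsorization, the Mahalanobis outlier screen, and restriction to the
#' fixed 11-feature candidate subset.
#'
#' @param table raw feature table from [assemble_features()].
#' @param eps transform offset.
#' @param winsor_k winsorization width in MADs.
#' @param mahalanobis_quantile chi-square cutoff probability.
#' @param use_candidate_subset restrict to the fixed 11 predictors
#'   (default) instead of correlation pruning.
#' @param prune_cutoff correlation-pruning cutoff used when
#'   `use_candidate_subset = FALSE`.
#' @return The preprocessed feature table; rows removed by the screen are
#'   recorded in attribute `"screened_out"`.
#' @export
preprocess_features <- function(table, eps = 1e-6, winsor_k = 3,
                                mahalanobis_quantile = 0.975,
                                use_candidate_subset = TRUE,
                                prune_cutoff = 0.8) {
  tab <- transform_features(table, eps = eps)
  for (col in intersect(predictor_columns(), names(tab))) {
    tab[[col]] <- suppressWarnings(winsorize_mad(tab[[col]], k = winsor_k))
  }
  scr <- mahalanobis_screen(tab, quantile = mahalanobis_quantile)
  tab <- scr$kept
  tab <- if (use_candidate_subset) candidate_subset(tab)
         else prune_correlated(tab, cutoff = prune_cutoff)
  attr(tab, "screened_out") <- scr$flagged
  tab
}
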