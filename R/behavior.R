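#' Composite social-motivation score
#'
#' Per-session mean of the sociability preference (S1, percent time
#' exploring the social target in the SB stage) and the social-novelty
#' preference (S2, percent time exploring the novel target in the SN
#' stage).
#'
#' @param S1,S2 percentages in `[0, 100]` (vectorized).
#' @return `(S1 + S2) / 2`, on the percent scale.
#' @export
composite_score <- function(S1, S2) {
  if (any(!is.finite(S1)) || any(!is.finite(S2)) ||
      any(S1 < 0 | S1 > 100) || any(S2 < 0 | S2 > 100))
    stopf("S1 and S2 must be percentages in [0, 100]")
  (S1 + S2) / 2
}

#' ROC-derived motivation threshold
#'
#' Finds the composite-score threshold that best discriminates the two
#' genotypes, as the candidate value nearest the top-left corner of the
#' ROC curve, i.e. minimizing `sqrt((1 - sensitivity)^2 +
#' (1 - specificity)^2)`. The positive class is the lower-scoring genotype
#' (the affected group), predicted positive when the score is at or below
#' the threshold. Candidates are midpoints between adjacent sorted unique
#' scores; ties in the corner distance are broken toward the smaller
#' threshold. The threshold is computed once on the full dataset and is
#' never re-tuned inside cross-validation.
#'
#' @param scores numeric vector of composite scores (percent).
#' @param genotypes vector of genotype labels, exactly two classes present.
#' @return A list with `threshold`, `sensitivity`, `specificity`,
#'   `positive_class`.
#' @export
roc_motivation_threshold <- function(scores, genotypes) {
  if (length(scores) != length(genotypes)) stopf("length mismatch")
  cls <- unique(genotypes)
  if (length(cls) != 2) stopf("exactly two genotype classes are required")
  u <- sort(unique(scores))
  if (length(u) < 2) stopf("need at least 2 distinct score values")
  means <- tapply(scores, genotypes, mean)
  positive <- names(means)[which.min(means)]   # affected = lower-scoring
  is_pos <- genotypes == positive
  candidates <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  best <- NULL
  for (thr in candidates) {                    # ascending: first win = smallest
    sens <- mean(scores[is_pos] <= thr)
    spec <- mean(scores[!is_pos] > thr)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    if (is.null(best) || d < best$d - 1e-12) {
      best <- list(d = d, threshold = thr, sensitivity = sens,
                   specificity = spec)
    }
  }
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, positive_class = positive)
}

#' Binarize composite scores into motivation labels
#'
#' `"high"` iff the score strictly exceeds the threshold, else `"low"`
#' (a score exactly at the threshold is `"low"`).
#'
#' @param S_avg composite score(s), percent.
#' @param threshold threshold from [roc_motivation_threshold()].
#' @return Character vector of `"high"` / `"low"`.
#' @export
binarize_motivation <- function(S_avg, threshold) {
  ifelse(S_avg > threshold, "high", "low")
}

#' Full behavior labeling of a cohort behavior table
#'
#' Computes per-session composite scores, derives the genotype-ROC
#' threshold once from the full table, and appends motivation labels. Uses
#' only the exploration percentages and genotype — never imaging features.
#'
#' @param behavior data.frame with `mouse_id`, `genotype`, `session`,
#'   `S1_percent`, `S2_percent`.
#' @return The input with added columns `S_avg` and `motivation_label`,
#'   plus the threshold as attribute `"motivation_threshold"`.
#' @export
label_motivation <- function(behavior) {
  need <- c("mouse_id", "genotype", "session", "S1_percent", "S2_percent")
  if (!all(need %in% names(behavior)))
    stopf("behavior table needs columns: %s", paste(need, collapse = ", "))
  behavior$S_avg <- composite_score(behavior$S1_percent, behavior$S2_percent)
  thr <- roc_motivation_threshold(behavior$S_avg, behavior$genotype)
  behavior$motivation_label <- binarize_motivation(behavior$S_avg,
                                                   thr$threshold)
  attr(behavior, "motivation_threshold") <- thr
  behavior
}
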