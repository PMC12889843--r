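#' Per-session calcium trace set
#'
#' Container for one mouse-session: a neurons-by-frames dF/F matrix with
#' the three behavioral stage windows (habituation H, sociability SB,
#' social novelty SN) and cohort metadata. Stage windows are half-open
#' 0-based frame intervals `[start, end)`, disjoint and ordered, and all
#' three labels must appear exactly once.
#'
#' @param dff numeric matrix, neurons x frames, finite.
#' @param frame_rate_hz sampling rate, frames/s.
#' @param stages data.frame with columns `label` (exactly `"H"`, `"SB"`,
#'   `"SN"` once each), `start`, `end` (half-open, 0-based frames).
#' @param mouse_id,genotype,session_index cohort metadata.
#' @return Object of class `trace_set`.
#' @export
trace_set <- function(dff, frame_rate_hz, stages, mouse_id = NA_character_,
                      genotype = NA_character_, session_index = NA_integer_) {
  dff <- as.matrix(dff)
  if (!all(is.finite(dff))) stopf("dff must be finite")
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be positive")
  stages <- as.data.frame(stages)
  if (!all(c("label", "start", "end") %in% names(stages)))
    stopf("stages needs columns label, start, end")
  if (!setequal(stages$label, c("H", "SB", "SN")) || nrow(stages) != 3)
    stopf("stages must contain exactly the labels H, SB, SN")
  stages <- stages[order(stages$start), ]
  if (any(stages$end <= stages$start))
    stopf("each stage interval must be nonempty")
  if (any(stages$start < 0) || any(stages$end > ncol(dff)))
    stopf("stage intervals must lie within [0, n_frames)")
  if (any(utils::head(stages$end, -1) > utils::tail(stages$start, -1)))
    stopf("stage intervals must be disjoint and ordered")
  if (is.null(rownames(dff))) rownames(dff) <- paste0("n", seq_len(nrow(dff)))
  structure(
    list(dff = dff, frame_rate_hz = frame_rate_hz, stages = stages,
         mouse_id = mouse_id, genotype = genotype,
         session_index = as.integer(session_index)),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %s session %s (%s): %d neurons x %d frames @ %g Hz\n",
              x$mouse_id, x$session_index, x$genotype,
              nrow(x$dff), ncol(x$dff), x$frame_rate_hz))
  invisible(x)
}

#' Extract one stage's frames
#' @param ts a [trace_set()].
#' @param stage stage label (`"H"`, `"SB"`, `"SN"`).
#' @return Matrix of that stage's dF/F frames (neurons x frames).
#' @export
stage_frames <- function(ts, stage) {
  row <- ts$stages[ts$stages$label == stage, ]
  if (nrow(row) != 1) stopf("unknown stage '%s'", stage)
  ts$dff[, (row$start + 1):row$end, drop = FALSE]
}

#' Normalize a calcium trace to its maximum
#'
#' Divides a raw trace by its maximum, putting it on a `[min/max, 1]`
#' scale. Degenerate traces whose maximum is not positive are returned as
#' all zeros with a warning so they propagate 0 activity rather than NaN.
#'
#' @param raw finite numeric vector.
#' @return Vector of the same length.
#' @export
normalize_trace <- function(raw) {
  if (!length(raw) || !all(is.finite(raw))) stopf("raw must be finite, length >= 1")
  m <- max(raw)
  if (m <= 0) {
    warnf("trace maximum is not positive; returning all zeros")
    return(rep(0, length(raw)))
  }
  raw / m
}

#' Activity level as area under curve per 100 seconds
#'
#' For a max-normalized trace, 100 times its time mean: the integral of the
#' trace divided by the recording duration, scaled to a 100-second window.
#' Bounded in `[0, 100]` for nonnegative normalized traces and invariant to
#' the frame rate for a constant signal.
#'
#' @param normalized max-normalized trace vector.
#' @param frame_rate_hz sampling rate (only used to document units; the
#'   time-mean formulation cancels it).
#' @return Scalar AUC per 100 s.
#' @export
auc_per_100s <- function(normalized, frame_rate_hz = NULL) {
  if (!length(normalized)) stopf("empty trace")
  100 * mean(normalized)
}

#' Detect calcium events by rising-edge thresholding
#'
#' A frame t is an event onset iff the first difference
#' `v[t] - v[t-1]` exceeds `k_sd` standard deviations of all first
#' differences while the previous difference did not (rising edge), so a
#' single fast transient contributes one event. The first frame is never
#' an event, and a constant trace (zero SD) yields no events.
#'
#' @param normalized numeric trace, length >= 2.
#' @param k_sd threshold in SDs of the first differences (default 5).
#' @return Integer 0/1 vector, same length as the input.
#' @export
detect_events <- function(normalized, k_sd = 5) {
  if (length(normalized) < 2) stopf("trace must have length >= 2")
  d <- diff(normalized)
  s <- stats::sd(d)
  out <- integer(length(normalized))
  if (!is.finite(s) || s == 0) return(out)
  thr <- k_sd * s
  above <- d > thr                      # above[t] refers to step into frame t+1
  onset <- above & !c(FALSE, utils::head(above, -1))
  out[which(onset) + 1L] <- 1L
  out
}

#' Per-stage activity summary of a session
#'
#' Normalizes each neuron's trace over the whole session (so stage AUCs
#' are comparable within a neuron), then computes per neuron and stage the
#' AUC per 100 s and the event rate, plus the across-neuron mean AUC per
#' stage.
#'
#' @param ts a [trace_set()].
#' @param k_sd event-detection threshold in SDs (default 5).
#' @return A list with `per_neuron` (data.frame: `mouse_id`, `session`,
#'   `stage`, `neuron`, `auc_per_100s`, `event_rate_hz`) and `per_stage`
#'   (data.frame: `mouse_id`, `session`, `stage`, `stage_mean_auc`).
#' @export
summarize_activity <- function(ts, k_sd = 5) {
  stopifnot(inherits(ts, "trace_set"))
  norm <- t(apply(ts$dff, 1, function(v) {
    m <- max(v)
    if (m <= 0) rep(0, length(v)) else v / m
  }))
  per_neuron <- list()
  for (st in ts$stages$label) {
    row <- ts$stages[ts$stages$label == st, ]
    idx <- (row$start + 1):row$end
    block <- norm[, idx, drop = FALSE]
    dur_s <- ncol(block) / ts$frame_rate_hz
    auc <- apply(block, 1, function(v) auc_per_100s(v))
    rate <- apply(block, 1, function(v) sum(detect_events(v, k_sd)) / dur_s)
    per_neuron[[st]] <- data.frame(
      mouse_id = ts$mouse_id, session = ts$session_index, stage = st,
      neuron = rownames(ts$dff), auc_per_100s = auc, event_rate_hz = rate,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  per_neuron <- do.call(rbind, c(per_neuron, list(make.row.names = FALSE)))
  per_stage <- stats::aggregate(auc_per_100s ~ mouse_id + session + stage,
                                data = per_neuron, FUN = mean)
  names(per_stage)[names(per_stage) == "auc_per_100s"] <- "stage_mean_auc"
  list(per_neuron = per_neuron, per_stage = per_stage)
}
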