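## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

## Validate a binary, symmetric, zero-diagonal adjacency matrix.
check_adjacency <- function(adj, arg = "adjacency") {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stopf("%s must be a square matrix", arg)
  if (any(!adj %in% c(0, 1)))
    stopf("%s must be binary (0/1)", arg)
  if (any(diag(adj) != 0))
    stopf("%s must have a zero diagonal", arg)
  if (any(adj != t(adj)))
    stopf("%s must be symmetric", arg)
  invisible(adj)
}

## Rank-based (Mann-Whitney) ROC-AUC used inside the inner CV loop, where
## calling a full ROC constructor thousands of times would dominate runtime.
## Tested against pROC::auc. `labels` is logical/0-1 with TRUE = positive.
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## Deterministic child seeds below 2^31, derived from a user seed and a
## stream index so independent pipeline stages do not share RNG streams.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647
}
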