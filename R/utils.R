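# Internal helpers shared across modules.

# Deterministic fan-out of a master seed into per-component streams.
# Keeps derived seeds inside the 32-bit signed integer range.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) * 48271 + index * 7919) %% 2147483647)
}

# Rank-based AUC (Mann-Whitney statistic). `scores` are decision values,
# larger meaning more confidence in the positive class.
rank_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, length(scores) == length(labels))
  if (is.null(positive)) positive <- levels(labels)[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_square_symmetric <- function(w, tol = 1e-8, what = "weight matrix") {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop(what, " must be a square matrix")
  }
  if (any(!is.finite(w))) stop(what, " contains non-finite entries")
  denom <- max(abs(w), 1)
  if (max(abs(w - t(w))) > tol * denom) {
    stop(what, " is asymmetric beyond tolerance ", tol)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
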