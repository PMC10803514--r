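# Soft-max, cross-entropy, the concurrent soft-max with label co-occurrence
# statistics, and the four per-index evaluation metrics.

#' Numerically stable soft-max
#'
#' `sigma_i = exp(z_i) / sum_j exp(z_j)`, computed max-shifted so arbitrarily
#' large logits cannot overflow.
#'
#' @param z numeric vector of finite logits, or a matrix (one row per
#'   sample).
#' @return probabilities of the same shape; each row/vector sums to 1.
#' @export
softmax_probs <- function(z) {
  if (is.matrix(z)) return(t(apply(z, 1L, softmax_probs)))
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Batch-averaged cross-entropy loss
#'
#' `L = -mean_rows sum_i y_i log(sigma_i)`.  A zero probability at a positive
#' target is clamped at 1e-12; the number of clamped entries is attached as
#' attribute `clamped`.
#'
#' @param sigma probability matrix (rows are samples) or vector.
#' @param y 0/1 target matrix/vector of the same shape.
#' @return non-negative scalar loss.
#' @export
cross_entropy_loss <- function(sigma, y) {
  if (!is.matrix(sigma)) sigma <- matrix(sigma, nrow = 1L)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  stopifnot(identical(dim(sigma), dim(y)))
  clamped <- sum(y > 0 & sigma < 1e-12)
  if (clamped > 0) warning(sprintf("%d probabilities clamped at 1e-12", clamped))
  s <- pmax(sigma, 1e-12)
  L <- -mean(rowSums(y * log(s)))
  attr(L, "clamped") <- clamped
  L
}

#' Concurrent soft-max scores
#'
#' For a multi-label tag vector, co-occurring non-target tags are
#' down-weighted in the normaliser:
#' `sigma*_i = exp(z_i) / (sum_{j != i} (1 - y_j) (1 - r_ij) exp(z_j) +
#' exp(z_i))`.  With `r = 0` and a one-hot `y` this reduces exactly to the
#' plain soft-max.  Each score lies in (0, 1]; rows need not sum to 1.
#'
#' @param z numeric vector of tag logits (length C).
#' @param y 0/1 target vector (length C).
#' @param r C x C symmetric co-occurrence matrix with entries in `[0, 1]`
#'   (diagonal unused).
#' @param suppress_by which indicator weights the suppression term:
#'   `"target_j"` (default; suppresses tags that are not targets) or
#'   `"target_i"` (the verbatim printed form).
#' @return numeric vector of scores in (0, 1].
#' @export
concurrent_softmax_probs <- function(z, y, r,
                                     suppress_by = c("target_j", "target_i")) {
  suppress_by <- match.arg(suppress_by)
  C <- length(z)
  stopifnot(length(y) == C, all(dim(r) == C), all(r >= 0), all(r <= 1))
  e <- exp(z - max(z))
  out <- numeric(C)
  for (i in seq_len(C)) {
    wj <- if (suppress_by == "target_j") (1 - y) else rep(1 - y[i], C)
    coef <- wj * (1 - r[i, ])
    coef[i] <- 0
    out[i] <- e[i] / (sum(coef * e) + e[i])
  }
  out
}

# gradient of -sum_i y_i log sigma*_i w.r.t. z (one sample)
concurrent_softmax_grad <- function(z, y, r) {
  C <- length(z)
  e <- exp(z - max(z))
  g <- numeric(C)
  D <- numeric(C)
  for (i in seq_len(C)) {
    coef <- (1 - y) * (1 - r[i, ])
    coef[i] <- 0
    D[i] <- sum(coef * e) + e[i]
  }
  for (k in seq_len(C)) {
    acc <- -y[k] + y[k] * e[k] / D[k]
    for (i in seq_len(C)) {
      if (i == k) next
      acc <- acc + y[i] * (1 - y[k]) * (1 - r[i, k]) * e[k] / D[i]
    }
    g[k] <- acc
  }
  g
}

#' Estimate the pairwise label co-occurrence matrix
#'
#' `r_ij` is the fraction of training records in which tags `i` and `j` are
#' both positive.  The diagonal holds each tag's marginal frequency; it is
#' excluded from the concurrent soft-max by construction.
#'
#' @param labels 0/1 matrix or data frame, one row per record, one column
#'   per tag.
#' @return symmetric matrix of joint frequencies in `[0, 1]`.
#' @export
estimate_cooccurrence <- function(labels) {
  labels <- as.matrix(labels)
  if (nrow(labels) < 1L) stop("estimate_cooccurrence: empty label table")
  storage.mode(labels) <- "double"
  r <- crossprod(labels) / nrow(labels)
  dimnames(r) <- list(colnames(labels), colnames(labels))
  r
}

#' Confusion counts and the four evaluation metrics
#'
#' For 0/1 predictions against 0/1 truths: `PREC = TP/(TP+FP)`,
#' `REC = TP/(TP+FN)`, `ACC = (TP+TN)/total`,
#' `F1 = 2 * PREC * REC / (PREC + REC)`.  A zero denominator yields 0 for
#' that metric, flagged via the `undefined` field.
#'
#' @param predictions 0/1 vector of predicted labels.
#' @param truths 0/1 vector of reference labels, same length.
#' @return list with `tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `accuracy`, `f1`, `undefined` (character vector of metrics that had a
#'   zero denominator).
#' @export
confusion_and_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("confusion_and_metrics: prediction/truth length mismatch")
  p <- as.integer(predictions); y <- as.integer(truths)
  stopifnot(all(p %in% 0:1), all(y %in% 0:1))
  tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0); fn <- sum(p == 0 & y == 1)
  undef <- character(0)
  ratio <- function(num, den, nm) {
    if (den == 0) { undef <<- c(undef, nm); return(0) }
    num / den
  }
  prec <- ratio(tp, tp + fp, "precision")
  rec <- ratio(tp, tp + fn, "recall")
  acc <- ratio(tp + tn, tp + fp + tn + fn, "accuracy")
  f1 <- ratio(2 * prec * rec, prec + rec, "f1")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = prec, recall = rec, accuracy = acc, f1 = f1,
       undefined = undef)
}

#' F1 score from a precision/recall pair
#'
#' Harmonic mean, `2 * p * r / (p + r)`; 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]` (or percentages; the result is
#'   on the same scale).
#' @return F1 on the scale of the inputs.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}
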