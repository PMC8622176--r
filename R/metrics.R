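# Evaluation suite: accuracy, balanced accuracy, Matthews correlation,
# AUROC, average precision, F-beta, confusion matrices, with one-vs-rest
# weighted averaging for the multiclass ranking metrics. AUROC delegates to
# pROC (trapezoidal rule with midrank tie handling); the closed-form
# statistics are computed directly.

#' Confusion matrix
#'
#' @param y_true,y_pred Integer class codes (0-based) of equal length.
#' @param n_classes Number of classes.
#' @param normalize_rows If `TRUE`, each non-empty row is scaled to sum to
#'   1 (the per-true-class prediction proportions); empty rows are left as
#'   zeros.
#' @return `n_classes x n_classes` matrix, entry (i, j) = count (or row
#'   proportion) of true class i-1 predicted as class j-1.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes,
                             normalize_rows = FALSE) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true >= 0 & y_true < n_classes),
            all(y_pred >= 0 & y_pred < n_classes))
  M <- matrix(0, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    M[y_true[i] + 1L, y_pred[i] + 1L] <- M[y_true[i] + 1L, y_pred[i] + 1L] + 1
  }
  if (normalize_rows) {
    rs <- rowSums(M)
    nz <- rs > 0
    M[nz, ] <- M[nz, , drop = FALSE] / rs[nz]
  }
  M
}

#' Binary classification statistics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, balanced accuracy
#' `(TP/(TP+FN) + TN/(TN+FP))/2`, the Matthews correlation coefficient
#' `(TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when the
#' denominator vanishes), precision and recall.
#'
#' @param counts List or vector with non-negative `TP`, `TN`, `FP`, `FN`.
#' @return Named list `accuracy`, `bac`, `mcc`, `precision`, `recall`.
#' @examples
#' binary_metrics(list(TP = 8, TN = 5, FP = 2, FN = 1))
#' @export
binary_metrics <- function(counts) {
  cn <- as.list(counts)
  TP <- cn$TP; TN <- cn$TN; FP <- cn$FP; FN <- cn$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  n <- TP + TN + FP + FN
  if (n == 0) {
    stop(structure(
      class = c("meshgcn_undefined_metric", "error", "condition"),
      list(message = "binary_metrics: all counts are zero", call = NULL)))
  }
  acc <- (TP + TN) / n
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  bac <- mean(c(sens, spec), na.rm = TRUE)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  list(accuracy = acc, bac = bac, mcc = mcc, precision = prec, recall = sens)
}

#' Average precision over descending score thresholds
#'
#' `AP = sum_n (REC_n - REC_{n-1}) * PRE_n`, evaluated at every distinct
#' score threshold in descending order (tied scores enter together), so it
#' is invariant to strictly monotone transformations of the scores.
#'
#' @param scores Numeric prediction scores, larger meaning more positive.
#' @param y_binary 0/1 labels; at least one positive required.
#' @return Scalar average precision.
#' @export
average_precision <- function(scores, y_binary) {
  y <- as.numeric(y_binary)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  P <- sum(y)
  if (P == 0) {
    stop(structure(
      class = c("meshgcn_undefined_metric", "error", "condition"),
      list(message = "average_precision: no positive samples", call = NULL)))
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  cum_tp <- cumsum(y)
  n_pred <- seq_along(y)
  # thresholds at the last index of each tied-score block
  last_of_block <- which(c(s[-1] != s[-length(s)], TRUE))
  rec <- cum_tp[last_of_block] / P
  pre <- cum_tp[last_of_block] / n_pred[last_of_block]
  sum((rec - c(0, rec[-length(rec)])) * pre)
}

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; beta > 1 weights recall more.
#' Defined as 0 when precision and recall are both 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @param beta Weighting coefficient (default 2).
#' @return Scalar.
#' @export
fbeta <- function(precision, recall, beta = 2) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' AUROC for a binary task
#'
#' Area under the ROC curve via the trapezoidal rule with midrank handling
#' of tied scores.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param y_binary 0/1 labels with both classes present.
#' @return Scalar AUROC.
#' @export
auroc <- function(scores, y_binary) {
  y <- as.numeric(y_binary)
  stopifnot(length(unique(y)) == 2)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Multiclass metric suite
#'
#' Accuracy, balanced accuracy (unweighted mean of per-class recall),
#' generalized multiclass Matthews correlation (covariance form, reducing
#' to the binary formula for two classes), and one-vs-rest AUROC and
#' average precision averaged with class-support weights. Classes absent
#' from `y_true` are excluded from the averaged ranking metrics (with a
#' message).
#'
#' @param y_true,y_pred Integer class codes (0-based).
#' @param scores Matrix (n x C) of class scores or probabilities (rows need
#'   not be normalized for the ranking metrics).
#' @return Named list `accuracy`, `bac`, `mcc`, `auroc`, `ap`.
#' @export
multiclass_metrics <- function(y_true, y_pred, scores) {
  n <- length(y_true)
  C <- ncol(scores)
  stopifnot(length(y_pred) == n, nrow(scores) == n)
  acc <- mean(y_true == y_pred)
  present <- sort(unique(y_true))
  recalls <- vapply(present, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  bac <- mean(recalls)
  # covariance-form multiclass MCC
  conf <- confusion_matrix(y_true, y_pred, C)
  s <- n
  c_ <- sum(diag(conf))
  t_k <- rowSums(conf)
  p_k <- colSums(conf)
  num <- c_ * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den
  absent <- setdiff(seq_len(C) - 1L, present)
  if (length(absent) > 0) {
    message("multiclass_metrics: class(es) absent from y_true excluded ",
            "from AUROC/AP averaging: ", paste(absent, collapse = ", "))
  }
  support <- vapply(present, function(cl) sum(y_true == cl), numeric(1))
  auc_c <- vapply(present, function(cl) {
    yb <- as.numeric(y_true == cl)
    if (length(unique(yb)) < 2) return(NA_real_)
    auroc(scores[, cl + 1L], yb)
  }, numeric(1))
  ap_c <- vapply(present, function(cl) {
    average_precision(scores[, cl + 1L], as.numeric(y_true == cl))
  }, numeric(1))
  ok <- !is.na(auc_c)
  list(accuracy = acc, bac = bac, mcc = mcc,
       auroc = sum(auc_c[ok] * support[ok]) / sum(support[ok]),
       ap = sum(ap_c * support) / sum(support))
}

#' Multi-label metric suite
#'
#' Accuracy is label-wise binary accuracy at the 0.5 threshold averaged
#' over classes (subset exact-match accuracy is reported alongside for
#' transparency). F-beta (beta = 2 by default), AUROC and average
#' precision are computed one-vs-rest per class and averaged weighted by
#' class support; `fbeta_average` switches to micro or per-sample
#' averaging.
#'
#' @param y_true 0/1 matrix (n x C) of true label sets.
#' @param y_pred 0/1 matrix of thresholded predictions.
#' @param prob Matrix of predicted class probabilities (for AUROC/AP).
#' @param beta F-beta coefficient.
#' @param fbeta_average `"weighted"`, `"micro"` or `"samples"`.
#' @return Named list `accuracy`, `subset_accuracy`, `fbeta`, `auroc`,
#'   `ap`.
#' @export
multilabel_metrics <- function(y_true, y_pred, prob, beta = 2,
                               fbeta_average = c("weighted", "micro",
                                                 "samples")) {
  fbeta_average <- match.arg(fbeta_average)
  Y <- as.matrix(y_true); P <- as.matrix(y_pred)
  stopifnot(all(dim(Y) == dim(P)))
  C <- ncol(Y)
  acc <- mean(colMeans(Y == P))
  subset_acc <- mean(apply(Y == P, 1, all))
  prf <- function(tp, fp, fn) {
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    fbeta(pr, rc, beta)
  }
  fb <- switch(fbeta_average,
    weighted = {
      support <- colSums(Y)
      fb_c <- vapply(seq_len(C), function(j) {
        prf(sum(Y[, j] == 1 & P[, j] == 1),
            sum(Y[, j] == 0 & P[, j] == 1),
            sum(Y[, j] == 1 & P[, j] == 0))
      }, numeric(1))
      if (sum(support) == 0) 0 else sum(fb_c * support) / sum(support)
    },
    micro = prf(sum(Y == 1 & P == 1), sum(Y == 0 & P == 1),
                sum(Y == 1 & P == 0)),
    samples = mean(vapply(seq_len(nrow(Y)), function(i) {
      prf(sum(Y[i, ] == 1 & P[i, ] == 1),
          sum(Y[i, ] == 0 & P[i, ] == 1),
          sum(Y[i, ] == 1 & P[i, ] == 0))
    }, numeric(1)))
  )
  support <- colSums(Y)
  usable <- which(support > 0 & support < nrow(Y))
  auc_c <- vapply(usable, function(j) auroc(prob[, j], Y[, j]), numeric(1))
  ap_usable <- which(support > 0)
  ap_c <- vapply(ap_usable, function(j) average_precision(prob[, j], Y[, j]),
                 numeric(1))
  list(accuracy = acc, subset_accuracy = subset_acc, fbeta = fb,
       auroc = sum(auc_c * support[usable]) / sum(support[usable]),
       ap = sum(ap_c * support[ap_usable]) / sum(support[ap_usable]))
}

#' Write a metrics summary as TSV
#'
#' @param report A `metrics_report` from [gcn_cross_validate()].
#' @param path Output TSV path (`metric`, `mean`, `std`).
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(report, path) {
  write_tsv(report$summary, path)
}
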