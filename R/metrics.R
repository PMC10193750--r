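# Binary-classification evaluation: confusion counts, the SN/SP/PRE/ACC/
# F-score/MCC bundle, and trapezoidal ROC AUC. "coding" is the positive
# class throughout.

#' Confusion counts for coding/noncoding predictions
#'
#' @param truth,predicted Character vectors over `{"coding", "noncoding"}`.
#' @return A one-row tibble with columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  check_labels(truth)
  check_labels(predicted)
  tibble(TP = sum(truth == "coding" & predicted == "coding"),
         FP = sum(truth == "noncoding" & predicted == "coding"),
         TN = sum(truth == "noncoding" & predicted == "noncoding"),
         FN = sum(truth == "coding" & predicted == "noncoding"))
}

check_labels <- function(x) {
  bad <- setdiff(unique(x), c("coding", "noncoding"))
  if (length(bad) > 0L) {
    abort(sprintf("Labels must be 'coding' or 'noncoding'; found: %s",
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s is 0/0; returning 0.", what),
         class = "orfvec_degenerate_input")
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, precision
#' `TP/(TP+FP)`, accuracy, F-score `2*PRE*SN/(PRE+SN)`, and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`. Ratios with a
#' zero denominator return 0 with a warning.
#'
#' @param counts A one-row data frame with columns `TP`, `FP`, `TN`, `FN`
#'   (as from [confusion_counts()]).
#' @return A one-row tibble with `SN`, `SP`, `PRE`, `ACC`, `F_score`, `MCC`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- as.numeric(counts$TP)
  fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN)
  fn <- as.numeric(counts$FN)
  sn <- safe_ratio(tp, tp + fn, "SN")
  sp <- safe_ratio(tn, fp + tn, "SP")
  pre <- safe_ratio(tp, tp + fp, "PRE")
  acc <- safe_ratio(tp + tn, tp + tn + fp + fn, "ACC")
  f <- safe_ratio(2 * pre * sn, pre + sn, "F_score")
  denom <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) {
    warn("MCC denominator is 0; returning 0.",
         class = "orfvec_degenerate_input")
    0
  } else {
    (tp * tn - fp * fn) / denom
  }
  tibble(SN = sn, SP = sp, PRE = pre, ACC = acc, F_score = f, MCC = mcc)
}

#' ROC points over the coding-probability score
#'
#' Scores are sorted in decreasing order; tied scores collapse into a
#' single ROC point (so the trapezoid over a tie group credits half).
#'
#' @param truth Character vector over `{"coding", "noncoding"}`.
#' @param scores Numeric scores (higher = more coding-like).
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, starting at
#'   `(0, 0)` and ending at `(1, 1)`.
#' @export
roc_points <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), length(truth) > 0L)
  check_labels(truth)
  npos <- sum(truth == "coding")
  nneg <- sum(truth == "noncoding")
  if (npos == 0L || nneg == 0L) {
    abort("ROC needs at least one sample of each class.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- truth[ord] == "coding"
  grp_last <- which(!duplicated(s, fromLast = TRUE)) # last index of each tie group
  tp <- cumsum(pos)[grp_last]
  fp <- cumsum(!pos)[grp_last]
  out <- tibble(threshold = c(Inf, s[grp_last]),
                fpr = c(0, fp / nneg),
                tpr = c(0, tp / npos))
  class(out) <- c("orfvec_roc", class(out))
  out
}

#' Area under the ROC curve by trapezoidal integration
#'
#' @inheritParams roc_points
#' @return The AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(truth, scores) {
  r <- roc_points(truth, scores)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1L) + utils::tail(r$tpr, -1L)) / 2)
}

#' Full evaluation of scored predictions
#'
#' Thresholds the coding probability at `threshold`, computes the confusion
#' counts, the metric bundle and the trapezoidal AUC.
#'
#' @param truth Character vector over `{"coding", "noncoding"}`.
#' @param coding_prob Numeric coding probabilities (or scores).
#' @param threshold Decision threshold (default 0.5): predicted coding iff
#'   `coding_prob >= threshold`.
#' @return A one-row tibble: `TP`, `FP`, `TN`, `FN`, `SN`, `SP`, `PRE`,
#'   `ACC`, `F_score`, `MCC`, `AUC`.
#' @export
classification_metrics <- function(truth, coding_prob, threshold = 0.5) {
  stopifnot(length(truth) == length(coding_prob), length(truth) > 0L)
  predicted <- ifelse(coding_prob >= threshold, "coding", "noncoding")
  counts <- confusion_counts(truth, predicted)
  dplyr::bind_cols(counts, metrics_from_counts(counts),
                   tibble(AUC = auc_trapezoid(truth, coding_prob)))
}
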