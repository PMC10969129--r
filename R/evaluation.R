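#' Confusion counts for binary predictions
#'
#' Class 1 (the screening-positive class, "ASD" in the default naming)
#' is the positive class: `Tp` counts true 1s predicted 1.
#'
#' @param truth,predicted Equal-length integer vectors over `{0, 1}`.
#' @return An object of class `confusion_counts` with fields `Tp`, `Tn`,
#'   `Fp`, `Fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_param("predicted", "length mismatch with truth")
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (anyNA(truth) || anyNA(predicted) ||
      !all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stop_param("labels", "labels must be 0 or 1")
  structure(list(Tp = sum(truth == 1L & predicted == 1L),
                 Tn = sum(truth == 0L & predicted == 0L),
                 Fp = sum(truth == 0L & predicted == 1L),
                 Fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

# Trapezoidal ROC AUC with threshold set = unique scores. Equivalent to
# the Mann-Whitney statistic with ties counted 1/2.
auc_trapezoid <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- truth[ord]
  # cumulative counts at each distinct threshold
  brk <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y == 1L)[brk]; fp <- cumsum(y == 0L)[brk]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Compute the evaluation metrics from confusion counts
#'
#' Accuracy `(Tp+Tn)/(Tp+Tn+Fp+Fn)`, precision `Tp/(Tp+Fp)`, recall
#' `Tp/(Tp+Fn)`, F1 `2PR/(P+R)`, and (when scores are given) the
#' trapezoidal ROC AUC. A zero denominator yields the value 0 with the
#' affected metric named in the `degenerate` field, so sweeps never
#' crash but degenerate rows remain identifiable. Macro-averaged
#' precision/recall/F1 (mean of the two per-class values) are also
#' reported for comparison with the positive-class values.
#'
#' @param counts A [confusion_counts()].
#' @param scores Optional class-1 scores (needed for AUC).
#' @param truth Optional true labels matching `scores`.
#' @param weights_tag,test_set_tag Bookkeeping tags carried into the
#'   record (e.g. `"w1"` and `"T1+T2"`).
#' @return An object of class `metrics_record`.
#' @export
compute_metrics <- function(counts, scores = NULL, truth = NULL,
                            weights_tag = "", test_set_tag = "") {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$Tp + counts$Tn + counts$Fp + counts$Fn
  if (n == 0L) stop_param("counts", "no evaluated samples")
  degenerate <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); 0 } else num / den
  }
  accuracy <- (counts$Tp + counts$Tn) / n
  precision <- safe_div(counts$Tp, counts$Tp + counts$Fp, "precision")
  recall <- safe_div(counts$Tp, counts$Tp + counts$Fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  # macro averages: same formulas with class 0 as positive, then mean
  prec0 <- safe_div(counts$Tn, counts$Tn + counts$Fn, "precision_class0")
  rec0 <- safe_div(counts$Tn, counts$Tn + counts$Fp, "recall_class0")
  f10 <- safe_div(2 * prec0 * rec0, prec0 + rec0, "f1_class0")
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth) || length(truth) != length(scores))
      stop_param("truth", "scores require matching true labels")
    auc <- auc_trapezoid(as.numeric(scores), as.integer(truth))
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, auc = auc,
                 macro_precision = (precision + prec0) / 2,
                 macro_recall = (recall + rec0) / 2,
                 macro_f1 = (f1 + f10) / 2,
                 n_samples = n, counts = counts,
                 degenerate = degenerate,
                 weights_tag = weights_tag, test_set_tag = test_set_tag),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record %s x %s> n=%d acc=%.3f prec=%.3f rec=%.3f f1=%.3f auc=%s%s\n",
              x$weights_tag, x$test_set_tag, x$n_samples, x$accuracy,
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              if (length(x$degenerate))
                paste0(" [degenerate: ", paste(x$degenerate, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Evaluate a classifier on a labeled test set
#'
#' Predicts with [predict_proba()] (decision threshold 0.5) and returns
#' the full [compute_metrics()] record including AUC.
#'
#' @param classifier An `al_classifier`.
#' @param samples List of labeled `image_sample`s.
#' @param weights_tag,test_set_tag Tags recorded on the result.
#' @return A `metrics_record`.
#' @export
evaluate_classifier <- function(classifier, samples,
                                weights_tag = classifier$weights_tag,
                                test_set_tag = "") {
  truth <- sample_labels(samples)
  if (anyNA(truth)) stop_param("samples", "test samples must be labeled")
  p1 <- predict_proba(classifier, samples)
  pred <- as.integer(p1 > 0.5)
  compute_metrics(confusion_counts(truth, pred), scores = p1, truth = truth,
                  weights_tag = weights_tag, test_set_tag = test_set_tag)
}

#' Pool two test sets into a combined test set
#'
#' Plain concatenation preserving each sample's `domain_id` — no
#' re-sampling or re-weighting, so combined metrics are pooled-count
#' metrics over all samples from both domains.
#'
#' @param test_A,test_B Lists of labeled `image_sample`s.
#' @return Concatenated list with attribute `test_set_tag = "T1+T2"`.
#' @export
build_combined_test <- function(test_A, test_B) {
  for (s in c(test_A, test_B))
    if (is.null(s$label) || is.na(s$label))
      stop("configuration error: combined test sets must be fully labeled",
           call. = FALSE)
  out <- c(test_A, test_B)
  attr(out, "test_set_tag") <- "T1+T2"
  out
}

#' Evaluation matrix over weight snapshots and test sets
#'
#' One metrics row per (weight snapshot, test set) pair, mirroring the
#' protocol's matrix: rows such as (`w1`, `T1`), (`w1`, `T1+T2`),
#' (`w2`, `T2`), (`w12`, `T2`), (`w12`, `T1+T2`).
#'
#' @param classifiers Named list of `al_classifier`s (names are the
#'   weight tags).
#' @param test_sets Named list of labeled sample lists (names are the
#'   test-set tags).
#' @return A tidy data frame with one row per pair.
#' @export
evaluate_matrix <- function(classifiers, test_sets) {
  stopifnot(length(names(classifiers)) == length(classifiers),
            length(names(test_sets)) == length(test_sets))
  rows <- list()
  for (wt in names(classifiers)) {
    for (tt in names(test_sets)) {
      r <- evaluate_classifier(classifiers[[wt]], test_sets[[tt]],
                               weights_tag = wt, test_set_tag = tt)
      rows[[length(rows) + 1L]] <- data.frame(
        weights_tag = wt, test_set_tag = tt, n_samples = r$n_samples,
        accuracy = r$accuracy, precision = r$precision, recall = r$recall,
        f1 = r$f1, auc = r$auc, macro_f1 = r$macro_f1)
    }
  }
  do.call(rbind, rows)
}
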