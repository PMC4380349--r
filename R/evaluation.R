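#' Fourfold confusion matrix
#'
#' Counts true/false positives and negatives of a binary classifier against
#' the actual labels.
#'
#' @param predicted,actual equal-length vectors of binary labels.
#' @param positive the label treated as the positive class (for survival
#'   prognosis, the long-survival state).
#' @return A `confusion_matrix`: list with integer `tp`, `fp`, `fn`, `tn`
#'   and the `positive` label.
#' @export
#' @examples
#' cm <- confusion_matrix(
#'   predicted = rep(c(">10m", "<=10m"), c(197, 102)),
#'   actual = rep(c(">10m", "<=10m", ">10m", "<=10m"), c(124, 73, 25, 77)),
#'   positive = ">10m")
#' accuracy(cm)  # 0.672
confusion_matrix <- function(predicted, actual, positive) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length", call. = FALSE)
  labs <- unique(c(predicted, actual))
  if (length(labs) > 2L)
    stop("labels outside a binary domain: ", paste(labs, collapse = ", "),
         call. = FALSE)
  if (!(positive %in% labs))
    stop("positive label '", positive, "' not among the labels",
         call. = FALSE)
  pp <- predicted == positive
  ap <- actual == positive
  structure(list(tp = sum(pp & ap), fp = sum(pp & !ap),
                 fn = sum(!pp & ap), tn = sum(!pp & !ap),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = '%s'\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  print(m)
  cat(sprintf("accuracy %.4f\n", accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)`: the proportion of correct predictions.
#' Note that accuracy alone is misleading under class imbalance -- a
#' classifier calling everything negative on a 1:99 mix is 99% accurate --
#' which is why [rates()] and [roc_curve()] accompany it.
#'
#' @param cm a `confusion_matrix`.
#' @return Proportion in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0L) stop("empty confusion matrix", call. = FALSE)
  (cm$tp + cm$tn) / n
}

#' True-positive rate, false-positive rate, and row reliability
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (TN + FP)`; reliability is the
#' per-predicted-row proportion of correct calls (the positive row's
#' reliability is the positive predictive value).
#'
#' @param cm a `confusion_matrix`.
#' @return List with `tpr`, `fpr`, and `reliability` (named vector for the
#'   predicted-positive and predicted-negative rows).
#' @export
rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0L)
    stop("undefined rate: TPR has zero denominator (no actual positives)",
         call. = FALSE)
  if (cm$tn + cm$fp == 0L)
    stop("undefined rate: FPR has zero denominator (no actual negatives)",
         call. = FALSE)
  rel <- c(positive = if (cm$tp + cm$fp > 0L) cm$tp / (cm$tp + cm$fp)
                      else NA_real_,
           negative = if (cm$tn + cm$fn > 0L) cm$tn / (cm$tn + cm$fn)
                      else NA_real_)
  list(tpr = cm$tp / (cm$tp + cm$fn),
       fpr = cm$fp / (cm$tn + cm$fp),
       reliability = rel)
}

.binary_truth <- function(actual, positive) {
  labs <- unique(actual)
  if (length(labs) < 2L)
    stop("AUC undefined: only one class present in the truth labels",
         call. = FALSE)
  if (length(labs) > 2L)
    stop("labels outside a binary domain", call. = FALSE)
  actual == positive
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over every distinct predicted probability
#' (plus sentinels beyond both ends), classifying positive on the strict
#' rule `probability > threshold` -- the same rule [classify()] uses -- and
#' records the (FPR, TPR) pair at each threshold. The area under the curve
#' is the trapezoid-rule integral, which for this construction equals the
#' concordance probability with ties counted one half.
#'
#' @param probabilities predicted positive-class probabilities in `[0, 1]`.
#' @param actual true labels (binary).
#' @param positive the positive-class label.
#' @return A `roc_curve`: data frame `points` with columns `threshold`,
#'   `fpr`, `tpr` (from (0,0) to (1,1)), and scalar `auc`.
#' @export
roc_curve <- function(probabilities, actual, positive) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  if (length(probabilities) != length(actual))
    stop("probabilities and actual must have equal length", call. = FALSE)
  truth <- .binary_truth(actual, positive)
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  np <- sum(truth); nn <- sum(!truth)
  pts <- t(vapply(thr, function(t) {
    pos <- probabilities > t
    c(fpr = sum(pos & !truth) / nn, tpr = sum(pos & truth) / np)
  }, numeric(2)))
  points <- data.frame(threshold = thr, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1L) +
                                   utils::tail(points$tpr, -1L)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Accuracy-maximizing decision threshold
#'
#' Scans the candidate grid formed by 0 and every distinct predicted
#' probability, scores the accuracy of the strict rule
#' `probability > threshold` at each, and returns the smallest candidate
#' achieving the maximum accuracy.
#'
#' @inheritParams roc_curve
#' @return List with `threshold`, its in-sample `accuracy`, and the scanned
#'   `grid` (data frame of candidate thresholds and accuracies).
#' @export
select_threshold <- function(probabilities, actual, positive) {
  truth <- .binary_truth(actual, positive)
  if (length(unique(probabilities)) == 1L)
    warning("all predicted probabilities identical; threshold is degenerate",
            call. = FALSE)
  cand <- sort(unique(c(0, probabilities)))
  acc <- vapply(cand, function(t) {
    pos <- probabilities > t
    mean(pos == truth)
  }, numeric(1))
  best <- which.max(acc)  # which.max returns the first (smallest) maximizer
  list(threshold = cand[best], accuracy = acc[best],
       grid = data.frame(threshold = cand, accuracy = acc))
}

#' In-sample evaluation of a fitted model
#'
#' Predicts every record of a cohort with the model, then assembles the
#' confusion matrix, accuracy, rates and ROC curve at a fixed or
#' accuracy-maximizing threshold. In-sample (train = test) evaluation is the
#' default usage; pass a held-out cohort for out-of-sample figures.
#'
#' @param model a fitted `tan_model` with a binary class.
#' @param table a `tan_cohort` containing the true class column.
#' @param threshold a fixed threshold in `[0, 1]`, or `NULL` (default) to
#'   pick the accuracy-maximizing one via [select_threshold()].
#' @return List with `threshold`, `confusion` (a `confusion_matrix`),
#'   `accuracy`, `rates`, `roc` (a `roc_curve`) and the per-record
#'   `predictions` data frame.
#' @export
evaluate_model <- function(model, table, threshold = NULL) {
  cls <- model$structure$class_var
  cls_states <- names(model$prior)
  positive <- cls_states[2L]
  probs <- predict(model, table)$probability
  actual <- cls_states[table[[cls]] + 1L]
  if (is.null(threshold))
    threshold <- select_threshold(probs, actual, positive)$threshold
  predicted <- ifelse(probs > threshold, cls_states[2L], cls_states[1L])
  cm <- confusion_matrix(predicted, actual, positive)
  list(threshold = threshold,
       confusion = cm,
       accuracy = accuracy(cm),
       rates = rates(cm),
       roc = roc_curve(probs, actual, positive),
       predictions = data.frame(probability = probs, label = predicted,
                                actual = actual, stringsAsFactors = FALSE))
}
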