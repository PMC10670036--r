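#' Threshold probabilities into class labels
#'
#' Label 1 (ASD) iff the probability is greater than or equal to the
#' threshold.
#'
#' @param probabilities Numeric vector in [0, 1].
#' @param threshold Decision cutoff, default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probabilities, threshold = 0.5) {
    p <- as.numeric(probabilities)
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop_ns("probabilities must lie in [0, 1]",
                "neuroslice_validation_error")
    as.integer(p >= threshold)
}

check_labels <- function(pred, truth) {
    if (length(pred) != length(truth))
        stop_ns("label vectors must have equal length",
                "neuroslice_validation_error")
    if (length(pred) == 0L)
        stop_ns("label vectors must be nonempty",
                "neuroslice_validation_error")
}

#' Classification accuracy
#'
#' The ratio C/N of correctly classified samples C to total samples N.
#'
#' @param pred_labels,true_labels Equal-length 0/1 vectors.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(pred_labels, true_labels) {
    check_labels(pred_labels, true_labels)
    sum(pred_labels == true_labels) / length(true_labels)
}

#' Precision, recall and F1 score
#'
#' F1 is the harmonic mean `2 * precision * recall / (precision + recall)`
#' for the positive class (ASD = 1 by convention); it is defined as 0 when
#' precision + recall is 0 (degenerate predictors).
#'
#' @param pred_labels,true_labels Equal-length 0/1 vectors.
#' @param positive Positive class value (default 1).
#' @return `f1_score` returns the F1 value; `precision_recall` the named
#'   vector `c(precision, recall)` (0 on empty denominators).
#' @export
f1_score <- function(pred_labels, true_labels, positive = 1L) {
    pr <- precision_recall(pred_labels, true_labels, positive)
    if (pr[["precision"]] + pr[["recall"]] == 0) return(0)
    2 * pr[["precision"]] * pr[["recall"]] /
        (pr[["precision"]] + pr[["recall"]])
}

#' @rdname f1_score
#' @export
precision_recall <- function(pred_labels, true_labels, positive = 1L) {
    check_labels(pred_labels, true_labels)
    tp <- sum(pred_labels == positive & true_labels == positive)
    fp <- sum(pred_labels == positive & true_labels != positive)
    fn <- sum(pred_labels != positive & true_labels == positive)
    c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Binary cross-entropy
#'
#' Mean over samples of `-[p log q + (1-p) log(1-q)]` in natural log, with
#' the predicted probability q clipped to `[eps, 1-eps]` so that degenerate
#' 0/1 predictions stay finite.
#'
#' @param probabilities Predicted probabilities q in [0, 1].
#' @param true_labels 0/1 labels (the true distribution p).
#' @param eps Clipping constant, default 1e-7.
#' @return Non-negative mean cross-entropy.
#' @export
cross_entropy <- function(probabilities, true_labels, eps = 1e-7) {
    p <- as.numeric(probabilities)
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop_ns("probabilities must lie in [0, 1]",
                "neuroslice_validation_error")
    check_labels(p, true_labels)
    q <- pmin(pmax(p, eps), 1 - eps)
    y <- as.numeric(true_labels)
    -mean(y * log(q) + (1 - y) * log(1 - q))
}

#' Build an evaluation report
#'
#' Thresholds the probabilities and assembles all test-set metrics into one
#' object: sample count N, correct count C, accuracy C/N, precision,
#' recall, F1 and mean cross-entropy.
#'
#' @param probabilities Predicted ASD probabilities.
#' @param true_labels 0/1 labels.
#' @param threshold Decision cutoff.
#' @return An `eval_report` list.
#' @export
eval_report <- function(probabilities, true_labels, threshold = 0.5) {
    pred <- classify(probabilities, threshold)
    pr <- precision_recall(pred, true_labels)
    structure(list(
        n = length(true_labels),
        n_correct = sum(pred == true_labels),
        accuracy = accuracy(pred, true_labels),
        precision = unname(pr["precision"]),
        recall = unname(pr["recall"]),
        f1 = f1_score(pred, true_labels),
        cross_entropy = cross_entropy(probabilities, true_labels),
        threshold = threshold), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
    cat(sprintf(
        "<eval_report> n=%d correct=%d accuracy=%.4f F1=%.4f loss=%.4f\n",
        x$n, x$n_correct, x$accuracy, x$f1, x$cross_entropy))
    invisible(x)
}
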