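# Cosine-similarity template matching and fall/not-fall evaluation.
#
# A recalled 25-neuron state is compared against the stored class templates
# by cosine similarity; for bipolar vectors of length N this reduces to
# (N - 2 * hamming) / N. The binary decision (fall vs not) thresholds the
# similarity to the fall template; accuracy follows the standard
# (TP + TN) / (TP + FP + TN + FN) formula.

#' Cosine similarity of two vectors
#'
#' `dot(a, b) / (|a| |b|)`. For bipolar vectors of equal length N this
#' equals `(N - 2 * hamming(a, b)) / N`.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Classify a recalled state against class templates
#'
#' Computes the cosine similarity of the recalled state to every template.
#' The binary fall decision is positive iff the similarity to the
#' `positive_label` template is at least `threshold`. When several class
#' templates are supplied the predicted label is the argmax similarity (ties
#' broken by lexicographic label order); with only the fall template the
#' predicted label is `positive_label` or `"negative"` according to the
#' decision.
#'
#' @param recalled bipolar vector (or [template()]).
#' @param templates a single [template()] or a list of them; labels are taken
#'   from the templates or the list names.
#' @param positive_label label of the fall template.
#' @param threshold decision threshold on the similarity, in (-1, 1].
#' @return a `fall_classification`: list with `similarities` (named),
#'   `predicted`, `positive` (logical), `confidence` (similarity of the best
#'   template), `threshold`.
#' @export
classify_sample <- function(recalled, templates, positive_label = "Fall",
                            threshold = 0.8) {
  stopifnot(threshold > -1, threshold <= 1)
  if (inherits(recalled, "pattern_template")) recalled <- recalled$vector
  assert_bipolar(recalled, "recalled state")
  if (inherits(templates, "pattern_template")) templates <- list(templates)
  if (!length(templates)) stop("at least one template is required")
  labels <- names(templates)
  tlabels <- vapply(templates, function(tp) {
    if (inherits(tp, "pattern_template") && !is.null(tp$label)) tp$label else NA_character_
  }, "")
  if (is.null(labels)) labels <- tlabels
  labels[is.na(labels) | labels == ""] <- tlabels[is.na(labels) | labels == ""]
  if (anyNA(labels) || any(labels == "")) stop("every template must carry a label")
  if (!positive_label %in% labels) {
    stop("no template labeled '", positive_label, "' (the positive class) was supplied")
  }
  sims <- vapply(templates, function(tp) {
    v <- if (inherits(tp, "pattern_template")) tp$vector else as.numeric(tp)
    cosine_similarity(recalled, v)
  }, numeric(1))
  names(sims) <- labels
  positive <- sims[[positive_label]] >= threshold
  ord <- order(-sims, labels)                  # argmax, ties lexicographic
  predicted <- if (length(sims) > 1L) labels[ord[1L]] else {
    if (positive) positive_label else "negative"
  }
  structure(list(similarities = sims, predicted = predicted,
                 positive = positive, confidence = sims[ord[1L]],
                 threshold = threshold),
            class = "fall_classification")
}

#' @export
print.fall_classification <- function(x, ...) {
  cat(sprintf("<fall_classification> %s (fall decision: %s at threshold %g)\n",
              x$predicted, if (x$positive) "POSITIVE" else "negative",
              x$threshold))
  print(round(x$similarities, 3))
  invisible(x)
}

#' Confusion counts and accuracy of fall decisions
#'
#' Tallies decisions against ground truth: a positive decision on a true
#' fall is a TP, on a non-fall an FP, and so on; accuracy is
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param truth ground-truth labels (character; compared to
#'   `positive_label`) or a logical vector of "is a fall".
#' @param decision logical vector of positive (fall) decisions, or a list of
#'   `fall_classification` objects.
#' @param positive_label the positive class label.
#' @return an `evaluation_report`: list with `TP`, `FP`, `TN`, `FN`,
#'   `accuracy`, `n`.
#' @export
evaluate_decisions <- function(truth, decision, positive_label = "Fall") {
  if (is.list(decision)) {
    decision <- vapply(decision, function(d) isTRUE(d$positive), logical(1))
  }
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == positive_label
  }
  stopifnot(is.logical(truth), is.logical(decision))
  if (!length(truth)) stop("at least one decision is required")
  if (length(truth) != length(decision)) {
    stop("`truth` and `decision` lengths differ")
  }
  TP <- sum(truth & decision); FN <- sum(truth & !decision)
  FP <- sum(!truth & decision); TN <- sum(!truth & !decision)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 accuracy = (TP + TN) / (TP + FP + TN + FN),
                 n = length(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d\n", x$n))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy = %.4f\n", x$accuracy))
  invisible(x)
}
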