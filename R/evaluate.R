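#' Confusion matrix
#'
#' Tallies predictions into a K-by-K integer matrix with true classes in
#' rows and predicted classes in columns.
#'
#' @param true_labels,predicted_labels character vectors of equal length;
#'   every label must appear in `class_list`.
#' @param class_list ordered class vocabulary.
#' @return integer matrix of class `confusion_matrix` with dimnames
#'   `(true, predicted)`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_list) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors differ in length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_list)
  if (length(bad)) stop("label(s) not in class list: ", paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = class_list)
  pf <- factor(predicted_labels, levels = class_list)
  cm <- unclass(table(true = tf, predicted = pf))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class precision, recall, F1 and support
#'
#' For class `c` with `TP = cm[c,c]`, `FP` the off-diagonal column sum and
#' `FN` the off-diagonal row sum: `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Zero-division convention: a
#' class never predicted gets precision 0, a class never true gets recall 0,
#' and F1 is 0 when precision and recall are both 0 (a warning notes the
#' convention when it fires).
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
per_class_metrics <- function(cm) {
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  degenerate <- (tp + fp == 0) | (tp + fn == 0)
  if (any(degenerate))
    warning("zero-division convention applied for class(es): ",
            paste(rownames(cm)[degenerate], collapse = ", "))
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  data.frame(class = rownames(cm), precision = precision, recall = recall,
             f1 = f1, support = as.integer(tp + fn), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Support-weighted precision, recall, F1 and accuracy
#'
#' Each weighted metric is the per-class metric averaged with weights equal
#' to the class's true-sample count (its support); classes with support 0
#' contribute nothing. Weighted recall is algebraically identical to
#' accuracy (`sum_c (n_c/N)(TP_c/n_c) = trace/N`) — the identity visible in
#' published per-cohort tables where the recall and accuracy columns agree.
#' This support-weighting is also what makes a weighted precision of 100%
#' coexist with a recall of 75.8%: classes that are never true carry no
#' weight, however often they are (mis)predicted.
#'
#' @param cm a [confusion_matrix()] with at least one counted sample.
#' @return list with `precision`, `recall`, `f1`, `accuracy` (all in
#'   `[0, 1]`), plus `per_class` (the [per_class_metrics()] table).
#' @export
weighted_metrics <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  pc <- suppressWarnings(per_class_metrics(cm))
  w <- pc$support / n
  list(precision = sum(w * pc$precision),
       recall = sum(w * pc$recall),
       f1 = sum(w * pc$f1),
       accuracy = sum(diag(cm)) / n,
       per_class = pc)
}

#' F1 from precision and recall
#'
#' The harmonic combination `2PR/(P+R)`, symmetric in its arguments and
#' defined as 0 when both are 0. Reproduces a published F1 column from the
#' corresponding printed precision and recall columns.
#'
#' @param precision,recall values in `[0, 1]` (vectorised).
#' @return F1 score(s) in `[0, 1]`.
#' @export
f1_from_pr <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Full classification report
#'
#' @param true_labels,predicted_labels label vectors.
#' @param class_list optional class vocabulary; defaults to the union of
#'   classes with nonzero support and classes actually predicted, sorted.
#' @return list of class `classification_report`: the weighted block, the
#'   per-class table and the confusion matrix.
#' @export
classification_report <- function(true_labels, predicted_labels,
                                  class_list = NULL) {
  if (is.null(class_list))
    class_list <- sort(unique(c(true_labels, predicted_labels)))
  cm <- confusion_matrix(true_labels, predicted_labels, class_list)
  out <- weighted_metrics(cm)
  out$confusion <- cm
  class(out) <- "classification_report"
  out
}

#' @exportS3Method base::print
print.classification_report <- function(x, ...) {
  # display rounding mirrors the field's tables: percentages to 1 dp, F1 to 3
  cat(sprintf("precision %.1f%%  recall %.1f%%  F1 %.3f  accuracy %.1f%%  (n=%d)\n",
              100 * x$precision, 100 * x$recall, x$f1, 100 * x$accuracy,
              sum(x$confusion)))
  invisible(x)
}

#' Evaluate a trained model on the other species
#'
#' The cross-species harness: project the target-species matrix onto the
#' model's feature space, predict, remap the target labels into the model's
#' class vocabulary, and score. `label_map` is a named character vector
#' applied to the true labels (e.g. `c(HGG = "GBM")` when the model knows
#' GBM but the target cohort is graded HGG/LGG); entries are also applied to
#' predicted labels, which enables grade-collapsed scoring — mapping e.g.
#' both `GBM` and `LGG` to `"glioma"` on both sides counts any glioma
#' prediction for any glioma sample as correct, the "regardless of grade"
#' reading.
#'
#' @param model a [train_model()] result.
#' @param target an [expr_matrix()] in `log10_tpm` (projected on the fly if
#'   it still carries all source genes).
#' @param target_labels named character vector of true labels for the
#'   columns of `target`.
#' @param feature_space the [build_feature_space()] result shared with
#'   training.
#' @param label_map optional named character vector; unmapped labels pass
#'   through, but a true label that is neither mapped nor a model class is
#'   an error.
#' @return a `classification_report` over the union of classes with nonzero
#'   mapped support and classes actually predicted.
#' @export
cross_species_evaluate <- function(model, target, target_labels,
                                   feature_space, label_map = NULL) {
  proj <- if (identical(feature_fingerprint(gene_ids(target)),
                        model$fingerprint)) target
          else project_to_feature_space(target, feature_space)
  pred <- predict(model, proj)
  truth <- target_labels[sample_ids(proj)]
  if (anyNA(truth)) stop("missing labels for some target samples")
  apply_map <- function(lbl) {
    hit <- lbl %in% names(label_map)
    lbl[hit] <- label_map[lbl[hit]]
    lbl
  }
  if (!is.null(label_map)) {
    truth <- apply_map(truth)
    pred$label <- apply_map(pred$label)
  }
  bad <- setdiff(unique(truth), c(model$classes, unname(label_map)))
  if (length(bad))
    stop("unmapped target label(s): ", paste(bad, collapse = ", "))
  classification_report(unname(truth), pred$label)
}
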