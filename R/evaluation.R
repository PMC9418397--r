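# Stratified k-fold splitting, confusion matrices and one-vs-rest
# class-wise metrics (accuracy, specificity, sensitivity, precision,
# F-measure) with macro averaging.

#' Stratified k-fold split
#'
#' Shuffles ids within each class (seeded) and deals them round-robin to the
#' k folds, so every fold's class count is within one sample of `n_c / k`.
#'
#' @param labels vector of class labels (one per sample).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the within-class shuffles.
#' @return object of class `fold_split`: list with `assignments` (fold id
#'   per sample), `folds` (per fold, `train`/`val` index vectors), `k`,
#'   `seed`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  k <- as.integer(k)
  stopifnot(k >= 2)
  counts <- table(labels)
  short <- counts[counts < k]
  if (length(short) > 0)
    stop(sprintf("class %s has %d samples; need at least k = %d",
                 names(short)[1], short[[1]], k))
  set.seed(seed)
  assignments <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    assignments[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  folds <- lapply(seq_len(k), function(f)
    list(train = which(assignments != f), val = which(assignments == f)))
  structure(list(assignments = assignments, folds = folds, k = k, seed = seed),
            class = "fold_split")
}

#' Multi-class confusion matrix
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param levels class levels in display order; default `0:(K-1)` inferred
#'   from the data.
#' @return object of class `confusion_matrix`: a K x K integer matrix,
#'   rows = true class, columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (is.null(levels)) levels <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% levels))
    stop("labels outside the declared levels")
  cm <- table(true = factor(y_true, levels = levels),
              pred = factor(y_pred, levels = levels))
  cm <- unclass(cm)
  structure(cm, class = "confusion_matrix", levels = levels)
}

#' One-vs-rest class-wise metrics
#'
#' For each class c (treated as positive, all others negative):
#' `TP = cm[c,c]`, `FN` the rest of row c, `FP` the rest of column c,
#' `TN` everything else; then accuracy `(TP+TN)/N`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and
#' F-measure the harmonic mean of precision and sensitivity. A class with
#' zero true and zero predicted samples is flagged undefined (`NA` metrics)
#' and excluded from the macro average, with a warning.
#'
#' @param cm a [confusion()] matrix.
#' @return object of class `eval_report`: a data.frame with one row per
#'   class (columns `class`, `accuracy`, `specificity`, `sensitivity`,
#'   `precision`, `f_measure`, `support`, `defined`).
#' @examples
#' cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' classwise_metrics(cm)
#' @export
classwise_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  levels <- attr(cm, "levels")
  K <- nrow(cm)
  out <- lapply(seq_len(K), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- N - TP - FN - FP
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    data.frame(class = levels[i], accuracy = (TP + TN) / N,
               specificity = spec, sensitivity = sens, precision = prec,
               f_measure = f, support = TP + FN,
               defined = (TP + FN > 0) || (TP + FP > 0))
  })
  rep <- do.call(rbind, out)
  if (any(!rep$defined))
    warning(sprintf("class(es) %s have no true or predicted samples; excluded from macro averages",
                    paste(rep$class[!rep$defined], collapse = ", ")))
  structure(rep, class = c("eval_report", "data.frame"))
}

#' Macro (arithmetic-mean) average of an evaluation report
#'
#' Averages each metric over the defined classes. Values are kept at full
#' precision; the print method displays four decimals (rounded half away
#' from zero).
#'
#' @param report an `eval_report` from [classwise_metrics()], or a
#'   data.frame with the same metric columns.
#' @return named numeric vector with the macro `accuracy`, `specificity`,
#'   `sensitivity`, `precision`, `f_measure`.
#' @export
macro_average <- function(report) {
  keep <- if ("defined" %in% names(report)) report$defined else
    rep(TRUE, nrow(report))
  if (!any(keep)) stop("no defined class to average")
  cols <- c("accuracy", "specificity", "sensitivity", "precision", "f_measure")
  cols <- intersect(cols, names(report))
  vapply(cols, function(cn) mean(report[[cn]][keep], na.rm = TRUE), numeric(1))
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round_half_away(v, digits))
  print.data.frame(df, row.names = FALSE)
  mac <- round_half_away(macro_average(x), digits)
  cat("macro:", paste(sprintf("%s=%.4f", names(mac), mac), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: confusion matrix, class-wise metrics and macro
#' averages in one object.
#'
#' @inheritParams confusion
#' @return list with `confusion`, `classwise`, `macro`.
#' @export
evaluate_predictions <- function(y_true, y_pred, levels = NULL) {
  cm <- confusion(y_true, y_pred, levels = levels)
  cw <- classwise_metrics(cm)
  list(confusion = cm, classwise = cw, macro = macro_average(cw))
}

#' Published class-wise reference metrics of the holistic 6-class model
#'
#' The class-wise validation metrics reported for the original holistic
#' six-class model (control plus five severity grades), as printed to four
#' decimals. Used for internal-consistency checks of the macro-averaging
#' implementation; these are inputs, not values computed by this package.
#'
#' @return data.frame with columns `class`, `accuracy`, `specificity`,
#'   `sensitivity`, `precision`, `f_measure`.
#' @export
reference_classwise_metrics <- function() {
  data.frame(
    class = 0:5,
    accuracy    = c(0.9867, 0.9920, 0.9947, 0.9947, 0.9813, 0.9867),
    specificity = c(0.9968, 0.9936, 0.9936, 0.9968, 0.9840, 0.9968),
    sensitivity = c(0.9365, 0.9844, 1.0000, 0.9836, 0.9677, 0.9365),
    precision   = c(0.9833, 0.9692, 0.9688, 0.9836, 0.9231, 0.9833),
    f_measure   = c(0.9593, 0.9767, 0.9841, 0.9836, 0.9449, 0.9593))
}
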