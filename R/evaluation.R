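#' Confusion matrix from label sequences
#'
#' Tallies `counts[i, j]` = number of beats whose ground truth is class `i`
#' and whose prediction is class `j`. Rows are ground truth, columns are
#' predictions, both in `class_order`.
#'
#' @param truth,predicted Equal-length vectors of class labels; every label
#'   must appear in `class_order`.
#' @param class_order Class order fixing rows/columns (default
#'   [beat_classes()]).
#' @return An integer matrix of class `confusion_matrix` with dimnames
#'   `truth` x `predicted`.
#' @export
#' @examples
#' confusion(c("NSR", "PVC", "APC"), c("NSR", "APC", "APC"))
confusion <- function(truth, predicted, class_order = beat_classes()) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad) > 0) {
    abort(sprintf("labels outside `class_order`: %s", paste(bad, collapse = ", ")))
  }
  tf <- factor(truth, levels = class_order)
  pf <- factor(predicted, levels = class_order)
  m <- as.matrix(table(truth = tf, predicted = pf))
  as_confusion_matrix(m, class_order)
}

#' Construct a confusion matrix from counts
#'
#' @param counts Square matrix of non-negative counts, rows = ground truth,
#'   columns = predicted.
#' @param class_order Class names for rows and columns.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, class_order = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("`counts` must be square")
  if (is.null(class_order)) class_order <- paste0("C", seq_len(nrow(counts)))
  if (length(class_order) != nrow(counts)) {
    abort("`class_order` must name every row/column")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth = class_order, predicted = class_order)
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>  truth in rows, predictions in columns\n")
  print(unclass(x))
  err <- misclassification_error(x)
  cat("misclassification error (%):",
      paste(sprintf("%s=%.2f", names(err), err), collapse = " "), "\n")
  invisible(x)
}

#' Per-predicted-class misclassification error
#'
#' For each predicted class (column), the percentage of beats assigned to
#' that class whose ground truth differs:
#' `100 * (column total - diagonal) / column total`, i.e. `100 - PPV` of
#' that class. Classes never predicted get `NA` (the ratio is undefined,
#' not zero).
#'
#' @param matrix A `confusion_matrix`.
#' @param predicted_class Optional class name(s) to report; defaults to all.
#' @return Named numeric vector of percentages in `[0, 100]` (or `NA`).
#' @export
misclassification_error <- function(matrix, predicted_class = NULL) {
  m <- unclass(matrix)
  col_tot <- colSums(m)
  err <- ifelse(col_tot > 0, 100 * (col_tot - diag(m)) / col_tot, NA_real_)
  names(err) <- colnames(m)
  if (!is.null(predicted_class)) {
    bad <- setdiff(predicted_class, colnames(m))
    if (length(bad) > 0) {
      abort(sprintf("unknown predicted class(es): %s", paste(bad, collapse = ", ")))
    }
    err <- err[predicted_class]
  }
  err
}

#' Overall multiclass accuracy
#'
#' `100 * trace / total`: the percentage of beats whose prediction equals
#' their ground truth.
#'
#' @param matrix A `confusion_matrix` with at least one count.
#' @return Percentage in `[0, 100]`.
#' @export
overall_accuracy <- function(matrix) {
  m <- unclass(matrix)
  tot <- sum(m)
  if (tot == 0) abort("empty confusion matrix")
  100 * sum(diag(m)) / tot
}

#' Binary (normal vs. abnormal) metrics from a multiclass matrix
#'
#' Collapses the matrix to 2x2 by treating `positive_classes` as the
#' positive (abnormal) pool and everything else as negative, then computes
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and positive predictive value `TP/(TP+FP)`, each as a
#' percentage. Ratios with zero denominators are reported as `NA`
#' (undefined, not zero).
#'
#' @param matrix A `confusion_matrix`.
#' @param positive_classes Nonempty proper subset of the matrix's classes.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
binary_metrics <- function(matrix, positive_classes = c("APC", "PVC")) {
  m <- unclass(matrix)
  classes <- colnames(m)
  if (length(positive_classes) == 0 ||
      !all(positive_classes %in% classes) ||
      length(positive_classes) >= length(classes)) {
    abort("`positive_classes` must be a nonempty proper subset of the classes")
  }
  pos <- classes %in% positive_classes
  tp <- sum(m[pos, pos, drop = FALSE])
  fn <- sum(m[pos, !pos, drop = FALSE])
  fp <- sum(m[!pos, pos, drop = FALSE])
  tn <- sum(m[!pos, !pos, drop = FALSE])
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp)
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `truth`, `predicted`, `n`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  df$truth <- rownames(df)
  out <- tidyr::pivot_longer(tibble::as_tibble(df), -"truth",
                             names_to = "predicted", values_to = "n")
  out$truth <- factor(out$truth, levels = rownames(x))
  out$predicted <- factor(out$predicted, levels = colnames(x))
  out
}

#' One-row summary of a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with total count, overall accuracy and error rate (%).
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  acc <- overall_accuracy(x)
  tibble::tibble(n = sum(x), accuracy = acc, error_rate = 100 - acc)
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot with counts annotated.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "ground truth") +
    ggplot2::theme_minimal()
}

#' Round half away from zero
#'
#' Display rounding used for reported percentages (so 13.985 prints as
#' 13.99 rather than banker's-rounded 13.98). Internal values are kept at
#' full precision; this is only for formatting.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Patient-specific normal/abnormal relabeling
#'
#' For patient-specific evaluation every beat is reduced to `normal` or
#' `abnormal`. NSR is always normal and APC/PVC always abnormal. Bundle
#' branch block beats (LBBB/RBBB) count as normal only for records whose
#' baseline rhythm is a bundle branch block — by default the seven MIT-BIH
#' records 109, 111, 118, 124, 207, 214 and 232, which contain no NSR
#' beats; elsewhere they are abnormal.
#'
#' @param record_id Character vector of record IDs.
#' @param label Vector of class labels ([beat_classes()]).
#' @param bbb_normal_records Record IDs whose LBBB/RBBB beats are normal.
#' @return Factor with levels `normal`, `abnormal`.
#' @export
#' @examples
#' patient_specific_relabel(c("109", "100", "100"), c("LBBB", "LBBB", "PVC"))
patient_specific_relabel <- function(record_id, label,
                                     bbb_normal_records = bbb_record_ids()) {
  label <- assert_class_labels(label, "label")
  record_id <- as.character(record_id)
  out <- ifelse(
    label == "NSR", "normal",
    ifelse(label %in% c("LBBB", "RBBB"),
           ifelse(record_id %in% bbb_normal_records, "normal", "abnormal"),
           "abnormal"))
  factor(out, levels = c("normal", "abnormal"))
}

#' Records whose baseline rhythm is a bundle branch block
#'
#' The seven MIT-BIH arrhythmia records that contain no NSR beats, only
#' LBBB/RBBB rhythm, so bundle branch block is their normal rhythm for
#' patient-specific evaluation.
#'
#' @return Character vector of record IDs.
#' @export
bbb_record_ids <- function() {
  c("109", "111", "118", "124", "207", "214", "232")
}

#' Read / write a labelled confusion-matrix CSV
#'
#' The CSV has a `truth` column of class names followed by one column per
#' predicted class.
#'
#' @param path File path.
#' @return A `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "truth") abort("first CSV column must be `truth`")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$truth
  if (!identical(rownames(m), colnames(m))) {
    abort("row and column class order must agree")
  }
  as_confusion_matrix(m, rownames(m))
}

#' @rdname read_confusion_csv
#' @param matrix A `confusion_matrix` to write.
#' @export
write_confusion_csv <- function(matrix, path) {
  df <- data.frame(truth = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published benchmark confusion matrices
#'
#' Count matrices from published MIT-BIH beat-classification experiments,
#' bundled as plain-text CSVs so the metric arithmetic (per-predicted-class
#' misclassification error, overall accuracy, Se/Sp/PPV) can be validated
#' against reported values without any model run. Available matrices:
#' * `basic_5class` — five-class results of the basic `[1,3,5]`-kernel
#'   inception model;
#' * `expanded_5class` — five-class results of the expanded
#'   `[10,50,100]`-kernel model;
#' * `proposed_3class`, `kiranyaz_3class`, `luo_3class` — three-class
#'   (NSR/APC/PVC) comparison matrices of the expanded model and two
#'   earlier patient-specific CNN classifiers.
#'
#' @param name Which matrix to load.
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' m <- benchmark_matrix("basic_5class")
#' misclassification_error(m)
benchmark_matrix <- function(name = c("basic_5class", "expanded_5class",
                                      "proposed_3class", "kiranyaz_3class",
                                      "luo_3class")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("confusion_", name, ".csv"),
                      package = "ecgincept", mustWork = TRUE)
  read_confusion_csv(path)
}
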