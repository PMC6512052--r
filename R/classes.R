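#' The five beat classes
#'
#' The closed, ordered set of heartbeat classes the classifier works with:
#' normal sinus rhythm (`NSR`), left and right bundle branch block
#' (`LBBB`, `RBBB`), atrial premature contraction (`APC`) and premature
#' ventricular contraction (`PVC`). The order is fixed; it determines the
#' row/column order of every confusion matrix produced by the package.
#'
#' @return Character vector of the five class names, in canonical order.
#' @export
#' @examples
#' beat_classes()
beat_classes <- function() {
  c("NSR", "LBBB", "RBBB", "APC", "PVC")
}

#' Map annotation symbols to beat classes
#'
#' Translates single-character WFDB/MIT beat annotation symbols into the five
#' study classes: `N` (normal) -> NSR, `L` -> LBBB, `R` -> RBBB,
#' `A` (atrial premature) -> APC, `V` (ventricular premature) -> PVC. Every
#' other symbol (paced beats, fusion beats, non-beat annotations, ...) maps to
#' `NA`, which marks the beat as excluded from training and testing.
#'
#' @param symbol Character vector of single-character annotation symbols.
#' @return Factor vector with levels [beat_classes()]; `NA` for symbols
#'   outside the five recognized codes.
#' @export
#' @examples
#' symbol_to_class(c("N", "V", "A", "/", "L", "R", "x"))
symbol_to_class <- function(symbol) {
  stopifnot(is.character(symbol))
  map <- c(N = "NSR", L = "LBBB", R = "RBBB", A = "APC", V = "PVC")
  factor(unname(map[symbol]), levels = beat_classes())
}

assert_class_labels <- function(labels, arg = "labels") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels[!is.na(labels)]), beat_classes())
  if (length(bad) > 0) {
    abort(sprintf("`%s` contains unknown class labels: %s",
                  arg, paste(bad, collapse = ", ")))
  }
  factor(labels, levels = beat_classes())
}
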