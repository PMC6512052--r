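#' Construct an annotated ECG record
#'
#' Bundles a sampled single-lead ECG signal with its sampling rate and beat
#' annotations. Annotations carry the 0-based sample index of each R-peak and
#' its single-character beat symbol; they must be strictly increasing and fall
#' inside the signal.
#'
#' @param record_id Record identifier (coerced to character scalar).
#' @param signal Numeric vector of amplitude samples, in millivolts.
#' @param fs Sampling rate in Hz; must be positive.
#' @param annotations A data frame with columns `sample` (0-based integer
#'   R-peak sample index) and `symbol` (single-character beat code).
#' @return An object of class `ecg_record`: a list with elements `record_id`,
#'   `signal`, `fs` and `annotations` (a tibble).
#' @export
#' @examples
#' rec <- ecg_record("r1", sin(seq(0, 2 * pi, length.out = 100)), fs = 100,
#'                   annotations = data.frame(sample = c(20L, 70L),
#'                                            symbol = c("N", "V")))
#' rec
ecg_record <- function(record_id, signal, fs, annotations) {
  record_id <- as.character(record_id)
  stopifnot(length(record_id) == 1L, !is.na(record_id))
  signal <- as.double(signal)
  if (anyNA(signal)) abort("`signal` must not contain missing values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz)")
  }
  annotations <- tibble::as_tibble(annotations)
  if (!all(c("sample", "symbol") %in% names(annotations))) {
    abort("`annotations` needs columns `sample` and `symbol`")
  }
  annotations$sample <- as.integer(annotations$sample)
  annotations$symbol <- as.character(annotations$symbol)
  annotations <- annotations[, c("sample", "symbol")]
  if (nrow(annotations) > 0) {
    if (anyNA(annotations$sample) || anyNA(annotations$symbol)) {
      abort("annotations must not contain missing values")
    }
    if (any(diff(annotations$sample) <= 0L)) {
      abort("annotation sample indices must be strictly increasing")
    }
    if (annotations$sample[1] < 0L ||
        annotations$sample[nrow(annotations)] >= length(signal)) {
      abort("annotation sample indices must lie in [0, length(signal))")
    }
    if (any(nchar(annotations$symbol) != 1L)) {
      abort("annotation symbols must be single characters")
    }
  }
  structure(
    list(record_id = record_id, signal = signal, fs = fs,
         annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'>  %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$record_id, length(x$signal), x$fs,
              length(x$signal) / x$fs, nrow(x$annotations)))
  if (nrow(x$annotations) > 0) {
    tab <- table(x$annotations$symbol)
    cat("  symbols:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
format.ecg_record <- function(x, ...) {
  sprintf("<ecg_record '%s': %d samples @ %g Hz>",
          x$record_id, length(x$signal), x$fs)
}

#' Tidy an ECG record into a sample-per-row tibble
#'
#' @param x An [ecg_record()].
#' @param ... Unused.
#' @return A tibble with columns `record_id`, `sample` (0-based), `time`
#'   (seconds) and `amplitude` (mV).
#' @method tidy ecg_record
#' @export
tidy.ecg_record <- function(x, ...) {
  n <- length(x$signal)
  tibble::tibble(
    record_id = x$record_id,
    sample = seq_len(n) - 1L,
    time = (seq_len(n) - 1L) / x$fs,
    amplitude = x$signal
  )
}

#' Plot an ECG record with its beat annotations
#'
#' @param object An [ecg_record()].
#' @param from,to Time range to display, in seconds.
#' @param ... Unused.
#' @return A ggplot object: the trace with R-peak annotations marked and
#'   labelled by symbol.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, from = 0,
                                to = min(10, length(object$signal) / object$fs),
                                ...) {
  df <- tidy.ecg_record(object)
  df <- df[df$time >= from & df$time <= to, ]
  ann <- object$annotations
  ann$time <- ann$sample / object$fs
  ann <- ann[ann$time >= from & ann$time <= to, ]
  ann$amplitude <- object$signal[ann$sample + 1L]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = ann, colour = "red", size = 1) +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$symbol),
                       vjust = -1, size = 3, colour = "red") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = sprintf("record %s", object$record_id)) +
    ggplot2::theme_minimal()
}
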