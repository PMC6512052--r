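#' Segmentation configuration
#'
#' Controls R-peak-anchored window extraction. `k` is the number of ECG
#' segments (R-R intervals of context) a window covers, between 3 and 7;
#' every window is then resampled to `(k - 1) * samples_per_interval`
#' samples, so the defaults span input lengths 200 (k = 3) to 600 (k = 7).
#'
#' @param k Integer in 3..7: ECG segments per window.
#' @param samples_per_interval Samples each R-R interval is normalized to
#'   (default 100).
#' @return A list of class `segment_config`.
#' @export
#' @examples
#' segment_config(k = 3)
segment_config <- function(k = 3L, samples_per_interval = 100L) {
  k <- as.integer(k)
  samples_per_interval <- as.integer(samples_per_interval)
  if (is.na(k) || k < 3L || k > 7L) abort("`k` must be an integer in 3..7")
  if (is.na(samples_per_interval) || samples_per_interval < 2L) {
    abort("`samples_per_interval` must be an integer >= 2")
  }
  structure(list(k = k, samples_per_interval = samples_per_interval),
            class = "segment_config")
}

#' Normalized window length implied by a segmentation configuration
#'
#' The network input length is a pure function of the configuration:
#' `(k - 1) * samples_per_interval`, independent of heart rate, sampling
#' rate, or window duration.
#'
#' @param config A [segment_config()].
#' @return Integer window length.
#' @export
normalized_length <- function(config) {
  stopifnot(inherits(config, "segment_config"))
  (config$k - 1L) * config$samples_per_interval
}

#' Window boundaries around a reference beat
#'
#' For reference beat `n` (1-based position in the annotation list) and
#' segment count `k`, the window starts at the midpoint between the R-peaks
#' `k - 1` and `k - 2` beats before the reference, and ends at the midpoint
#' between the first and second R-peaks after it; midpoints are rounded
#' down. The window therefore spans about `k` R-R intervals centred on the
#' reference beat. Beats without enough neighbouring peaks on either side
#' get `NA` boundaries and are skipped by [extract_windows()].
#'
#' @param record An [ecg_record()].
#' @param n Reference beat position(s), 1-based in the annotation list.
#' @param k Segment count (3..7).
#' @return A tibble with columns `n`, `first_sample`, `end_sample` (0-based,
#'   half-open; `NA` where context is insufficient).
#' @export
boundary_samples <- function(record, n, k) {
  stopifnot(inherits(record, "ecg_record"))
  k <- as.integer(k)
  peaks <- record$annotations$sample
  n_ann <- length(peaks)
  peak_at <- function(i) {
    out <- rep(NA_integer_, length(i))
    ok <- i >= 1L & i <= n_ann
    out[ok] <- peaks[i[ok]]
    out
  }
  left1 <- peak_at(n - k + 1L)
  left2 <- peak_at(n - k + 2L)
  right1 <- peak_at(n + 1L)
  right2 <- peak_at(n + 2L)
  first_sample <- (left1 + left2) %/% 2L
  end_sample <- (right1 + right2) %/% 2L
  tibble::tibble(n = as.integer(n),
                 first_sample = first_sample,
                 end_sample = end_sample)
}

#' Extract labelled beat windows from a record
#'
#' Walks the annotation list, keeps beats whose symbol maps to one of the
#' five classes ([symbol_to_class()]) and whose neighbourhood contains the
#' peaks [boundary_samples()] needs, and cuts the raw window for each.
#' Each window is labelled by its own reference beat's class.
#'
#' @param record An [ecg_record()].
#' @param config A [segment_config()].
#' @return A tibble with one row per eligible beat: `record_id`,
#'   `beat` (1-based reference position in the annotation list),
#'   `r_sample` (the reference R-peak, 0-based), `label`, `first_sample`,
#'   `end_sample`, and `raw` (list column of amplitude vectors).
#' @export
extract_windows <- function(record, config = segment_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "segment_config"))
  ann <- record$annotations
  if (nrow(ann) == 0) return(empty_windows())
  labels <- symbol_to_class(ann$symbol)
  bounds <- boundary_samples(record, seq_len(nrow(ann)), config$k)
  keep <- !is.na(labels) & !is.na(bounds$first_sample) &
    !is.na(bounds$end_sample)
  if (!any(keep)) return(empty_windows())
  idx <- which(keep)
  tibble::tibble(
    record_id = record$record_id,
    beat = idx,
    r_sample = ann$sample[idx],
    label = labels[idx],
    first_sample = bounds$first_sample[idx],
    end_sample = bounds$end_sample[idx],
    raw = purrr::map2(bounds$first_sample[idx], bounds$end_sample[idx],
                      function(a, b) record$signal[(a + 1L):b])
  )
}

empty_windows <- function() {
  tibble::tibble(record_id = character(), beat = integer(),
                 r_sample = integer(),
                 label = factor(character(), levels = beat_classes()),
                 first_sample = integer(), end_sample = integer(),
                 raw = list())
}

#' Normalize beat windows to the network input length
#'
#' Resamples every raw window to exactly `(k - 1) * samples_per_interval`
#' samples with the anti-aliased band-limited resampler
#' ([resample_signal()]), then z-scores each window (mean 0, unit standard
#' deviation) to remove per-record gain and baseline differences. Windows
#' with (near-)zero variance are returned as all zeros rather than dividing
#' by a vanishing denominator.
#'
#' @param windows A tibble from [extract_windows()].
#' @param config The [segment_config()] used for extraction.
#' @return The input tibble with the `raw` column replaced by `values`, a
#'   list column of length-`normalized_length(config)` standardized vectors.
#' @export
normalize_beats <- function(windows, config = segment_config()) {
  stopifnot(inherits(config, "segment_config"))
  m <- normalized_length(config)
  out <- windows
  out$values <- purrr::map(windows$raw, function(x) {
    y <- resample_signal(x, m)
    s <- sd(y)
    if (!is.finite(s) || s < 1e-12) return(rep(0, m))
    (y - mean(y)) / s
  })
  out$raw <- NULL
  out
}

#' Stack normalized beats into a numeric matrix
#'
#' @param beats A tibble from [normalize_beats()] (needs a `values` list
#'   column of equal-length vectors).
#' @return Numeric matrix, one row per beat.
#' @export
beats_matrix <- function(beats) {
  lens <- lengths(beats$values)
  if (length(unique(lens)) > 1) {
    abort("all `values` must have the same length")
  }
  do.call(rbind, beats$values)
}
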