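# Small record builders shared across test files.

# Evenly spaced beats; signal is a unit spike train at the R-peaks on a
# zero baseline, enough for boundary/extraction arithmetic.
uniform_record <- function(n_beats = 10, rr = 360L, fs = 360,
                           symbol = "N", first = 0L, id = "U001") {
  samples <- first + rr * (seq_len(n_beats) - 1L)
  signal <- numeric(max(samples) + rr)
  signal[samples + 1L] <- 1
  ecg_record(id, signal, fs,
             tibble::tibble(sample = samples,
                            symbol = rep_len(symbol, n_beats)))
}

# Record with hand-chosen irregular R-R intervals (in samples).
irregular_record <- function(intervals = c(300L, 250L, 400L, 350L, 320L),
                             fs = 360, symbol = "N", id = "I001") {
  samples <- c(100L, 100L + cumsum(intervals))
  signal <- numeric(max(samples) + 200L)
  signal[samples + 1L] <- 1
  ecg_record(id, signal, fs,
             tibble::tibble(sample = samples,
                            symbol = rep_len(symbol, length(samples))))
}

# ---- WFDB encoders (test-side, independent of the package reader) ----------

encode_dat_212 <- function(adc) {
  if (length(adc) %% 2 == 1) adc <- c(adc, 0L)
  s1 <- adc[seq(1, length(adc), by = 2)]
  s2 <- adc[seq(2, length(adc), by = 2)]
  s1 <- ifelse(s1 < 0, s1 + 4096L, s1)
  s2 <- ifelse(s2 < 0, s2 + 4096L, s2)
  b0 <- s1 %% 256L
  b1 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  b2 <- s2 %% 256L
  as.raw(as.vector(rbind(b0, b1, b2)))
}

# MIT annotation stream words: code in the top 6 bits, interval below.
encode_atr <- function(samples, codes, use_skip = FALSE) {
  words <- integer(0)
  prev <- 0L
  for (i in seq_along(samples)) {
    gap <- samples[i] - prev
    if (gap > 1023L || (use_skip && i == 1L)) {
      words <- c(words, 59L * 1024L, gap %/% 65536L, gap %% 65536L)
      gap <- 0L
    }
    words <- c(words, codes[i] * 1024L + gap)
    prev <- samples[i]
  }
  words <- c(words, 0L)
  raw <- as.raw(as.vector(rbind(words %% 256L, words %/% 256L)))
  raw
}

# Writes a complete single-lead WFDB record; returns the path stem.
write_wfdb_record <- function(dir, id, adc, fs, ann_samples, ann_codes,
                              gain = 200L, use_skip = FALSE) {
  stem <- file.path(dir, id)
  writeLines(c(sprintf("%s 1 %d %d", id, fs, length(adc)),
               sprintf("%s.dat 212 %d 11 0 0 0 0 MLII", id, gain)),
             paste0(stem, ".hea"))
  writeBin(encode_dat_212(adc), paste0(stem, ".dat"))
  writeBin(encode_atr(ann_samples, ann_codes, use_skip), paste0(stem, ".atr"))
  stem
}
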