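# Minimal WFDB reader: .hea header, format-212 .dat signal, MIT .atr
# annotations. Covers the subset of the format family that single-lead beat
# classification needs; formats other than 212 are rejected.

wfdb_beat_symbols <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "25" = "B", "34" = "e", "35" = "n", "38" = "f", "41" = "r"
)

read_record_wfdb <- function(path, channel = 1L) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("file not found: %s", hea))
  header <- parse_wfdb_header(hea)
  if (channel < 1L || channel > header$n_sig) {
    abort(sprintf("record %s has %d signal(s); channel %d requested",
                  header$record_id, header$n_sig, channel))
  }
  dat <- file.path(dirname(hea), header$signals$file[channel])
  atr <- paste0(path, ".atr")
  for (f in c(dat, atr)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  sig <- header$signals[channel, ]
  adc <- read_dat_212(dat, n_sig = header$n_sig, n_samp = header$n_samp,
                      channel = channel)
  signal <- (adc - sig$baseline) / sig$gain
  ann <- read_atr(atr)
  ecg_record(header$record_id, signal, header$fs, ann)
}

parse_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) abort(sprintf("%s: malformed header line", path))
  record_id <- sub("/.*", "", top[1])
  n_sig <- as.integer(top[2])
  fs <- as.double(sub("/.*", "", top[3]))
  n_samp <- as.integer(top[4])
  if (is.na(n_sig) || is.na(fs) || is.na(n_samp)) {
    abort(sprintf("%s: malformed header line", path))
  }
  if (length(lines) < 1 + n_sig) abort(sprintf("%s: truncated header", path))
  sigs <- lapply(lines[1 + seq_len(n_sig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- sub("x.*", "", f[2])
    # gain field: gain(baseline)/units
    gspec <- if (length(f) >= 3) f[3] else "200"
    gain <- as.double(sub("[(/].*", "", gspec))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gspec)) {
      as.double(sub(".*\\(([-0-9]+)\\).*", "\\1", gspec))
    } else if (length(f) >= 5) as.double(f[5]) else 0  # default: adczero
    list(file = f[1], format = fmt, gain = gain, baseline = baseline)
  })
  list(record_id = record_id, n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = tibble::tibble(
         file = vapply(sigs, `[[`, "", "file"),
         format = vapply(sigs, `[[`, "", "format"),
         gain = vapply(sigs, `[[`, 0, "gain"),
         baseline = vapply(sigs, `[[`, 0, "baseline")
       ))
}

# Format 212 packs two 12-bit two's-complement samples into 3 bytes.
read_dat_212 <- function(path, n_sig, n_samp, channel) {
  raw <- readBin(path, "raw", n = file.size(path))
  n_total <- n_samp * n_sig
  n_pairs <- ceiling(n_total / 2)
  if (length(raw) < 3 * n_pairs) {
    abort(sprintf("%s: file too short for %d samples", path, n_total))
  }
  b <- as.integer(raw[seq_len(3 * n_pairs)])
  b0 <- b[seq(1, length(b), by = 3)]
  b1 <- b[seq(2, length(b), by = 3)]
  b2 <- b[seq(3, length(b), by = 3)]
  s1 <- bitwAnd(b1, 0x0FL) * 256L + b0
  s2 <- bitwAnd(bitwShiftR(b1, 4L), 0x0FL) * 256L + b2
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  all_samples <- as.vector(rbind(s1, s2))[seq_len(n_total)]
  all_samples[seq(channel, n_total, by = n_sig)]
}

# MIT annotation stream: 2-byte little-endian words; code in the upper 6
# bits, time increment in the lower 10. SKIP (59) carries a 4-byte increment
# (high word first); NUM/SUB/CHN (60-62) are modifiers; AUX (63) skips its
# even-padded payload; code 0 with increment 0 ends the stream. Only beat
# annotations are kept.
read_atr <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw) %/% 2
  words <- as.integer(raw[seq(1, 2 * n)][seq(1, 2 * n, by = 2)]) +
    256L * as.integer(raw[seq(1, 2 * n)][seq(2, 2 * n, by = 2)])
  i <- 1L
  t <- 0L
  samples <- integer(0)
  symbols <- character(0)
  while (i <= n) {
    code <- bitwShiftR(words[i], 10L)
    interval <- bitwAnd(words[i], 0x3FFL)
    if (code == 0L && interval == 0L) break
    if (code == 59L) {          # SKIP
      if (i + 2L > n) abort(sprintf("%s: truncated SKIP annotation", path))
      t <- t + words[i + 1L] * 65536L + words[i + 2L]
      i <- i + 3L
      next
    }
    if (code %in% 60:62) {      # NUM / SUB / CHN modifiers
      i <- i + 1L
      next
    }
    if (code == 63L) {          # AUX: payload of `interval` bytes, even-padded
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
      next
    }
    t <- t + interval
    sym <- wfdb_beat_symbols[as.character(code)]
    if (!is.na(sym)) {
      samples <- c(samples, t)
      symbols <- c(symbols, sym)
    }
    i <- i + 1L
  }
  tibble::tibble(sample = samples, symbol = symbols)
}
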