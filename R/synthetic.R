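#' Synthetic ECG generator configuration
#'
#' Settings for the seeded five-class synthetic ECG generator. Each beat is
#' a sum of Gaussian-shaped P/Q/R/S/T waves with class-specific morphology,
#' and premature beats carry their timing signatures: an APC shortens the
#' R-R interval that precedes it (by `apc_prematurity`), a PVC stretches
#' the one that follows it (compensatory pause, factor `pvc_pause`).
#'
#' @param fs Sampling rate, Hz (default 360, the MIT-BIH rate).
#' @param n_beats Number of beats in a record.
#' @param class_mix Named proportions over [beat_classes()]; must sum to 1.
#' @param mean_rr Mean R-R interval, seconds.
#' @param rr_jitter Coefficient of variation of the R-R intervals.
#' @param noise_sd Additive white-noise standard deviation, millivolts.
#' @param apc_prematurity Fractional shortening of the interval before an
#'   APC beat.
#' @param pvc_pause Multiplicative lengthening of the interval after a PVC.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 360, n_beats = 600L,
                         class_mix = c(NSR = 0.55, LBBB = 0.12, RBBB = 0.11,
                                       APC = 0.10, PVC = 0.12),
                         mean_rr = 0.8, rr_jitter = 0.05, noise_sd = 0.02,
                         apc_prematurity = 0.25, pvc_pause = 1.5,
                         seed = 1L) {
  if (!all(beat_classes() %in% names(class_mix))) {
    abort("`class_mix` must name all five beat classes")
  }
  class_mix <- class_mix[beat_classes()]
  if (any(class_mix < 0)) abort("`class_mix` entries must be non-negative")
  if (abs(sum(class_mix) - 1) > 1e-9) abort("`class_mix` must sum to 1")
  stopifnot(fs > 0, n_beats >= 0, mean_rr > 0, rr_jitter >= 0, noise_sd >= 0,
            apc_prematurity > 0, apc_prematurity < 1, pvc_pause > 1)
  structure(list(fs = fs, n_beats = as.integer(n_beats),
                 class_mix = class_mix, mean_rr = mean_rr,
                 rr_jitter = rr_jitter, noise_sd = noise_sd,
                 apc_prematurity = apc_prematurity, pvc_pause = pvc_pause,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Per-class wave tables: centre offset (s) relative to the R-peak,
# amplitude (mV), Gaussian width sigma (s). Morphologies are caricatures
# built for clear class separation: bundle branch blocks widen/deform the
# QRS, the APC has an early altered P wave, the PVC is wide and bizarre
# with no P wave and a discordant T.
beat_wave_table <- function(class) {
  switch(as.character(class),
    NSR = rbind(c(-0.200, 0.15, 0.025),   # P
                c(-0.035, -0.10, 0.010),  # Q
                c(0.000, 1.00, 0.012),    # R
                c(0.035, -0.15, 0.010),   # S
                c(0.250, 0.30, 0.040)),   # T
    LBBB = rbind(c(-0.200, 0.12, 0.025),
                 c(0.000, 0.90, 0.035),   # broad slurred R
                 c(0.075, -0.35, 0.030),
                 c(0.300, -0.25, 0.050)), # discordant T
    RBBB = rbind(c(-0.200, 0.14, 0.025),
                 c(0.000, 0.85, 0.014),
                 c(0.035, -0.30, 0.015),
                 c(0.070, 0.55, 0.022),   # R' second peak
                 c(0.280, -0.15, 0.045)),
    APC = rbind(c(-0.120, 0.22, 0.035),   # early, altered P
                c(-0.035, -0.08, 0.010),
                c(0.000, 0.95, 0.013),
                c(0.035, -0.12, 0.010),
                c(0.250, 0.28, 0.040)),
    PVC = rbind(c(0.000, 1.25, 0.045),    # wide bizarre QRS, no P
                c(0.100, -0.50, 0.035),
                c(0.320, -0.45, 0.060)),
    abort(sprintf("unknown class '%s'", class)))
}

class_to_symbol <- function(class) {
  map <- c(NSR = "N", LBBB = "L", RBBB = "R", APC = "A", PVC = "V")
  unname(map[as.character(class)])
}

#' Generate one annotated synthetic ECG record
#'
#' Draws a seeded class sequence from `class_mix`, builds the R-R interval
#' train (jitter, APC prematurity, PVC compensatory pause), renders each
#' beat from its class wave table, annotates every true R-peak sample with
#' the class's beat symbol, and adds white noise.
#'
#' @param config A [synth_config()].
#' @param record_id Identifier for the record.
#' @return An [ecg_record()].
#' @export
#' @examples
#' rec <- generate_record(synth_config(n_beats = 20, seed = 7))
#' rec
generate_record <- function(config = synth_config(), record_id = "S001") {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  if (config$n_beats == 0L) {
    return(withr::with_seed(config$seed, {
      n <- as.integer(round(fs))
      ecg_record(record_id, rnorm(n, 0, config$noise_sd), fs,
                 tibble::tibble(sample = integer(), symbol = character()))
    }))
  }
  withr::with_seed(config$seed, {
    classes <- sample(beat_classes(), config$n_beats, replace = TRUE,
                      prob = config$class_mix)
    nb <- config$n_beats
    intervals <- if (nb > 1) {
      pmax(config$mean_rr * (1 + config$rr_jitter * rnorm(nb - 1L)),
           0.4 * config$mean_rr)
    } else numeric(0)
    if (nb > 1) {
      for (i in 2:nb) {          # APC arrives early
        if (classes[i] == "APC") {
          intervals[i - 1L] <- intervals[i - 1L] * (1 - config$apc_prematurity)
        }
      }
      for (i in 1:(nb - 1L)) {   # PVC is followed by a compensatory pause
        if (classes[i] == "PVC") {
          intervals[i] <- intervals[i] * config$pvc_pause
        }
      }
    }
    r_times <- 0.5 + cumsum(c(0, intervals))
    r_samples <- as.integer(round(r_times * fs))
    n_samples <- as.integer(round((r_times[nb] + 0.6) * fs))
    signal <- numeric(n_samples)
    t_axis <- (seq_len(n_samples) - 1L) / fs
    for (i in seq_len(nb)) {
      waves <- beat_wave_table(classes[i])
      lo <- max(1L, as.integer(floor((r_times[i] - 0.45) * fs)))
      hi <- min(n_samples, as.integer(ceiling((r_times[i] + 0.55) * fs)))
      tt <- t_axis[lo:hi] - r_times[i]
      seg <- numeric(length(tt))
      for (w in seq_len(nrow(waves))) {
        seg <- seg + waves[w, 2] * exp(-0.5 * ((tt - waves[w, 1]) / waves[w, 3])^2)
      }
      signal[lo:hi] <- signal[lo:hi] + seg
    }
    if (config$noise_sd > 0) {
      signal <- signal + rnorm(n_samples, 0, config$noise_sd)
    }
    ecg_record(record_id, signal, fs,
               tibble::tibble(sample = r_samples,
                              symbol = class_to_symbol(classes)))
  })
}

#' Generate a dataset of independent synthetic records
#'
#' Each record gets a seed derived from the master seed and a unique ID, so
#' the whole dataset is reproducible from `config$seed` alone.
#'
#' @param config A [synth_config()]; `config$seed` is the master seed.
#' @param n_records Number of records (>= 1).
#' @param id_prefix Prefix for generated record IDs.
#' @return A list of [ecg_record()] objects.
#' @export
generate_dataset <- function(config = synth_config(), n_records = 1L,
                             id_prefix = "S") {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L) abort("`n_records` must be >= 1")
  lapply(seq_len(n_records), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    generate_record(cfg, record_id = sprintf("%s%03d", id_prefix, i))
  })
}

#' Extract and normalize beats from many records
#'
#' Convenience wrapper: runs [extract_windows()] and [normalize_beats()]
#' over a list of records and binds the results.
#'
#' @param records A list of [ecg_record()] objects.
#' @param config A [segment_config()].
#' @param exclude_records Record IDs to drop (e.g. [paced_record_ids()]).
#' @return A normalized-beats tibble.
#' @export
dataset_beats <- function(records, config = segment_config(),
                          exclude_records = character()) {
  records <- records[!vapply(records, function(r) r$record_id, "") %in%
                       exclude_records]
  dplyr::bind_rows(lapply(records, function(r) {
    normalize_beats(extract_windows(r, config), config)
  }))
}
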