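#' Resample a signal to a fixed length with anti-aliasing
#'
#' Band-limited resampling by windowed-sinc interpolation. Output sample `j`
#' (0-based) is taken at position `j * n / m` on the input grid, so the
#' output spans the same time interval as the input. When decimating
#' (`m < n`) the sinc kernel's cutoff is lowered to the output Nyquist rate,
#' which is the anti-aliasing low-pass; when interpolating the kernel is a
#' plain interpolating sinc. Kernel rows are renormalized to unit DC gain,
#' which keeps constants exact and tames edge droop from kernel truncation.
#'
#' @param x Numeric vector to resample.
#' @param m Target length (integer >= 2).
#' @param zeros Half-width of the truncated sinc kernel, in zero crossings.
#'   Larger values sharpen the low-pass at linear cost.
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * (0:1079) / 360)  # 5 Hz sine at 360 Hz
#' y <- resample_signal(x, 200)
#' length(y)
resample_signal <- function(x, m, zeros = 10) {
  n <- length(x)
  if (n < 2) abort("`x` must have at least 2 samples")
  m <- as.integer(m)
  if (is.na(m) || m < 2) abort("`m` must be an integer >= 2")
  if (m == n) return(as.double(x))
  cutoff <- min(1, m / n)            # fraction of the input Nyquist kept
  half <- zeros / cutoff             # kernel half-width in input samples
  pos <- (seq_len(m) - 1) * n / m    # output positions on the input grid
  i0 <- pmax(1L, as.integer(ceiling(pos - half)) + 1L)
  i1 <- pmin(n, as.integer(floor(pos + half)) + 1L)
  y <- numeric(m)
  for (j in seq_len(m)) {
    idx <- i0[j]:i1[j]
    u <- (idx - 1L) - pos[j]
    w <- cutoff * sinc(cutoff * u) * hann_taper(u / half)
    y[j] <- sum(w * x[idx]) / sum(w)
  }
  y
}

sinc <- function(u) {
  out <- rep(1, length(u))
  nz <- u != 0
  out[nz] <- sin(pi * u[nz]) / (pi * u[nz])
  out
}

# Hann window on [-1, 1]; zero outside.
hann_taper <- function(v) {
  w <- 0.5 * (1 + cos(pi * pmin(1, pmax(-1, v))))
  w[abs(v) >= 1] <- 0
  w
}
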