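# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (triple loops, dense sums) and share no code with the
# package internals they check.

naive_conv1d <- function(x, k, stride = 1, padding = "valid") {
  K <- length(k)
  if (padding == "same") {
    L_out <- ceiling(length(x) / stride)
    total <- max((L_out - 1) * stride + K - length(x), 0)
    pl <- total %/% 2
    x <- c(rep(0, pl), x, rep(0, total - pl))
  }
  n <- length(x)
  out <- c()
  i <- 1
  while (i + K - 1 <= n) {
    acc <- 0
    for (j in seq_len(K)) acc <- acc + x[i + j - 1] * k[j]
    out <- c(out, acc)
    i <- i + stride
  }
  out
}

naive_maxpool1d <- function(x, size, stride = size, padding = "valid") {
  if (padding == "same") {
    L_out <- ceiling(length(x) / stride)
    total <- max((L_out - 1) * stride + size - length(x), 0)
    pl <- total %/% 2
    x <- c(rep(-Inf, pl), x, rep(-Inf, total - pl))
  }
  n <- length(x)
  out <- c()
  i <- 1
  while (i + size - 1 <= n) {
    out <- c(out, max(x[i:(i + size - 1)]))
    i <- i + stride
  }
  out
}

naive_confusion <- function(truth, predicted, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    m[truth[i], predicted[i]] <- m[truth[i], predicted[i]] + 1L
  }
  m
}

# Reference Adam update, written out longhand from the published formulas.
reference_adam <- function(theta, g, m, v, t, lr = 0.001, b1 = 0.9,
                           b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  theta - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
}

# A band-limited test signal: a random sum of sinusoids whose frequencies
# stay below `max_freq` cycles per input sample.
bandlimited_signal <- function(n, max_freq, n_tones = 6) {
  freqs <- runif(n_tones, 0.002, max_freq)
  phases <- runif(n_tones, 0, 2 * pi)
  amps <- runif(n_tones, 0.2, 1)
  f <- function(t) colSums(amps * sin(outer(2 * pi * freqs, t) + phases))
  list(at = f, x = f(0:(n - 1)))
}
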