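#' 1-D convolution (cross-correlation)
#'
#' Single-channel 1-D convolution in the machine-learning convention
#' (cross-correlation, no kernel flip). With `padding = "same"` and stride 1
#' the output has the input's length; the total padding is split with the
#' extra element, if any, on the right (so an even kernel pads one more on
#' the right).
#'
#' @param signal Numeric vector.
#' @param kernel Numeric vector of weights (nonempty).
#' @param stride Positive integer step.
#' @param padding `"valid"` or `"same"`.
#' @return Numeric vector of the convolved signal.
#' @export
#' @examples
#' conv1d(c(1, 2, 3, 4), c(1, 1))          # sliding sums: 3 5 7
#' conv1d(1:5, c(1), padding = "same")     # identity kernel
conv1d <- function(signal, kernel, stride = 1L, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (length(kernel) == 0) abort("`kernel` must be nonempty")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) abort("`stride` must be a positive integer")
  X <- array(as.double(signal), dim = c(1L, length(signal), 1L))
  W <- array(as.double(kernel), dim = c(length(kernel), 1L, 1L))
  out <- conv1d_batch(X, W, b = 0, stride = stride, padding = padding)$out
  as.double(out)
}

#' 1-D max pooling
#'
#' Windowed maximum over a sliding window. `padding = "same"` pads with
#' `-Inf` so the output length is `ceiling(length(signal) / stride)`.
#'
#' @param signal Numeric vector (nonempty).
#' @param pool_size Window length (>= 1).
#' @param stride Step between windows; defaults to `pool_size`
#'   (non-overlapping windows).
#' @param padding `"valid"` or `"same"`.
#' @return Numeric vector of windowed maxima.
#' @export
#' @examples
#' maxpool1d(c(1, 3, 2, 5), pool_size = 2, stride = 2)  # 3 5
maxpool1d <- function(signal, pool_size, stride = pool_size,
                      padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (length(signal) == 0) abort("`signal` must be nonempty")
  pool_size <- as.integer(pool_size)
  if (is.na(pool_size) || pool_size < 1L) abort("`pool_size` must be >= 1")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) abort("`stride` must be a positive integer")
  X <- array(as.double(signal), dim = c(1L, length(signal), 1L))
  out <- maxpool1d_batch(X, pool_size, stride, padding)$out
  as.double(out)
}

# ---- internal batched tensor ops -------------------------------------------
# X is always an array c(batch, length, channels). The per-kernel-position
# loop turns each convolution into K dense matrix products, which keeps the
# heavy lifting in BLAS.

pad_amount <- function(L, K, stride, padding) {
  if (padding == "valid") {
    if (L < K) abort(sprintf("input length %d shorter than kernel %d", L, K))
    return(c(0L, 0L))
  }
  L_out <- as.integer(ceiling(L / stride))
  total <- max((L_out - 1L) * stride + K - L, 0L)
  c(total %/% 2L, total - total %/% 2L)
}

pad_batch <- function(X, pl, pr, fill = 0) {
  if (pl == 0L && pr == 0L) return(X)
  d <- dim(X)
  Xp <- array(fill, dim = c(d[1], d[2] + pl + pr, d[3]))
  Xp[, pl + seq_len(d[2]), ] <- X
  Xp
}

conv1d_batch <- function(X, W, b, stride, padding) {
  d <- dim(X)
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  stopifnot(d[3] == Cin)
  pads <- pad_amount(d[2], K, stride, padding)
  Xp <- pad_batch(X, pads[1], pads[2])
  Lp <- dim(Xp)[2]
  L_out <- (Lp - K) %/% stride + 1L
  B <- d[1]
  Ymat <- matrix(rep(b, each = B * L_out), nrow = B * L_out)
  for (k in seq_len(K)) {
    pos <- seq(k, by = stride, length.out = L_out)
    Xk <- Xp[, pos, , drop = FALSE]
    dim(Xk) <- c(B * L_out, Cin)
    Ymat <- Ymat + Xk %*% matrix(W[k, , ], Cin, Cout)
  }
  out <- Ymat
  dim(out) <- c(B, L_out, Cout)
  list(out = out, cache = list(Xp = Xp, pads = pads, stride = stride,
                               L_out = L_out, in_len = d[2]))
}

conv1d_batch_backward <- function(dY, W, cache) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  Xp <- cache$Xp
  B <- dim(Xp)[1]
  L_out <- cache$L_out
  dYmat <- dY
  dim(dYmat) <- c(B * L_out, Cout)
  dW <- array(0, dim = dim(W))
  dXp <- array(0, dim = dim(Xp))
  for (k in seq_len(K)) {
    pos <- seq(k, by = cache$stride, length.out = L_out)
    Xk <- Xp[, pos, , drop = FALSE]
    dim(Xk) <- c(B * L_out, Cin)
    dW[k, , ] <- crossprod(Xk, dYmat)
    dXk <- dYmat %*% t(matrix(W[k, , ], Cin, Cout))
    dim(dXk) <- c(B, L_out, Cin)
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] + dXk
  }
  db <- colSums(dYmat)
  pl <- cache$pads[1]
  dX <- dXp[, pl + seq_len(cache$in_len), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

maxpool1d_batch <- function(X, pool_size, stride, padding) {
  d <- dim(X)
  pads <- pad_amount(d[2], pool_size, stride, padding)
  Xp <- pad_batch(X, pads[1], pads[2], fill = -Inf)
  Lp <- dim(Xp)[2]
  L_out <- (Lp - pool_size) %/% stride + 1L
  B <- d[1]; C <- d[3]
  Y <- array(-Inf, dim = c(B, L_out, C))
  arg <- array(0L, dim = c(B, L_out, C))
  for (k in seq_len(pool_size)) {
    pos <- seq(k, by = stride, length.out = L_out)
    Xk <- Xp[, pos, , drop = FALSE]
    better <- Xk > Y
    Y[better] <- Xk[better]
    arg[better] <- k
  }
  list(out = Y, cache = list(arg = arg, pads = pads, stride = stride,
                             in_len = d[2], Lp = Lp, pool_size = pool_size))
}

maxpool1d_batch_backward <- function(dY, cache) {
  arg <- cache$arg
  d <- dim(arg)
  dXp <- array(0, dim = c(d[1], cache$Lp, d[3]))
  for (k in seq_len(cache$pool_size)) {
    pos <- seq(k, by = cache$stride, length.out = d[2])
    mask <- arg == k
    if (!any(mask)) next
    dXk <- array(0, dim = d)
    dXk[mask] <- dY[mask]
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] + dXk
  }
  pl <- cache$pads[1]
  dXp[, pl + seq_len(cache$in_len), , drop = FALSE]
}

relu_forward <- function(X) {
  mask <- X > 0
  Y <- X
  Y[!mask] <- 0
  list(out = Y, cache = mask)
}

relu_backward <- function(dY, mask) {
  dX <- dY
  dX[!mask] <- 0
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
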