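#' Inception module specification
#'
#' One inception module: parallel 1-D convolution branches with different
#' kernel sizes plus a max-pooling branch, concatenated along the channel
#' axis. The basic kernel set is `c(1, 3, 5)`; the expanded set
#' `c(10, 50, 100)` reaches across R-R intervals and is only allowed in the
#' module that sees the raw ECG input directly (see [model_spec()]).
#' Branches use same-padding so all outputs share the input's temporal
#' length; the pooling branch (stride 1, same-padding) passes channels
#' through unchanged.
#'
#' @param kernel_sizes Positive integers, one per convolution branch.
#' @param filters_per_branch Filters in every convolution branch.
#' @param pool_size Pooling-branch window (>= 2).
#' @return A list of class `inception_spec`.
#' @export
#' @examples
#' inception_spec()                      # basic [1, 3, 5]
#' inception_spec(c(10, 50, 100), 9)     # expanded kernels
inception_spec <- function(kernel_sizes = c(1L, 3L, 5L),
                           filters_per_branch = 8L,
                           pool_size = 3L) {
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(kernel_sizes) < 1 || anyNA(kernel_sizes) || any(kernel_sizes < 1)) {
    abort("`kernel_sizes` must be positive integers (at least one branch)")
  }
  filters_per_branch <- as.integer(filters_per_branch)
  if (is.na(filters_per_branch) || filters_per_branch < 1) {
    abort("`filters_per_branch` must be a positive integer")
  }
  pool_size <- as.integer(pool_size)
  if (is.na(pool_size) || pool_size < 2) abort("`pool_size` must be >= 2")
  structure(list(kernel_sizes = kernel_sizes,
                 filters_per_branch = filters_per_branch,
                 pool_size = pool_size),
            class = "inception_spec")
}

#' Network design specification
#'
#' Declarative description of the three network designs:
#' * Design I — one inception module;
#' * Design II — two stacked inception modules;
#' * Design III — a plain convolution layer (valid padding, followed by
#'   ReLU and a non-overlapping max-pool) in front of one inception module.
#'
#' Every design flattens the final feature map into two fully connected
#' ReLU layers (defaults 100 and 50 neurons) and a 5-class softmax output.
#' Kernel sizes above 5 (the expanded set) are only accepted in an
#' inception module that is computed directly on the ECG input, i.e. the
#' first module of designs I and II.
#'
#' @param design `"I"`, `"II"` or `"III"`.
#' @param input_length Normalized beat length the network expects
#'   (see [normalized_length()]).
#' @param inception A single [inception_spec()] (designs I/III) or a list of
#'   two (design II).
#' @param cnn_filters,cnn_kernel,cnn_stride Front convolution layer
#'   (design III only); defaults 15 filters, kernel 5, stride 1, no padding,
#'   followed by max-pooling of size 2, stride 2.
#' @param fc_widths Hidden fully connected layer widths.
#' @param n_classes Output classes (default the five beat classes).
#' @return A list of class `model_spec`.
#' @export
#' @examples
#' model_spec("I")
#' model_spec("II", inception = list(inception_spec(), inception_spec()))
model_spec <- function(design = c("I", "II", "III"),
                       input_length = 200L,
                       inception = inception_spec(),
                       cnn_filters = 15L, cnn_kernel = 5L, cnn_stride = 1L,
                       fc_widths = c(100L, 50L),
                       n_classes = 5L) {
  design <- match.arg(design)
  if (inherits(inception, "inception_spec")) inception <- list(inception)
  if (!all(vapply(inception, inherits, TRUE, "inception_spec"))) {
    abort("`inception` must be one or a list of `inception_spec` objects")
  }
  n_incep <- length(inception)
  if (design == "II" && n_incep != 2L) {
    abort("design II requires exactly two inception specs")
  }
  if (design %in% c("I", "III") && n_incep != 1L) {
    abort(sprintf("design %s requires exactly one inception spec", design))
  }
  for (i in seq_along(inception)) {
    expanded_ok <- (design %in% c("I", "II")) && i == 1L
    if (!expanded_ok && any(inception[[i]]$kernel_sizes > 5L)) {
      abort(paste0("expanded kernels (> 5) are only allowed in an inception ",
                   "module computed directly on the ECG input"))
    }
  }
  input_length <- as.integer(input_length)
  if (is.na(input_length) || input_length < 2L) {
    abort("`input_length` must be an integer >= 2")
  }
  fc_widths <- as.integer(fc_widths)
  if (anyNA(fc_widths) || any(fc_widths < 1L)) {
    abort("`fc_widths` must be positive integers")
  }
  structure(list(design = design, input_length = input_length,
                 inception = inception,
                 cnn_filters = as.integer(cnn_filters),
                 cnn_kernel = as.integer(cnn_kernel),
                 cnn_stride = as.integer(cnn_stride),
                 fc_widths = fc_widths,
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

glorot_init <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

new_conv_layer <- function(K, Cin, Cout, stride, padding) {
  list(type = "conv",
       W = glorot_init(c(K, Cin, Cout), K * Cin, K * Cout),
       b = numeric(Cout), stride = stride, padding = padding)
}

new_dense_layer <- function(n_in, n_out) {
  list(type = "dense",
       W = glorot_init(c(n_in, n_out), n_in, n_out),
       b = numeric(n_out))
}

new_inception_layer <- function(spec, Cin) {
  branches <- lapply(spec$kernel_sizes, function(K) {
    new_conv_layer(K, Cin, spec$filters_per_branch, 1L, "same")
  })
  list(type = "inception", branches = branches, pool_size = spec$pool_size)
}

inception_out_channels <- function(spec, Cin) {
  length(spec$kernel_sizes) * spec$filters_per_branch + Cin
}

#' Build a network from a specification
#'
#' Instantiates all layers of a [model_spec()] with Glorot-uniform weight
#' initialization driven by `seed`; the same spec and seed always produce
#' bit-identical parameters. The returned object can be trained with
#' [train_model()] and applied with [forward()] or [predict()][predict.inception_model].
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `inception_model`.
#' @export
#' @examples
#' m <- build_model(model_spec("I"), seed = 1)
#' m
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  layers <- withr::with_seed(as.integer(seed), {
    out <- list()
    L <- spec$input_length
    C <- 1L
    if (spec$design == "III") {
      out <- c(out, list(new_conv_layer(spec$cnn_kernel, C, spec$cnn_filters,
                                        spec$cnn_stride, "valid")),
               list(list(type = "relu")),
               list(list(type = "pool", pool_size = 2L, stride = 2L,
                         padding = "valid")))
      L <- (L - spec$cnn_kernel) %/% spec$cnn_stride + 1L
      L <- (L - 2L) %/% 2L + 1L
      C <- spec$cnn_filters
    }
    for (isp in spec$inception) {
      out <- c(out, list(new_inception_layer(isp, C)))
      C <- inception_out_channels(isp, C)
    }
    out <- c(out, list(list(type = "flatten")))
    n_in <- L * C
    for (w in spec$fc_widths) {
      out <- c(out, list(new_dense_layer(n_in, w)), list(list(type = "relu")))
      n_in <- w
    }
    c(out, list(new_dense_layer(n_in, spec$n_classes)))
  })
  structure(list(spec = spec, seed = as.integer(seed), layers = layers,
                 trace = NULL, train_config = NULL),
            class = "inception_model")
}

#' @export
print.inception_model <- function(x, ...) {
  kstr <- paste(vapply(x$spec$inception, function(s) {
    sprintf("[%s]x%d", paste(s$kernel_sizes, collapse = ","),
            s$filters_per_branch)
  }, ""), collapse = " + ")
  cat(sprintf("<inception_model design %s>  input %d, inception %s, fc [%s], %d classes, %d parameters%s\n",
              x$spec$design, x$spec$input_length, kstr,
              paste(x$spec$fc_widths, collapse = ", "), x$spec$n_classes,
              n_parameters(x),
              if (is.null(x$trace)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model An `inception_model`.
#' @return Integer count of all weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(get_param_arrays(model$layers), length, 0L))
}

# Flat named list of every trainable array ("3.W", "4.b2.W", ...).
get_param_arrays <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      out[[sprintf("%d.W", i)]] <- ly$W
      out[[sprintf("%d.b", i)]] <- ly$b
    } else if (ly$type == "inception") {
      for (j in seq_along(ly$branches)) {
        out[[sprintf("%d.b%d.W", i, j)]] <- ly$branches[[j]]$W
        out[[sprintf("%d.b%d.b", i, j)]] <- ly$branches[[j]]$b
      }
    }
  }
  out
}

set_param_arrays <- function(layers, values) {
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1])
    if (length(parts) == 2) {
      layers[[i]][[parts[2]]] <- values[[nm]]
    } else {
      j <- as.integer(sub("^b", "", parts[2]))
      layers[[i]]$branches[[j]][[parts[3]]] <- values[[nm]]
    }
  }
  layers
}

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(ly, X) {
  switch(ly$type,
    conv = conv1d_batch(X, ly$W, ly$b, ly$stride, ly$padding),
    relu = relu_forward(X),
    pool = maxpool1d_batch(X, ly$pool_size, ly$stride, ly$padding),
    flatten = {
      d <- dim(X)
      Y <- X
      dim(Y) <- c(d[1], d[2] * d[3])
      list(out = Y, cache = d)
    },
    dense = list(out = sweep(X %*% ly$W, 2, ly$b, "+"), cache = X),
    inception = {
      outs <- vector("list", length(ly$branches) + 1L)
      caches <- vector("list", length(ly$branches))
      masks <- vector("list", length(ly$branches))
      for (j in seq_along(ly$branches)) {
        cv <- conv1d_batch(X, ly$branches[[j]]$W, ly$branches[[j]]$b, 1L, "same")
        rl <- relu_forward(cv$out)
        outs[[j]] <- rl$out
        caches[[j]] <- cv$cache
        masks[[j]] <- rl$cache
      }
      pool <- maxpool1d_batch(X, ly$pool_size, 1L, "same")
      outs[[length(outs)]] <- pool$out
      d <- dim(X)
      widths <- vapply(outs, function(o) dim(o)[3], 0L)
      Y <- array(0, dim = c(d[1], d[2], sum(widths)))
      off <- 0L
      for (o in outs) {
        w <- dim(o)[3]
        Y[, , off + seq_len(w)] <- o
        off <- off + w
      }
      list(out = Y, cache = list(conv = caches, mask = masks, pool = pool$cache,
                                 widths = widths))
    },
    abort(sprintf("unknown layer type '%s'", ly$type)))
}

layer_backward <- function(ly, cache, dY) {
  switch(ly$type,
    conv = {
      bk <- conv1d_batch_backward(dY, ly$W, cache)
      list(dX = bk$dX, grads = list(W = bk$dW, b = bk$db))
    },
    relu = list(dX = relu_backward(dY, cache), grads = NULL),
    pool = list(dX = maxpool1d_batch_backward(dY, cache), grads = NULL),
    flatten = {
      dX <- dY
      dim(dX) <- cache
      list(dX = dX, grads = NULL)
    },
    dense = list(dX = dY %*% t(ly$W),
                 grads = list(W = crossprod(cache, dY), b = colSums(dY))),
    inception = {
      widths <- cache$widths
      off <- 0L
      dX <- NULL
      grads <- list()
      for (j in seq_along(ly$branches)) {
        dYj <- dY[, , off + seq_len(widths[j]), drop = FALSE]
        off <- off + widths[j]
        dYj <- relu_backward(dYj, cache$mask[[j]])
        bk <- conv1d_batch_backward(dYj, ly$branches[[j]]$W, cache$conv[[j]])
        grads[[sprintf("b%d.W", j)]] <- bk$dW
        grads[[sprintf("b%d.b", j)]] <- bk$db
        dX <- if (is.null(dX)) bk$dX else dX + bk$dX
      }
      dYp <- dY[, , off + seq_len(widths[length(widths)]), drop = FALSE]
      dX <- dX + maxpool1d_batch_backward(dYp, cache$pool)
      list(dX = dX, grads = grads)
    },
    abort(sprintf("unknown layer type '%s'", ly$type)))
}

forward_layers <- function(layers, X, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], X)
    X <- res$out
    if (keep_caches) caches[[i]] <- res$cache
  }
  list(out = X, caches = caches)
}

backward_layers <- function(layers, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- bk$dX
    if (!is.null(bk$grads)) {
      for (nm in names(bk$grads)) {
        key <- if (nm %in% c("W", "b")) sprintf("%d.%s", i, nm)
               else sprintf("%d.%s", i, nm)
        grads[[key]] <- bk$grads[[nm]]
      }
    }
  }
  grads
}

as_input_array <- function(batch, input_length) {
  X <- if (is.matrix(batch)) batch
       else if (is.data.frame(batch) && "values" %in% names(batch)) {
         beats_matrix(batch)
       } else if (is.numeric(batch)) matrix(batch, nrow = 1)
       else abort("`batch` must be a matrix, a normalized-beats tibble, or a vector")
  if (ncol(X) != input_length) {
    abort(sprintf("input length %d does not match the model's input_length %d",
                  ncol(X), input_length))
  }
  array(X, dim = c(nrow(X), ncol(X), 1L))
}

#' Forward pass: class probabilities for a batch of beats
#'
#' @param model An `inception_model` from [build_model()] or [train_model()].
#' @param batch A numeric matrix (one beat per row), a tibble from
#'   [normalize_beats()], or a single numeric vector. Beat length must equal
#'   the model's `input_length`.
#' @return Numeric matrix, one row per beat and one column per class
#'   (softmax probabilities; rows sum to 1).
#' @export
forward <- function(model, batch) {
  stopifnot(inherits(model, "inception_model"))
  X <- as_input_array(batch, model$spec$input_length)
  logits <- forward_layers(model$layers, X)$out
  P <- softmax_rows(logits)
  colnames(P) <- class_names(model)
  P
}

class_names <- function(model) {
  if (model$spec$n_classes == length(beat_classes())) beat_classes()
  else paste0("C", seq_len(model$spec$n_classes))
}

#' Predict beat classes or probabilities
#'
#' @param object An `inception_model`.
#' @param batch Beats as in [forward()].
#' @param type `"class"` for hard labels, `"prob"` for the probability
#'   matrix.
#' @param ... Unused.
#' @return A factor of predicted classes, or the probability matrix.
#' @export
predict.inception_model <- function(object, batch, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  P <- forward(object, batch)
  if (type == "prob") return(P)
  factor(colnames(P)[max.col(P, ties.method = "first")],
         levels = colnames(P))
}
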