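#' Training configuration
#'
#' Optimization settings: Adam with learning rate 0.001, beta1 0.9 and
#' beta2 0.999, mini-batches of 100, 10 epochs, categorical cross-entropy
#' loss. Epsilon (1e-8) and bias correction follow the reference Adam
#' formulation.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size Mini-batch size.
#' @param epochs Passes over the training set (>= 1).
#' @param seed Seed controlling mini-batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 100L, epochs = 10L,
                         seed = 1L) {
  stopifnot(learning_rate >= 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Per-class train/test split plan
#'
#' Requested training and test beat counts per class. The defaults are the
#' standard counts for five-class MIT-BIH experiments: NSR 10,000/5,000,
#' LBBB 6,025/2,000, RBBB 5,728/1,400, APC 1,870/600, PVC 4,928/1,200.
#' When a class has fewer beats than requested, both counts are scaled down
#' proportionally (with a warning), keeping train and test disjoint.
#'
#' @param train,test Named numeric vectors (names = [beat_classes()]) of
#'   requested counts.
#' @param seed Seed for the (without-replacement) sampling.
#' @return A list of class `split_plan`.
#' @export
split_plan <- function(train = c(NSR = 10000, LBBB = 6025, RBBB = 5728,
                                 APC = 1870, PVC = 4928),
                       test = c(NSR = 5000, LBBB = 2000, RBBB = 1400,
                                APC = 600, PVC = 1200),
                       seed = 1L) {
  for (v in list(train, test)) {
    if (!all(beat_classes() %in% names(v))) {
      abort("`train` and `test` must name all five beat classes")
    }
    if (any(v < 0)) abort("counts must be non-negative")
  }
  structure(list(train = train[beat_classes()], test = test[beat_classes()],
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Split normalized beats into disjoint train and test sets
#'
#' Samples, without replacement and deterministically given the plan's
#' seed, the per-class counts the plan requests. Classes with too few beats
#' are scaled down proportionally (train and test together never exceed the
#' available beats); a warning reports the reduction.
#'
#' @param beats A tibble with a `label` column ([normalize_beats()] output).
#' @param plan A [split_plan()].
#' @return A list with tibbles `train` and `test` (disjoint rows of
#'   `beats`).
#' @export
make_split <- function(beats, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  labels <- assert_class_labels(beats$label, "beats$label")
  requested <- names(which(plan$train + plan$test > 0))
  missing_cls <- setdiff(requested, as.character(unique(labels)))
  if (length(missing_cls) > 0) {
    abort(sprintf("class(es) absent from `beats`: %s",
                  paste(missing_cls, collapse = ", ")))
  }
  train_idx <- integer(0)
  test_idx <- integer(0)
  withr::with_seed(plan$seed, {
    for (cls in beat_classes()) {
      pool <- which(labels == cls)
      want_train <- plan$train[[cls]]
      want_test <- plan$test[[cls]]
      want <- want_train + want_test
      if (want == 0) next
      if (length(pool) < want) {
        f <- length(pool) / want
        want_train <- floor(want_train * f)
        want_test <- floor(want_test * f)
        warn(sprintf(
          "class %s: %d beats available for %d requested; scaled to %d/%d",
          cls, length(pool), want, want_train, want_test))
      }
      pick <- sample(pool, want_train + want_test)
      train_idx <- c(train_idx, pick[seq_len(want_train)])
      test_idx <- c(test_idx, pick[want_train + seq_len(want_test)])
    }
  })
  list(train = beats[sort(train_idx), ], test = beats[sort(test_idx), ])
}

#' One Adam parameter update
#'
#' The reference Adam step with bias correction: given gradient `g` at step
#' `t`, updates the first and second moment estimates and returns the new
#' parameter value. Exposed mainly so the update rule can be checked in
#' isolation; [train_model()] uses the same function.
#'
#' @param param,g Parameter array and its gradient (same shape).
#' @param state List with moment arrays `m`, `v` (or `NULL` to start).
#' @param t Step counter (1-based).
#' @param config A [train_config()].
#' @return List with updated `param` and `state`.
#' @export
adam_step <- function(param, g, state, t, config) {
  if (is.null(state)) {
    state <- list(m = param * 0, v = param * 0)  # zeros, same shape as param
  }
  state$m <- config$beta1 * state$m + (1 - config$beta1) * g
  state$v <- config$beta2 * state$v + (1 - config$beta2) * g^2
  m_hat <- state$m / (1 - config$beta1^t)
  v_hat <- state$v / (1 - config$beta2^t)
  param <- param - config$learning_rate * m_hat / (sqrt(v_hat) + config$epsilon)
  list(param = param, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a network on labelled beats
#'
#' Minimizes categorical cross-entropy with mini-batch Adam. Each epoch the
#' training set is reshuffled (seeded, so the whole run is deterministic
#' given model, data and config) and split into batches of
#' `config$batch_size`. The returned model carries a per-epoch trace of
#' mean loss and training accuracy, accessible with [tidy()].
#'
#' @param model An `inception_model` from [build_model()].
#' @param beats Training beats: a tibble from [normalize_beats()] with a
#'   `label` column, or a list `list(x = matrix, y = factor)`.
#' @param config A [train_config()].
#' @return The trained `inception_model`, with `$trace` and
#'   `$train_config` filled in.
#' @export
train_model <- function(model, beats, config = train_config()) {
  stopifnot(inherits(model, "inception_model"), inherits(config, "train_config"))
  if (is.data.frame(beats)) {
    x <- beats_matrix(beats)
    y <- assert_class_labels(beats$label)
  } else {
    x <- beats$x
    y <- factor(beats$y, levels = class_names(model))
  }
  if (is.null(x) || nrow(x) == 0) abort("empty training set")
  if (anyNA(y)) abort("training labels contain values outside the model's classes")
  n <- nrow(x)
  K <- model$spec$n_classes
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  layers <- model$layers
  opt_state <- list()
  t_step <- 0L
  trace <- vector("list", config$epochs)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      correct <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- array(x[idx, , drop = FALSE], dim = c(length(idx), ncol(x), 1L))
        Yb <- Y[idx, , drop = FALSE]
        fw <- forward_layers(layers, Xb, keep_caches = TRUE)
        P <- softmax_rows(fw$out)
        losses <- c(losses, -mean(log(rowSums(P * Yb) + 1e-12)))
        correct <- correct + sum(max.col(P, ties.method = "first") ==
                                   max.col(Yb, ties.method = "first"))
        dLogits <- (P - Yb) / length(idx)
        grads <- backward_layers(layers, fw$caches, dLogits)
        t_step <- t_step + 1L
        params <- get_param_arrays(layers)
        for (nm in names(params)) {
          st <- adam_step(params[[nm]], grads[[nm]], opt_state[[nm]],
                          t_step, config)
          params[[nm]] <- st$param
          opt_state[[nm]] <- st$state
        }
        layers <- set_param_arrays(layers, params)
      }
      trace[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                       accuracy = correct / n)
    }
  })
  model$layers <- layers
  model$trace <- dplyr::bind_rows(trace)
  model$train_config <- config
  model
}

#' Per-epoch training trace of a fitted model
#'
#' @param x A trained `inception_model`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss` and `accuracy`.
#' @method tidy inception_model
#' @export
tidy.inception_model <- function(x, ...) {
  if (is.null(x$trace)) {
    return(tibble::tibble(epoch = integer(), loss = double(),
                          accuracy = double()))
  }
  x$trace
}

#' One-row model summary
#'
#' @param x An `inception_model`.
#' @param ... Unused.
#' @return A tibble with design, input length, parameter count, epochs
#'   trained and final loss/accuracy (NA if untrained).
#' @method glance inception_model
#' @export
glance.inception_model <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    design = x$spec$design,
    input_length = x$spec$input_length,
    n_parameters = n_parameters(x),
    epochs = if (is.null(tr)) 0L else nrow(tr),
    final_loss = if (is.null(tr)) NA_real_ else tr$loss[nrow(tr)],
    final_accuracy = if (is.null(tr)) NA_real_ else tr$accuracy[nrow(tr)]
  )
}

#' Plot the training trace
#'
#' @param object A trained `inception_model`.
#' @param ... Unused.
#' @return A ggplot with loss and training accuracy per epoch.
#' @method autoplot inception_model
#' @export
autoplot.inception_model <- function(object, ...) {
  tr <- tidy.inception_model(object)
  if (nrow(tr) == 0) abort("model has no training trace")
  long <- tidyr::pivot_longer(tr, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
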