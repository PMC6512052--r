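#' Save or load a model as a portable JSON container
#'
#' The container embeds the declarative [model_spec()], the initialization
#' seed, the training configuration and trace (if trained), and every
#' parameter array with its dimensions, at full double precision. Loading
#' restores a model whose [forward()] output is identical to the saved
#' one's.
#'
#' @param model An `inception_model`.
#' @param path File path (conventionally `.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `inception_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "inception_model"))
  params <- get_param_arrays(model$layers)
  obj <- list(
    container = "ecgincept-model",
    version = 1L,
    spec = spec_to_list(model$spec),
    seed = model$seed,
    train_config = if (!is.null(model$train_config)) {
      unclass(model$train_config)
    },
    trace = if (!is.null(model$trace)) as.list(model$trace),
    parameters = lapply(params, function(p) {
      list(dim = as.integer(dim(p) %||% length(p)), values = as.double(p))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$container, "ecgincept-model")) {
    abort(sprintf("%s is not an ecgincept model container", path))
  }
  spec <- spec_from_list(obj$spec)
  model <- build_model(spec, seed = obj$seed)
  params <- lapply(obj$parameters, function(p) {
    array(as.double(unlist(p$values)), dim = as.integer(unlist(p$dim)))
  })
  model$layers <- set_param_arrays(model$layers, params)
  if (!is.null(obj$train_config)) {
    model$train_config <- do.call(train_config, lapply(obj$train_config, unlist))
  }
  if (!is.null(obj$trace) && length(obj$trace) > 0) {
    model$trace <- tibble::as_tibble(lapply(obj$trace, unlist))
  }
  model
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$inception <- lapply(spec$inception, unclass)
  out
}

spec_from_list <- function(lst) {
  incep <- lapply(lst$inception, function(s) {
    inception_spec(unlist(s$kernel_sizes), unlist(s$filters_per_branch),
                   unlist(s$pool_size))
  })
  model_spec(design = lst$design, input_length = lst$input_length,
             inception = incep, cnn_filters = lst$cnn_filters,
             cnn_kernel = lst$cnn_kernel, cnn_stride = lst$cnn_stride,
             fc_widths = unlist(lst$fc_widths), n_classes = lst$n_classes)
}
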