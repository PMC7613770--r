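# Layer containers, initialization, parameter bookkeeping and checkpoints.
#
# A "layer" is a list holding `ag_param` leaves (and, for batch norm, an
# environment of running statistics).  A "model" is an environment with a
# nested list of layers under $layers, a $training flag, and forward
# functions defined elsewhere.  Environments make train/eval switching and
# running-stat updates natural.

kaiming_sd <- function(fan_in, slope = 0.1) sqrt(2 / (1 + slope^2)) / sqrt(fan_in)

#' 2-D convolution layer
#' @param cin,cout channel counts; k kernel; stride,pad geometry
#' @param bias include a bias vector (convolutions feeding batch norm do not)
#' @keywords internal
layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L, bias = FALSE,
                       init_sd = NULL) {
  fan_in <- k * k * cin
  sd <- if (is.null(init_sd)) kaiming_sd(fan_in) else init_sd
  W <- ag_param(matrix(stats::rnorm(fan_in * cout, sd = sd), fan_in, cout))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  list(type = "conv", W = W, b = b, k = k, stride = stride, pad = pad,
       cin = cin, cout = cout)
}

#' Transposed 2-D convolution layer (4x4, stride 2, pad 1 — exact x2 upsampling)
#' @keywords internal
layer_convT <- function(cin, cout, k = 4L, stride = 2L, pad = 1L, bias = FALSE) {
  fan_in <- k * k * cin
  W <- ag_param(matrix(stats::rnorm(fan_in * cout, sd = kaiming_sd(fan_in)), fan_in, cout))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  list(type = "convT", W = W, b = b, k = k, stride = stride, pad = pad,
       cin = cin, cout = cout)
}

#' Batch-normalization layer (affine, running statistics)
#' @keywords internal
layer_bn <- function(c) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(c)
  state$running_var <- rep(1, c)
  list(type = "bn", gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
       state = state, c = c)
}

fwd_conv <- function(layer, x) {
  ag_conv2d(x, layer$W, layer$b, k = layer$k, stride = layer$stride, pad = layer$pad)
}

fwd_convT <- function(layer, x) {
  ag_conv_transpose2d(x, layer$W, layer$b, k = layer$k, stride = layer$stride,
                      pad = layer$pad)
}

fwd_bn <- function(layer, x, training) {
  ag_batchnorm(x, layer$gamma, layer$beta, layer$state, training = training)
}

# conv -> bn -> LeakyReLU(0.1), the standard block in this architecture
fwd_cbl <- function(conv, bn, x, training, slope = 0.1) {
  ag_leaky_relu(fwd_bn(bn, fwd_conv(conv, x), training), slope)
}

# ---- parameter bookkeeping -------------------------------------------------

# Recursively collect ag_param leaves (named by path) from a nested list.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (is_ag(x)) {
    if (isTRUE(x$is_param)) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      out <- c(out, collect_params(x[[i]], key))
    }
  }
  out
}

# Collect batch-norm state environments, named by path.
collect_bn_states <- function(x, prefix = "") {
  out <- list()
  if (is.list(x)) {
    if (identical(x$type, "bn")) {
      out[[prefix]] <- x$state
      return(out)
    }
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      out <- c(out, collect_bn_states(x[[i]], key))
    }
  }
  out
}

#' Number of trainable scalar parameters in a nested layer structure
#' @keywords internal
n_params <- function(layers) {
  sum(vapply(collect_params(layers), function(p) length(p$value), numeric(1)))
}

# ---- checkpoints -----------------------------------------------------------

#' Extract a flat named-parameter archive from a model
#'
#' The archive holds every trainable parameter plus batch-norm running
#' statistics, a variant tag and a framework-version field.
#' @param model a model environment from [model_factory()]
#' @return a list suitable for [save_checkpoint()]
#' @export
state_dict <- function(model) {
  ps <- collect_params(model$layers)
  bs <- collect_bn_states(model$layers)
  list(
    format_version = 1L,
    variant = model$variant,
    heads = model$heads,
    width_scale = model$width_scale,
    max_disparity = model$max_disparity,
    params = lapply(ps, function(p) p$value),
    bn_running = lapply(bs, function(s)
      list(mean = s$running_mean, var = s$running_var))
  )
}

#' Load a flat named-parameter archive into a model
#'
#' Rejects archives whose encoder variant does not match the model's.
#' Parameters present in the archive overwrite the model's; parameters absent
#' from the archive (e.g. a head the source model never had) are left at
#' their current initialization.
#' @param model model environment; sd archive from [state_dict()]
#' @param strict error when the archive misses parameters the model has
#' @return the model, invisibly
#' @export
load_state_dict <- function(model, sd, strict = FALSE) {
  if (!identical(sd$variant, model$variant))
    stop(sprintf("checkpoint variant '%s' does not match model variant '%s'",
                 sd$variant, model$variant))
  ps <- collect_params(model$layers)
  for (nm in names(ps)) {
    if (!is.null(sd$params[[nm]])) {
      stopifnot(length(sd$params[[nm]]) == length(ps[[nm]]$value))
      ps[[nm]]$value <- sd$params[[nm]]
    } else if (strict) stop(sprintf("checkpoint is missing parameter '%s'", nm))
  }
  bs <- collect_bn_states(model$layers)
  for (nm in names(bs)) {
    if (!is.null(sd$bn_running[[nm]])) {
      bs[[nm]]$running_mean <- sd$bn_running[[nm]]$mean
      bs[[nm]]$running_var <- sd$bn_running[[nm]]$var
    }
  }
  invisible(model)
}

#' Save / load a checkpoint file
#' @param model model environment
#' @param path file path (RDS serialization)
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(state_dict(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param strict passed to [load_state_dict()]
#' @export
load_checkpoint <- function(model, path, strict = FALSE) {
  load_state_dict(model, readRDS(path), strict = strict)
}
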