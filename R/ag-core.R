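# Reverse-mode automatic differentiation on dense numeric arrays.
#
# The engine is deliberately small: a global tape records operation nodes in
# creation order (which is a topological order), and `ag_backward()` walks it
# in reverse, calling each node's pullback to accumulate gradients into its
# parents.  Arrays are plain base-R arrays in H x W x C (column-major) layout.
# When no tape is recording, every operation degrades to a plain numeric
# computation and returns a bare array, so inference costs nothing extra.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

#' Is an object an autodiff node?
#' @param x any object
#' @return logical scalar
#' @keywords internal
is_ag <- function(x) inherits(x, "ag_node")

#' Extract the numeric value of a node (identity on plain arrays)
#' @param x node or array
#' @return numeric array
#' @keywords internal
ag_value <- function(x) if (is_ag(x)) x$value else x

ag_requires_grad <- function(x) is_ag(x) && isTRUE(x$req)

#' Create a gradient-tracked leaf (an input one wants gradients for)
#' @param value numeric array
#' @return an `ag_node` leaf
#' @keywords internal
ag_input <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$req <- TRUE
  n$parents <- list()
  n$pullback <- NULL
  class(n) <- "ag_node"
  if (.ag$recording) ag_record(n)
  n
}

#' Create a trainable parameter leaf
#'
#' Parameter nodes persist across tapes; their gradients accumulate during
#' [ag_backward()] and are consumed/zeroed by the optimizer.
#' @param value numeric array of initial values
#' @return an `ag_node` marked as parameter
#' @keywords internal
ag_param <- function(value) {
  n <- ag_input(value)
  n$is_param <- TRUE
  n
}

ag_record <- function(node) {
  .ag$n <- .ag$n + 1L
  .ag$tape[[.ag$n]] <- node
  invisible(node)
}

# Construct an interior node.  `pullback(grad)` must return a list of
# gradients aligned with `parents` (NULL entries allowed for parents that do
# not need gradients).  If no tape is active or no parent requires a
# gradient, the bare value is returned instead of a node.
ag_op <- function(value, parents, pullback) {
  if (!.ag$recording) return(value)
  req <- vapply(parents, ag_requires_grad, logical(1))
  if (!any(req)) return(value)
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$req <- TRUE
  n$parents <- parents
  n$preq <- req
  n$pullback <- pullback
  class(n) <- "ag_node"
  ag_record(n)
  n
}

#' Evaluate an expression while recording a fresh gradient tape
#' @param expr expression building a scalar loss from `ag_param`/`ag_input` leaves
#' @return the expression's value (usually an `ag_node`)
#' @keywords internal
ag_with_tape <- function(expr) {
  old_rec <- .ag$recording; old_tape <- .ag$tape; old_n <- .ag$n
  .ag$recording <- TRUE
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  on.exit({ .ag$recording <- old_rec; .ag$tape <- old_tape; .ag$n <- old_n })
  expr
}

# Accumulate `g` into node's grad slot.
ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#'
#' Walks the active tape in reverse creation order; afterwards every
#' parameter/input leaf reachable from `loss` carries its gradient in `$grad`.
#' Must be called inside the [ag_with_tape()] call that built `loss`.
#' @param loss an `ag_node` holding a scalar
#' @param seed gradient seeded at the loss (default 1)
#' @keywords internal
ag_backward <- function(loss, seed = 1) {
  if (!is_ag(loss)) stop("loss is not a gradient-tracked node; was a tape recording?")
  ag_accum(loss, seed)
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (is.null(node$grad) || is.null(node$pullback)) next
    gs <- node$pullback(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      if (node$preq[j] && !is.null(gs[[j]])) ag_accum(ps[[j]], gs[[j]])
    }
    # free intermediate grads/values early to bound memory
    if (!isTRUE(node$is_param)) node$grad <- NULL
  }
  invisible(NULL)
}

#' Zero the gradient buffers of a list of parameters
#' @param params list of `ag_node` parameters
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
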