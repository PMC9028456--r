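#' @useDynLib cowreid, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reverse-mode automatic differentiation over numeric arrays.
#
# A "tape" records operation nodes in creation order while `ag_recording()`
# is active; creation order is a valid topological order for a dynamically
# built graph, so `ag_backward()` simply walks it in reverse. Nodes are
# environments so gradient accumulation mutates in place. Parameters
# (`ag_param`) live outside the tape and persist across iterations; their
# gradients accumulate until `ag_zero_grad()`.

.autograd <- new.env(parent = emptyenv())
.autograd$recording <- FALSE
.autograd$nodes <- vector("list", 0L)
.autograd$n <- 0L

is_node <- function(x) inherits(x, "ag_node")

#' Numeric value of a node or plain array
#' @param x an `ag_node` or numeric array
#' @return the underlying numeric value
#' @keywords internal
ag_value <- function(x) if (is_node(x)) x$value else x

ag_node <- function(value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  class(node) <- "ag_node"
  if (.autograd$recording && !is.null(backward)) {
    node$backward <- backward
    n <- .autograd$n + 1L
    if (n > length(.autograd$nodes))
      length(.autograd$nodes) <- max(64L, 2L * n)
    .autograd$nodes[[n]] <- node
    .autograd$n <- n
  }
  node
}

#' Create a trainable parameter
#'
#' Parameters receive gradients during [ag_backward()] and carry the momentum
#' buffer used by the SGD step.
#' @param value initial numeric array
#' @param name optional label used in diagnostics
#' @return an `ag_node` with `$param = TRUE`
#' @keywords internal
ag_param <- function(value, name = NULL) {
  node <- ag_node(value)
  node$param <- TRUE
  node$name <- name
  node$momentum <- NULL
  node
}

ag_accum <- function(node, g) {
  if (!is_node(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ag_reset_tape <- function() {
  .autograd$nodes <- vector("list", 0L)
  .autograd$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression while recording operations for backpropagation
#' @param expr expression building the computation graph
#' @return the value of `expr`
#' @keywords internal
ag_record <- function(expr) {
  old <- .autograd$recording
  .autograd$recording <- TRUE
  ag_reset_tape()
  on.exit(.autograd$recording <- old)
  expr
}

#' Evaluate an expression with recording disabled (inference mode)
#' @param expr expression
#' @return the value of `expr`
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .autograd$recording
  .autograd$recording <- FALSE
  on.exit(.autograd$recording <- old)
  expr
}

#' Backpropagate from a scalar loss node through the recorded tape
#' @param loss an `ag_node` holding a scalar
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  n <- .autograd$n
  if (n > 0L) {
    for (i in n:1L) {
      node <- .autograd$nodes[[i]]
      if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
    }
  }
  ag_reset_tape()
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# SGD with classical momentum and decoupled-from-nothing L2 weight decay
# (gradient + wd * w enters the momentum buffer, as in standard SGD
# implementations). `lr` is applied to the updated buffer.
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    if (momentum > 0) {
      p$momentum <- if (is.null(p$momentum)) g else momentum * p$momentum + g
      g <- p$momentum
    }
    p$value <- p$value - lr * g
  }
  invisible(NULL)
}
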