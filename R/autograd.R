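#' @useDynLib yologinseng, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- reverse-mode tape ----------------------------------------------------
# A node is an environment holding the forward value, its parents on the tape
# and a vector-Jacobian product closure. Creation order doubles as a valid
# topological order because graphs are built strictly forward.

.ag <- new.env(parent = emptyenv())
.ag$serial <- 0L

ag_node <- function(val, parents = list(), vjp = NULL, pid = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$serial <- .ag$serial + 1L
  e$id <- .ag$serial
  e$val <- val
  e$parents <- parents
  e$vjp <- vjp
  e$pid <- pid
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

is_node <- function(x) inherits(x, "ag_node")

#' @keywords internal
vof <- function(x) if (is_node(x)) x$val else x

# Wrap a forward result: records a tape node when any input is a node.
# `vjp` receives the output gradient and must return a list of gradients,
# one per element of `inputs` (NULL for non-node inputs is tolerated).
ag_op <- function(val, inputs, vjp) {
  if (!any(vapply(inputs, is_node, logical(1)))) return(val)
  ag_node(val, parents = inputs, vjp = vjp)
}

ag_leaf <- function(val, pid = NULL) ag_node(val, pid = pid)

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Reverse-mode sweep from a scalar loss node.
#'
#' Accumulates gradients into every reachable leaf; leaves carrying a `pid`
#' additionally deposit their gradient into the `grads` environment under
#' that name (summed if already present).
#' @keywords internal
ag_backward <- function(loss, grads = NULL) {
  stopifnot(is_node(loss))
  # collect reachable nodes
  stack <- list(loss); seen <- new.env(parent = emptyenv()); nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) if (is_node(p)) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- array(1, dim = dim(loss$val) %||% 1L)
  if (is.null(dim(loss$val))) loss$grad <- rep(1, length(loss$val))
  for (i in ord) {
    n <- nodes[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$pid) && !is.null(grads)) {
      if (is.null(grads[[n$pid]])) grads[[n$pid]] <- n$grad
      else grads[[n$pid]] <- grads[[n$pid]] + n$grad
    }
    if (!is.null(n$vjp)) {
      gs <- n$vjp(n$grad)
      for (k in seq_along(n$parents)) {
        p <- n$parents[[k]]
        if (is_node(p) && !is.null(gs[[k]])) acc_grad(p, gs[[k]])
      }
      n$grad <- NULL  # free interior activations as we go; leaves keep theirs
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Central-difference gradient check used by the test-suite helpers.
#' @keywords internal
ag_gradcheck <- function(f, xs, eps = 1e-5) {
  leaves <- lapply(xs, ag_leaf)
  loss <- f(leaves)
  ag_backward(loss)
  out <- list()
  for (k in seq_along(xs)) {
    x <- xs[[k]]
    num <- array(0, dim = dim(x) %||% length(x))
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      args_p <- xs; args_p[[k]] <- xp
      args_m <- xs; args_m[[k]] <- xm
      num[i] <- (vof(f(args_p)) - vof(f(args_m))) / (2 * eps)
    }
    out[[k]] <- list(analytic = leaves[[k]]$grad %||% (num * 0), numeric = num)
  }
  out
}
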