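# Minimal reverse-mode automatic differentiation over numeric matrices.
#
# Every differentiable quantity is an `ad_node` (an environment holding a
# value, its parents and a backward closure). Node creation order is a
# topological order of the graph, so backpropagation just walks nodes in
# reverse id order. The engine is deliberately small: exactly the operator
# set the emotion-recognition networks need, each with a hand-written
# vector-Jacobian product. Gradients are checked against finite differences
# in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1L)
}

ad_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  class(e) <- "ad_node"
  e
}

#' Wrap a numeric matrix as an autodiff leaf
#'
#' Leaves created with `ad_param()` receive gradients from [ad_backward()];
#' `ad_const()` leaves do not differ structurally but signal intent.
#'
#' @param v Numeric vector/matrix (vectors become 1-row matrices).
#' @return An `ad_node`.
#' @export
ad_param <- function(v) ad_node(as_mat(v))

#' @rdname ad_param
#' @export
ad_const <- function(v) ad_node(as_mat(v))

#' Value of an autodiff node
#' @param x An `ad_node`.
#' @return The numeric matrix held by the node.
#' @export
ad_value <- function(x) x$value

#' Gradient accumulated at a node by the last [ad_backward()] call
#' @param x An `ad_node`.
#' @return Numeric matrix of the same shape as the value (or NULL).
#' @export
ad_grad <- function(x) x$grad

#' Reverse-mode backward pass
#'
#' Seeds the root (a scalar node, typically a loss) with gradient 1 and
#' accumulates gradients into every reachable node.
#'
#' @param root Scalar `ad_node`.
#' @return Invisibly, the root.
#' @export
ad_backward <- function(root) {
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack) > 0) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      nodes[[length(nodes) + 1L]] <- n
      for (p in n$parents) stack[[length(stack) + 1L]] <- p
    }
  }
  ids <- vapply(nodes, function(n) n$id, 0L)
  nodes <- nodes[order(ids, decreasing = TRUE)]
  for (n in nodes) n$grad <- NULL
  root$grad <- matrix(1, nrow(root$value), ncol(root$value))
  for (n in nodes) {
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (i in seq_along(n$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- n$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- primitive operators ------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# a (n x m) plus a 1 x m bias row, recycled over rows
ad_addbias <- function(a, bias) {
  ad_node(sweep(a$value, 2L, as.vector(bias$value), `+`), list(a, bias),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

# scale each row of a (n x m) by the matching entry of s (n x 1)
ad_rowscale <- function(a, s) {
  sv <- as.vector(s$value)
  ad_node(a$value * sv, list(a, s), function(g) {
    list(g * sv, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

ad_scale <- function(a, k) {
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_node(v, list(a), function(g) list(g * (1 - v^2)))
}

ad_exp <- function(a) {
  v <- exp(a$value)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  ad_node(log(a$value), list(a), function(g) list(g / a$value))
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(a) {
  n <- length(a$value)
  ad_node(matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

ad_rowsums <- function(a) {
  ad_node(matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    list(matrix(as.vector(g), nrow(a$value), ncol(a$value)))
  })
}

ad_colsums <- function(a) {
  ad_node(matrix(colSums(a$value), nrow = 1L), list(a), function(g) {
    list(matrix(as.vector(g), nrow(a$value), ncol(a$value), byrow = TRUE))
  })
}

ad_t <- function(a) {
  ad_node(t(a$value), list(a), function(g) list(t(g)))
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, `[[`, "value")
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_slice_rows <- function(a, idx) {
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[idx, ] <- out[idx, ] + g
    list(out)
  })
}

ad_slice_cols <- function(a, idx) {
  ad_node(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

# tile a 1 x m row `times` times along columns -> 1 x (m*times)
ad_tile_cols <- function(a, times) {
  m <- ncol(a$value)
  ad_node(matrix(rep(as.vector(a$value), times), 1L), list(a), function(g) {
    acc <- matrix(0, 1L, m)
    for (t in seq_len(times)) acc <- acc + g[, ((t - 1L) * m + 1L):(t * m), drop = FALSE]
    list(acc)
  })
}

ad_pmax <- function(a, b) {
  amax <- a$value >= b$value
  ad_node(pmax(a$value, b$value), list(a, b), function(g) {
    list(g * amax, g * (!amax))
  })
}

# rows normalized to unit Euclidean norm
ad_rownorm <- function(a, eps = 1e-12) {
  r <- sqrt(rowSums(a$value^2)) + eps
  v <- a$value / r
  ad_node(v, list(a), function(g) {
    dot <- rowSums(g * v)
    list(g / r - v * (dot / r))
  })
}

ad_logsumexp_rows <- function(a) {
  mx <- apply(a$value, 1L, max)
  e <- exp(a$value - mx)
  se <- rowSums(e)
  sm <- e / se
  ad_node(matrix(log(se) + mx, ncol = 1L), list(a), function(g) {
    list(sm * as.vector(g))
  })
}

ad_softmax_rows <- function(a) {
  mx <- apply(a$value, 1L, max)
  e <- exp(a$value - mx)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

# M' x (B*N) column-stacked batch -> (B*M') x N row-stacked batch
ad_colstack_to_rowstack <- function(x, B) {
  mp <- nrow(x$value)
  n <- ncol(x$value) %/% B
  fwd <- function(v) {
    arr <- array(v, c(mp, n, B))
    matrix(aperm(arr, c(1L, 3L, 2L)), mp * B, n)
  }
  bwd <- function(g) {
    arr <- array(g, c(mp, B, n))
    matrix(aperm(arr, c(1L, 3L, 2L)), mp, n * B)
  }
  ad_node(fwd(x$value), list(x), function(g) list(bwd(g)))
}

# (B*M') x K row-stacked batch -> B x (M'*K): sample b's row is its matrix
# flattened column-major (row index fastest within each column block).
ad_rowstack_to_batchmat <- function(x, B) {
  k <- ncol(x$value)
  mp <- nrow(x$value) %/% B
  fwd <- function(v) {
    arr <- array(v, c(mp, B, k))
    matrix(aperm(arr, c(2L, 1L, 3L)), B, mp * k)
  }
  bwd <- function(g) {
    arr <- array(g, c(B, mp, k))
    matrix(aperm(arr, c(2L, 1L, 3L)), mp * B, k)
  }
  ad_node(fwd(x$value), list(x), function(g) list(bwd(g)))
}

# ---- parameter plumbing -------------------------------------------------

# Recursively wrap every numeric leaf of a nested parameter list in
# ad_param nodes, preserving structure.
ad_wrap_params <- function(params) {
  if (is.numeric(params)) return(ad_param(params))
  lapply(params, ad_wrap_params)
}

# Flatten the wrapped tree into a named list of nodes (names joined by ".")
ad_param_leaves <- function(wrapped, prefix = NULL) {
  if (inherits(wrapped, "ad_node")) {
    out <- list(wrapped)
    names(out) <- prefix %||% "param"
    return(out)
  }
  nms <- names(wrapped) %||% as.character(seq_along(wrapped))
  out <- list()
  for (i in seq_along(wrapped)) {
    p <- if (is.null(prefix)) nms[i] else paste(prefix, nms[i], sep = ".")
    out <- c(out, ad_param_leaves(wrapped[[i]], p))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric leaves of a nested parameter list, flattened to one vector
flatten_params <- function(params) {
  if (is.numeric(params)) return(as.vector(params))
  unlist(lapply(params, flatten_params), use.names = FALSE)
}

# Inverse of flatten_params: pour a vector back into the template structure
unflatten_params <- function(template, vec) {
  fill <- function(tpl, offset) {
    if (is.numeric(tpl)) {
      n <- length(tpl)
      out <- tpl
      out[] <- vec[(offset + 1L):(offset + n)]
      return(list(value = out, offset = offset + n))
    }
    res <- tpl
    for (i in seq_along(tpl)) {
      r <- fill(tpl[[i]], offset)
      res[[i]] <- r$value
      offset <- r$offset
    }
    list(value = res, offset = offset)
  }
  fill(template, 0L)$value
}

# Central finite-difference gradient of f (scalar-valued over a nested
# parameter list), used by the gradient-correctness tests.
numeric_grad <- function(f, params, eps = 1e-5) {
  v <- flatten_params(params)
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    g[i] <- (f(unflatten_params(params, vp)) - f(unflatten_params(params, vm))) /
      (2 * eps)
  }
  g
}

# Collect analytic gradients (after ad_backward) in flatten_params order
collect_grads <- function(wrapped) {
  if (inherits(wrapped, "ad_node")) {
    g <- wrapped$grad
    if (is.null(g)) g <- matrix(0, nrow(wrapped$value), ncol(wrapped$value))
    return(as.vector(g))
  }
  unlist(lapply(wrapped, collect_grads), use.names = FALSE)
}
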