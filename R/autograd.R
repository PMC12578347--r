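# Tape-based reverse-mode automatic differentiation over base-R matrices.
#
# Every differentiable quantity is a `pf_tensor`: an environment holding a
# numeric matrix `value`, an accumulated `grad`, the `parents` it was computed
# from and a `backward` function that maps the node's output gradient to a
# list of parent gradients.  Nodes receive a monotone id at creation, so the
# creation order is already a topological order of the computation graph and
# `pf_backward()` can propagate gradients by a single reverse sweep.

.pf <- new.env(parent = emptyenv())
.pf$counter <- 0L

pf_next_id <- function() {
  .pf$counter <- .pf$counter + 1L
  .pf$counter
}

#' Create an autodiff tensor
#'
#' Wraps a numeric matrix (or vector, promoted to a one-column matrix) as a
#' node in the reverse-mode autodiff graph.
#'
#' @param value Numeric matrix or vector.
#' @param requires_grad Should gradients be accumulated for this leaf?
#' @return A `pf_tensor` (environment) with fields `value` and, after
#'   [pf_backward()], `grad`.
#' @export
pf_tensor <- function(value, requires_grad = FALSE) {
  if (!is.matrix(value)) value <- matrix(as.numeric(value), ncol = 1L)
  storage.mode(value) <- "double"
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$backward <- NULL
  node$requires <- isTRUE(requires_grad)
  node$id <- pf_next_id()
  class(node) <- "pf_tensor"
  node
}

#' @export
print.pf_tensor <- function(x, ...) {
  cat(sprintf("<pf_tensor %dx%d id=%d%s>\n", nrow(x$value), ncol(x$value),
              x$id, if (x$requires) " grad" else ""))
  invisible(x)
}

pf_const <- function(value) pf_tensor(value, requires_grad = FALSE)

is_pf <- function(x) inherits(x, "pf_tensor")

as_pf <- function(x) if (is_pf(x)) x else pf_const(x)

# internal node constructor; `backward` takes the output gradient matrix and
# returns a list of gradients, one per parent (NULL for parents that need none)
pf_node <- function(value, parents, backward) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  node$id <- pf_next_id()
  class(node) <- "pf_tensor"
  node
}

#' Run the backward pass from a scalar loss node
#'
#' Accumulates `grad` fields on every `requires_grad` leaf reachable from
#' `node`. Existing gradients are overwritten, not accumulated across calls.
#'
#' @param node A `pf_tensor` holding a 1x1 value.
#' @export
pf_backward <- function(node) {
  stopifnot(is_pf(node), length(node$value) == 1L)
  # collect reachable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(node)
  nodes <- list()
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(cur$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- cur
    for (p in cur$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  for (n in nodes) n$grad <- NULL
  node$grad <- matrix(1, 1L, 1L)
  for (n in nodes) {
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!p$requires || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(node)
}

# reduce a gradient to the shape of the (possibly broadcast) operand
pf_reduce_to <- function(g, target) {
  if (nrow(target) == nrow(g) && ncol(target) == ncol(g)) return(g)
  if (nrow(target) == 1L && ncol(target) == ncol(g)) {
    return(matrix(colSums(g), 1L))
  }
  if (length(target) == 1L) return(matrix(sum(g), 1L, 1L))
  stop("pf: cannot reduce gradient of dim ", nrow(g), "x", ncol(g),
       " to ", nrow(target), "x", ncol(target))
}

# broadcast b (same-shape, 1-row, or scalar) to the shape of a
pf_bcast <- function(b, nr, nc) {
  if (nrow(b) == nr && ncol(b) == nc) return(b)
  if (nrow(b) == 1L && ncol(b) == nc) return(matrix(b, nr, nc, byrow = TRUE))
  if (length(b) == 1L) return(matrix(b[1L], nr, nc))
  stop("pf: incompatible broadcast ", nrow(b), "x", ncol(b), " to ", nr, "x", nc)
}

#' @rdname pf_ops
#' @export
pf_add <- function(a, b) {
  a <- as_pf(a); b <- as_pf(b)
  v <- a$value + pf_bcast(b$value, nrow(a$value), ncol(a$value))
  pf_node(v, list(a, b), function(g) {
    list(g, pf_reduce_to(g, b$value))
  })
}

#' @rdname pf_ops
#' @export
pf_sub <- function(a, b) {
  a <- as_pf(a); b <- as_pf(b)
  v <- a$value - pf_bcast(b$value, nrow(a$value), ncol(a$value))
  pf_node(v, list(a, b), function(g) {
    list(g, -pf_reduce_to(g, b$value))
  })
}

#' Elementwise and matrix operations on autodiff tensors
#'
#' Elementwise arithmetic supports broadcasting of the second operand when it
#' is a scalar or a single-row matrix.
#'
#' @param a,b `pf_tensor` objects (plain matrices are promoted to constants).
#' @name pf_ops
#' @export
pf_mul <- function(a, b) {
  a <- as_pf(a); b <- as_pf(b)
  bb <- pf_bcast(b$value, nrow(a$value), ncol(a$value))
  v <- a$value * bb
  pf_node(v, list(a, b), function(g) {
    list(g * bb, pf_reduce_to(g * a$value, b$value))
  })
}

#' @rdname pf_ops
#' @export
pf_div <- function(a, b) {
  a <- as_pf(a); b <- as_pf(b)
  bb <- pf_bcast(b$value, nrow(a$value), ncol(a$value))
  v <- a$value / bb
  pf_node(v, list(a, b), function(g) {
    list(g / bb, pf_reduce_to(-g * a$value / (bb * bb), b$value))
  })
}

#' @rdname pf_ops
#' @export
pf_matmul <- function(a, b) {
  a <- as_pf(a); b <- as_pf(b)
  v <- a$value %*% b$value
  pf_node(v, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

#' @rdname pf_ops
#' @export
pf_scale <- function(a, s) {
  a <- as_pf(a)
  pf_node(a$value * s, list(a), function(g) list(g * s))
}

#' @rdname pf_ops
#' @export
pf_addc <- function(a, cst) {
  a <- as_pf(a)
  pf_node(a$value + cst, list(a), function(g) list(g))
}

#' @rdname pf_ops
#' @export
pf_sigmoid <- function(a) {
  a <- as_pf(a)
  s <- 1 / (1 + exp(-a$value))
  pf_node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' @rdname pf_ops
#' @export
pf_tanh <- function(a) {
  a <- as_pf(a)
  t <- tanh(a$value)
  pf_node(t, list(a), function(g) list(g * (1 - t * t)))
}

#' @rdname pf_ops
#' @export
pf_relu <- function(a) {
  a <- as_pf(a)
  keep <- a$value > 0
  pf_node(a$value * keep, list(a), function(g) list(g * keep))
}

#' @rdname pf_ops
#' @export
pf_lrelu <- function(a, slope = 0.2) {
  a <- as_pf(a)
  fac <- ifelse(a$value > 0, 1, slope)
  pf_node(a$value * fac, list(a), function(g) list(g * fac))
}

#' @rdname pf_ops
#' @export
pf_exp <- function(a) {
  a <- as_pf(a)
  e <- exp(a$value)
  pf_node(e, list(a), function(g) list(g * e))
}

#' @rdname pf_ops
#' @export
pf_log <- function(a) {
  a <- as_pf(a)
  pf_node(log(a$value), list(a), function(g) list(g / a$value))
}

#' @rdname pf_ops
#' @export
pf_pow <- function(a, p) {
  a <- as_pf(a)
  pf_node(a$value^p, list(a), function(g) list(g * p * a$value^(p - 1)))
}

# min(a, cst) elementwise with a constant
#' @rdname pf_ops
#' @export
pf_pmin_const <- function(a, cst) {
  a <- as_pf(a)
  keep <- a$value < cst
  pf_node(pmin(a$value, cst), list(a), function(g) list(g * keep))
}

#' @rdname pf_ops
#' @export
pf_colsums <- function(a) {
  a <- as_pf(a)
  nr <- nrow(a$value)
  pf_node(matrix(colSums(a$value), 1L), list(a), function(g) {
    list(matrix(g, nr, ncol(g), byrow = TRUE))
  })
}

#' @rdname pf_ops
#' @export
pf_sum <- function(a) {
  a <- as_pf(a)
  dims <- dim(a$value)
  pf_node(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], dims[1L], dims[2L]))
  })
}

#' @rdname pf_ops
#' @export
pf_mean <- function(a) {
  a <- as_pf(a)
  dims <- dim(a$value)
  n <- length(a$value)
  pf_node(matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L] / n, dims[1L], dims[2L]))
  })
}

# column-block concatenation
#' @rdname pf_ops
#' @export
pf_cbind <- function(parts) {
  parts <- lapply(parts, as_pf)
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  v <- do.call(cbind, lapply(parts, function(p) p$value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  pf_node(v, parts, function(g) {
    lapply(seq_along(parts), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

#' @rdname pf_ops
#' @export
pf_cols <- function(a, from, to) {
  a <- as_pf(a)
  nc <- ncol(a$value)
  pf_node(a$value[, from:to, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, from:to] <- g
    list(out)
  })
}

# Row gather with implicit zero row: idx[i] == 0 yields a zero row; backward
# scatter-adds into the gathered rows.  Used for embeddings and im2col.
#' @rdname pf_ops
#' @export
pf_rows <- function(a, idx) {
  a <- as_pf(a)
  nr <- nrow(a$value)
  nc <- ncol(a$value)
  keep <- idx > 0L
  v <- matrix(0, length(idx), nc)
  v[keep, ] <- a$value[idx[keep], , drop = FALSE]
  pf_node(v, list(a), function(g) {
    if (!any(keep)) return(list(matrix(0, nr, nc)))
    acc <- rowsum(g[keep, , drop = FALSE], group = idx[keep])
    out <- matrix(0, nr, nc)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# replicate every column `k` times in place: (r x n) -> (r x n*k)
#' @rdname pf_ops
#' @export
pf_rep_cols <- function(a, k) {
  a <- as_pf(a)
  n <- ncol(a$value)
  v <- a$value[, rep(seq_len(n), each = k), drop = FALSE]
  pf_node(v, list(a), function(g) {
    out <- matrix(0, nrow(g), n)
    for (j in seq_len(k)) out <- out + g[, (seq_len(n) - 1L) * k + j, drop = FALSE]
    list(out)
  })
}

# zero out rows where mask is FALSE
#' @rdname pf_ops
#' @export
pf_mask_rows <- function(a, mask) {
  a <- as_pf(a)
  m <- as.numeric(mask)
  pf_node(a$value * m, list(a), function(g) list(g * m))
}

# inverted-scale dropout; `keep` mask supplied by the caller for determinism
pf_dropout <- function(a, rate, keep = NULL) {
  a <- as_pf(a)
  if (rate <= 0) return(a)
  if (is.null(keep)) {
    keep <- matrix(stats::runif(length(a$value)) >= rate,
                   nrow(a$value), ncol(a$value))
  }
  fac <- keep / (1 - rate)
  pf_node(a$value * fac, list(a), function(g) list(g * fac))
}

#' Row-wise layer normalization with learned gain and bias
#'
#' @param x `pf_tensor` (n x d); `gain`, `bias` are 1 x d tensors.
#' @param eps Variance floor.
#' @export
pf_layernorm <- function(x, gain, bias, eps = 1e-5) {
  x <- as_pf(x); gain <- as_pf(gain); bias <- as_pf(bias)
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gvec <- as.numeric(gain$value)
  y <- sweep(xhat, 2L, gvec, "*")
  y <- sweep(y, 2L, as.numeric(bias$value), "+")
  pf_node(y, list(x, gain, bias), function(g) {
    dgain <- matrix(colSums(g * xhat), 1L)
    dbias <- matrix(colSums(g), 1L)
    dxhat <- sweep(g, 2L, gvec, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    list(dx, dgain, dbias)
  })
}

#' Embedding lookup
#'
#' Gathers rows of an embedding matrix by token index; index 0 (padding)
#' yields a zero row and receives no gradient.
#'
#' @param E `pf_tensor` of shape (vocab x d), row r for token r.
#' @param tokens Integer vector in `0:vocab`.
#' @export
pf_embedding <- function(E, tokens) pf_rows(E, as.integer(tokens))
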