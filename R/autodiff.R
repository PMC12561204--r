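#' @title Minimal reverse-mode automatic differentiation on matrices
#'
#' @description
#' All stage models in this package (the tabular transformer encoder, the
#' cross-attention fusion, the modality weight networks, the edge-aware
#' graph transformer, the VAE aligner and the contrastive projections) are
#' trained by gradient descent. No deep-learning framework is assumed:
#' instead the package carries a small tape-based reverse-mode autodiff
#' engine over dense matrices. Every value on the tape is a numeric matrix
#' (scalars are 1x1), nodes record their parents and a backward closure,
#' and \code{tp_backward()} replays the tape in reverse creation order.
#'
#' The engine is deliberately small: only the operations the models need
#' are implemented, and each is checked against central finite differences
#' in the test suite.
#'
#' @name autodiff
#' @keywords internal
NULL

#' Create a fresh autodiff tape
#'
#' @return An environment holding the node list; pass it to every `tp_*` op.
#' @export
tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

node_new <- function(tape, value, parents = list(), bw = NULL, needs_grad = NA) {
  if (!is.matrix(value)) value <- as.matrix(value)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  if (is.na(needs_grad)) {
    needs_grad <- any(vapply(parents, function(p) p$needs_grad, logical(1)))
  }
  nd$needs_grad <- needs_grad
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

acc_grad <- function(p, g) {
  if (isTRUE(p$needs_grad)) {
    if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  }
  invisible(NULL)
}

#' Register a constant (no gradient) on a tape
#' @param tape a tape from [tape_new()]
#' @param x numeric matrix/vector/scalar
#' @export
tp_const <- function(tape, x) node_new(tape, x, needs_grad = FALSE)

#' Register a trainable parameter on a tape
#' @inheritParams tp_const
#' @export
tp_param <- function(tape, x) node_new(tape, x, needs_grad = TRUE)

op2 <- function(tape, a, b, value, bw) node_new(tape, value, list(a, b), bw)
op1 <- function(tape, a, value, bw) node_new(tape, value, list(a), bw)

tape_of <- function(...) {
  # nodes do not carry their tape; ops take it explicitly
  invisible(NULL)
}

#' Matrix product of two tape nodes
#' @param tape tape
#' @param a,b nodes with conformable matrix values
#' @export
tp_matmul <- function(tape, a, b) {
  op2(tape, a, b, a$value %*% b$value, function(nd) {
    acc_grad(nd$parents[[1]], nd$grad %*% t(nd$parents[[2]]$value))
    acc_grad(nd$parents[[2]], t(nd$parents[[1]]$value) %*% nd$grad)
  })
}

#' Product a %*% t(b) without materializing the transpose on the tape
#' @inheritParams tp_matmul
#' @export
tp_matmul_t <- function(tape, a, b) {
  op2(tape, a, b, a$value %*% t(b$value), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad %*% nd$parents[[2]]$value)
    acc_grad(nd$parents[[2]], t(nd$grad) %*% nd$parents[[1]]$value)
  })
}

# b may be same-shaped, a 1 x ncol(a) row vector (broadcast over rows),
# or 1 x 1 scalar.
tp_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  v <- if (identical(dim(av), dim(bv))) {
    av + bv
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    sweep(av, 2L, as.numeric(bv), "+")
  } else if (length(bv) == 1L) {
    av + as.numeric(bv)
  } else stop("tp_add: incompatible shapes")
  op2(tape, a, b, v, function(nd) {
    acc_grad(nd$parents[[1]], nd$grad)
    bv <- nd$parents[[2]]$value
    g <- nd$grad
    if (identical(dim(bv), dim(g))) acc_grad(nd$parents[[2]], g)
    else if (nrow(bv) == 1L && ncol(bv) == ncol(g)) acc_grad(nd$parents[[2]], matrix(colSums(g), 1L))
    else acc_grad(nd$parents[[2]], matrix(sum(g), 1L, 1L))
  })
}

tp_sub <- function(tape, a, b) tp_add(tape, a, tp_scale(tape, b, -1))

#' Elementwise product; b may be same-shaped, an n x 1 column (broadcast
#' over columns) or 1 x 1 scalar.
#' @inheritParams tp_matmul
#' @export
tp_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  mode <- if (identical(dim(av), dim(bv))) "full"
          else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) "col"
          else if (length(bv) == 1L) "scalar"
          else stop("tp_mul: incompatible shapes")
  v <- switch(mode,
    full = av * bv,
    col = av * as.numeric(bv),
    scalar = av * as.numeric(bv))
  nd <- op2(tape, a, b, v, function(nd) {
    a <- nd$parents[[1]]; b <- nd$parents[[2]]; g <- nd$grad
    m <- nd$mode
    if (m == "full") {
      acc_grad(a, g * b$value); acc_grad(b, g * a$value)
    } else if (m == "col") {
      acc_grad(a, g * as.numeric(b$value))
      acc_grad(b, matrix(rowSums(g * a$value), ncol = 1L))
    } else {
      acc_grad(a, g * as.numeric(b$value))
      acc_grad(b, matrix(sum(g * a$value), 1L, 1L))
    }
  })
  nd$mode <- mode
  nd
}

#' Multiply a node by a fixed scalar
#' @inheritParams tp_matmul
#' @param k numeric scalar constant
#' @export
tp_scale <- function(tape, a, k) {
  op1(tape, a, a$value * k, local({ kk <- k; function(nd) acc_grad(nd$parents[[1]], nd$grad * kk) }))
}

#' Add a fixed constant (matrix or scalar) to a node
#' @inheritParams tp_scale
#' @param cmat numeric constant, same shape or scalar
#' @export
tp_addc <- function(tape, a, cmat) {
  op1(tape, a, a$value + cmat, function(nd) acc_grad(nd$parents[[1]], nd$grad))
}

#' Elementwise multiply by a fixed constant matrix/scalar
#' @inheritParams tp_addc
#' @export
tp_mulc <- function(tape, a, cmat) {
  op1(tape, a, a$value * cmat,
      local({ cc <- cmat; function(nd) acc_grad(nd$parents[[1]], nd$grad * cc) }))
}

#' Broadcast an n x 1 column node across columns and multiply by a constant
#' n x m matrix (used for scalar edge weights entering attention scores).
#' @inheritParams tp_addc
#' @export
tp_colbroadcast_mul <- function(tape, a, cmat) {
  stopifnot(ncol(a$value) == 1L, nrow(a$value) == nrow(cmat))
  v <- matrix(as.numeric(a$value), nrow(cmat), ncol(cmat)) * cmat
  op1(tape, a, v, local({ cc <- cmat; function(nd) {
    acc_grad(nd$parents[[1]], matrix(rowSums(nd$grad * cc), ncol = 1L))
  }}))
}

unary <- function(tape, a, f, df) {
  op1(tape, a, f(a$value), local({ dff <- df; function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * dff(nd$parents[[1]]$value, nd$value))
  }}))
}

#' @rdname autodiff-unary
#' @title Elementwise nonlinearities on tape nodes
#' @param tape tape
#' @param a node
#' @name autodiff-unary
#' @export
tp_relu <- function(tape, a) unary(tape, a, function(x) pmax(x, 0), function(x, y) (x > 0) * 1)

#' @rdname autodiff-unary
#' @export
tp_gelu <- function(tape, a) unary(tape, a,
  function(x) x * stats::pnorm(x),
  function(x, y) stats::pnorm(x) + x * stats::dnorm(x))

#' @rdname autodiff-unary
#' @export
tp_sigmoid <- function(tape, a) unary(tape, a,
  function(x) stats::plogis(x),
  function(x, y) y * (1 - y))

#' @rdname autodiff-unary
#' @export
tp_softplus <- function(tape, a) unary(tape, a,
  function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
  function(x, y) stats::plogis(x))

#' @rdname autodiff-unary
#' @export
tp_tanh <- function(tape, a) unary(tape, a, tanh, function(x, y) 1 - y^2)

#' @rdname autodiff-unary
#' @export
tp_exp <- function(tape, a) unary(tape, a, exp, function(x, y) y)

#' @rdname autodiff-unary
#' @export
tp_log <- function(tape, a) unary(tape, a, log, function(x, y) 1 / x)

#' @rdname autodiff-unary
#' @export
tp_square <- function(tape, a) unary(tape, a, function(x) x^2, function(x, y) 2 * x)

#' Raise to a fixed power elementwise (values must be nonnegative)
#' @inheritParams tp_scale
#' @param p numeric exponent
#' @export
tp_pow_const <- function(tape, a, p) {
  unary(tape, a, function(x) x^p, local({ pp <- p; function(x, y) pp * x^(pp - 1) }))
}

#' Row-wise softmax with optional additive mask (-Inf entries are excluded)
#' @inheritParams tp_scale
#' @param mask optional constant matrix added to the logits before softmax
#' @export
tp_softmax_rows <- function(tape, a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x <- x + mask
  mx <- apply(x, 1L, max)
  e <- exp(x - mx)
  e[is.nan(e)] <- 0 # rows can contain -Inf from the mask
  p <- e / rowSums(e)
  nd <- op1(tape, a, p, function(nd) {
    p <- nd$value; g <- nd$grad
    acc_grad(nd$parents[[1]], p * (g - rowSums(g * p)))
  })
  nd
}

#' Row-wise log-softmax
#' @inheritParams tp_scale
#' @export
tp_logsoftmax_rows <- function(tape, a) {
  x <- a$value
  mx <- apply(x, 1L, max)
  ls <- x - mx - log(rowSums(exp(x - mx)))
  op1(tape, a, ls, function(nd) {
    p <- exp(nd$value); g <- nd$grad
    acc_grad(nd$parents[[1]], g - p * rowSums(g))
  })
}

#' Row-wise layer normalization with learned gain/bias
#' @inheritParams tp_scale
#' @param gamma,beta 1 x d parameter nodes
#' @param eps variance floor
#' @export
tp_layernorm_rows <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xh <- xc / sd
  val <- sweep(sweep(xh, 2L, as.numeric(gamma$value), "*"), 2L, as.numeric(beta$value), "+")
  nd <- node_new(tape, val, list(a, gamma, beta), function(nd) {
    a <- nd$parents[[1]]; gamma <- nd$parents[[2]]; beta <- nd$parents[[3]]
    g <- nd$grad
    xh <- nd$xh; sd <- nd$sd
    acc_grad(gamma, matrix(colSums(g * xh), 1L))
    acc_grad(beta, matrix(colSums(g), 1L))
    dxh <- sweep(g, 2L, as.numeric(gamma$value), "*")
    d <- ncol(xh)
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * xh)
    acc_grad(a, (dxh - m1 - xh * m2) / sd)
  })
  nd$xh <- xh
  nd$sd <- sd
  nd
}

#' Select rows of a node (with scatter-add backward)
#' @inheritParams tp_scale
#' @param idx integer row indices (duplicates allowed)
#' @export
tp_rows <- function(tape, a, idx) {
  nd <- op1(tape, a, a$value[idx, , drop = FALSE], function(nd) {
    a <- nd$parents[[1]]
    g0 <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- rowsum(nd$grad, group = nd$idx)
    g0[as.integer(rownames(agg)), ] <- agg
    acc_grad(a, g0)
  })
  nd$idx <- as.integer(idx)
  nd
}

#' Select columns of a node
#' @inheritParams tp_rows
#' @export
tp_cols <- function(tape, a, idx) {
  nd <- op1(tape, a, a$value[, idx, drop = FALSE], function(nd) {
    a <- nd$parents[[1]]
    g0 <- matrix(0, nrow(a$value), ncol(a$value))
    g0[, nd$idx] <- g0[, nd$idx] + nd$grad
    acc_grad(a, g0)
  })
  nd$idx <- as.integer(idx)
  nd
}

#' Stack nodes by rows
#' @param tape tape
#' @param nodes list of nodes with equal column counts
#' @export
tp_rbind <- function(tape, nodes) {
  v <- do.call(rbind, lapply(nodes, function(n) n$value))
  nd <- node_new(tape, v, nodes, function(nd) {
    off <- 0L
    for (p in nd$parents) {
      nr <- nrow(p$value)
      acc_grad(p, nd$grad[(off + 1L):(off + nr), , drop = FALSE])
      off <- off + nr
    }
  })
  nd
}

#' Stack nodes by columns
#' @inheritParams tp_rbind
#' @export
tp_cbind <- function(tape, nodes) {
  v <- do.call(cbind, lapply(nodes, function(n) n$value))
  node_new(tape, v, nodes, function(nd) {
    off <- 0L
    for (p in nd$parents) {
      nc <- ncol(p$value)
      acc_grad(p, nd$grad[, (off + 1L):(off + nc), drop = FALSE])
      off <- off + nc
    }
  })
}

#' Row sums as an n x 1 node
#' @inheritParams tp_scale
#' @export
tp_rowsums <- function(tape, a) {
  op1(tape, a, matrix(rowSums(a$value), ncol = 1L), function(nd) {
    a <- nd$parents[[1]]
    acc_grad(a, matrix(as.numeric(nd$grad), nrow(a$value), ncol(a$value)))
  })
}

#' Sum of all entries (1 x 1 node)
#' @inheritParams tp_scale
#' @export
tp_sum <- function(tape, a) {
  op1(tape, a, matrix(sum(a$value), 1L, 1L), function(nd) {
    a <- nd$parents[[1]]
    acc_grad(a, matrix(as.numeric(nd$grad), nrow(a$value), ncol(a$value)))
  })
}

#' Mean of all entries (1 x 1 node)
#' @inheritParams tp_scale
#' @export
tp_mean <- function(tape, a) {
  n <- length(a$value)
  op1(tape, a, matrix(mean(a$value), 1L, 1L), local({ nn <- n; function(nd) {
    a <- nd$parents[[1]]
    acc_grad(a, matrix(as.numeric(nd$grad) / nn, nrow(a$value), ncol(a$value)))
  }}))
}

#' L2-normalize each row (zero rows pass through as zeros)
#' @inheritParams tp_scale
#' @param eps norm floor
#' @export
tp_normalize_rows <- function(tape, a, eps = 1e-12) {
  x <- a$value
  nrm <- sqrt(rowSums(x^2))
  nrm2 <- pmax(nrm, eps)
  r <- x / nrm2
  nd <- op1(tape, a, r, function(nd) {
    r <- nd$value; g <- nd$grad
    acc_grad(nd$parents[[1]], (g - r * rowSums(g * r)) / nd$nrm2)
  })
  nd$nrm2 <- nrm2
  nd
}

#' Pick one entry per row: value[i, j[i]] as an n x 1 node
#' @inheritParams tp_scale
#' @param j integer column index per row
#' @export
tp_pick <- function(tape, a, j) {
  ij <- cbind(seq_len(nrow(a$value)), as.integer(j))
  nd <- op1(tape, a, matrix(a$value[ij], ncol = 1L), function(nd) {
    a <- nd$parents[[1]]
    g0 <- matrix(0, nrow(a$value), ncol(a$value))
    g0[nd$ij] <- as.numeric(nd$grad)
    acc_grad(a, g0)
  })
  nd$ij <- ij
  nd
}

#' Run the backward pass from a node (usually a 1 x 1 loss)
#'
#' Gradients of all ancestor parameter nodes are accumulated in their
#' `$grad` fields. Gradients are reset before the pass only for nodes at or
#' below `node` on the tape; call [tape_zero_grad()] to clear everything.
#'
#' @param tape tape
#' @param node node to differentiate
#' @param seed_grad optional gradient seed (defaults to all ones)
#' @export
tp_backward <- function(tape, node, seed_grad = NULL) {
  if (is.null(seed_grad)) seed_grad <- matrix(1, nrow(node$value), ncol(node$value))
  node$grad <- seed_grad
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd) && !is.null(nd$grad) && !is.null(nd$bw) && identical(nd$id, i)) nd$bw(nd)
  }
  invisible(NULL)
}

#' Clear every gradient on a tape
#' @param tape tape
#' @export
tape_zero_grad <- function(tape) {
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  invisible(NULL)
}

# ---- parameter handling ---------------------------------------------------

#' Register a (possibly nested) named list of matrices as parameter nodes
#' @param tape tape
#' @param params named list of numeric matrices
#' @return list of parameter nodes with the same structure
#' @export
bind_params <- function(tape, params) {
  lapply(params, function(p) {
    if (is.list(p)) bind_params(tape, p) else tp_param(tape, p)
  })
}

#' Collect gradients from bound parameter nodes (zeros when untouched)
#' @param pnodes result of [bind_params()]
#' @export
collect_grads <- function(pnodes) {
  lapply(pnodes, function(p) {
    if (is.list(p)) collect_grads(p)
    else if (is.null(p$grad)) matrix(0, nrow(p$value), ncol(p$value))
    else p$grad
  })
}

flatten_mats <- function(x, prefix = "") {
  out <- list()
  if (is.null(names(x))) names(x) <- paste0("i", seq_along(x))
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) out <- c(out, flatten_mats(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

relist_mats <- function(flat, skeleton, prefix = "") {
  out <- skeleton
  for (nm in names(skeleton)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(skeleton[[nm]])) out[[nm]] <- relist_mats(flat, skeleton[[nm]], key)
    else out[[nm]] <- flat[[key]]
  }
  out
}

#' L2 norm of a set of gradients (concatenated)
#' @param grads named (possibly nested) list of gradient matrices
#' @export
grad_l2_norm <- function(grads) {
  f <- flatten_mats(grads)
  sqrt(sum(vapply(f, function(g) sum(g^2), numeric(1))))
}

# ---- Adam optimizer -------------------------------------------------------

#' Initialize Adam state for a parameter list
#' @param params named (possibly nested) list of matrices
#' @export
adam_new <- function(params) {
  f <- flatten_mats(params)
  list(m = lapply(f, function(p) p * 0), v = lapply(f, function(p) p * 0), t = 0L)
}

#' One Adam update; returns list(params, state)
#' @param params parameter list
#' @param grads gradient list (same structure)
#' @param state state from [adam_new()]
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decays and floor
#' @param weight_decay decoupled (AdamW-style) weight decay
#' @export
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  fp <- flatten_mats(params)
  fg <- flatten_mats(grads)
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(fp)) {
    g <- fg[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    fp[[k]] <- fp[[k]] - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * fp[[k]])
  }
  list(params = relist_mats(fp, params), state = state)
}

# ---- test helper: numerical gradient -------------------------------------

#' Central finite-difference gradient of a scalar function of a matrix
#' @param f function(matrix) -> scalar
#' @param x matrix evaluation point
#' @param h step
#' @export
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
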