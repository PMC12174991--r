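# Reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; every op appends its node to a tape, and backward() walks
# the tape in reverse creation order (a valid topological order of the DAG).
# Parameters live off-tape and persist across passes; their gradients
# accumulate until ag_zero_grad().

.ag <- new.env(parent = emptyenv())
.ag$tape <- vector("list", 0L)
.ag$n <- 0L

#' Reset the autograd tape
#'
#' Discards all intermediate nodes of the previous forward pass. Parameters
#' (created with [ag_param()]) are unaffected.
#' @export
ag_reset <- function() {
  if (length(.ag$tape) < 4096L) .ag$tape <- vector("list", 4096L)
  .ag$n <- 0L
  invisible(NULL)
}

# parents are captured by the backward closures; the node itself stays lean
ag_node <- function(val, parents = NULL, bw = NULL, on_tape = TRUE) {
  e <- new.env(parent = emptyenv(), size = 4L)
  e$val <- val
  e$grad <- NULL
  e$bw <- bw
  class(e) <- "ag_node"
  if (on_tape) {
    n <- .ag$n + 1L
    .ag$n <- n
    if (n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape)
    .ag$tape[[n]] <- e
  }
  e
}

#' Create a trainable parameter node
#' @param val numeric matrix initial value.
#' @export
ag_param <- function(val) {
  e <- ag_node(as.matrix(val), on_tape = FALSE)
  e$is_param <- TRUE
  e
}

#' Create a constant (non-trainable) node
#' @param val numeric matrix.
#' @export
ag_const <- function(val) ag_node(as.matrix(val), on_tape = FALSE)

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Run backpropagation from a scalar loss node
#' @param loss a 1x1 `ag_node`.
#' @export
ag_backward <- function(loss) {
  loss$grad <- matrix(1, 1, 1)
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in rev(seq_len(.ag$n))) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

#' Zero the gradients of a parameter list
#' @param params list of `ag_node` parameters.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' @export
print.ag_node <- function(x, ...) {
  cat(sprintf("<ag_node %dx%d%s>\n", nrow(x$val), ncol(x$val),
              if (isTRUE(x$is_param)) " param" else ""))
  invisible(x)
}

# ---- operations ------------------------------------------------------------

#' Matrix product of two nodes
#' @param a,b `ag_node`s with conformable values.
#' @export
ag_mm <- function(a, b) {
  out <- ag_node(a$val %*% b$val, list(a, b))
  out$bw <- function(g) {
    acc_grad(a, g %*% t(b$val))
    acc_grad(b, crossprod(a$val, g))
  }
  out
}

#' Elementwise / broadcast addition
#'
#' `b` may be a 1-row matrix, broadcast over the rows of `a`.
#' @param a,b `ag_node`s.
#' @export
ag_add <- function(a, b) {
  bcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  v <- if (bcast) sweep(a$val, 2, b$val[1, ], "+") else a$val + b$val
  out <- ag_node(v, list(a, b))
  out$bw <- function(g) {
    acc_grad(a, g)
    acc_grad(b, if (bcast) matrix(colSums(g), 1) else g)
  }
  out
}

#' Elementwise product (same shapes)
#' @param a,b `ag_node`s.
#' @export
ag_mul <- function(a, b) {
  out <- ag_node(a$val * b$val, list(a, b))
  out$bw <- function(g) {
    acc_grad(a, g * b$val)
    acc_grad(b, g * a$val)
  }
  out
}

#' Scale by a fixed scalar
#' @param a an `ag_node`; `s` a plain numeric scalar.
#' @export
ag_scale <- function(a, s) {
  out <- ag_node(a$val * s, list(a))
  out$bw <- function(g) acc_grad(a, g * s)
  out
}

#' Transpose
#' @param a an `ag_node`.
#' @export
ag_t <- function(a) {
  out <- ag_node(t(a$val), list(a))
  out$bw <- function(g) acc_grad(a, t(g))
  out
}

#' Product with a transposed right factor, `a %*% t(b)`
#' @param a,b `ag_node`s with equal column counts.
#' @export
ag_tcross <- function(a, b) {
  out <- ag_node(tcrossprod(a$val, b$val), list(a, b))
  out$bw <- function(g) {
    acc_grad(a, g %*% b$val)
    acc_grad(b, crossprod(g, a$val))
  }
  out
}

#' Gaussian-error linear unit (tanh approximation)
#' @param a an `ag_node`.
#' @export
ag_gelu <- function(a) {
  x <- a$val
  k <- 0.7978845608028654            # sqrt(2/pi)
  th <- tanh(k * (x + 0.044715 * x^3))
  out <- ag_node(0.5 * x * (1 + th), list(a))
  out$bw <- function(g) {
    acc_grad(a, g * (0.5 * (1 + th) +
                       0.5 * x * (1 - th^2) * k * (1 + 0.134145 * x^2)))
  }
  out
}

#' Logistic sigmoid
#' @param a an `ag_node`.
#' @export
ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  out <- ag_node(s, list(a))
  out$bw <- function(g) acc_grad(a, g * s * (1 - s))
  out
}

#' Row-wise softmax
#' @param a an `ag_node`.
#' @export
ag_softmax <- function(a) {
  z <- a$val - apply(a$val, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  out <- ag_node(s, list(a))
  out$bw <- function(g) acc_grad(a, s * (g - rowSums(g * s)))
  out
}

#' Row-wise layer normalisation with learned affine
#' @param a input `ag_node` (rows are tokens).
#' @param gamma,beta 1xW parameter nodes.
#' @param eps variance floor.
#' @export
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  w <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- ag_node(sweep(xhat, 2, gamma$val[1, ], "*") +
                   matrix(beta$val[1, ], nrow(x), w, byrow = TRUE),
                 list(a, gamma, beta))
  out$bw <- function(g) {
    acc_grad(beta, matrix(colSums(g), 1))
    acc_grad(gamma, matrix(colSums(g * xhat), 1))
    gh <- sweep(g, 2, gamma$val[1, ], "*")
    acc_grad(a, inv * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat)))
  }
  out
}

#' Gather rows by index
#' @param a an `ag_node`; `idx` 1-based row indices (may repeat).
#' @export
ag_gather <- function(a, idx) {
  out <- ag_node(a$val[idx, , drop = FALSE], list(a))
  out$bw <- function(g) {
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nrow(a$val), ncol(a$val))
    full[as.integer(rownames(acc)), ] <- acc
    acc_grad(a, full)
  }
  out
}

#' Scatter-add rows into a zero matrix of `nrows` rows
#' @param a an `ag_node`; `idx` destination row per input row; `nrows` output
#'   row count.
#' @export
ag_scatter <- function(a, idx, nrows) {
  acc <- rowsum(a$val, group = idx)
  full <- matrix(0, nrows, ncol(a$val))
  full[as.integer(rownames(acc)), ] <- acc
  out <- ag_node(full, list(a))
  out$bw <- function(g) acc_grad(a, g[idx, , drop = FALSE])
  out
}

#' Column-wise concatenation
#' @param ... `ag_node`s with equal row counts.
#' @export
ag_cbind <- function(...) {
  nodes <- list(...)
  widths <- vapply(nodes, function(n) ncol(n$val), integer(1))
  out <- ag_node(do.call(cbind, lapply(nodes, function(n) n$val)), nodes)
  out$bw <- function(g) {
    at <- 0L
    for (k in seq_along(nodes)) {
      acc_grad(nodes[[k]], g[, (at + 1L):(at + widths[k]), drop = FALSE])
      at <- at + widths[k]
    }
  }
  out
}

#' Row-wise concatenation
#' @param ... `ag_node`s with equal column counts.
#' @export
ag_rbind <- function(...) {
  nodes <- list(...)
  heights <- vapply(nodes, function(n) nrow(n$val), integer(1))
  out <- ag_node(do.call(rbind, lapply(nodes, function(n) n$val)), nodes)
  out$bw <- function(g) {
    at <- 0L
    for (k in seq_along(nodes)) {
      acc_grad(nodes[[k]], g[(at + 1L):(at + heights[k]), , drop = FALSE])
      at <- at + heights[k]
    }
  }
  out
}

#' Column slice
#' @param a an `ag_node`; `j0`,`j1` first/last column (inclusive).
#' @export
ag_cols <- function(a, j0, j1) {
  out <- ag_node(a$val[, j0:j1, drop = FALSE], list(a))
  out$bw <- function(g) {
    full <- matrix(0, nrow(a$val), ncol(a$val))
    full[, j0:j1] <- g
    acc_grad(a, full)
  }
  out
}

#' Mean of all elements (scalar node)
#' @param a an `ag_node`.
#' @export
ag_mean <- function(a) {
  out <- ag_node(matrix(mean(a$val), 1, 1), list(a))
  out$bw <- function(g) {
    acc_grad(a, matrix(g[1, 1] / length(a$val), nrow(a$val), ncol(a$val)))
  }
  out
}

#' Sum of scalar nodes
#' @param nodes list of 1x1 `ag_node`s.
#' @export
ag_sum_scalars <- function(nodes) {
  out <- ag_node(matrix(sum(vapply(nodes, function(n) n$val[1, 1],
                                   numeric(1))), 1, 1), nodes)
  out$bw <- function(g) for (n in nodes) acc_grad(n, g)
  out
}

# ---- losses ----------------------------------------------------------------

#' Mean softmax cross-entropy against integer class targets
#' @param logits NxC `ag_node`; `target` length-N 1-based class indices.
#' @export
ag_xent <- function(logits, target) {
  z <- logits$val - apply(logits$val, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  ll <- -mean(log(pmax(p[cbind(seq_len(n), target)], 1e-12)))
  out <- ag_node(matrix(ll, 1, 1), list(logits))
  out$bw <- function(g) {
    gr <- p
    gr[cbind(seq_len(n), target)] <- gr[cbind(seq_len(n), target)] - 1
    acc_grad(logits, gr * (g[1, 1] / n))
  }
  out
}

#' Weighted mean binary cross-entropy on logits
#'
#' Element `j`'s term is multiplied by `weights[j]` (recycled over rows).
#' @param logits NxK `ag_node`; `targets` NxK 0/1 matrix; `weights` length-K.
#' @export
ag_bce <- function(logits, targets, weights = NULL) {
  z <- logits$val
  y <- as.matrix(targets)
  if (is.null(weights)) weights <- rep(1, ncol(z))
  w <- matrix(weights, nrow(z), ncol(z), byrow = TRUE)
  # stable: log(1+exp(-|z|)) + max(z,0) - z*y
  lse <- log1p(exp(-abs(z))) + pmax(z, 0)
  loss <- mean(w * (lse - z * y))
  out <- ag_node(matrix(loss, 1, 1), list(logits))
  out$bw <- function(g) {
    s <- 1 / (1 + exp(-z))
    acc_grad(logits, w * (s - y) * (g[1, 1] / length(z)))
  }
  out
}

#' Mean squared error against a fixed target
#' @param pred an `ag_node`; `target` numeric of the same shape.
#' @export
ag_mse <- function(pred, target) {
  d <- pred$val - as.matrix(target)
  out <- ag_node(matrix(mean(d * d), 1, 1), list(pred))
  out$bw <- function(g) acc_grad(pred, 2 * d * (g[1, 1] / length(d)))
  out
}

# ---- optimiser -------------------------------------------------------------

#' Create an AdamW optimiser state
#'
#' Decoupled weight decay; bias-corrected first and second moments.
#'
#' @param params list of parameter nodes.
#' @param lr base learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps denominator floor.
#' @param weight_decay decoupled decay coefficient.
#' @export
adamw <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                  eps = 1e-8, weight_decay = 1e-2) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$wd <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) 0 * p$val)
  st$v <- lapply(params, function(p) 0 * p$val)
  class(st) <- "adamw"
  st
}

#' Apply one AdamW update using accumulated gradients
#' @param opt an [adamw()] state.
#' @param lr_scale multiplier on the base learning rate (warm-up/decay).
#' @export
adamw_step <- function(opt, lr_scale = 1) {
  opt$t <- opt$t + 1L
  lr <- opt$lr * lr_scale
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in seq_along(opt$params)) {
    p <- opt$params[[k]]
    if (is.null(p$grad)) next
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * p$grad
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * p$grad^2
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    p$val <- p$val - lr * (mhat / (sqrt(vhat) + opt$eps) + opt$wd * p$val)
  }
  invisible(opt)
}

#' Learning-rate schedule: linear warm-up then linear decay to zero
#'
#' @param step current step (1-based).
#' @param total total number of steps.
#' @param warmup_frac fraction of steps spent warming up.
#' @return multiplier in `[0, 1]`.
#' @export
lr_schedule <- function(step, total, warmup_frac = 0.05) {
  warm <- max(1, round(warmup_frac * total))
  if (step <= warm) return(step / warm)
  max(0, (total - step) / max(1, total - warm))
}
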