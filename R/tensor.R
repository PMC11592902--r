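# Reverse-mode automatic differentiation over base-R matrices.
#
# Every value in the compute graph is a "tnode": an environment holding a
# numeric matrix (`val`), an accumulated gradient (`grad`), the list of
# differentiable `parents`, and a `bwd` closure that maps the node's gradient
# to gradients for those parents.  Graphs are rebuilt every forward pass;
# parameters are long-lived leaf nodes whose `val` the optimizer mutates in
# place.  Matrix multiplies go through BLAS; convolutions are realised by
# im2col gathers so that their heavy lifting is also a matmul.

.tn_counter <- new.env(parent = emptyenv())
.tn_counter$n <- 0L

tn_new <- function(val, parents = list(), bwd = NULL, req = NULL) {
  if (!is.matrix(val)) val <- as.matrix(val)
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$bwd <- bwd
  e$req <- if (is.null(req)) any(vapply(parents, function(p) p$req, TRUE)) else req
  .tn_counter$n <- .tn_counter$n + 1L
  e$pid <- as.character(.tn_counter$n)
  class(e) <- "tnode"
  e
}

#' Create a constant (non-trainable) tensor node
#' @param val numeric matrix, vector or scalar
#' @return a `tnode`
#' @keywords internal
#' @export
tn_const <- function(val) tn_new(val, req = FALSE)

#' Create a trainable parameter node
#' @param val numeric matrix, vector or scalar (initial value)
#' @return a `tnode` participating in gradient computation
#' @keywords internal
#' @export
tn_param <- function(val) tn_new(val, req = TRUE)

#' Current value of a tensor node
#' @param x a `tnode`
#' @return numeric matrix
#' @keywords internal
#' @export
tn_val <- function(x) x$val

.accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Backpropagate gradients from a scalar loss node
#'
#' Walks the reachable differentiable subgraph with Kahn's algorithm on
#' reversed edges so every node's gradient is complete before it is pushed to
#' its parents (required for shared subexpressions).
#' @param root scalar `tnode` (the loss)
#' @keywords internal
#' @export
tn_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  # collect reachable req nodes + consumer counts
  cnt <- new.env(parent = emptyenv())
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes[[root$pid]] <- root
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (p in nd$parents) {
      if (!p$req) next
      k <- p$pid
      cnt[[k]] <- (if (is.null(cnt[[k]])) 0L else cnt[[k]]) + 1L
      if (is.null(nodes[[k]])) {
        nodes[[k]] <- p
        stack[[length(stack) + 1L]] <- p
      }
    }
  }
  for (k in ls(nodes)) nodes[[k]]$grad <- NULL
  root$grad <- matrix(1, 1, 1)
  queue <- list(root)
  while (length(queue)) {
    nd <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    if (!is.null(nd$bwd) && length(nd$parents)) {
      gs <- nd$bwd(nd, nd$grad)
      for (i in seq_along(nd$parents)) {
        p <- nd$parents[[i]]
        if (!p$req) next
        .accum(p, gs[[i]])
        cnt[[p$pid]] <- cnt[[p$pid]] - 1L
        if (cnt[[p$pid]] == 0L) queue[[length(queue) + 1L]] <- p
      }
    }
  }
  invisible(root)
}

# ---- elementwise / broadcast arithmetic -------------------------------------

.bcast_grad <- function(g, dims) {
  # reduce gradient g to the shape `dims` it was broadcast from
  if (identical(dim(g), dims)) return(g)
  if (all(dims == c(1L, 1L))) return(matrix(sum(g), 1, 1))
  if (dims[1] == 1L && dims[2] == ncol(g)) return(matrix(colSums(g), 1))
  if (dims[2] == 1L && dims[1] == nrow(g)) return(matrix(rowSums(g), ncol = 1))
  stop("unsupported broadcast shape")
}

.bcast_up <- function(v, ref) {
  # expand v (matrix) to the shape of ref for elementwise ops
  if (identical(dim(v), dim(ref))) return(v)
  if (all(dim(v) == c(1L, 1L))) return(matrix(v[1], nrow(ref), ncol(ref)))
  if (nrow(v) == 1L && ncol(v) == ncol(ref))
    return(matrix(v, nrow(ref), ncol(ref), byrow = TRUE))
  if (ncol(v) == 1L && nrow(v) == nrow(ref))
    return(matrix(v, nrow(ref), ncol(ref)))
  stop("incompatible shapes ", paste(dim(v), collapse = "x"), " vs ",
       paste(dim(ref), collapse = "x"))
}

#' Elementwise sum of two nodes (row-vector and scalar broadcasting)
#' @keywords internal
#' @export
tn_add <- function(a, b) {
  tn_new(a$val + .bcast_up(b$val, a$val), list(a, b), function(nd, g)
    list(g, .bcast_grad(g, dim(b$val))))
}

#' Elementwise difference of two nodes
#' @keywords internal
#' @export
tn_sub <- function(a, b) {
  tn_new(a$val - .bcast_up(b$val, a$val), list(a, b), function(nd, g)
    list(g, -.bcast_grad(g, dim(b$val))))
}

#' Elementwise product (row-vector and scalar broadcasting on `b`)
#' @keywords internal
#' @export
tn_mul <- function(a, b) {
  tn_new(a$val * .bcast_up(b$val, a$val), list(a, b), function(nd, g)
    list(g * .bcast_up(b$val, a$val), .bcast_grad(g * a$val, dim(b$val))))
}

#' Multiply a node by a fixed scalar
#' @keywords internal
#' @export
tn_scale <- function(a, k) {
  tn_new(a$val * k, list(a), function(nd, g) list(g * k))
}

#' Add a fixed numeric (matrix or scalar) to a node
#' @keywords internal
#' @export
tn_addc <- function(a, k) {
  tn_new(a$val + k, list(a), function(nd, g) list(g))
}

#' Matrix product of two nodes
#' @keywords internal
#' @export
tn_matmul <- function(a, b) {
  tn_new(a$val %*% b$val, list(a, b), function(nd, g)
    list(g %*% t(b$val), t(a$val) %*% g))
}

# ---- nonlinearities ---------------------------------------------------------

#' Rectified linear unit
#' @keywords internal
#' @export
tn_relu <- function(a) {
  m <- a$val > 0
  tn_new(a$val * m, list(a), function(nd, g) list(g * m))
}

#' Hyperbolic tangent
#' @keywords internal
#' @export
tn_tanh <- function(a) {
  y <- tanh(a$val)
  tn_new(y, list(a), function(nd, g) list(g * (1 - y^2)))
}

#' Logistic sigmoid
#' @keywords internal
#' @export
tn_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$val))
  tn_new(y, list(a), function(nd, g) list(g * y * (1 - y)))
}

# ---- softmax / layer norm ---------------------------------------------------

#' Row-wise softmax with optional additive mask
#'
#' The mask (a fixed numeric matrix, typically 0 / -1e9) is added to the
#' pre-activation scores; max-subtraction keeps the exponentials stable.
#' @keywords internal
#' @export
tn_softmax_rows <- function(a, mask = NULL) {
  x <- a$val
  if (!is.null(mask)) x <- x + mask
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  tn_new(y, list(a), function(nd, g)
    list((g - rowSums(g * y)) * y))
}

#' Row-wise layer normalisation with affine scale/shift
#'
#' Each row is centred and scaled to unit (population) variance, then an
#' affine transform with learnable `gamma`, `beta` (1 x d nodes) is applied.
#' @keywords internal
#' @export
tn_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gvec <- as.numeric(gamma$val)
  y <- sweep(xhat, 2L, gvec, `*`)
  y <- sweep(y, 2L, as.numeric(beta$val), `+`)
  tn_new(y, list(a, gamma, beta), function(nd, g) {
    dxh <- sweep(g, 2L, gvec, `*`)
    dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
    list(dx,
         matrix(colSums(g * xhat), 1),
         matrix(colSums(g), 1))
  })
}

# ---- reshaping / gathering --------------------------------------------------

#' Reshape a node (column-major, gradient reshaped back)
#' @keywords internal
#' @export
tn_reshape <- function(a, nr, nc) {
  tn_new(matrix(a$val, nr, nc), list(a), function(nd, g)
    list(matrix(g, nrow(a$val), ncol(a$val))))
}

#' Select columns of a node
#' @keywords internal
#' @export
tn_cols <- function(a, idx) {
  tn_new(a$val[, idx, drop = FALSE], list(a), function(nd, g) {
    da <- matrix(0, nrow(a$val), ncol(a$val))
    da[, idx] <- da[, idx] + g
    list(da)
  })
}

#' Gather rows of a node (repeated indices allowed; gradient scatter-adds)
#' @keywords internal
#' @export
tn_rows <- function(a, idx) {
  tn_new(a$val[idx, , drop = FALSE], list(a), function(nd, g) {
    da <- matrix(0, nrow(a$val), ncol(a$val))
    acc <- rowsum(g, group = idx)
    da[as.integer(rownames(acc)), ] <- acc
    list(da)
  })
}

#' Column-bind a list of nodes
#' @keywords internal
#' @export
tn_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$val), 1L)
  tn_new(do.call(cbind, lapply(nodes, tn_val)), nodes, function(nd, g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[, at + seq_len(widths[i]), drop = FALSE]
      at <- at + widths[i]
    }
    out
  })
}

#' Row-bind a list of nodes
#' @keywords internal
#' @export
tn_rbind <- function(nodes) {
  heights <- vapply(nodes, function(n) nrow(n$val), 1L)
  tn_new(do.call(rbind, lapply(nodes, tn_val)), nodes, function(nd, g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[at + seq_len(heights[i]), , drop = FALSE]
      at <- at + heights[i]
    }
    out
  })
}

#' Sum of all elements (scalar node)
#' @keywords internal
#' @export
tn_sum <- function(a) {
  tn_new(matrix(sum(a$val), 1, 1), list(a), function(nd, g)
    list(matrix(g[1], nrow(a$val), ncol(a$val))))
}

#' Mean of all elements (scalar node)
#' @keywords internal
#' @export
tn_mean <- function(a) {
  n <- length(a$val)
  tn_new(matrix(mean(a$val), 1, 1), list(a), function(nd, g)
    list(matrix(g[1] / n, nrow(a$val), ncol(a$val))))
}

# ---- convolution ------------------------------------------------------------

#' Precompute im2col row indices for a 2-D convolution
#'
#' Returns an (Ho*Wo) x (k*k) integer matrix of positions into an H x W grid
#' stored row-major as rows ((r-1)*W + c); 0 marks zero padding.  Shared by
#' the dense, depthwise and 3-D convolution ops.
#' @keywords internal
#' @export
conv_index <- function(H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  idx <- matrix(0L, Ho * Wo, k * k)
  pos <- 1L
  for (r in seq_len(Ho)) {
    for (cc in seq_len(Wo)) {
      r0 <- (r - 1L) * stride - pad
      c0 <- (cc - 1L) * stride - pad
      j <- 1L
      for (dr in 0:(k - 1L)) {
        for (dc in 0:(k - 1L)) {
          rr <- r0 + dr + 1L
          cw <- c0 + dc + 1L
          idx[pos, j] <- if (rr >= 1L && rr <= H && cw >= 1L && cw <= W)
            (rr - 1L) * W + cw else 0L
          j <- j + 1L
        }
      }
      pos <- pos + 1L
    }
  }
  attr(idx, "out") <- c(Ho, Wo)
  idx
}

.batch_idx <- function(idx, B, HW) {
  # expand per-position indices to a batch: 0 (pad) -> augmented zero row
  zrow <- B * HW + 1L
  out <- matrix(0L, nrow(idx) * B, ncol(idx))
  for (b in seq_len(B)) {
    block <- idx
    nz <- block != 0L
    block[nz] <- block[nz] + (b - 1L) * HW
    block[!nz] <- zrow
    out[(b - 1L) * nrow(idx) + seq_len(nrow(idx)), ] <- block
  }
  out
}

#' Dense 2-D convolution via im2col
#'
#' `x` holds a batch of feature maps as a (B*H*W) x Cin matrix (row-major
#' spatial order, batch-major rows).  `w` is (k*k*Cin) x Cout, `b` 1 x Cout.
#' @param meta list(B, H, W, k, stride, pad)
#' @keywords internal
#' @export
tn_conv2d <- function(x, w, b, meta) {
  idx <- conv_index(meta$H, meta$W, meta$k, meta$stride,
                    if (is.null(meta$pad)) (meta$k - 1L) %/% 2L else meta$pad)
  HW <- meta$H * meta$W
  bidx <- .batch_idx(idx, meta$B, HW)
  Cin <- ncol(x$val)
  kk <- ncol(idx)
  xa <- rbind(x$val, 0)
  # cols: [offset j][channel c] -> (j-1)*Cin + c
  Xg <- matrix(0, nrow(bidx), kk * Cin)
  for (j in seq_len(kk))
    Xg[, (j - 1L) * Cin + seq_len(Cin)] <- xa[bidx[, j], , drop = FALSE]
  y <- Xg %*% w$val
  y <- sweep(y, 2L, as.numeric(b$val), `+`)
  nd <- tn_new(y, list(x, w, b), function(nd, g) {
    dW <- t(Xg) %*% g
    db <- matrix(colSums(g), 1)
    dx <- matrix(0, nrow(x$val), Cin)
    if (x$req) {
      dXg <- g %*% t(w$val)
      for (j in seq_len(kk)) {
        rows <- bidx[, j]
        keep <- rows <= nrow(x$val)
        if (!any(keep)) next
        blk <- dXg[keep, (j - 1L) * Cin + seq_len(Cin), drop = FALSE]
        rs <- rows[keep]
        # rows within one offset are distinct -> direct indexed add
        dx[rs, ] <- dx[rs, ] + blk
      }
    }
    list(dx, dW, db)
  })
  attr(nd, "out_hw") <- attr(idx, "out")
  nd
}

#' Depthwise 2-D convolution (one k x k kernel per channel)
#'
#' `w` is (k*k) x C; channel c of the output only sees channel c of the input.
#' @keywords internal
#' @export
tn_conv_dw <- function(x, w, b, meta) {
  idx <- conv_index(meta$H, meta$W, meta$k, meta$stride,
                    if (is.null(meta$pad)) (meta$k - 1L) %/% 2L else meta$pad)
  HW <- meta$H * meta$W
  bidx <- .batch_idx(idx, meta$B, HW)
  C <- ncol(x$val)
  kk <- ncol(idx)
  xa <- rbind(x$val, 0)
  gathers <- lapply(seq_len(kk), function(j) xa[bidx[, j], , drop = FALSE])
  y <- matrix(0, nrow(bidx), C)
  for (j in seq_len(kk))
    y <- y + sweep(gathers[[j]], 2L, w$val[j, ], `*`)
  y <- sweep(y, 2L, as.numeric(b$val), `+`)
  nd <- tn_new(y, list(x, w, b), function(nd, g) {
    dW <- matrix(0, kk, C)
    dx <- matrix(0, nrow(x$val), C)
    for (j in seq_len(kk)) {
      dW[j, ] <- colSums(gathers[[j]] * g)
      if (!x$req) next
      rows <- bidx[, j]
      keep <- rows <= nrow(x$val)
      if (!any(keep)) next
      blk <- sweep(g[keep, , drop = FALSE], 2L, w$val[j, ], `*`)
      rs <- rows[keep]
      dx[rs, ] <- dx[rs, ] + blk
    }
    db <- matrix(colSums(g), 1)
    list(dx, dW, db)
  })
  attr(nd, "out_hw") <- attr(idx, "out")
  nd
}

#' 3-D convolution over a stacked feature volume (single kernel, same padding)
#'
#' `x` is (B*H*W) x D — D feature maps as columns.  The kernel `w` is a
#' (k*k) x kd matrix (spatial taps by depth taps), `b` a scalar node; depth is
#' zero-padded so the output keeps shape (B*H*W) x D.
#' @keywords internal
#' @export
tn_conv3d <- function(x, w, b, meta) {
  k <- meta$k
  kd <- ncol(w$val)
  idx <- conv_index(meta$H, meta$W, k, 1L)
  HW <- meta$H * meta$W
  bidx <- .batch_idx(idx, meta$B, HW)
  D <- ncol(x$val)
  kk <- k * k
  cd <- (kd - 1L) %/% 2L
  xa <- rbind(x$val, 0)
  gathers <- lapply(seq_len(kk), function(j) xa[bidx[, j], , drop = FALSE])
  shift_cols <- function(m, o) {
    # column d of result = column d+o of m (zero outside 1..D)
    out <- matrix(0, nrow(m), D)
    src <- seq_len(D) + o
    ok <- src >= 1L & src <= D
    out[, ok] <- m[, src[ok], drop = FALSE]
    out
  }
  y <- matrix(0, nrow(bidx), D)
  for (j in seq_len(kk))
    for (z in seq_len(kd))
      y <- y + shift_cols(gathers[[j]], z - 1L - cd) * w$val[j, z]
  y <- y + b$val[1]
  tn_new(y, list(x, w, b), function(nd, g) {
    dW <- matrix(0, kk, kd)
    dx <- matrix(0, nrow(x$val), D)
    for (j in seq_len(kk)) {
      rows <- bidx[, j]
      keep <- rows <= nrow(x$val)
      dxg <- matrix(0, nrow(g), D)   # gradient wrt gathers[[j]]
      for (z in seq_len(kd)) {
        o <- z - 1L - cd
        dW[j, z] <- sum(shift_cols(gathers[[j]], o) * g)
        # d y[,d] / d gather[,d+o] = w -> scatter back with opposite shift
        dxg <- dxg + shift_cols(g, -o) * w$val[j, z]
      }
      if (any(keep)) {
        rs <- rows[keep]
        dx[rs, ] <- dx[rs, ] + dxg[keep, , drop = FALSE]
      }
    }
    list(dx, dW, matrix(sum(g), 1, 1))
  })
}

# ---- recurrent cell ---------------------------------------------------------

#' Fused LSTM cell
#'
#' Computes one step for a batch: gates = x W + h U + b with gate order
#' (input, forget, cell, output).  Returns a (B x 2H) node holding
#' `cbind(h, c)`; callers slice with [tn_cols()].
#' @keywords internal
#' @export
tn_lstm_cell <- function(x, hprev, cprev, W, U, b) {
  H <- ncol(hprev$val)
  pre <- x$val %*% W$val + hprev$val %*% U$val
  pre <- pre + rep(as.numeric(b$val), each = nrow(pre))
  ii <- 1 / (1 + exp(-pre[, seq_len(H), drop = FALSE]))
  ff <- 1 / (1 + exp(-pre[, H + seq_len(H), drop = FALSE]))
  gg <- tanh(pre[, 2L * H + seq_len(H), drop = FALSE])
  oo <- 1 / (1 + exp(-pre[, 3L * H + seq_len(H), drop = FALSE]))
  cnew <- ff * cprev$val + ii * gg
  tc <- tanh(cnew)
  hnew <- oo * tc
  tn_new(cbind(hnew, cnew), list(x, hprev, cprev, W, U, b), function(nd, g) {
    dh <- g[, seq_len(H), drop = FALSE]
    dc <- g[, H + seq_len(H), drop = FALSE]
    do_ <- dh * tc
    dc_tot <- dc + dh * oo * (1 - tc^2)
    di <- dc_tot * gg
    df <- dc_tot * cprev$val
    dg <- dc_tot * ii
    dcprev <- dc_tot * ff
    dpre <- cbind(di * ii * (1 - ii),
                  df * ff * (1 - ff),
                  dg * (1 - gg^2),
                  do_ * oo * (1 - oo))
    list(dpre %*% t(W$val),
         dpre %*% t(U$val),
         dcprev,
         t(x$val) %*% dpre,
         t(hprev$val) %*% dpre,
         matrix(colSums(dpre), 1))
  })
}

# ---- loss -------------------------------------------------------------------

#' Weighted softmax cross-entropy from logits
#'
#' loss = mean_i w_i * (-log p_i[y_i]) with p = row softmax(logits); the true
#' label's probability is clamped at 1e-12 before the log.
#' @param logits (n x C) node
#' @param labels integer vector in 1..C
#' @param wts per-sample numeric weights (default all 1)
#' @keywords internal
#' @export
tn_cross_entropy <- function(logits, labels, wts = NULL) {
  n <- nrow(logits$val)
  C <- ncol(logits$val)
  if (is.null(wts)) wts <- rep(1, n)
  x <- logits$val - apply(logits$val, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  pick <- cbind(seq_len(n), labels)
  ptrue <- pmax(p[pick], 1e-12)
  loss <- mean(wts * (-log(ptrue)))
  tn_new(matrix(loss, 1, 1), list(logits), function(nd, g) {
    onehot <- matrix(0, n, C)
    onehot[pick] <- 1
    list(g[1] * (wts / n) * (p - onehot))
  })
}

# ---- optimizers -------------------------------------------------------------

#' One Adam step over a list of parameter nodes (in place)
#' @keywords internal
#' @export
adam_step <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- p$grad * 0
      p$adam_v <- p$grad * 0
      p$adam_t <- 0L
    }
    p$adam_t <- p$adam_t + 1L
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * p$grad
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * p$grad^2
    mhat <- p$adam_m / (1 - beta1^p$adam_t)
    vhat <- p$adam_v / (1 - beta2^p$adam_t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(params)
}

#' One plain stochastic-gradient-descent step (in place)
#' @keywords internal
#' @export
sgd_step <- function(params, lr) {
  for (p in params)
    if (!is.null(p$grad)) p$val <- p$val - lr * p$grad
  invisible(params)
}

#' Clear gradients on a list of parameter nodes
#' @keywords internal
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

#' Finite-difference gradient of a scalar-valued graph w.r.t. one node
#'
#' Test utility: `fn` rebuilds the graph from current parameter values and
#' returns the scalar loss (a numeric).
#' @keywords internal
#' @export
numeric_grad <- function(fn, param, h = 1e-5) {
  g <- param$val * 0
  for (i in seq_along(param$val)) {
    old <- param$val[i]
    param$val[i] <- old + h
    up <- fn()
    param$val[i] <- old - h
    dn <- fn()
    param$val[i] <- old
    g[i] <- (up - dn) / (2 * h)
  }
  g
}
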