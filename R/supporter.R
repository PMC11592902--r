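# Supporter context module: a 3-D convolution over a stack of feature maps
# drawn from different backbone stages (depth axis = provenance, not a
# volumetric z-stack), a BiLSTM over the row-major raster of spatial
# positions, attention pooling into a context vector, and a 1x1 residual
# projection whose output re-enters the classifier stream.

#' Supporter module configuration
#' @param depth number of backbone stage outputs stacked into the volume
#' @param kernel 3-D convolution kernel side (applied spatially and across
#'   the depth axis, zero-padded to preserve shape)
#' @param lstm_hidden hidden units per LSTM direction
#' @param attn_dim hidden width of the attention scorer
#' @param seq_pool spatial average-pooling factor applied to the convolved
#'   volume before the raster scan (keeps the recurrence length H*W/seq_pool^2
#'   tractable; 1 disables)
#' @param seed initialisation seed
#' @return a `supporter_config`
#' @export
supporter_config <- function(depth = 3L, kernel = 3L, lstm_hidden = 8L,
                             attn_dim = 16L, seq_pool = 2L, seed = 1L) {
  if (any(c(depth, kernel, lstm_hidden, attn_dim, seq_pool) < 1))
    stop("all supporter dimensions must be positive")
  structure(list(depth = as.integer(depth), kernel = as.integer(kernel),
                 lstm_hidden = as.integer(lstm_hidden),
                 attn_dim = as.integer(attn_dim),
                 seq_pool = as.integer(seq_pool), seed = as.integer(seed)),
            class = "supporter_config")
}

#' Build supporter parameters (deterministic given seed)
#' @param cfg a [supporter_config()]
#' @param in_depth depth D of the stacked volume
#' @return list of parameter nodes (class `supporter_params`)
#' @export
build_supporter <- function(cfg, in_depth = cfg$depth) {
  s <- cfg$seed
  H <- cfg$lstm_hidden
  D <- as.integer(in_depth)
  structure(list(
    w_conv = tn_param(init_mat(cfg$kernel^2, cfg$kernel, derive_seed(s, 21),
                               sd = sqrt(1 / (cfg$kernel^3)))),
    b_conv = tn_param(matrix(0, 1, 1)),
    Wf = tn_param(init_mat(D, 4L * H, derive_seed(s, 22), sd = 0.4)),
    Uf = tn_param(init_mat(H, 4L * H, derive_seed(s, 23), sd = 0.4)),
    bf = tn_param(matrix(0, 1, 4L * H)),
    Wb = tn_param(init_mat(D, 4L * H, derive_seed(s, 24), sd = 0.4)),
    Ub = tn_param(init_mat(H, 4L * H, derive_seed(s, 25), sd = 0.4)),
    bb = tn_param(matrix(0, 1, 4L * H)),
    W_h = tn_param(init_mat(2L * H, cfg$attn_dim, derive_seed(s, 26))),
    b_h = tn_param(matrix(0, 1, cfg$attn_dim)),
    v = tn_param(init_mat(cfg$attn_dim, 1L, derive_seed(s, 27))),
    w_proj = tn_param(init_mat(2L * H, D, derive_seed(s, 28))),
    b_proj = tn_param(matrix(0, 1, D))),
    class = "supporter_params", cfg = cfg, in_depth = D)
}

#' 3-D convolution over a stacked feature volume
#'
#' A single kernel (spatial k x k, depth k_d) slides over the volume with
#' zero same-padding in all three axes, so the output has the input's shape.
#' @param volume H x W x D array (D stacked single-channel maps)
#' @param kernel (k*k) x k_d matrix of taps (spatial row-major by depth), or
#'   a k x k x k_d array
#' @param bias scalar
#' @return H x W x D array
#' @export
conv3d_aggregate <- function(volume, kernel, bias = 0) {
  if (length(dim(volume)) != 3L) stop("volume must be an H x W x D array")
  H <- dim(volume)[1]; W <- dim(volume)[2]; D <- dim(volume)[3]
  if (length(dim(kernel)) == 3L)
    kernel <- matrix(kernel, dim(kernel)[1] * dim(kernel)[2], dim(kernel)[3])
  k <- as.integer(sqrt(nrow(kernel)))
  if (k * k != nrow(kernel)) stop("kernel spatial taps must form a square")
  if (k > H + 2 * ((k - 1) %/% 2)) stop("kernel larger than padded input")
  x <- matrix(0, H * W, D)
  for (dd in seq_len(D)) x[, dd] <- as.vector(t(volume[, , dd]))
  out <- tn_val(tn_conv3d(tn_const(x), tn_const(kernel),
                          tn_const(matrix(bias, 1, 1)),
                          list(B = 1L, H = H, W = W, k = k)))
  res <- array(0, c(H, W, D))
  for (dd in seq_len(D)) res[, , dd] <- matrix(out[, dd], H, W, byrow = TRUE)
  res
}

# engine BiLSTM over T timesteps; xt_fn(t) returns the (B x D) input node
.bilstm_engine <- function(xt_fn, T, sp, B) {
  H <- ncol(sp$Uf$val) / 4L
  zero <- tn_const(matrix(0, B, H))
  hf <- vector("list", T); hb <- vector("list", T)
  h <- zero; cst <- zero
  for (t in seq_len(T)) {
    hc <- tn_lstm_cell(xt_fn(t), h, cst, sp$Wf, sp$Uf, sp$bf)
    h <- tn_cols(hc, seq_len(H)); cst <- tn_cols(hc, H + seq_len(H))
    hf[[t]] <- h
  }
  h <- zero; cst <- zero
  for (t in rev(seq_len(T))) {
    hc <- tn_lstm_cell(xt_fn(t), h, cst, sp$Wb, sp$Ub, sp$bb)
    h <- tn_cols(hc, seq_len(H)); cst <- tn_cols(hc, H + seq_len(H))
    hb[[t]] <- h
  }
  lapply(seq_len(T), function(t) tn_cbind(list(hf[[t]], hb[[t]])))
}

#' BiLSTM encoding of a vector sequence
#'
#' Runs forward and backward LSTM passes; output t is the concatenation of
#' the forward state after steps 1..t and the backward state after steps
#' T..t, giving dimension 2*lstm_hidden.
#' @param x T x D matrix (one row per step)
#' @param params a `supporter_params` (uses Wf/Uf/bf and Wb/Ub/bb)
#' @return T x (2*lstm_hidden) matrix
#' @export
bilstm_encode <- function(x, params) {
  if (!is.matrix(x) || nrow(x) < 1L) stop("x must be a T x D matrix, T >= 1")
  xt <- lapply(seq_len(nrow(x)), function(t) tn_const(x[t, , drop = FALSE]))
  hs <- .bilstm_engine(function(t) xt[[t]], nrow(x), params, 1L)
  do.call(rbind, lapply(hs, tn_val))
}

.attention_pool_engine <- function(hs, sp, B) {
  T <- length(hs)
  scores <- vector("list", T)
  for (t in seq_len(T)) {
    e <- tn_matmul(tn_tanh(tn_add(tn_matmul(hs[[t]], sp$W_h), sp$b_h)), sp$v)
    scores[[t]] <- e                       # B x 1
  }
  emat <- tn_cbind(scores)                  # B x T
  alpha <- tn_softmax_rows(emat)
  ctx <- NULL
  for (t in seq_len(T)) {
    term <- tn_mul(hs[[t]], tn_cols(alpha, t))  # column-broadcast
    ctx <- if (is.null(ctx)) term else tn_add(ctx, term)
  }
  list(alpha = alpha, ctx = ctx)
}

#' Attention pooling of a BiLSTM output sequence
#'
#' Scores e_t = v' tanh(W_h h_t + b_h); weights are the softmax over t; the
#' context vector is the weighted sum of the h_t.
#' @param h T x (2*lstm_hidden) matrix
#' @param params a `supporter_params` (uses W_h, b_h, v)
#' @return list with `weights` (length T, sums to 1) and `context`
#' @export
attention_pool <- function(h, params) {
  if (!is.matrix(h) || nrow(h) < 1L) stop("h must be a T x dim matrix")
  hs <- lapply(seq_len(nrow(h)), function(t) tn_const(h[t, , drop = FALSE]))
  ap <- .attention_pool_engine(hs, params, 1L)
  list(weights = as.numeric(tn_val(ap$alpha)),
       context = as.numeric(tn_val(ap$ctx)))
}

#' 1x1 residual projection of a supporter map
#'
#' Pure channel mixing: output at each spatial position depends only on the
#' input channels at that position.  When `residual` is supplied it is added
#' to the projected map.
#' @param Fs H x W x C array
#' @param W C x C_out mixing matrix
#' @param b length-C_out bias (default zeros)
#' @param residual optional H x W x C_out array added to the projection
#' @return H x W x C_out array
#' @export
project_residual <- function(Fs, W, b = NULL, residual = NULL) {
  if (length(dim(Fs)) != 3L) stop("Fs must be an H x W x C array")
  H <- dim(Fs)[1]; Wd <- dim(Fs)[2]; C <- dim(Fs)[3]
  if (nrow(W) != C) stop("channel mismatch: map has ", C, " channels, W has ",
                         nrow(W), " rows")
  x <- matrix(Fs, H * Wd, C)
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2L, as.numeric(b), `+`)
  out <- array(y, c(H, Wd, ncol(W)))
  if (!is.null(residual)) out <- out + residual
  out
}

#' Fused classification head
#'
#' Concatenates the pooled CNN features, pooled transformer features and the
#' supporter context vector, applies an affine map and softmax.
#' @param f_cnn,f_transformer,context numeric vectors
#' @param W (sum of lengths) x C matrix
#' @param b length-C bias
#' @return length-C probability vector
#' @export
fuse_classify <- function(f_cnn, f_transformer, context, W, b) {
  v <- matrix(c(f_cnn, f_transformer, context), 1L)
  if (ncol(v) != nrow(W)) stop("fused feature dim mismatch")
  logits <- v %*% W + as.numeric(b)
  e <- exp(logits - max(logits))
  as.numeric(e / sum(e))
}

# resize taps for mapping an Hi x Wi map onto H x W (bilinear, linear op)
.resize_taps <- function(Hi, Wi, H, W) {
  ry <- (seq_len(H) - 0.5) * Hi / H
  rx <- (seq_len(W) - 0.5) * Wi / W
  y0 <- pmin(pmax(floor(ry - 0.5) + 1, 1), Hi); y1 <- pmin(y0 + 1, Hi)
  x0 <- pmin(pmax(floor(rx - 0.5) + 1, 1), Wi); x1 <- pmin(x0 + 1, Wi)
  wy <- pmin(pmax(ry + 0.5 - y0, 0), 1); wx <- pmin(pmax(rx + 0.5 - x0, 0), 1)
  pos <- function(yy, xx) (yy - 1L) * Wi + xx
  grid <- expand.grid(x = seq_len(W), y = seq_len(H))  # row-major out order
  o_y0 <- y0[grid$y]; o_y1 <- y1[grid$y]
  o_x0 <- x0[grid$x]; o_x1 <- x1[grid$x]
  o_wy <- wy[grid$y]; o_wx <- wx[grid$x]
  list(idx = cbind(pos(o_y0, o_x0), pos(o_y1, o_x0),
                   pos(o_y0, o_x1), pos(o_y1, o_x1)),
       w = cbind((1 - o_wy) * (1 - o_wx), o_wy * (1 - o_wx),
                 (1 - o_wy) * o_wx, o_wy * o_wx))
}

# engine resize of a (B*Hi*Wi) x 1 node to (B*H*W) x 1
.resize_engine <- function(xn, B, Hi, Wi, H, W) {
  if (Hi == H && Wi == W) return(xn)
  taps <- .resize_taps(Hi, Wi, H, W)
  out <- NULL
  for (t in 1:4) {
    rows <- as.vector(vapply(seq_len(B), function(b)
      as.integer((b - 1L) * Hi * Wi + taps$idx[, t]), integer(H * W)))
    term <- tn_mul(tn_rows(xn, rows),
                   tn_const(matrix(rep(taps$w[, t], B), ncol = 1L)))
    out <- if (is.null(out)) term else tn_add(out, term)
  }
  out
}

#' Supporter forward on the graph (batched)
#'
#' Stacks the channel-means of the last `cfg$depth` backbone stage outputs
#' (bilinearly resized to the final stage's H x W), applies the 3-D
#' convolution, runs the BiLSTM over the row-major raster of positions,
#' pools with attention into the context vector, and adds the 1x1-projected
#' BiLSTM map back onto the volume (residual).
#' @return list: `ctx` (B x 2H node), `alpha` (B x T numeric),
#'   `enhanced` ((B*H*W) x D node), `H`, `W`
#' @keywords internal
supporter_forward <- function(sp, stage_outputs, B) {
  cfg <- attr(sp, "cfg")
  S <- min(cfg$depth, length(stage_outputs))
  picks <- stage_outputs[seq(length(stage_outputs) - S + 1L,
                             length(stage_outputs))]
  last <- picks[[length(picks)]]
  H <- last$H; W <- last$W
  cols <- lapply(picks, function(st) {
    cmean <- tn_matmul(st$x, tn_const(matrix(1 / st$C, st$C, 1L)))
    .resize_engine(cmean, B, st$H, st$W, H, W)
  })
  vol <- tn_cbind(cols)                       # (B*H*W) x D
  fconv <- tn_conv3d(vol, sp$w_conv, sp$b_conv,
                     list(B = B, H = H, W = W, k = cfg$kernel))
  q <- cfg$seq_pool %||% 1L
  if (q > 1L && H %% q == 0L && W %% q == 0L) {
    Hs <- H %/% q; Ws <- W %/% q
    fseq <- .resize_engine(fconv, B, H, W, Hs, Ws)   # exact q x q average
    vres <- .resize_engine(vol, B, H, W, Hs, Ws)
  } else {
    Hs <- H; Ws <- W; fseq <- fconv; vres <- vol
  }
  T <- Hs * Ws
  HW <- T
  xt_fn <- function(t) tn_rows(fseq, (seq_len(B) - 1L) * HW + t)
  hs <- .bilstm_engine(xt_fn, T, sp, B)
  ap <- .attention_pool_engine(hs, sp, B)
  # reassemble h map in sample-major row order, project 1x1, residual add
  hmap_tmajor <- tn_rbind(hs)                 # rows: (t-1)*B + b
  perm <- as.vector(vapply(seq_len(B), function(b)
    (seq_len(T) - 1L) * B + b, integer(T)))
  hmap <- tn_rows(hmap_tmajor, perm)          # rows: (b-1)*T + t
  proj <- tn_add(tn_matmul(hmap, sp$w_proj), sp$b_proj)
  enhanced <- tn_add(proj, vres)
  list(ctx = ap$ctx, alpha = tn_val(ap$alpha), enhanced = enhanced,
       H = Hs, W = Ws)
}

#' @keywords internal
supporter_param_list <- function(sp) {
  sp2 <- unclass(sp)
  sp2[vapply(sp2, inherits, TRUE, "tnode")]
}
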