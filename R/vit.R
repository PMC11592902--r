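# Vision-transformer patch encoder over the backbone feature map: patch
# extraction + affine projection, learned position embeddings, scaled
# dot-product attention, multi-head self-attention, a post-norm
# residual/LayerNorm block order (LN applied AFTER each residual sum), and a
# classification head over the concatenated patch outputs (no class token).

#' Patch configuration
#' @param P patch side length (must divide the feature-map height and width)
#' @param d embedding dimension
#' @param W_e,b_e optional affine projection ((P^2*C) x d and 1 x d); when
#'   omitted they are initialised at encoder build time
#' @return a `patch_config`
#' @export
patch_config <- function(P, d, W_e = NULL, b_e = NULL) {
  if (P < 1 || d < 1) stop("P and d must be positive")
  structure(list(P = as.integer(P), d = as.integer(d), W_e = W_e, b_e = b_e),
            class = "patch_config")
}

#' Encoder configuration
#' @param depth number of encoder blocks L
#' @param heads number of attention heads h (must divide d)
#' @param d embedding dimension
#' @param ffn_dim hidden width of the feed-forward sublayer
#' @param seed initialisation seed
#' @return an `encoder_config`
#' @export
encoder_config <- function(depth = 2L, heads = 2L, d = 16L, ffn_dim = 32L,
                           seed = 1L) {
  if (d %% heads != 0) stop("d must be divisible by heads")
  structure(list(depth = as.integer(depth), heads = as.integer(heads),
                 d = as.integer(d), d_k = as.integer(d / heads),
                 ffn_dim = as.integer(ffn_dim), seed = as.integer(seed)),
            class = "encoder_config")
}

#' Row-major patch index table
#'
#' Row p lists the P^2 positions (row-major within the patch) of patch p,
#' patches ordered row-major over the (H/P) x (W/P) grid; positions index an
#' H x W map stored row-major.
#' @keywords internal
patch_index <- function(H, W, P) {
  if (H %% P != 0 || W %% P != 0)
    stop("patch size ", P, " does not divide the feature map ", H, "x", W)
  gh <- H %/% P; gw <- W %/% P
  idx <- matrix(0L, gh * gw, P * P)
  p <- 1L
  for (gr in seq_len(gh)) {
    for (gc in seq_len(gw)) {
      j <- 1L
      for (dr in seq_len(P)) {
        for (dc in seq_len(P)) {
          idx[p, j] <- ((gr - 1L) * P + dr - 1L) * W + (gc - 1L) * P + dc
          j <- j + 1L
        }
      }
      p <- p + 1L
    }
  }
  idx
}

# engine-level patchify: fmap node (B*H*W) x C -> tokens (B*N) x (P^2*C),
# columns ordered position-major then channel
.patchify_engine <- function(xn, B, H, W, P) {
  idx <- patch_index(H, W, P)
  N <- nrow(idx); kk <- ncol(idx)
  cols <- vector("list", kk)
  for (j in seq_len(kk)) {
    rows <- as.vector(vapply(seq_len(B), function(b)
      (b - 1L) * H * W + idx[, j], integer(N)))
    cols[[j]] <- tn_rows(xn, rows)
  }
  tn_cbind(cols)
}

#' Extract, flatten and project non-overlapping patches
#'
#' The number of patches is N = H*W/P^2; patch order is row-major raster.
#' Each patch is flattened (position-major, then channel) and mapped by the
#' affine projection (W_e, b_e).
#' @param fmap feature map: H x W matrix or H x W x C array, or a
#'   `feature_map` object (single sample)
#' @param cfg a [patch_config()] carrying `W_e`/`b_e`
#' @return N x d matrix of patch embeddings
#' @export
patchify_project <- function(fmap, cfg) {
  fm <- .as_fmap_matrix(fmap)
  C <- ncol(fm$x)
  if (is.null(cfg$W_e))
    stop("patch_config must carry W_e (and b_e) for direct use")
  xn <- tn_const(fm$x)
  tok <- .patchify_engine(xn, 1L, fm$H, fm$W, cfg$P)
  out <- tn_val(tok) %*% cfg$W_e
  sweep(out, 2L, as.numeric(cfg$b_e %||% matrix(0, 1, ncol(cfg$W_e))), `+`)
}

.as_fmap_matrix <- function(fmap) {
  if (inherits(fmap, "feature_map")) {
    stopifnot(fmap$B == 1L)
    return(list(x = fmap$x, H = fmap$H, W = fmap$W))
  }
  if (is.matrix(fmap))
    return(list(x = matrix(as.vector(t(fmap)), ncol = 1L),
                H = nrow(fmap), W = ncol(fmap)))
  if (length(dim(fmap)) == 3L) {
    H <- dim(fmap)[1]; W <- dim(fmap)[2]; C <- dim(fmap)[3]
    x <- matrix(0, H * W, C)
    for (cc in seq_len(C)) x[, cc] <- as.vector(t(fmap[, , cc]))
    return(list(x = x, H = H, W = W))
  }
  stop("fmap must be a matrix, 3-d array or feature_map")
}

#' Add position embeddings to a patch sequence
#' @param z N x d matrix of patch embeddings
#' @param E N x d matrix of position embeddings
#' @return N x d matrix `z + E`
#' @export
add_positions <- function(z, E) {
  if (!all(dim(z) == dim(E)))
    stop("position embedding shape ", paste(dim(E), collapse = "x"),
         " does not match patch sequence ", paste(dim(z), collapse = "x"))
  z + E
}

#' Scaled dot-product attention
#'
#' Weights are the row softmax of Q K' / sqrt(d_k); the output is
#' `weights %*% V`.
#' @param Q,K,V numeric matrices; Q and K share column count d_k, K and V
#'   share row count
#' @param d_k key dimension used for scaling (default `ncol(K)`)
#' @return list with `output` and `weights`
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must share their row count")
  qn <- tn_const(Q)
  at <- .attention_engine(qn, tn_const(K), tn_const(V), d_k)
  list(output = tn_val(at$out), weights = at$weights)
}

.attention_engine <- function(qn, kn, vn, d_k, mask = NULL) {
  scores <- tn_scale(tn_matmul(qn, tn_new(t(kn$val), list(kn), function(nd, g)
    list(t(g)))), 1 / sqrt(d_k))
  w <- tn_softmax_rows(scores, mask)
  list(out = tn_matmul(w, vn), weights = tn_val(w), wnode = w)
}

#' Build encoder parameters (deterministic given seed)
#'
#' @param cfg an [encoder_config()]
#' @param patch_dim flattened patch length P^2*C (input to the projection)
#' @param N number of patches (for the position table and head)
#' @param n_classes classification-head width (0 = no head)
#' @return list of parameter nodes (class `vit_params`)
#' @export
build_vit <- function(cfg, patch_dim, N, n_classes = 0L) {
  s <- cfg$seed
  d <- cfg$d
  p <- list(
    W_e = tn_param(init_mat(patch_dim, d, derive_seed(s, 1))),
    b_e = tn_param(matrix(0, 1, d)),
    E_p = tn_param(init_mat(N, d, derive_seed(s, 2), sd = 0.02)))
  for (l in seq_len(cfg$depth)) {
    q <- list(
      W_q = tn_param(init_mat(d, d, derive_seed(s, 10 * l + 1), sd = sqrt(1 / d))),
      W_k = tn_param(init_mat(d, d, derive_seed(s, 10 * l + 2), sd = sqrt(1 / d))),
      W_v = tn_param(init_mat(d, d, derive_seed(s, 10 * l + 3), sd = sqrt(1 / d))),
      W_o = tn_param(init_mat(d, d, derive_seed(s, 10 * l + 4), sd = sqrt(1 / d))),
      ln1_g = tn_param(matrix(1, 1, d)), ln1_b = tn_param(matrix(0, 1, d)),
      W_1 = tn_param(init_mat(d, cfg$ffn_dim, derive_seed(s, 10 * l + 5))),
      b_1 = tn_param(matrix(0, 1, cfg$ffn_dim)),
      W_2 = tn_param(init_mat(cfg$ffn_dim, d, derive_seed(s, 10 * l + 6))),
      b_2 = tn_param(matrix(0, 1, d)),
      ln2_g = tn_param(matrix(1, 1, d)), ln2_b = tn_param(matrix(0, 1, d)))
    p[[paste0("layer", l)]] <- q
  }
  if (n_classes > 0L) {
    p$W_c <- tn_param(init_mat(N * d, n_classes, derive_seed(s, 900)))
    p$b_c <- tn_param(matrix(0, 1, n_classes))
  }
  structure(p, class = "vit_params", cfg = cfg, N = N)
}

#' @keywords internal
vit_param_list <- function(vp) {
  flat <- list()
  for (nm in names(vp)) {
    if (inherits(vp[[nm]], "tnode")) flat[[nm]] <- vp[[nm]]
    else flat <- c(flat, vp[[nm]])
  }
  flat
}

.block_mask <- function(B, N) {
  if (B == 1L) return(NULL)
  m <- matrix(-1e9, B * N, B * N)
  for (b in seq_len(B))
    m[(b - 1L) * N + seq_len(N), (b - 1L) * N + seq_len(N)] <- 0
  m
}

.mhsa_engine <- function(zn, lp, cfg, mask = NULL) {
  d <- cfg$d; h <- cfg$heads; dk <- cfg$d_k
  qf <- tn_matmul(zn, lp$W_q)
  kf <- tn_matmul(zn, lp$W_k)
  vf <- tn_matmul(zn, lp$W_v)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- (i - 1L) * dk + seq_len(dk)
    heads[[i]] <- .attention_engine(tn_cols(qf, cols), tn_cols(kf, cols),
                                    tn_cols(vf, cols), dk, mask)$out
  }
  tn_matmul(tn_cbind(heads), lp$W_o)
}

#' Multi-head self-attention over a patch sequence
#'
#' Per-head scaled dot-product attentions (columns of the d-dimensional
#' Q/K/V projections sliced into h blocks of d_k) are concatenated and
#' projected by W_o; the sequence shape is preserved.
#' @param z N x d matrix
#' @param params the layer parameter group (W_q, W_k, W_v, W_o) — e.g.
#'   `build_vit(...)$layer1`
#' @param cfg an [encoder_config()]
#' @return N x d matrix
#' @export
mhsa <- function(z, params, cfg) {
  if (ncol(z) != cfg$d) stop("sequence dim does not match cfg$d")
  tn_val(.mhsa_engine(tn_const(z), params, cfg))
}

.encoder_block_engine <- function(zn, lp, cfg, mask = NULL) {
  a <- .mhsa_engine(zn, lp, cfg, mask)
  z1 <- tn_layernorm(tn_add(zn, a), lp$ln1_g, lp$ln1_b)
  f <- tn_add(tn_matmul(tn_relu(tn_add(tn_matmul(z1, lp$W_1), lp$b_1)),
                        lp$W_2), lp$b_2)
  tn_layernorm(tn_add(z1, f), lp$ln2_g, lp$ln2_b)
}

#' One post-norm encoder block
#'
#' z <- LayerNorm(z + MHSA(z)); z <- LayerNorm(z + FFN(z)) with
#' FFN(z) = ReLU(z W1 + b1) W2 + b2.  Layer normalisation sits after each
#' residual sum (post-norm), intentionally not the modern pre-norm order.
#' @param z N x d matrix
#' @param params one layer parameter group from [build_vit()]
#' @param cfg an [encoder_config()]
#' @return N x d matrix
#' @export
encoder_block <- function(z, params, cfg) {
  tn_val(.encoder_block_engine(tn_const(z), params, cfg))
}

#' Classification head over concatenated patch outputs
#'
#' All N patch vectors are concatenated (column-major vec of the N x d
#' matrix) and passed through an affine map and softmax.
#' @param z_out N x d matrix of encoder outputs
#' @param W_c (N*d) x C matrix, `b_c` 1 x C
#' @param b_c bias
#' @return length-C probability vector (sums to 1)
#' @export
vit_classify <- function(z_out, W_c, b_c) {
  v <- matrix(as.vector(z_out), 1L)
  if (ncol(v) != nrow(W_c)) stop("head input dim mismatch")
  logits <- v %*% W_c + as.numeric(b_c)
  e <- exp(logits - max(logits))
  as.numeric(e / sum(e))
}

#' Full encoder forward on the graph (batched)
#' @keywords internal
vit_forward <- function(vp, fmap_node, B, H, W, P) {
  cfg <- attr(vp, "cfg")
  N <- attr(vp, "N")
  tok <- .patchify_engine(fmap_node, B, H, W, P)
  z <- tn_add(tn_matmul(tok, vp$W_e), vp$b_e)
  pos <- tn_rows(vp$E_p, rep(seq_len(N), times = B))
  z <- tn_add(z, pos)
  mask <- .block_mask(B, N)
  for (l in seq_len(cfg$depth))
    z <- .encoder_block_engine(z, vp[[paste0("layer", l)]], cfg, mask)
  z
}
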