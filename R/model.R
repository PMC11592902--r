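# Full hybrid classifier: backbone -> {ViT patch encoder, supporter module}
# -> fused softmax head.  The fusion concatenates the global-average-pooled
# CNN map, the mean-pooled transformer tokens, the supporter context vector
# and the global pool of the supporter-enhanced volume; the final head
# (affine + softmax) produces the class probabilities.  An auxiliary head
# over the concatenated transformer tokens is kept as an optional readout.

#' Build the complete classifier
#'
#' @param config a run configuration from [default_config()] (sections
#'   `data`, `backbone`, `vit`, `supporter` are used)
#' @param n_classes number of classes
#' @return an object of class `cyto_model`
#' @export
build_model <- function(config, n_classes) {
  bcfg <- backbone_config(stages = config$backbone$stages,
                          in_channels = 1L,
                          supporter_insertion = config$backbone$supporter_insertion,
                          seed = derive_seed(config$seed, 101))
  bb <- build_backbone(bcfg)
  sp_strides <- stride_product(bcfg)
  H <- config$data$image_size[1]; W <- config$data$image_size[2]
  if (H %% sp_strides != 0 || W %% sp_strides != 0)
    stop("image_size must be divisible by the backbone stride product ",
         sp_strides)
  Hp <- H %/% sp_strides; Wp <- W %/% sp_strides
  P <- config$vit$P
  if (Hp %% P != 0 || Wp %% P != 0)
    stop("vit$P must divide the backbone output ", Hp, "x", Wp)
  N <- (Hp %/% P) * (Wp %/% P)
  ecfg <- encoder_config(depth = config$vit$depth, heads = config$vit$heads,
                         d = config$vit$d, ffn_dim = config$vit$ffn,
                         seed = derive_seed(config$seed, 102))
  vp <- build_vit(ecfg, P * P * bb$out_channels, N, n_classes = n_classes)
  scfg <- supporter_config(depth = config$supporter$depth,
                           kernel = config$supporter$kernel,
                           lstm_hidden = config$supporter$lstm_hidden,
                           attn_dim = config$supporter$attn_dim,
                           seq_pool = config$supporter$seq_pool %||% 1L,
                           seed = derive_seed(config$seed, 103))
  D <- min(scfg$depth, length(bcfg$stages))
  sp <- build_supporter(scfg, in_depth = D)
  fdim <- bb$out_channels + ecfg$d + 2L * scfg$lstm_hidden + D
  head <- list(
    W_fc = tn_param(init_mat(fdim, n_classes,
                             derive_seed(config$seed, 104))),
    b_fc = tn_param(matrix(0, 1, n_classes)))
  m <- list(backbone = bb, vit = vp, supporter = sp, head = head,
            n_classes = as.integer(n_classes),
            image_size = c(H, W), patch = P,
            use_supporter = isTRUE(config$model_use_supporter %||% TRUE),
            config = config)
  m$n_params <- .n_el(model_params(m))
  class(m) <- "cyto_model"
  m
}

#' All trainable parameter nodes of a model
#' @param m a `cyto_model`
#' @return named list of parameter nodes
#' @export
model_params <- function(m) {
  c(backbone_params(m$backbone), vit_param_list(m$vit),
    supporter_param_list(m$supporter), m$head)
}

#' Forward pass over a batch of images
#'
#' @param m a `cyto_model`
#' @param images (B, H, W) array of preprocessed values in `[0, 1]`
#' @return list: `logits` (node), `probs` (B x C numeric), `tokens` (node),
#'   `fcnn_pooled` (B x C_cnn numeric), `ctx` (B x 2H numeric or NULL),
#'   `alpha` (B x T numeric or NULL), and `aux_probs` — the auxiliary
#'   softmax readout over the concatenated transformer tokens
#' @export
model_forward <- function(m, images) {
  if (is.matrix(images)) images <- array(images, c(1L, dim(images)))
  B <- dim(images)[1]
  H <- dim(images)[2]; W <- dim(images)[3]
  xn <- tn_const(images_to_rows(images))
  bf <- backbone_forward(m$backbone, xn, B, H, W)
  HW <- bf$H * bf$W
  pool <- tn_const(.pool_matrix(B, HW))
  fcnn_pooled <- tn_matmul(pool, bf$out)          # B x C_cnn
  tokens <- vit_forward(m$vit, bf$out, B, bf$H, bf$W, m$patch)
  N <- attr(m$vit, "N")
  tpool <- tn_matmul(tn_const(.pool_matrix(B, N)), tokens)  # B x d
  if (m$use_supporter) {
    sf <- supporter_forward(m$supporter, bf$stage_outputs, B)
    epool <- tn_matmul(tn_const(.pool_matrix(B, sf$H * sf$W)), sf$enhanced)
    fused <- tn_cbind(list(fcnn_pooled, tpool, sf$ctx, epool))
    ctx <- tn_val(sf$ctx); alpha <- sf$alpha
  } else {
    fdim <- nrow(m$head$W_fc$val)
    have <- ncol(fcnn_pooled$val) + ncol(tpool$val)
    pad <- tn_const(matrix(0, B, fdim - have))
    fused <- tn_cbind(list(fcnn_pooled, tpool, pad))
    ctx <- NULL; alpha <- NULL
  }
  logits <- tn_add(tn_matmul(fused, m$head$W_fc), m$head$b_fc)
  lv <- tn_val(logits)
  e <- exp(lv - apply(lv, 1L, max))
  # auxiliary readout over the concatenated transformer tokens
  aux <- if (!is.null(m$vit$W_c)) {
    tv <- tn_val(tokens)
    t(vapply(seq_len(B), function(b)
      vit_classify(tv[(b - 1L) * N + seq_len(N), , drop = FALSE],
                   tn_val(m$vit$W_c), tn_val(m$vit$b_c)),
      numeric(m$n_classes)))
  } else NULL
  list(logits = logits, probs = e / rowSums(e), tokens = tokens,
       fcnn_pooled = tn_val(fcnn_pooled), ctx = ctx, alpha = alpha,
       aux_probs = aux)
}

#' Predict class probabilities for an image array
#'
#' @param m a `cyto_model`
#' @param x (n, H, W) array
#' @param batch_size forward batch size
#' @return n x C matrix of probabilities
#' @export
model_predict <- function(m, x, batch_size = 32L) {
  n <- dim(x)[1]
  out <- matrix(0, n, m$n_classes)
  at <- 1L
  while (at <= n) {
    take <- seq(at, min(at + batch_size - 1L, n))
    out[take, ] <- model_forward(m, x[take, , , drop = FALSE])$probs
    at <- at + batch_size
  }
  out
}

#' Snapshot all parameter values of a model
#' @param m a `cyto_model`
#' @return named list of numeric matrices
#' @export
model_state <- function(m) lapply(model_params(m), tn_val)

#' Restore parameter values from [model_state()]
#' @param m a `cyto_model`
#' @param state named list of matrices
#' @return the model, invisibly
#' @export
model_restore <- function(m, state) {
  ps <- model_params(m)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) {
    stopifnot(all(dim(ps[[i]]$val) == dim(state[[i]])))
    ps[[i]]$val <- state[[i]]
  }
  invisible(m)
}
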