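# Compact EfficientNetV2-style convolutional backbone: a stack of
# Fused-MBConv stages (3x3 expand conv + 1x1 project) followed by MBConv
# stages (1x1 expand + depthwise 3x3 + 1x1 project), each with an optional
# squeeze/recalibration "supporter" path that reweights channels from their
# global means.  Feature maps travel as (B*H*W) x C matrices, rows row-major
# within each sample, samples contiguous.

#' Backbone configuration
#'
#' @param stages list of stage descriptors, each
#'   `list(type, repeats, channels, stride, expansion)` with `type` in
#'   `{"fused_mbconv", "mbconv"}` and stride in `{1, 2}`
#' @param in_channels input image channels (1 = greyscale)
#' @param supporter_insertion logical, recycled per stage: insert the
#'   squeeze/recalibration supporter path after each block of that stage
#' @param seed parameter initialisation seed
#' @return a `backbone_config`
#' @export
backbone_config <- function(stages = list(
                              list(type = "fused_mbconv", repeats = 1L,
                                   channels = 8L, stride = 2L, expansion = 2),
                              list(type = "fused_mbconv", repeats = 1L,
                                   channels = 16L, stride = 2L, expansion = 2),
                              list(type = "mbconv", repeats = 1L,
                                   channels = 16L, stride = 1L, expansion = 2)),
                            in_channels = 1L, supporter_insertion = FALSE,
                            seed = 1L) {
  for (s in stages) {
    if (!s$type %in% c("fused_mbconv", "mbconv"))
      stop("unknown block type: ", s$type)
    if (!s$stride %in% c(1L, 2L)) stop("strides must be 1 or 2")
    if (s$channels < 1) stop("channels must be positive")
    if ((s$repeats %||% 1L) < 1) stop("repeats must be >= 1")
  }
  structure(list(stages = stages, in_channels = as.integer(in_channels),
                 supporter_insertion = rep_len(supporter_insertion,
                                               length(stages)),
                 seed = as.integer(seed)),
            class = "backbone_config")
}

#' Total spatial downsampling factor of a backbone config
#' @keywords internal
stride_product <- function(config) {
  as.integer(prod(vapply(config$stages, function(s) s$stride, 1L)))
}

.n_el <- function(params) sum(vapply(params, function(p) length(p$val), 1))

.bb_block_params <- function(type, cin, cout, expansion, se, seed) {
  ce <- max(1L, as.integer(round(cin * expansion)))
  p <- list()
  if (type == "fused_mbconv") {
    p$w_expand <- tn_param(init_mat(9L * cin, ce, derive_seed(seed, 1)))
    p$b_expand <- tn_param(matrix(0, 1, ce))
    p$w_project <- tn_param(init_mat(ce, cout, derive_seed(seed, 2)))
    p$b_project <- tn_param(matrix(0, 1, cout))
  } else {
    p$w_expand <- tn_param(init_mat(cin, ce, derive_seed(seed, 3)))
    p$b_expand <- tn_param(matrix(0, 1, ce))
    p$w_dw <- tn_param(init_mat(9L, ce, derive_seed(seed, 4), sd = 0.3))
    p$b_dw <- tn_param(matrix(0, 1, ce))
    p$w_project <- tn_param(init_mat(ce, cout, derive_seed(seed, 5)))
    p$b_project <- tn_param(matrix(0, 1, cout))
  }
  if (se) {
    cr <- max(1L, cout %/% 4L)
    p$w_se1 <- tn_param(init_mat(cout, cr, derive_seed(seed, 6)))
    p$b_se1 <- tn_param(matrix(0, 1, cr))
    p$w_se2 <- tn_param(init_mat(cr, cout, derive_seed(seed, 7)))
    p$b_se2 <- tn_param(matrix(0, 1, cout))
  }
  p
}

#' Build a backbone feature extractor
#'
#' Initialisation is deterministic given `config$seed`.  The returned object
#' carries its parameter nodes, the per-stage plan, and the parameter count.
#' @param config a [backbone_config()]
#' @return an object of class `cyto_backbone`
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  blocks <- list()
  cin <- config$in_channels
  bi <- 0L
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    for (r in seq_len(st$repeats %||% 1L)) {
      bi <- bi + 1L
      stride <- if (r == 1L) st$stride else 1L
      blocks[[bi]] <- list(
        type = st$type, stride = stride, cin = cin, cout = st$channels,
        stage = si, se = config$supporter_insertion[si],
        params = .bb_block_params(st$type, cin, st$channels, st$expansion,
                                  config$supporter_insertion[si],
                                  derive_seed(config$seed, si * 131L + r)))
      cin <- st$channels
    }
  }
  params <- unlist(lapply(blocks, function(b) b$params), recursive = FALSE)
  structure(list(config = config, blocks = blocks,
                 out_channels = cin,
                 n_params = .n_el(params)),
            class = "cyto_backbone")
}

#' @export
print.cyto_backbone <- function(x, ...) {
  cat(sprintf("Backbone: %d blocks, %d output channels, %d parameters\n",
              length(x$blocks), x$out_channels, x$n_params))
  invisible(x)
}

#' Flatten all trainable parameter nodes of a backbone
#' @keywords internal
backbone_params <- function(bb) {
  unlist(lapply(bb$blocks, function(b) b$params), recursive = FALSE)
}

.se_apply <- function(xn, p, B, HW) {
  # squeeze: per-sample channel means; excite: bottleneck MLP -> sigmoid gate
  pool <- .pool_matrix(B, HW)
  s <- tn_matmul(tn_const(pool), xn)                 # B x C
  s <- tn_relu(tn_add(tn_matmul(s, p$w_se1), p$b_se1))
  s <- tn_sigmoid(tn_add(tn_matmul(s, p$w_se2), p$b_se2))
  gate <- tn_rows(s, rep(seq_len(B), each = HW))      # back to B*HW rows
  tn_mul(xn, gate)
}

.pool_cache <- new.env(parent = emptyenv())
.pool_matrix <- function(B, HW) {
  key <- paste0(B, "_", HW)
  if (is.null(.pool_cache[[key]])) {
    P <- matrix(0, B, B * HW)
    for (b in seq_len(B)) P[b, (b - 1L) * HW + seq_len(HW)] <- 1 / HW
    .pool_cache[[key]] <- P
  }
  .pool_cache[[key]]
}

#' Backbone forward pass on the autodiff graph
#'
#' @param bb a `cyto_backbone`
#' @param xn input node, (B*H*W) x in_channels
#' @param B,H,W batch and spatial dimensions
#' @return list: `out` final node, `H`, `W`, and `stage_outputs` — one
#'   `list(x, H, W, C)` per stage (post last block of the stage)
#' @keywords internal
backbone_forward <- function(bb, xn, B, H, W) {
  cur <- xn; ch <- H; cw <- W
  stage_out <- vector("list", length(bb$config$stages))
  for (b in bb$blocks) {
    p <- b$params
    meta <- list(B = B, H = ch, W = cw, k = 3L, stride = b$stride)
    if (b$type == "fused_mbconv") {
      cv <- tn_conv2d(cur, p$w_expand, p$b_expand, meta)
      oh <- attr(cv, "out_hw")
      h <- tn_add(tn_matmul(tn_relu(cv), p$w_project), p$b_project)
    } else {
      h <- tn_relu(tn_add(tn_matmul(cur, p$w_expand), p$b_expand))
      cv <- tn_conv_dw(h, p$w_dw, p$b_dw, meta)
      oh <- attr(cv, "out_hw")
      h <- tn_add(tn_matmul(tn_relu(cv), p$w_project), p$b_project)
    }
    nh <- oh[1]; nw <- oh[2]
    if (b$se) h <- .se_apply(h, p, B, nh * nw)
    if (b$stride == 1L && b$cin == b$cout) h <- tn_add(h, cur)
    cur <- h; ch <- nh; cw <- nw
    stage_out[[b$stage]] <- list(x = cur, H = ch, W = cw, C = b$cout)
  }
  list(out = cur, H = ch, W = cw, stage_outputs = stage_out)
}

#' Extract feature maps from a batch of preprocessed images
#'
#' @param bb a `cyto_backbone` from [build_backbone()]
#' @param images array (B, H, W) of preprocessed values, or a single H x W
#'   matrix
#' @return a `feature_map` object: list with `x` ((B*H'*W') x C matrix of
#'   activations), `B`, `H`, `W`, `C`, and `stage_outputs` (numeric, per
#'   stage)
#' @export
extract_features <- function(bb, images) {
  if (is.matrix(images)) images <- array(images, c(1L, dim(images)))
  B <- dim(images)[1]; H <- dim(images)[2]; W <- dim(images)[3]
  sp <- stride_product(bb$config)
  if (H %% sp != 0 || W %% sp != 0)
    stop("input size ", H, "x", W, " is not divisible by the stride product ",
         sp)
  xn <- tn_const(images_to_rows(images))
  fw <- backbone_forward(bb, xn, B, H, W)
  structure(list(x = tn_val(fw$out), B = B, H = fw$H, W = fw$W,
                 C = ncol(tn_val(fw$out)),
                 stage_outputs = lapply(fw$stage_outputs, function(s)
                   list(x = tn_val(s$x), H = s$H, W = s$W, C = s$C))),
            class = "feature_map")
}

#' Convert a (B, H, W) image array to the row-major (B*H*W) x 1 layout
#' @keywords internal
images_to_rows <- function(images) {
  B <- dim(images)[1]; H <- dim(images)[2]; W <- dim(images)[3]
  out <- matrix(0, B * H * W, 1L)
  for (b in seq_len(B))
    out[(b - 1L) * H * W + seq_len(H * W), 1L] <- as.vector(t(images[b, , ]))
  out
}

#' Number of trainable parameters in a backbone
#' @param bb a `cyto_backbone`
#' @return integer count
#' @export
n_parameters <- function(bb) bb$n_params
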