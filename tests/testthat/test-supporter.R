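sp_params <- function(D = 3L, hidden = 4L, seed = 2L)
  build_supporter(supporter_config(depth = D, lstm_hidden = hidden,
                                   attn_dim = 6L, seed = seed), in_depth = D)

test_that("conv3d identity and zero kernels behave exactly", {
  set.seed(71)
  vol <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  ident <- matrix(0, 9, 3); ident[5, 2] <- 1   # centre tap only
  expect_equal(conv3d_aggregate(vol, ident, 0), vol, tolerance = 1e-12)
  zero <- matrix(0, 9, 3)
  expect_equal(conv3d_aggregate(vol, zero, 0.7),
               array(0.7, dim(vol)), tolerance = 1e-12)
  # interior of an averaging kernel over a constant volume stays constant
  avg <- matrix(1 / 27, 9, 3)
  kvol <- array(4, c(8, 8, 3))
  out <- conv3d_aggregate(kvol, avg, 0)
  expect_equal(out[4, 4, 2], 4, tolerance = 1e-12)
  expect_error(conv3d_aggregate(matrix(0, 3, 3), ident), "array")
})

test_that("BiLSTM output dimension and reversal symmetry hold", {
  sp <- sp_params()
  set.seed(72)
  for (T in c(1L, 4L, 7L)) {
    x <- matrix(rnorm(T * 3), T, 3)
    h <- bilstm_encode(x, sp)
    expect_identical(dim(h), c(T, 8L))   # 2 * lstm_hidden
    expect_true(all(is.finite(h)))
  }
  # swap the direction weights, feed the reversed sequence: position T+1-t
  # must hold the swapped halves of position t
  x <- matrix(rnorm(4 * 3), 4, 3)
  h <- bilstm_encode(x, sp)
  swapped <- sp
  swapped$Wf <- sp$Wb; swapped$Uf <- sp$Ub; swapped$bf <- sp$bb
  swapped$Wb <- sp$Wf; swapped$Ub <- sp$Uf; swapped$bb <- sp$bf
  hr <- bilstm_encode(x[4:1, , drop = FALSE], swapped)
  expect_equal(hr[4:1, c(5:8, 1:4)], h, tolerance = 1e-10)
  # determinism
  expect_identical(bilstm_encode(x, sp), bilstm_encode(x, sp))
  expect_error(bilstm_encode(matrix(0, 0, 3), sp), "T x D")
})

test_that("attention pooling matches closed-form softmax cases", {
  sp <- sp_params()
  # identical h_t -> uniform weights and c = h_1
  h <- matrix(rep(c(1, -1, 2, 0, 1, 1, -2, 3), 3), 3, 8, byrow = TRUE)
  ap <- attention_pool(h, sp)
  expect_equal(ap$weights, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(ap$context, h[1, ], tolerance = 1e-12)
  # T = 1
  ap1 <- attention_pool(h[1, , drop = FALSE], sp)
  expect_equal(ap1$weights, 1)
  expect_equal(ap1$context, h[1, ])
  # engineered scores e = (0, ln 2, 0) -> weights (1/4, 1/2, 1/4) and
  # c = 0.25 h1 + 0.5 h2 + 0.25 h3
  set.seed(77)
  h3 <- matrix(rnorm(24), 3, 8)
  h3[, 1] <- c(0, atanh(log(2)), 0)    # e_t = tanh(h_t[1]) via the wiring below
  forced <- sp
  Wh <- matrix(0, 8, 6); Wh[1, 1] <- 1
  forced$W_h <- tn_param(Wh)
  forced$b_h <- tn_param(matrix(0, 1, 6))
  v1 <- matrix(0, 6, 1); v1[1] <- 1
  forced$v <- tn_param(v1)
  apc <- attention_pool(h3, forced)
  expect_equal(apc$weights, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(apc$context,
               as.numeric(c(0.25, 0.5, 0.25) %*% h3), tolerance = 1e-12)
})

test_that("attention weights normalise and the context stays in the convex hull", {
  sp <- sp_params()
  set.seed(73)
  for (i in 1:60) {
    T <- sample(1:32, 1)
    h <- matrix(rnorm(T * 8, sd = runif(1, 0.2, 3)), T, 8)
    ap <- attention_pool(h, sp)
    expect_equal(sum(ap$weights), 1, tolerance = 1e-9)
    expect_true(all(ap$weights >= 0))
    expect_true(all(ap$context >= apply(h, 2, min) - 1e-9))
    expect_true(all(ap$context <= apply(h, 2, max) + 1e-9))
  }
})

test_that("the 1x1 projection mixes channels only and respects residuals", {
  set.seed(74)
  Fs <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_equal(project_residual(Fs, diag(3)), Fs, tolerance = 1e-12)
  # spatial locality: changing one position only changes that position
  W <- matrix(rnorm(9), 3, 3)
  base <- project_residual(Fs, W)
  Fs2 <- Fs; Fs2[2, 3, ] <- Fs2[2, 3, ] + 1
  out2 <- project_residual(Fs2, W)
  changed <- apply(abs(out2 - base) > 1e-12, c(1, 2), any)
  expect_true(changed[2, 3])
  expect_identical(sum(changed), 1L)
  # zero weights -> pure residual pass-through
  res <- array(rnorm(48), c(4, 4, 3))
  expect_equal(project_residual(Fs, matrix(0, 3, 3), residual = res), res,
               tolerance = 1e-12)
  expect_error(project_residual(Fs, matrix(0, 2, 3)), "channel mismatch")
})

test_that("the fused head is a proper softmax with shift invariance", {
  set.seed(75)
  fc <- rnorm(16); ft <- rnorm(16); ctx <- rnorm(8)
  W <- matrix(rnorm(40 * 4), 40, 4)
  p <- fuse_classify(fc, ft, ctx, W, rep(0, 4))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(fuse_classify(fc, ft, ctx, matrix(0, 40, 4), rep(0, 4)),
               rep(0.25, 4))
  expect_equal(fuse_classify(fc, ft, ctx, W, rep(3, 4)), p,
               tolerance = 1e-12)
  expect_error(fuse_classify(fc, ft, ctx, matrix(0, 10, 4), rep(0, 4)),
               "mismatch")
})

test_that("the end-to-end supporter path is deterministic given the seed", {
  bb <- build_backbone(backbone_config(seed = 4L))
  img <- array(runif(2 * 32 * 32), c(2, 32, 32))
  run_once <- function() {
    xn <- tn_const(images_to_rows(img))
    bf <- backbone_forward(bb, xn, 2L, 32L, 32L)
    sp <- sp_params(seed = 8L)
    sf <- cytoRL:::supporter_forward(sp, bf$stage_outputs, 2L)
    list(ctx = tn_val(sf$ctx), alpha = sf$alpha,
         enh = tn_val(sf$enhanced))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a, b)
  expect_equal(rowSums(a$alpha), rep(1, 2), tolerance = 1e-9)
})
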