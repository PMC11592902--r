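test_that("patch counts follow N = H*W/P^2 and projection behaves affinely", {
  expect_identical(nrow(patch_index(8L, 8L, 4L)), 4L)
  expect_identical(nrow(patch_index(224L, 224L, 16L)), 196L)
  expect_error(patch_index(8L, 8L, 3L), "divide")
  # identity projection, zero bias, constant map -> all patch vectors equal
  fm <- matrix(2.5, 8, 8)
  cfg <- patch_config(4L, 16L, W_e = diag(16), b_e = matrix(0, 1, 16))
  z <- patchify_project(fm, cfg)
  expect_identical(dim(z), c(4L, 16L))
  expect_true(all(z == 2.5))
})

test_that("position embeddings add elementwise and distinguish identical patches", {
  z <- matrix(0, 4, 8)
  E <- matrix(rnorm(32), 4, 8)
  expect_identical(add_positions(z, E), E)
  z2 <- matrix(rnorm(32), 4, 8)
  expect_identical(add_positions(z2, matrix(0, 4, 8)), z2)
  zsame <- matrix(1, 2, 3)
  Edist <- rbind(c(0, 0, 0), c(1, 0, 0))
  out <- add_positions(zsame, Edist)
  expect_false(identical(out[1, ], out[2, ]))
  expect_error(add_positions(z, E[1:2, ]), "match")
})

test_that("scaled dot-product attention matches hand-computed cases", {
  # all K rows identical -> uniform weights, output = mean of V rows
  Q <- matrix(rnorm(4), 2, 2)
  K <- matrix(1, 3, 2)
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  at <- scaled_dot_attention(Q, K, V)
  expect_equal(at$weights, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_equal(at$output, matrix(colMeans(V), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  # single token -> weight 1, output = V
  at1 <- scaled_dot_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                              matrix(c(7, 9), 1, 2))
  expect_equal(at1$weights, matrix(1, 1, 1))
  expect_equal(at1$output, matrix(c(7, 9), 1, 2))
  # worked example: softmax(1/sqrt(2), 0)
  at2 <- scaled_dot_attention(matrix(c(1, 0), 1, 2),
                              rbind(c(1, 0), c(0, 1)),
                              rbind(c(1, 0), c(0, 1)), d_k = 2)
  w <- exp(c(1 / sqrt(2), 0)); w <- w / sum(w)
  expect_equal(as.numeric(at2$weights), w, tolerance = 1e-4)
  expect_equal(round(as.numeric(at2$weights), 4), c(0.6698, 0.3302))
  expect_equal(as.numeric(at2$output), w, tolerance = 1e-4)
  expect_error(scaled_dot_attention(matrix(0, 1, 3), K, V), "key dimension")
})

test_that("attention weight rows always sum to 1", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(1:16, 1); m <- sample(1:16, 1); d <- sample(1:8, 1)
    at <- scaled_dot_attention(matrix(rnorm(n * d), n, d),
                               matrix(rnorm(m * d), m, d),
                               matrix(rnorm(m * 3), m, 3))
    expect_equal(rowSums(at$weights), rep(1, n), tolerance = 1e-9)
  }
})

test_that("MHSA with h=1 reduces to single-head attention composed with W_o", {
  cfg1 <- encoder_config(depth = 1L, heads = 1L, d = 8L, ffn_dim = 16L,
                         seed = 3L)
  vp <- build_vit(cfg1, patch_dim = 8L, N = 5L)
  z <- matrix(rnorm(40), 5, 8)
  lp <- vp$layer1
  got <- mhsa(z, lp, cfg1)
  q <- z %*% tn_val(lp$W_q); k <- z %*% tn_val(lp$W_k)
  v <- z %*% tn_val(lp$W_v)
  oracle <- scaled_dot_attention(q, k, v, d_k = 8)$output %*% tn_val(lp$W_o)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_identical(dim(got), dim(z))
})

test_that("MHSA is permutation-equivariant when no positions are added", {
  cfg <- encoder_config(depth = 1L, heads = 2L, d = 8L, ffn_dim = 16L,
                        seed = 4L)
  vp <- build_vit(cfg, patch_dim = 8L, N = 6L)
  set.seed(62)
  z <- matrix(rnorm(48), 6, 8)
  perm <- sample(6)
  out <- mhsa(z, vp$layer1, cfg)
  out_perm <- mhsa(z[perm, ], vp$layer1, cfg)
  expect_equal(out_perm, out[perm, ], tolerance = 1e-10)
})

test_that("encoder blocks are post-norm with row-normalised outputs", {
  cfg <- encoder_config(depth = 2L, heads = 2L, d = 8L, ffn_dim = 16L,
                        seed = 5L)
  vp <- build_vit(cfg, patch_dim = 8L, N = 4L)
  z <- matrix(rnorm(32), 4, 8)
  out <- encoder_block(z, vp$layer1, cfg)
  expect_identical(dim(out), c(4L, 8L))
  # with unit gamma / zero beta the output rows are standardised
  expect_equal(rowMeans(out), rep(0, 4), tolerance = 1e-8)
  expect_equal(apply(out, 1, function(r) mean(r^2)), rep(1, 4),
               tolerance = 1e-3)
  # zero-weight MHSA and FFN -> two successive row standardisations
  lp0 <- vp$layer1
  for (nm in c("W_q", "W_k", "W_v", "W_o", "W_1", "W_2")) lp0[[nm]]$val[] <- 0
  ln <- function(m) t(apply(m, 1, function(r)
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(encoder_block(z, lp0, cfg), ln(ln(z)), tolerance = 1e-10)
  # stacking preserves sequence length
  out2 <- encoder_block(out, vp$layer2, cfg)
  expect_identical(dim(out2), c(4L, 8L))
})

test_that("the classification head is a proper softmax over concatenated tokens", {
  set.seed(63)
  z <- matrix(rnorm(4 * 8), 4, 8)
  W <- matrix(rnorm(32 * 3), 32, 3)
  b <- rep(0, 3)
  p <- vit_classify(z, W, b)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # zero logits -> uniform
  expect_equal(vit_classify(z, matrix(0, 32, 3), rep(0, 3)), rep(1 / 3, 3))
  # shift invariance
  expect_equal(vit_classify(z, W, b + 5), p, tolerance = 1e-12)
  expect_error(vit_classify(z, matrix(0, 10, 3), rep(0, 3)), "mismatch")
})

test_that("encoder outputs stay finite and shape-stable over many random inputs", {
  cfg <- encoder_config(depth = 2L, heads = 2L, d = 8L, ffn_dim = 16L,
                        seed = 6L)
  vp <- build_vit(cfg, patch_dim = 8L, N = 4L)
  set.seed(64)
  for (i in 1:200) {
    z <- matrix(rnorm(32, sd = runif(1, 0.1, 10)), 4, 8)
    out <- encoder_block(z, vp$layer1, cfg)
    expect_true(all(is.finite(out)))
    expect_identical(dim(out), c(4L, 8L))
  }
})
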