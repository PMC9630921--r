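test_that("patch partition produces 48-channel tokens on the right grid", {
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))
  tk <- patch_partition(img)
  expect_equal(ncol(tk$x), 48L)
  expect_equal(c(tk$h, tk$w), c(16L, 24L))
  # constant image -> identical tokens
  tk2 <- patch_partition(array(0.5, c(32, 32, 3)))
  expect_true(all(abs(sweep(tk2$x, 2, tk2$x[1, ])) < 1e-15))
  expect_error(patch_partition(array(0, c(30, 32, 3))), "divisible")
  # content check: token (1,1) holds the top-left 4x4 patch
  expect_equal(sort(tk$x[1, ]), sort(as.vector(img[1:4, 1:4, ])))
})

test_that("linear embedding is an affine map shared across positions", {
  tk <- patch_partition(array(runif(32 * 32 * 3), c(32, 32, 3)))
  W <- matrix(rnorm(48 * 96, sd = 0.02), 48, 96); b <- rnorm(96)
  emb <- linear_embed(tk, W, b)
  expect_equal(dim(emb$x), c(64L, 96L))
  expect_equal(emb$x[5, ], as.numeric(tk$x[5, ] %*% W) + b)
  # zero tokens, zero bias -> zero output
  z <- linear_embed(list(x = matrix(0, 4, 48), h = 2, w = 2), W, numeric(96))
  expect_true(all(z$x == 0))
  expect_error(linear_embed(list(x = matrix(0, 4, 10), h = 2, w = 2), W, b),
               "mismatch")
})

test_that("window partition tiles with ceil padding and inverts exactly", {
  tok <- list(x = matrix(rnorm(28 * 28 * 4), 28 * 28, 4), h = 28L, w = 28L)
  p <- window_partition(tok, 7L)
  expect_equal(dim(p$windows)[1], 16L)           # (28/7)^2
  expect_true(all(p$real))
  tok2 <- list(x = matrix(rnorm(14 * 14 * 4), 14 * 14, 4), h = 14L, w = 14L)
  p2 <- window_partition(tok2, 9L)
  expect_equal(c(p2$hp, p2$wp), c(18L, 18L))
  expect_equal(dim(p2$windows)[1], 4L)
  # roundtrip is the identity, including through padding
  for (pp in list(p, p2)) {
    back <- window_reverse(pp)
    orig <- if (identical(pp$h, 28L)) tok else tok2
    expect_identical(back$x, orig$x)
  }
})

test_that("attention op: single token, uniform weights, brute-force match", {
  set.seed(31)
  V1 <- array(rnorm(1 * 1 * 8), c(1, 1, 8))
  expect_equal(attention(V1 * 0, V1 * 0, V1), V1)
  # Q = 0 -> uniform weights -> column means of V
  n <- 6; d <- 4
  V <- array(rnorm(n * d), c(1, n, d))
  out <- attention(array(0, c(1, n, d)), array(rnorm(n * d), c(1, n, d)), V)
  expect_equal(out[1, 1, ], colMeans(V[1, , ]), tolerance = 1e-12)
  expect_equal(out[1, n, ], colMeans(V[1, , ]), tolerance = 1e-12)
  # random 5-token window vs direct softmax(QK'/sqrt(d) + B)V
  Q <- array(rnorm(5 * 4), c(1, 5, 4)); K <- array(rnorm(5 * 4), c(1, 5, 4))
  V5 <- array(rnorm(5 * 4), c(1, 5, 4)); Bb <- array(rnorm(25), c(1, 5, 5))
  got <- attention(Q, K, V5, bias = Bb)
  L <- Q[1, , ] %*% t(K[1, , ]) / 2 + Bb[1, , ]
  P <- exp(L - apply(L, 1, max)); P <- P / rowSums(P)
  expect_equal(got[1, , ], P %*% V5[1, , ], tolerance = 1e-5)
  # masked entries get zero weight
  mask <- array(0, c(1, 5, 5)); mask[1, , 3] <- -1e9
  gotm <- attention(Q, K, V5, bias = Bb, mask = mask)
  Lm <- L; Lm[, 3] <- -Inf
  Pm <- exp(Lm - apply(Lm, 1, max)); Pm <- Pm / rowSums(Pm)
  expect_equal(gotm[1, , ], Pm %*% V5[1, , ], tolerance = 1e-5)
})

test_that("single full-map window equals dense attention (oracle)", {
  set.seed(32)
  C <- 32L; d <- 8L; h <- 8L; w <- 8L
  spec <- single_branch_spec(C, d, 8L)
  bp <- spikeformer:::init_block_params(C, spec)
  bp$attn$branches[[1]]$bias_table[] <- 0
  bp$attn$proj$W <- diag(C); bp$attn$proj$b <- numeric(C)
  x <- matrix(rnorm(h * w * C), h * w, C)
  out <- mw_msa(list(x = x, h = h, w = w), spec, bp)
  oracle <- dense_attention_oracle(x, bp$attn$branches[[1]]$Wqkv,
                                   bp$attn$branches[[1]]$bqkv, d)
  expect_lt(max(abs(out$x - oracle)), 1e-5)
})

test_that("shifted branch matches the per-token neighbourhood oracle", {
  set.seed(33)
  C <- 16L; d <- 8L; h <- 12L; w <- 12L; X <- 7L
  spec <- single_branch_spec(C, d, X)
  bp <- spikeformer:::init_block_params(C, spec)
  bp$attn$proj$W <- diag(C); bp$attn$proj$b <- numeric(C)
  x <- matrix(rnorm(h * w * C), h * w, C)
  out <- smw_msa(list(x = x, h = h, w = w), spec, bp)
  br <- bp$attn$branches[[1]]
  oracle <- shifted_attention_oracle(x, h, w, X, br$Wqkv, br$bqkv,
                                     br$bias_table, d)
  expect_lt(max(abs(out$x - oracle)), 1e-10)
})

test_that("padding tokens never influence real-token outputs", {
  # 5x6 grid under an 8-window: most of the window is padding; the oracle
  # attends over real tokens only, so agreement proves padding is inert
  set.seed(34)
  C <- 16L; d <- 8L; h <- 5L; w <- 6L; X <- 8L
  spec <- single_branch_spec(C, d, X)
  bp <- spikeformer:::init_block_params(C, spec)
  bp$attn$proj$W <- diag(C); bp$attn$proj$b <- numeric(C)
  x <- matrix(rnorm(h * w * C), h * w, C)
  out <- mw_msa(list(x = x, h = h, w = w), spec, bp)
  br <- bp$attn$branches[[1]]
  oracle <- shifted_attention_oracle(x, h, w, X, br$Wqkv, br$bqkv,
                                     br$bias_table, d, s = 0)
  expect_lt(max(abs(out$x - oracle)), 1e-10)
})

test_that("multi-window sublayer preserves shape; zero input, zero biases -> zero", {
  set.seed(35)
  spec <- variant_spec("tiny")
  bp <- spikeformer:::init_block_params(16L, spec)
  x <- matrix(rnorm(10 * 11 * 16), 110, 16)
  out <- mw_msa(list(x = x, h = 10L, w = 11L), spec, bp)
  expect_equal(dim(out$x), dim(x))
  bp0 <- bp
  for (k in 1:3) bp0$attn$branches[[k]]$bqkv[] <- 0
  bp0$attn$proj$b[] <- 0
  z <- mw_msa(list(x = x * 0, h = 10L, w = 11L), spec, bp0)
  expect_true(all(abs(z$x) < 1e-12))
})

test_that("spatial reduction preserves the grid in every mode", {
  set.seed(36)
  x <- matrix(rnorm(64 * 16), 64, 16)
  tok <- list(x = x, h = 8L, w = 8L)
  spec_id <- variant_spec("tiny")
  bp <- spikeformer:::init_block_params(16L, spec_id)
  expect_identical(spatial_reduce(tok, spec_id, bp), tok)

  spec_b2 <- variant_spec("tiny", sr_mode = list(type = "bottleneck", r = 2L))
  bp2 <- spikeformer:::init_block_params(16L, spec_b2)
  out <- spatial_reduce(tok, spec_b2, bp2)
  expect_equal(c(out$h, out$w), c(8L, 8L))
  # piecewise-constant over 2x2 blocks
  rowid <- function(r, c) (r - 1) * 8 + c
  expect_equal(out$x[rowid(1, 1), ], out$x[rowid(1, 2), ])
  expect_equal(out$x[rowid(1, 1), ], out$x[rowid(2, 2), ])
  expect_false(isTRUE(all.equal(out$x[rowid(1, 1), ], out$x[rowid(1, 3), ])))

  spec_b1 <- variant_spec("tiny", sr_mode = list(type = "bottleneck", r = 1L))
  bp1 <- spikeformer:::init_block_params(16L, spec_b1)
  out1 <- spatial_reduce(tok, spec_b1, bp1)
  expect_equal(out1$x, sweep(x %*% bp1$sr$W, 2, bp1$sr$b, `+`),
               tolerance = 1e-12)
})

test_that("block pair: shape, residual identity, finite-difference gradients", {
  set.seed(37)
  C <- 32L
  spec <- structure(list(name = "custom", patch_size = 4L,
                         channels = rep(C, 4), depths = rep(2L, 4),
                         head_dim = 8L, window_sizes = c(7L, 9L, 11L),
                         mlp_ratio = 4L, sr_mode = "identity"),
                    class = "variant_spec")
  pair <- list(spikeformer:::init_block_params(C, spec),
               spikeformer:::init_block_params(C, spec))
  x <- matrix(rnorm(36 * C, sd = 0.5), 36, C)
  tok <- list(x = x, h = 6L, w = 6L)
  out <- block_pair_forward(tok, spec, pair)
  expect_equal(dim(out$x), dim(x))

  # zero residual branches -> identity map
  pair0 <- lapply(pair, function(b) {
    b$attn$proj$W[] <- 0; b$attn$proj$b[] <- 0
    b$mlp$W2[] <- 0; b$mlp$b2[] <- 0
    b
  })
  out0 <- block_pair_forward(tok, spec, pair0)
  expect_equal(out0$x, x, tolerance = 1e-12)

  # finite-difference gradient spot check through both blocks
  wgt <- matrix(runif(length(x)), nrow(x), ncol(x))
  fwd <- function(xv) {
    ad_reset()
    cache <- new.env(parent = emptyenv())
    xn <- ad_leaf(xv)
    o <- spikeformer:::block_forward_ad(xn, 6L, 6L, C, spec,
           spikeformer:::params_to_nodes(pair[[1]]), FALSE, cache)
    o <- spikeformer:::block_forward_ad(o, 6L, 6L, C, spec,
           spikeformer:::params_to_nodes(pair[[2]]), TRUE, cache)
    list(loss = ad_dot_const(o, wgt), input = xn)
  }
  r <- fwd(x)
  ad_backward(r$loss)
  ga <- r$input$grad
  eps <- 1e-5
  set.seed(38)
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    gn <- (fwd(xp)$loss$value - fwd(xm)$loss$value) / (2 * eps)
    expect_lt(abs(ga[i] - gn) / max(abs(gn), 1e-3), 1e-3)
  }
  ad_reset()
})

test_that("patch merging halves the grid and doubles channels", {
  set.seed(39)
  spec <- variant_spec("tiny")
  params <- init_backbone(spec, seed = 40)
  mp <- params$stages[[1]]$merge
  x <- matrix(rnorm(8 * 8 * 16), 64, 16)
  out <- patch_merge(list(x = x, h = 8L, w = 8L), mp)
  expect_equal(c(out$h, out$w, ncol(out$x)), c(4L, 4L, 32L))
  # constant input -> constant output
  cst <- patch_merge(list(x = matrix(1, 64, 16), h = 8L, w = 8L), mp)
  expect_lt(max(abs(sweep(cst$x, 2, cst$x[1, ]))), 1e-12)
  # odd grid is padded up: 7x7 -> 4x4
  odd <- patch_merge(list(x = matrix(rnorm(49 * 16), 49, 16), h = 7L, w = 7L), mp)
  expect_equal(c(odd$h, odd$w), c(4L, 4L))
})

test_that("backbone satisfies the stage-resolution contract and determinism", {
  spec <- variant_spec("tiny")
  params <- init_backbone(spec, seed = 41)
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))
  out <- backbone_forward(img, params)
  dims <- t(sapply(out$features, function(f) c(f$h, f$w, ncol(f$x))))
  expect_equal(dims[, 1], c(16, 8, 4, 2))
  expect_equal(dims[, 2], c(24, 12, 6, 3))
  expect_equal(dims[, 3], c(16, 32, 64, 128))
  # non-multiple-of-32 input is padded up first
  img2 <- array(runif(50 * 70 * 3), c(50, 70, 3))
  out2 <- backbone_forward(img2, params)
  expect_equal(c(out2$padded_h, out2$padded_w), c(64, 96))
  expect_equal(out2$features[[1]]$h, 16L)
  expect_error(backbone_forward(array(0, c(16, 16, 3)), params), "at least")
  # bitwise determinism
  outb <- backbone_forward(img, params)
  expect_identical(out$features[[4]]$x, outb$features[[4]]$x)
})

test_that("parameter counting is exact against instantiation", {
  for (mode in list("identity", list(type = "bottleneck", r = 2L))) {
    spec <- variant_spec("tiny", sr_mode = mode)
    bb <- init_backbone(spec, seed = 42)
    expect_identical(count_parameters(spec, include_head = FALSE),
                     count_parameters_actual(bb))
    det <- init_detector(spec, seed = 43)
    expect_identical(
      count_parameters(spec, include_head = TRUE,
                       head = list(channels = 32L, n_convs = 2L,
                                   n_classes = 1L)),
      count_parameters_actual(bb) + count_parameters_actual(det))
  }
  # published-scale variants are ordered S < B < L, B-S = 4 stage-3 blocks
  cs <- count_parameters(variant_spec("S"))
  cb <- count_parameters(variant_spec("B"))
  cl <- count_parameters(variant_spec("L"))
  expect_lt(cs, cb); expect_lt(cb, cl)
  expect_equal((cb - cs) / 4, (cl - cb) / 12)   # same per-block cost at C=384
})

test_that("backbone init is seed-reproducible", {
  spec <- variant_spec("tiny")
  expect_identical(init_backbone(spec, seed = 7), init_backbone(spec, seed = 7))
  expect_false(identical(init_backbone(spec, seed = 7),
                         init_backbone(spec, seed = 8)))
})
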