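test_that("descriptor validates scales and sizes", {
  expect_error(scn_descriptor(scales = c(2L, 3L)), "odd")
  expect_error(scn_descriptor(depth = 0L), "depth")
  expect_error(scn_descriptor(filters = 0L), "filters")
  d <- scn_descriptor(scales = c(5L, 1L, 3L, 3L))
  expect_identical(d$scales, c(1L, 3L, 5L))
})

test_that("parameter count matches direct enumeration", {
  d <- scn_descriptor(depth = 3L, scales = c(1L, 3L, 5L), filters = 16L)
  m <- init_scn(d, seed = 1L)
  n_direct <- sum(vapply(m$blocks, function(bl)
    sum(vapply(bl, function(s) length(s$W) + length(s$b), numeric(1))),
    numeric(1)))
  expect_identical(scn_param_count(m), n_direct)
  # [DERIVED] closed form for the toy SCN-3:
  # block1 (1->16): (1*1+1)*16 + (1*9+1)*16 + (1*25+1)*16 = 608
  # block2 (16->16): (16+1)*16 + (144+1)*16 + (400+1)*16  = 9008
  # block3 (16->1): 17 + 145 + 401                        = 563
  expect_identical(scn_param_count(d), 608 + 9008 + 563)
})

test_that("block forward equals the brute-force multi-scale maxout oracle", {
  set.seed(21)
  for (scales in list(3L, c(1L, 3L), c(1L, 3L, 5L), c(1L, 3L, 5L, 7L))) {
    d <- scn_descriptor(depth = 2L, scales = scales, filters = 3L,
                        in_channels = 2L)
    m <- init_scn(d, init_std = 0.5, seed = 77L)
    X <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    got <- competitive_block_forward(X, m$blocks[[1]])
    want <- cb_oracle(X, m$blocks[[1]])
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("a single-scale block is exactly a plain rectified convolution", {
  set.seed(22)
  d <- scn_descriptor(depth = 2L, scales = 3L, filters = 4L)
  m <- init_scn(d, init_std = 0.5, seed = 3L)
  X <- array(rnorm(8 * 8 * 1 * 1), c(8, 8, 1, 1))
  got <- competitive_block_forward(X, m$blocks[[1]])
  p <- m$blocks[[1]][[1]]
  want <- pmax(conv_oracle(X, p$W, p$b), 0)
  dim(want) <- dim(want)[1:3]        # batches of one drop the batch axis
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("block output dominates every single scale and is non-negative", {
  set.seed(23)
  m <- tiny_model(scales = c(1L, 3L, 5L), filters = 3L)
  X <- array(rnorm(7 * 7), c(7, 7, 1, 1))
  out <- competitive_block_forward(X, m$blocks[[1]])
  expect_true(all(out >= 0))
  for (p in m$blocks[[1]]) {
    single <- pmax(conv_oracle(X, p$W, p$b), 0)
    dim(single) <- dim(single)[1:3]
    expect_true(all(out - single >= -1e-12))
  }
})

test_that("adding a scale can only increase the block response pointwise", {
  set.seed(24)
  d3 <- scn_descriptor(depth = 1L, scales = c(1L, 3L), filters = 2L)
  m3 <- init_scn(d3, init_std = 0.3, seed = 9L)
  X <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  out2 <- competitive_block_forward(X, m3$blocks[[1]])
  # drop the 3x3 scale: the maximum over fewer candidates cannot grow
  out1 <- competitive_block_forward(X, m3$blocks[[1]]["k1"])
  expect_true(all(out2 - out1 >= -1e-12))
})

test_that("network is fully convolutional and preserves spatial shape", {
  m <- tiny_model()
  for (sz in list(c(16L, 16L), c(20L, 33L))) {
    x <- matrix(runif(prod(sz)), sz[1], sz[2])
    y <- scn_forward(x, m)
    expect_identical(dim(y), dim(x))
  }
})

test_that("network forward is translation equivariant away from borders", {
  set.seed(25)
  m <- tiny_model(depth = 2L, scales = c(1L, 3L), filters = 2L)
  x <- matrix(runif(24 * 24), 24, 24)
  y <- scn_forward(x, m)
  xs <- rbind(x[3:24, ], matrix(0, 2, 24))   # shift up by 2 rows
  ys <- scn_forward(xs, m)
  # receptive field of the 2-block net is 5 px -> 2 px halo per side
  core <- 3:18
  expect_lt(max(abs(ys[core, core] - y[core + 2, core])), 1e-10)
})

test_that("final block is linear: no rectifier on the output head", {
  # a model whose last block has strongly negative bias must be able to
  # output negative values (a ReLU head could not)
  d <- scn_descriptor(depth = 1L, scales = 1L, filters = 1L)
  m <- init_scn(d, seed = 1L)
  m$blocks[[1]]$k1$W[] <- 1
  m$blocks[[1]]$k1$b <- -5
  y <- scn_forward(matrix(0.5, 8, 8), m)
  expect_true(all(y < 0))
})

test_that("training-path forward agrees with the double-precision forward", {
  set.seed(26)
  m <- tiny_model(depth = 3L, scales = c(1L, 3L, 5L), filters = 4L)
  x <- matrix(runif(16 * 16), 16, 16)
  X <- x; dim(X) <- c(16, 16, 1, 1)
  ref <- scn_forward(x, m)
  fused <- ldctscn:::scn_forward_train(X, m)$pred
  dim(fused) <- dim(ref)
  expect_lt(max(abs(fused - ref)), 1e-5)   # single-precision path
})

test_that("loss matches hand-enumerated values and vanishes at the optimum", {
  m <- tiny_model()
  pred <- matrix(c(1, 2, 3, 4), 2, 2)
  target <- matrix(c(0, 0, 1, 1), 2, 2)
  # [DERIVED] sum((1,2,3,4)-(0,0,1,1))^2 = 1+4+4+9 = 18, batch of 1
  expect_equal(scn_loss(pred, target, m, alpha = 0), 18)
  wn <- sum(unlist(lapply(m$blocks, function(bl)
    lapply(bl, function(s) sum(s$W^2)))))
  expect_equal(scn_loss(pred, target, m, alpha = 0.5), 18 + 0.5 * wn)
  expect_identical(scn_loss(target, target, m, alpha = 0), 0)
  # batched: mean over the batch axis of per-patch pixel sums
  P <- array(c(pred, pred + 1), c(2, 2, 1, 2))
  Tg <- array(c(target, target), c(2, 2, 1, 2))
  # second patch residuals (2,3,3,4): 4+9+9+16 = 38; mean(18, 38) = 28
  expect_equal(scn_loss(P, Tg, m, alpha = 0), 28)
})

test_that("checkpoints round trip and refuse mismatching weights", {
  m <- tiny_model(depth = 2L, scales = c(1L, 3L), filters = 3L)
  path <- tempfile(fileext = ".ckpt")
  on.exit(unlink(path))
  save_scn(m, path)
  back <- load_scn(path)
  expect_equal(back$descriptor, m$descriptor)
  expect_equal(back$blocks, m$blocks)
  x <- matrix(runif(12 * 12), 12, 12)
  expect_identical(scn_forward(x, back), scn_forward(x, m))
  # corrupt: weights of the wrong shape for the declared descriptor
  obj <- readRDS(path)
  obj$blocks[[1]]$k3$W <- array(0, c(5, 5, 1, 3))
  saveRDS(obj, path)
  expect_error(load_scn(path), "mismatch")
})

test_that("variant tags map to their published scale sets", {
  expect_identical(variant_scales("cnn3"), 3L)
  expect_identical(variant_scales("cnn5"), 5L)
  expect_identical(variant_scales("scn2"), c(1L, 3L))
  expect_identical(variant_scales("scn3"), c(1L, 3L, 5L))
  expect_identical(variant_scales("scn4"), c(1L, 3L, 5L, 7L))
  expect_error(variant_scales("vgg"), "arg")
})
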