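test_that("patch extraction enumerates the sliding-window count exactly", {
  img <- matrix(runif(64 * 64), 64, 64)
  cfg <- toy_train_config()            # 16 px patches, stride 4
  ps <- extract_patches(img, img, cfg, source_id = "a")
  # [DERIVED] floor((64 - 16) / 4) + 1 = 13 origins per axis
  expect_identical(dim(ps$ld)[4], 169L)
  expect_identical(nrow(ps$offsets), 169L)
  expect_identical(unique(ps$source), "a")
})

test_that("patches are aligned crops of both images at the recorded offsets", {
  set.seed(31)
  ld <- matrix(runif(32 * 32), 32, 32)
  nd <- matrix(runif(32 * 32), 32, 32)
  cfg <- toy_train_config(patch_size = 8L, stride = 6L)
  ps <- extract_patches(ld, nd, cfg)
  for (i in c(1L, 7L, dim(ps$ld)[4])) {
    r <- ps$offsets[i, 1]; c <- ps$offsets[i, 2]
    expect_identical(ps$ld[, , 1, i], ld[r + 1:8, c + 1:8])
    expect_identical(ps$nd[, , 1, i], nd[r + 1:8, c + 1:8])
  }
  expect_error(extract_patches(ld, nd[1:16, 1:16], cfg), "differ")
  expect_error(extract_patches(ld, nd, toy_train_config(patch_size = 64L)),
               "exceeds")
})

test_that("combining patch sets preserves counts and provenance", {
  img <- matrix(runif(24 * 24), 24, 24)
  cfg <- toy_train_config(patch_size = 8L, stride = 8L)
  a <- extract_patches(img, img, cfg, source_id = "s1")
  b <- extract_patches(img + 1, img, cfg, source_id = "s2")
  ab <- combine_patch_sets(list(a, b))
  expect_identical(dim(ab$ld)[4], 18L)
  expect_identical(table(ab$source), table(rep(c("s1", "s2"), each = 9L)))
  expect_identical(ab$ld[, , 1, 10], b$ld[, , 1, 1])
})

test_that("learning rate steps down by decades across the epoch budget", {
  cfg <- toy_train_config()   # 1e-2 -> 1e-5 over 30 epochs
  lrs <- vapply(1:30, ldctscn:::lr_at_epoch, numeric(1), cfg = cfg)
  expect_equal(lrs[1], 1e-2)
  expect_equal(lrs[30], 1e-5)
  expect_identical(sort(unique(lrs), decreasing = TRUE),
                   c(1e-2, 1e-3, 1e-4, 1e-5))
  expect_true(all(diff(lrs) <= 0))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(32)
  m <- tiny_model(depth = 2L, scales = c(1L, 3L), filters = 2L,
                  init_std = 0.3)
  patches <- list(ld = array(runif(6 * 6 * 1 * 3), c(6, 6, 1, 3)),
                  nd = array(runif(6 * 6 * 1 * 3), c(6, 6, 1, 3)))
  bg <- ldctscn:::batch_grads(m, patches, 1:3, alpha = 1e-3)
  loss_at <- function(model) {
    X <- patches$ld; Tg <- patches$nd
    pred <- scn_forward(X, model)
    sum((pred - Tg)^2) / 3 + 1e-3 * ldctscn:::scn_weight_norm(model)
  }
  h <- 1e-4
  for (probe in list(c(1L, 1L), c(2L, 2L))) {
    i <- probe[1]; s <- probe[2]
    W <- m$blocks[[i]][[s]]$W
    nw <- length(W)
    for (flat in unique(pmin(c(1L, nw %/% 2L, nw), nw))) {
      mp <- m; mp$blocks[[i]][[s]]$W[flat] <- W[flat] + h
      mm <- m; mm$blocks[[i]][[s]]$W[flat] <- W[flat] - h
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      an <- bg$grads[[i]][[s]]$W[flat]
      expect_lt(abs(fd - an) / max(abs(fd), 1e-3), 5e-3)
    }
    bp <- m; bp$blocks[[i]][[s]]$b[1] <- m$blocks[[i]][[s]]$b[1] + h
    bm <- m; bm$blocks[[i]][[s]]$b[1] <- m$blocks[[i]][[s]]$b[1] - h
    fd <- (loss_at(bp) - loss_at(bm)) / (2 * h)
    expect_lt(abs(fd - bg$grads[[i]][[s]]$b[1]) / max(abs(fd), 1e-3), 5e-3)
  }
})

test_that("fine-tuning reduces the training loss on a learnable mapping", {
  set.seed(33)
  base <- matrix(runif(32 * 32), 32, 32)
  nd <- base
  ld <- base + matrix(rnorm(32 * 32, sd = 0.05), 32, 32)
  cfg <- toy_train_config(patch_size = 8L, stride = 4L, epochs = 6L,
                          lr_init = 1e-3, lr_final = 1e-4, seed = 2L)
  ps <- extract_patches(ld, nd, cfg)
  m <- init_scn(scn_descriptor(depth = 2L, scales = c(1L, 3L),
                               filters = 4L), seed = 5L)
  ft <- fine_tune(ps, m, cfg, val_pairs = list(list(ld = ld, nd = nd)))
  expect_identical(nrow(ft$log), 6L)
  expect_lt(ft$log$train_loss[6], ft$log$train_loss[1])
  expect_true(all(c("adam", "sgd") %in% ft$log$phase))
  # denoised validation image beats the identity start of a random net
  expect_gt(max(ft$log$val_psnr), psnr(scn_forward(ld, m), nd))
})

test_that("the best-validation checkpoint is the one returned", {
  set.seed(34)
  nd <- matrix(runif(24 * 24), 24, 24)
  ld <- nd + matrix(rnorm(24 * 24, sd = 0.1), 24, 24)
  cfg <- toy_train_config(patch_size = 8L, stride = 8L, epochs = 4L,
                          lr_init = 1e-3, lr_final = 1e-3, seed = 3L)
  ps <- extract_patches(ld, nd, cfg)
  m <- init_scn(scn_descriptor(depth = 2L, scales = 3L, filters = 2L),
                seed = 8L)
  ft <- fine_tune(ps, m, cfg, val_pairs = list(list(ld = ld, nd = nd)))
  expect_identical(ft$best_epoch, which.max(ft$log$val_psnr))
  expect_equal(psnr(scn_forward(ld, ft$model), nd),
               max(ft$log$val_psnr))
})

test_that("training is deterministic given the configuration seed", {
  set.seed(35)
  nd <- matrix(runif(24 * 24), 24, 24)
  ld <- nd + matrix(rnorm(24 * 24, sd = 0.1), 24, 24)
  cfg <- toy_train_config(patch_size = 8L, stride = 8L, epochs = 2L,
                          lr_init = 1e-3, seed = 11L)
  ps <- extract_patches(ld, nd, cfg)
  run <- function() {
    m <- init_scn(scn_descriptor(depth = 2L, scales = c(1L, 3L),
                                 filters = 2L), seed = 4L)
    fine_tune(ps, m, cfg)$model
  }
  expect_equal(run(), run(), tolerance = 0)
})

test_that("greedy pretraining reduces each block's reconstruction error", {
  set.seed(36)
  A <- array(runif(8 * 8 * 1 * 40), c(8, 8, 1, 40))
  patches <- list(ld = A, nd = A)
  cfg <- toy_train_config(pretrain = "greedy", pretrain_epochs = 4L,
                          seed = 6L)
  m0 <- init_scn(scn_descriptor(depth = 2L, scales = c(1L, 3L),
                                filters = 4L), seed = 7L)
  m1 <- pretrain_blocks(patches, m0, cfg)
  # hidden block weights moved, final block untouched
  expect_false(identical(m0$blocks[[1]], m1$blocks[[1]]))
  expect_identical(m0$blocks[[2]], m1$blocks[[2]])
  # pretraining is deterministic
  m2 <- pretrain_blocks(patches, m0, cfg)
  expect_equal(m1, m2, tolerance = 0)
  # depth-1 networks have nothing to pretrain
  s <- init_scn(scn_descriptor(depth = 1L, scales = 1L, filters = 1L),
                seed = 1L)
  expect_identical(pretrain_blocks(patches, s, cfg), s)
})

test_that("training config rejects inconsistent rates and sizes", {
  expect_error(train_config(lr_init = 1e-4, lr_final = 1e-2), "lr_final")
  expect_error(train_config(alpha = -1), "alpha")
  expect_error(train_config(epochs = 0L), "positive")
  expect_error(train_config(pretrain = "magic"), "arg")
})
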