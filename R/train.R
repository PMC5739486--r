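#' Training configuration
#'
#' Collects every tunable of the training regimen with the package's
#' defaults. The full-scale profile mirrors a GPU-era recipe (100x100
#' patches at stride 4, about 1e6 patches, 96 filters); [toy_train_config()]
#' gives a CPU-scale profile used throughout the examples and tests.
#'
#' The learning rate follows a multiplicative step decay: it starts at
#' `lr_init` and drops by factors of 10 at evenly spaced epochs so the last
#' epoch runs at `lr_final`. Optimization runs in two phases: Adam for the
#' first `adam_frac` of the epochs, plain SGD for the rest.
#'
#' @param patch_size side of the square training patches (pixels).
#' @param stride sliding-window step between patch origins (pixels).
#' @param epochs total fine-tuning epochs.
#' @param batch_size patches per gradient step.
#' @param lr_init,lr_final initial and final learning rate.
#' @param adam_frac fraction of epochs optimized with Adam before the SGD
#'   phase.
#' @param alpha weight-decay coefficient on the squared Frobenius norm of
#'   the kernels.
#' @param init_std standard deviation of the Gaussian weight init.
#' @param pretrain `"none"` or `"greedy"` layer-wise pretraining of the
#'   first depth-1 blocks.
#' @param pretrain_epochs,pretrain_lr budget and Adam learning rate of each
#'   greedy pretraining phase.
#' @param val_frac fraction of training source images held out (at image
#'   level) for validation.
#' @param seed integer seed governing init, shuffling and pretraining.
#' @return a list of class `train_config`.
#' @export
train_config <- function(patch_size = 100L, stride = 4L, epochs = 100L,
                         batch_size = 32L, lr_init = 1e-2, lr_final = 1e-5,
                         adam_frac = 0.5, alpha = 1e-4, init_std = 0.01,
                         pretrain = c("none", "greedy"),
                         pretrain_epochs = 2L, pretrain_lr = 1e-3,
                         val_frac = 0.1, seed = 1L) {
  pretrain <- match.arg(pretrain)
  if (lr_final > lr_init) stopf("'lr_final' must be <= 'lr_init'")
  for (nm in c("lr_init", "lr_final", "pretrain_lr"))
    check_number(get(nm), nm, 0, strict = TRUE)
  check_number(alpha, "alpha", 0)
  if (patch_size < 1 || stride < 1 || epochs < 1 || batch_size < 1)
    stopf("sizes and budgets must be positive integers")
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_final = lr_final, adam_frac = adam_frac, alpha = alpha,
                 init_std = init_std, pretrain = pretrain,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_lr = pretrain_lr, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' CPU-scale training profile
#'
#' 16x16 patches at stride 4 from 64x64 slices, 30 epochs, batch 32 —
#' the configuration used by the package's worked examples.
#'
#' @param ... overrides passed to [train_config()].
#' @export
toy_train_config <- function(...) {
  args <- list(patch_size = 16L, stride = 4L, epochs = 30L, batch_size = 32L)
  do.call(train_config, utils::modifyList(args, list(...)))
}

#' Extract aligned low-dose / normal-dose patch pairs
#'
#' Slides a `patch_size` window over both images at the same offsets
#' (`stride` pixels apart, window fully inside the image), in deterministic
#' row-major offset order. Per axis there are
#' `floor((N - patch_size) / stride) + 1` origins.
#'
#' @param ld,nd low-dose and normal-dose images (same-shape matrices,
#'   typically normalized to `[0, 1]`).
#' @param cfg a [train_config()] (only `patch_size` and `stride` are used).
#' @param source_id provenance label recorded with every patch.
#' @return a `patch_set`: arrays `ld` and `nd` of shape
#'   patch x patch x 1 x n, integer offset matrix `offsets` (top-left,
#'   0-based), and `source` id per patch.
#' @export
extract_patches <- function(ld, nd, cfg, source_id = "img") {
  if (!identical(dim(ld), dim(nd))) stopf("'ld' and 'nd' shapes differ")
  ps <- cfg$patch_size; st <- cfg$stride
  if (ps > nrow(ld) || ps > ncol(ld))
    stopf("patch size %d exceeds image size %dx%d", ps, nrow(ld), ncol(ld))
  r0 <- seq(0L, nrow(ld) - ps, by = st)
  c0 <- seq(0L, ncol(ld) - ps, by = st)
  offs <- cbind(row = rep(r0, each = length(c0)),
                col = rep(c0, times = length(r0)))
  n <- nrow(offs)
  pl <- array(0, c(ps, ps, 1L, n)); pn <- array(0, c(ps, ps, 1L, n))
  for (i in seq_len(n)) {
    r <- offs[i, 1]; c <- offs[i, 2]
    pl[, , 1L, i] <- ld[r + seq_len(ps), c + seq_len(ps)]
    pn[, , 1L, i] <- nd[r + seq_len(ps), c + seq_len(ps)]
  }
  structure(list(ld = pl, nd = pn, offsets = offs,
                 source = rep(source_id, n), patch_size = ps),
            class = "patch_set")
}

#' Pool patch sets from several source images
#' @param sets list of `patch_set` objects with equal patch size.
#' @return one combined `patch_set`.
#' @export
combine_patch_sets <- function(sets) {
  ps <- sets[[1]]$patch_size
  if (!all(vapply(sets, function(s) s$patch_size == ps, logical(1))))
    stopf("patch sizes differ across sets")
  structure(list(
    ld = array(unlist(lapply(sets, `[[`, "ld")), c(ps, ps, 1L,
               sum(vapply(sets, function(s) dim(s$ld)[4], integer(1))))),
    nd = array(unlist(lapply(sets, `[[`, "nd")), c(ps, ps, 1L,
               sum(vapply(sets, function(s) dim(s$nd)[4], integer(1))))),
    offsets = do.call(rbind, lapply(sets, `[[`, "offsets")),
    source = unlist(lapply(sets, `[[`, "source")),
    patch_size = ps), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d pairs of %dx%d patches from %d source image(s)\n",
              dim(x$ld)[4], x$patch_size, x$patch_size,
              length(unique(x$source))))
  invisible(x)
}

# ---- optimizers ------------------------------------------------------------

# flat views over the model parameter tree, so optimizer code is generic
zero_like_params <- function(model) {
  lapply(model$blocks, function(bl) lapply(bl, function(s)
    list(W = array(0, dim(s$W)), b = numeric(length(s$b)))))
}

adam_init <- function(model) {
  list(m = zero_like_params(model), v = zero_like_params(model), t = 0L)
}

# one parameter update in place over the nested block/scale structure
apply_update <- function(model, grads, fun) {
  for (i in seq_along(model$blocks)) for (s in names(model$blocks[[i]])) {
    model$blocks[[i]][[s]]$W <- fun(i, s, "W", model$blocks[[i]][[s]]$W,
                                    grads[[i]][[s]]$W)
    model$blocks[[i]][[s]]$b <- fun(i, s, "b", model$blocks[[i]][[s]]$b,
                                    grads[[i]][[s]]$b)
  }
  model
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  model <- apply_update(model, grads, function(i, s, w, par, g) {
    m <- beta1 * state$m[[i]][[s]][[w]] + (1 - beta1) * g
    v <- beta2 * state$v[[i]][[s]][[w]] + (1 - beta2) * g^2
    state$m[[i]][[s]][[w]] <<- m
    state$v[[i]][[s]][[w]] <<- v
    par - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(model = model, state = state)
}

sgd_step <- function(model, grads, lr) {
  apply_update(model, grads, function(i, s, w, par, g) par - lr * g)
}

# stepped decade decay from lr_init to lr_final across the epoch budget
lr_at_epoch <- function(epoch, cfg) {
  if (cfg$epochs == 1L || cfg$lr_final == cfg$lr_init) return(cfg$lr_init)
  decades <- log10(cfg$lr_init / cfg$lr_final)
  lev <- floor(decades * (epoch - 1) / (cfg$epochs - 1))
  cfg$lr_init * 10^(-lev)
}

# loss and parameter gradients on one minibatch (indices into the patch set)
batch_grads <- function(model, patches, idx, alpha) {
  X <- patches$ld[, , , idx, drop = FALSE]
  Tg <- patches$nd[, , , idx, drop = FALSE]
  fw <- scn_forward_train(X, model)
  n <- length(idx)
  resid <- fw$pred - Tg
  loss <- sum(resid^2) / n + alpha * scn_weight_norm(model)
  grads <- scn_backward(fw, model, 2 * resid / n)
  if (alpha > 0)
    for (i in seq_along(grads)) for (s in names(grads[[i]]))
      grads[[i]][[s]]$W <- grads[[i]][[s]]$W +
        2 * alpha * model$blocks[[i]][[s]]$W
  list(loss = loss, grads = grads)
}

#' Greedy layer-wise pretraining of the hidden blocks
#'
#' Initializes the first depth-1 blocks one at a time: block i, together
#' with a throwaway linear convolutional head mapping back to the block's
#' input channels, is trained (Adam, `cfg$pretrain_lr`) to reconstruct its
#' own input — a per-block autoencoding objective computed on the low-dose
#' patches only. After each phase the head is discarded, the block's output
#' features become the next block's input, and training moves on. The final
#' reconstruction block keeps its random initialization. With depth 1
#' there is nothing to pretrain and the model is returned unchanged.
#'
#' @param patches a `patch_set` (only the `ld` member is used).
#' @param model a freshly initialized `scn_model`.
#' @param cfg a [train_config()].
#' @return the model with pretrained hidden blocks.
#' @export
pretrain_blocks <- function(patches, model, cfg) {
  d <- model$descriptor
  if (d$depth <= 1L) return(model)
  seeds <- derive_seeds(cfg$seed + 211L, d$depth)
  A <- patches$ld
  n <- dim(A)[4]
  ch <- block_channels(d)
  for (i in seq_len(d$depth - 1L)) {
    # temporary linear head: 3x3 kernels, block output -> block input
    head <- with_seed(seeds[i] + 1L, list(
      W = array(rnorm(9L * ch$cout[i] * ch$cin[i], sd = cfg$init_std),
                dim = c(3L, 3L, ch$cout[i], ch$cin[i])),
      b = numeric(ch$cin[i])))
    st_blk <- adam_init(structure(list(blocks = model$blocks[i]),
                                  class = "scn_model"))
    st_head <- list(m = list(W = array(0, dim(head$W)),
                             b = numeric(length(head$b))),
                    v = list(W = array(0, dim(head$W)),
                             b = numeric(length(head$b))), t = 0L)
    order_seed <- seeds[i] + 2L
    for (ep in seq_len(cfg$pretrain_epochs)) {
      perm <- with_seed(order_seed + ep, sample.int(n))
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
        Xb <- A[, , , idx, drop = FALSE]
        bl <- model$blocks[[i]]
        fwc <- cb_fwd_train_cpp(Xb, lapply(bl, `[[`, "W"),
                                lapply(bl, `[[`, "b"), TRUE)
        rec <- conv2d_forward_cpp(fwc$out, head$W, head$b)
        resid <- rec - Xb
        if (any(!is.finite(resid)))
          stopf("pretraining diverged at block %d epoch %d", i, ep)
        dRec <- 2 * resid / length(idx)
        gh <- conv2d_backward_cpp(fwc$out, head$W, dRec)
        bk <- cb_bwd_train_cpp(fwc$cache, lapply(bl, `[[`, "W"), fwc$out,
                               fwc$amax, gh$dX, TRUE)
        # Adam on the block
        st_blk$t <- st_blk$t + 1L
        bc1 <- 1 - 0.9^st_blk$t; bc2 <- 1 - 0.999^st_blk$t
        for (si in seq_along(bl)) {
          s <- names(bl)[si]
          for (w in c("W", "b")) {
            g <- if (w == "W") bk$gW[[si]] else bk$gb[[si]]
            m <- 0.9 * st_blk$m[[1]][[s]][[w]] + 0.1 * g
            v <- 0.999 * st_blk$v[[1]][[s]][[w]] + 0.001 * g^2
            st_blk$m[[1]][[s]][[w]] <- m
            st_blk$v[[1]][[s]][[w]] <- v
            model$blocks[[i]][[s]][[w]] <- model$blocks[[i]][[s]][[w]] -
              cfg$pretrain_lr * (m / bc1) / (sqrt(v / bc2) + 1e-8)
          }
        }
        # Adam on the head
        st_head$t <- st_head$t + 1L
        bc1 <- 1 - 0.9^st_head$t; bc2 <- 1 - 0.999^st_head$t
        for (w in c("W", "b")) {
          g <- if (w == "W") gh$dW else gh$db
          m <- 0.9 * st_head$m[[w]] + 0.1 * g
          v <- 0.999 * st_head$v[[w]] + 0.001 * g^2
          st_head$m[[w]] <- m; st_head$v[[w]] <- v
          head[[w]] <- head[[w]] - cfg$pretrain_lr * (m / bc1) /
            (sqrt(v / bc2) + 1e-8)
        }
      }
    }
    bl <- model$blocks[[i]]
    A <- cb_fwd_train_cpp(A, lapply(bl, `[[`, "W"), lapply(bl, `[[`, "b"),
                          TRUE)$out
  }
  model
}

#' Supervised fine-tuning of the whole network
#'
#' Minimizes the squared-error-plus-weight-decay loss end to end on the
#' patch pairs: an Adam phase followed by an SGD phase, with the stepped
#' learning-rate decay described in [train_config()]. After every epoch the
#' model is evaluated (PSNR) on the supplied validation image pairs and the
#' best-validation weights are retained.
#'
#' @param patches a `patch_set` of aligned training pairs.
#' @param model an `scn_model` (randomly initialized or pretrained).
#' @param cfg a [train_config()].
#' @param val_pairs list of validation pairs, each `list(ld =, nd =)` of
#'   same-shape matrices; may be empty, in which case the final weights are
#'   returned.
#' @return list with `model` (best weights), `log` (data frame: epoch,
#'   phase, lr, train_loss, val_psnr) and `best_epoch`.
#' @export
fine_tune <- function(patches, model, cfg, val_pairs = list()) {
  n <- dim(patches$ld)[4]
  adam_epochs <- floor(cfg$epochs * cfg$adam_frac)
  st <- adam_init(model)
  best <- list(psnr = -Inf, model = model, epoch = 0L)
  log <- vector("list", cfg$epochs)
  shuffle_seeds <- derive_seeds(cfg$seed + 977L, cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(ep, cfg)
    phase <- if (ep <= adam_epochs) "adam" else "sgd"
    perm <- with_seed(shuffle_seeds[ep], sample.int(n))
    tot <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
      bg <- batch_grads(model, patches, idx, cfg$alpha)
      if (!is.finite(bg$loss))
        stopf("fine-tuning diverged at epoch %d (lr %g, %s phase)",
              ep, lr, phase)
      if (phase == "adam") {
        up <- adam_step(model, bg$grads, st, lr)
        model <- up$model; st <- up$state
      } else {
        model <- sgd_step(model, bg$grads, lr)
      }
      tot <- tot + bg$loss; nb <- nb + 1L
    }
    vp <- if (length(val_pairs))
      mean(vapply(val_pairs, function(p)
        psnr(scn_forward(p$ld, model), p$nd), numeric(1)))
    else NA_real_
    log[[ep]] <- data.frame(epoch = ep, phase = phase, lr = lr,
                            train_loss = tot / nb, val_psnr = vp)
    if (!is.na(vp) && vp > best$psnr)
      best <- list(psnr = vp, model = model, epoch = ep)
  }
  final <- if (length(val_pairs) && best$epoch > 0L) best$model else model
  list(model = final, log = do.call(rbind, log),
       best_epoch = if (length(val_pairs)) best$epoch else cfg$epochs)
}
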