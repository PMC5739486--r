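#' Stacked competitive network model
#'
#' A stacked competitive network (SCN) is a fully convolutional image-to-
#' image network built from competitive blocks. Each block convolves its
#' input at several kernel scales (e.g. 1x1, 3x3 and 5x5), applies a ReLU to
#' each scale, and combines the scales by an element-wise maximum per pixel
#' and per filter — a multi-scale maxout. All scales use same-size zero
#' padding so their maps align spatially, and no pooling is used, so the
#' network preserves resolution and accepts any input size at inference.
#' The final block has a single output filter and reconstructs the denoised
#' image directly; by default its output is linear (max of affine responses,
#' no terminal ReLU).
#'
#' @param depth number of stacked competitive blocks (the last one is the
#'   reconstruction block).
#' @param scales integer vector of odd kernel sizes shared by all blocks,
#'   e.g. `c(1, 3, 5)` for an SCN-3.
#' @param filters output filters of every hidden block (the final block has
#'   one).
#' @param in_channels input channels (1 for grayscale CT slices).
#' @param final_relu apply ReLU to the final block's scales before the max
#'   (default `FALSE`: linear output head).
#' @param residual learn the correction to add to the input instead of the
#'   image itself (default `FALSE`: direct mapping).
#' @return an unweighted model descriptor of class `scn_descriptor`; give it
#'   weights with [init_scn()] or [load_scn()].
#' @export
scn_descriptor <- function(depth = 5L, scales = c(1L, 3L, 5L), filters = 96L,
                           in_channels = 1L, final_relu = FALSE,
                           residual = FALSE) {
  scales <- as.integer(sort(unique(scales)))
  if (any(scales < 1L) || any(scales %% 2L == 0L))
    stopf("kernel scales must be odd and >= 1")
  if (depth < 1L) stopf("'depth' must be >= 1")
  if (filters < 1L) stopf("'filters' must be >= 1")
  structure(list(depth = as.integer(depth), scales = scales,
                 filters = as.integer(filters),
                 in_channels = as.integer(in_channels),
                 final_relu = isTRUE(final_relu),
                 residual = isTRUE(residual)),
            class = "scn_descriptor")
}

# channel sizes entering/leaving each block
block_channels <- function(d) {
  cin <- c(d$in_channels, rep(d$filters, d$depth - 1L))
  cout <- c(rep(d$filters, d$depth - 1L), 1L)
  list(cin = cin, cout = cout)
}

#' Initialize SCN weights
#'
#' Kernels are drawn from zero-mean Gaussians with standard deviation
#' `init_std`; biases start at zero.
#'
#' @param descriptor an [scn_descriptor()].
#' @param init_std standard deviation of the Gaussian weight init.
#' @param seed integer seed for a reproducible draw.
#' @return an `scn_model`: the descriptor plus a `blocks` list; block i
#'   holds, per scale k, `W` (k x k x C_in x C_out array) and `b` (C_out).
#' @export
init_scn <- function(descriptor, init_std = 0.01, seed = NULL) {
  if (!inherits(descriptor, "scn_descriptor"))
    stopf("'descriptor' must be an scn_descriptor")
  ch <- block_channels(descriptor)
  blocks <- with_seed(seed, lapply(seq_len(descriptor$depth), function(i) {
    lapply(setNames(descriptor$scales, paste0("k", descriptor$scales)),
           function(k) {
             list(W = array(rnorm(k * k * ch$cin[i] * ch$cout[i],
                                  sd = init_std),
                            dim = c(k, k, ch$cin[i], ch$cout[i])),
                  b = numeric(ch$cout[i]))
           })
  }))
  structure(list(descriptor = descriptor, blocks = blocks),
            class = "scn_model")
}

#' @export
print.scn_model <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf("scn_model: depth %d, scales {%s}, %d filters, %s head%s; %d parameters\n",
              d$depth, paste(d$scales, collapse = ","), d$filters,
              if (d$final_relu) "ReLU" else "linear",
              if (d$residual) ", residual" else "", scn_param_count(x)))
  invisible(x)
}

#' Trainable parameter count
#'
#' Closed form: over blocks and scales, `(C_in * k^2 + 1) * C_out`.
#'
#' @param model an `scn_model` or `scn_descriptor`.
#' @return integer parameter count.
#' @export
scn_param_count <- function(model) {
  d <- if (inherits(model, "scn_model")) model$descriptor else model
  ch <- block_channels(d)
  sum(vapply(seq_len(d$depth), function(i)
    sum((ch$cin[i] * d$scales^2 + 1) * ch$cout[i]), numeric(1)))
}

# canonical 4-D (H, W, C, N) view of a matrix / 3-D array / 4-D array
as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  else if (length(dim(x)) != 4L) stopf("expected a matrix or 3-/4-D array")
  x
}

# forward pass of one block with everything backward needs cached
cb_forward_cache <- function(X, params, relu = TRUE) {
  scales <- names(params)
  Zs <- vector("list", length(scales))
  out <- NULL
  amax <- NULL
  for (si in seq_along(scales)) {
    p <- params[[si]]
    Z <- conv2d_forward_cpp(X, p$W, p$b)
    A <- if (relu) pmax(Z, 0) else Z
    dim(A) <- dim(Z)
    Zs[[si]] <- Z
    if (is.null(out)) {
      out <- A
      amax <- array(1L, dim = dim(A))
    } else {
      sel <- A > out             # strict: ties keep the earlier scale
      out[sel] <- A[sel]
      amax[sel] <- si
    }
  }
  list(out = out, Z = Zs, amax = amax)
}

cb_backward <- function(X, params, cache, dOut, relu = TRUE) {
  dX <- NULL
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  for (si in seq_along(params)) {
    mask <- cache$amax == si
    if (relu) mask <- mask & (cache$Z[[si]] > 0)
    dZ <- dOut * mask
    dim(dZ) <- dim(dOut)
    g <- conv2d_backward_cpp(X, params[[si]]$W, dZ)
    grads[[si]] <- list(W = g$dW, b = g$db)
    dX <- if (is.null(dX)) g$dX else dX + g$dX
  }
  list(dX = dX, grads = grads)
}

#' Forward pass of a single competitive block
#'
#' For each kernel scale k the input is convolved (same padding) with that
#' scale's kernels, a bias is added and a ReLU applied; the block output is
#' the element-wise maximum across scales, per pixel and per filter. The
#' output is therefore non-negative and pointwise no smaller than any single
#' scale's rectified response.
#'
#' @param a_prev input feature map: H x W matrix, H x W x C array, or
#'   H x W x C x N batch.
#' @param params one block of an `scn_model` (named per-scale list with `W`
#'   and `b`).
#' @param relu apply the rectifier before the max (hidden-block behaviour).
#' @return feature map array of shape H x W x C_out (x N when batched).
#' @export
competitive_block_forward <- function(a_prev, params, relu = TRUE) {
  X <- as_feature_map(a_prev)
  if (any(!is.finite(X))) stopf("input feature map must be finite")
  cin <- dim(params[[1]]$W)[3]
  if (dim(X)[3] != cin)
    stopf("channel mismatch: input has %d channels, block expects %d",
          dim(X)[3], cin)
  out <- cb_forward_cache(X, params, relu = relu)$out
  if (dim(out)[4] == 1L) dim(out) <- dim(out)[1:3]
  out
}

#' Forward pass of the full stacked network
#'
#' Sequential composition of competitive blocks: hidden blocks use
#' rectified multi-scale maxout, the final block maps to one channel with a
#' linear (or optionally rectified) head. Fully convolutional: any H x W
#' input is accepted, and the output has the same spatial size.
#'
#' @param x input image: H x W matrix (or H x W x 1 array), values
#'   typically in `[0, 1]`; a 4-D H x W x 1 x N batch is also accepted.
#' @param model an `scn_model` from [init_scn()] or training.
#' @return the estimated clean image, same spatial shape as the input.
#' @export
scn_forward <- function(x, model) {
  if (!inherits(model, "scn_model")) stopf("'model' must be an scn_model")
  was_matrix <- is.matrix(x)
  X <- as_feature_map(x)
  d <- model$descriptor
  A <- X
  for (i in seq_len(d$depth)) {
    relu <- i < d$depth || d$final_relu
    A <- cb_forward_cache(A, model$blocks[[i]], relu = relu)$out
    if (any(!is.finite(A)))
      stopf("non-finite activations after block %d", i)
  }
  if (d$residual) A <- A + X
  if (was_matrix && dim(A)[4] == 1L) dim(A) <- dim(A)[1:2]
  A
}

# full forward with caches, for training.  The training path runs in single
# precision through the fused block kernels (im2col shared across scales and
# reused by the backward pass); the inference/oracle path above stays in
# double precision.
scn_forward_train <- function(X, model) {
  d <- model$descriptor
  caches <- vector("list", d$depth)
  A <- X
  for (i in seq_len(d$depth)) {
    bl <- model$blocks[[i]]
    relu <- i < d$depth || d$final_relu
    caches[[i]] <- cb_fwd_train_cpp(A, lapply(bl, `[[`, "W"),
                                    lapply(bl, `[[`, "b"), relu)
    A <- caches[[i]]$out
  }
  pred <- if (d$residual) A + X else A
  list(pred = pred, caches = caches)
}

scn_backward <- function(fw, model, dPred) {
  d <- model$descriptor
  grads <- vector("list", d$depth)
  dA <- dPred
  for (i in rev(seq_len(d$depth))) {
    bl <- model$blocks[[i]]
    relu <- i < d$depth || d$final_relu
    bk <- cb_bwd_train_cpp(fw$caches[[i]]$cache, lapply(bl, `[[`, "W"),
                           fw$caches[[i]]$out, fw$caches[[i]]$amax, dA, relu)
    g <- vector("list", length(bl))
    names(g) <- names(bl)
    for (s in seq_along(bl)) g[[s]] <- list(W = bk$gW[[s]], b = bk$gb[[s]])
    grads[[i]] <- g
    dA <- bk$dX
  }
  grads
}

#' Training loss: squared error plus weight decay
#'
#' The data term is the squared L2 distance between prediction and target,
#' summed over pixels and averaged over the batch; the regularizer is
#' `alpha` times the total squared Frobenius norm of all convolution
#' kernels of all scales and blocks (biases excluded), discouraging large
#' weights.
#'
#' @param pred,target images or batches of identical shape.
#' @param model the `scn_model` whose weights enter the decay term.
#' @param alpha weight-decay coefficient (>= 0).
#' @return scalar loss.
#' @export
scn_loss <- function(pred, target, model, alpha = 0) {
  check_number(alpha, "alpha", 0)
  P <- as_feature_map(pred); Tg <- as_feature_map(target)
  if (!identical(dim(P), dim(Tg)))
    stopf("'pred' and 'target' shapes differ")
  n <- dim(P)[4]
  data_term <- sum((Tg - P)^2) / n
  data_term + alpha * scn_weight_norm(model)
}

# total squared Frobenius norm of all convolution kernels
scn_weight_norm <- function(model) {
  sum(vapply(model$blocks, function(bl)
    sum(vapply(bl, function(s) sum(s$W^2), numeric(1))), numeric(1)))
}

#' Save / load an SCN checkpoint
#'
#' A checkpoint is a single file holding the architecture descriptor
#' (stored as a JSON string) together with the weights. The loader
#' re-derives the expected weight shapes from the descriptor and refuses a
#' mismatching file.
#'
#' @param model an `scn_model`.
#' @param path checkpoint file path.
#' @return `save_scn()` the path, invisibly; `load_scn()` the restored
#'   `scn_model`.
#' @export
save_scn <- function(model, path) {
  if (!inherits(model, "scn_model")) stopf("'model' must be an scn_model")
  obj <- list(descriptor_json = as.character(
                jsonlite::toJSON(unclass(model$descriptor),
                                 auto_unbox = TRUE, digits = NA)),
              blocks = model$blocks)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_scn
#' @export
load_scn <- function(path) {
  obj <- readRDS(path)
  dj <- jsonlite::fromJSON(obj$descriptor_json)
  d <- scn_descriptor(depth = dj$depth, scales = dj$scales,
                      filters = dj$filters, in_channels = dj$in_channels,
                      final_relu = dj$final_relu, residual = dj$residual)
  ch <- block_channels(d)
  if (length(obj$blocks) != d$depth)
    stopf("checkpoint mismatch: %d blocks stored, descriptor says %d",
          length(obj$blocks), d$depth)
  for (i in seq_len(d$depth)) for (k in d$scales) {
    w <- obj$blocks[[i]][[paste0("k", k)]]$W
    want <- c(k, k, ch$cin[i], ch$cout[i])
    if (is.null(w) || !identical(dim(w), as.integer(want)))
      stopf("checkpoint mismatch at block %d scale %d", i, k)
  }
  structure(list(descriptor = d, blocks = obj$blocks), class = "scn_model")
}

#' Kernel scale sets of the named architecture variants
#'
#' `cnn3` and `cnn5` are single-scale ablations (plain ReLU convolutions at
#' 3x3 or 5x5); `scn2`/`scn3`/`scn4` use 2/3/4 scales per block.
#'
#' @param variant one of `"cnn3"`, `"cnn5"`, `"scn2"`, `"scn3"`, `"scn4"`.
#' @return integer vector of kernel sizes.
#' @export
variant_scales <- function(variant = c("scn3", "cnn3", "cnn5", "scn2",
                                       "scn4")) {
  switch(match.arg(variant),
         cnn3 = 3L, cnn5 = 5L, scn2 = c(1L, 3L),
         scn3 = c(1L, 3L, 5L), scn4 = c(1L, 3L, 5L, 7L))
}
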