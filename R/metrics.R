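#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB. Identical images have zero error and
#' return `Inf`.
#'
#' @param x,ref same-shape numeric matrices/arrays; `ref` is the ground
#'   truth.
#' @param peak data range (1.0 for unit-range images).
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref, peak = 1.0) {
  if (!identical(dim(x), dim(ref))) stopf("'x' and 'ref' shapes differ")
  check_number(peak, "peak", 0, strict = TRUE)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Root mean square error
#'
#' @inheritParams psnr
#' @return `sqrt(mean((x - ref)^2))`, on the scale of the image values
#'   (unit range after normalization).
#' @export
rmse <- function(x, ref) {
  if (!identical(dim(x), dim(ref))) stopf("'x' and 'ref' shapes differ")
  sqrt(mean((x - ref)^2))
}

# 11x11 Gaussian window, sigma 1.5, normalized to sum 1
ssim_window <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# windowed local mean via the package's convolution kernel, cropped to the
# valid region so zero padding never contaminates the statistics
ssim_filter <- function(x, w) {
  k <- nrow(w); m <- (k - 1L) / 2L
  X <- x; dim(X) <- c(dim(x), 1L, 1L)
  W <- w; dim(W) <- c(k, k, 1L, 1L)
  y <- conv2d_forward_cpp(X, W, 0)
  dim(y) <- dim(x)
  y[(m + 1):(nrow(x) - m), (m + 1):(ncol(x) - m)]
}

#' Structural similarity index
#'
#' Single-scale SSIM with the canonical constants: 11x11 Gaussian window
#' with sigma 1.5, `C1 = (0.01 * peak)^2`, `C2 = (0.03 * peak)^2`. Local
#' statistics are window-weighted moments; the reported value is the mean
#' of the local map over the valid (fully windowed) region.
#'
#' @inheritParams psnr
#' @return SSIM in `[-1, 1]` (1 for identical images).
#' @export
ssim <- function(x, ref, peak = 1.0) {
  if (!identical(dim(x), dim(ref))) stopf("'x' and 'ref' shapes differ")
  check_number(peak, "peak", 0, strict = TRUE)
  if (nrow(x) < 11L || ncol(x) < 11L)
    stopf("image smaller than the 11x11 SSIM window; use larger inputs or crop less")
  w <- ssim_window()
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  mx <- ssim_filter(x, w);  my <- ssim_filter(ref, w)
  sxx <- ssim_filter(x * x, w) - mx^2
  syy <- ssim_filter(ref * ref, w) - my^2
  sxy <- ssim_filter(x * ref, w) - mx * my
  map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(map)
}

#' Score a set of reconstructions against references
#'
#' Computes PSNR, RMSE and SSIM per image (optionally restricted to
#' rectangular regions of interest) and aggregates them as mean and
#' standard deviation over the per-image values (never over pooled pixels).
#'
#' @param preds,refs lists of same-shape matrices (predictions and ground
#'   truths, unit range).
#' @param ids character labels, one per image.
#' @param roi optional region `c(row, col, height, width)` (1-based
#'   top-left) applied to every image before scoring, or a list of such
#'   rectangles (one per image).
#' @param peak data range for PSNR/SSIM.
#' @return an `eval_report`: data frame `per_image` (image_id, psnr_db,
#'   rmse, ssim) plus `summary` (mean and sd per metric).
#' @export
eval_report <- function(preds, refs, ids = NULL, roi = NULL, peak = 1.0) {
  if (length(preds) != length(refs)) stopf("'preds'/'refs' length mismatch")
  n <- length(preds)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(n))
  crop <- function(m, r) m[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)]
  rows <- lapply(seq_len(n), function(i) {
    p <- preds[[i]]; r <- refs[[i]]
    if (!is.null(roi)) {
      rc <- if (is.list(roi)) roi[[i]] else roi
      p <- crop(p, rc); r <- crop(r, rc)
    }
    data.frame(image_id = ids[i], psnr_db = psnr(p, r, peak),
               rmse = rmse(p, r), ssim = ssim(p, r, peak))
  })
  per <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("psnr_db", "rmse", "ssim"),
    mean = c(mean(per$psnr_db), mean(per$rmse), mean(per$ssim)),
    sd = c(sd(per$psnr_db), sd(per$rmse), sd(per$ssim)))
  structure(list(per_image = per, summary = summ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", nrow(x$per_image), "image(s):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Write an evaluation report as CSV
#' @param report an [eval_report()].
#' @param path output CSV path (columns image_id, psnr_db, rmse, ssim).
#' @export
write_eval_report <- function(report, path) {
  write.csv(report$per_image, path, row.names = FALSE)
  invisible(path)
}
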