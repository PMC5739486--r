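# Independent reference implementations ("oracles") used by the tests.
# They are deliberately naive and share no code with the package internals.

# Dense line-sampling projection oracle: midpoint rule along each
# source-to-bin segment at a step of pixel_size * step_frac, replicating the
# published geometry convention (source at angle beta on a dso circle,
# flat detector behind the centre, bin centres offset along the tangential
# direction).
dense_project_oracle <- function(img, fov_mm, geom, step_frac = 1 / 1000) {
  n <- nrow(img)
  px <- fov_mm / n
  half <- fov_mm / 2
  side <- n * px
  dsd <- geom$dso + geom$dcd
  bw <- geom$det_len / geom$n_bins
  step <- px * step_frac
  out <- matrix(0, geom$n_views, geom$n_bins)
  for (v in seq_len(geom$n_views) - 1L) {
    beta <- (geom$ang_range * pi / 180) * v / geom$n_views
    cb <- cos(beta); sb <- sin(beta)
    sx <- geom$dso * cb; sy <- geom$dso * sb
    for (b in seq_len(geom$n_bins) - 1L) {
      s <- (b + 0.5 - geom$n_bins / 2) * bw
      pxw <- sx - dsd * cb - s * sb
      pyw <- sy - dsd * sb + s * cb
      # world -> grid frame (u rightward, v downward, origin top-left)
      su <- sx + half; sv <- half - sy
      pu <- pxw + half; pv <- half - pyw
      du <- pu - su; dv <- pv - sv
      L <- sqrt(du^2 + dv^2)
      # clip the segment to the grid square
      tmin <- 0; tmax <- 1
      ok <- TRUE
      for (ax in list(c(su, du), c(sv, dv))) {
        if (abs(ax[2]) < 1e-12) {
          if (ax[1] <= 0 || ax[1] >= side) { ok <- FALSE; break }
        } else {
          t1 <- (0 - ax[1]) / ax[2]; t2 <- (side - ax[1]) / ax[2]
          tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
        }
      }
      if (!ok || tmin >= tmax) next
      m <- max(1L, ceiling((tmax - tmin) * L / step))
      tm <- tmin + (seq_len(m) - 0.5) * (tmax - tmin) / m
      uu <- pmin(pmax(floor((su + tm * du) / px), 0), n - 1)
      vv <- pmin(pmax(floor((sv + tm * dv) / px), 0), n - 1)
      out[v + 1L, b + 1L] <- sum(img[cbind(vv + 1L, uu + 1L)]) *
        (tmax - tmin) * L / m
    }
  }
  out
}

# Naive same-padding 2-D convolution (H x W x Cin x N input,
# k x k x Cin x Cout kernels), quadruple loop per output pixel.
conv_oracle <- function(X, W, b) {
  dX <- dim(X); dW <- dim(W)
  H <- dX[1]; Wd <- dX[2]; Cin <- dX[3]; N <- dX[4]
  k <- dW[1]; Cout <- dW[4]
  p <- (k - 1) / 2
  out <- array(0, c(H, Wd, Cout, N))
  for (n in seq_len(N)) for (o in seq_len(Cout)) {
    acc <- matrix(b[o], H, Wd)
    for (c in seq_len(Cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
      w <- W[di, dj, c, o]
      if (w == 0) next
      for (i in seq_len(H)) for (j in seq_len(Wd)) {
        ii <- i + di - 1 - p; jj <- j + dj - 1 - p
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd)
          acc[i, j] <- acc[i, j] + w * X[ii, jj, c, n]
      }
    }
    out[, , o, n] <- acc
  }
  out
}

# Brute-force competitive block: per-scale naive convolution, optional
# rectifier, element-wise maximum across scales.
cb_oracle <- function(X, params, relu = TRUE) {
  out <- NULL
  for (p in params) {
    A <- conv_oracle(X, p$W, p$b)
    if (relu) A <- pmax(A, 0)
    out <- if (is.null(out)) A else pmax(out, A)
  }
  out
}

# tiny deterministic model for loss / gradient tests
tiny_model <- function(depth = 2L, scales = c(1L, 3L), filters = 2L,
                       seed = 42L, init_std = 0.1) {
  init_scn(scn_descriptor(depth = depth, scales = scales, filters = filters),
           init_std = init_std, seed = seed)
}
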