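# Independent oracle implementations used to cross-check the package's
# numerics. These deliberately take different computational routes
# (full 2-D kernel convolution and per-pixel eigen decompositions, explicit
# normal equations) from the vectorized separable implementations in R/.

# mirror boundary with edge duplication: ..., m2, m1 | m1, m2, ...
mirror_idx <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n + 1 - i, i)
}

# direct 2-D convolution with a full (outer-product) Gaussian kernel
conv2_bruteforce <- function(m, kx, ky) {
  k2 <- outer(kx, ky)
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    ii <- mirror_idx(i + (-rx:rx), nx)
    for (j in seq_len(ny)) {
      jj <- mirror_idx(j + (-ry:ry), ny)
      out[i, j] <- sum(m[ii, jj] * k2)
    }
  }
  out
}

gauss_kernel_oracle <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# brute-force multiscale Frangi vesselness: full-kernel smoothing, per-pixel
# finite-difference Hessian and base::eigen on each 2x2 matrix
frangi_bruteforce <- function(m, spacing_um, scales_um, beta = 0.5, c_frac = 0.5,
                              polarity = "bright") {
  nx <- nrow(m); ny <- ncol(m)
  sx <- spacing_um[1]; sy <- spacing_um[2]
  best <- matrix(0, nx, ny)
  for (sg in scales_um) {
    g <- conv2_bruteforce(m, gauss_kernel_oracle(sg / sx), gauss_kernel_oracle(sg / sy))
    l1m <- matrix(0, nx, ny); l2m <- matrix(0, nx, ny)
    for (i in seq_len(nx)) {
      ip <- mirror_idx(i + 1, nx); im <- mirror_idx(i - 1, nx)
      for (j in seq_len(ny)) {
        jp <- mirror_idx(j + 1, ny); jm <- mirror_idx(j - 1, ny)
        dxx <- (g[ip, j] - 2 * g[i, j] + g[im, j]) / sx^2 * sg^2
        dyy <- (g[i, jp] - 2 * g[i, j] + g[i, jm]) / sy^2 * sg^2
        dxy <- (g[ip, jp] + g[im, jm] - g[ip, jm] - g[im, jp]) / (4 * sx * sy) * sg^2
        ev <- eigen(matrix(c(dxx, dxy, dxy, dyy), 2, 2), symmetric = TRUE)$values
        ord <- order(abs(ev))
        l1m[i, j] <- ev[ord[1]]; l2m[i, j] <- ev[ord[2]]
      }
    }
    S <- sqrt(l1m^2 + l2m^2)
    smax <- max(S)
    if (smax == 0) next
    cp <- c_frac * smax
    rb2 <- ifelse(l2m != 0, (l1m / l2m)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cp^2)))
    ok <- if (polarity == "bright") l2m < 0 else l2m > 0
    v[!ok] <- 0
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

# explicit ANCOVA normal equations for the repeated-measures correlation:
# y ~ subject dummies + common slope, solved with base::solve on X'X
rmcorr_normal_equations <- function(subject, x, y) {
  f <- factor(subject)
  X <- cbind(stats::model.matrix(~ f - 1), x)
  bt <- solve(t(X) %*% X, t(X) %*% y)
  slope <- bt[length(bt)]
  resid_full <- y - X %*% bt
  ss_err <- sum(resid_full^2)
  # reduced model: subject dummies only
  X0 <- stats::model.matrix(~ f - 1)
  b0 <- solve(t(X0) %*% X0, t(X0) %*% y)
  ss_red <- sum((y - X0 %*% b0)^2)
  ss_x <- ss_red - ss_err
  df <- length(y) - nlevels(f) - 1
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  fstat <- (ss_x / 1) / (ss_err / df)
  list(r_rm = r, slope = slope, df = df,
       p = stats::pf(fstat, 1, df, lower.tail = FALSE))
}

# small helpers for image fixtures ------------------------------------------

# horizontal tube with flattened cross-section, plus optional isotropic blob
make_tube_image <- function(nx = 64, ny = 64, spacing = c(20, 20),
                            tube_sigma_um = 30, y0 = NULL, contrast = 1,
                            blob_at = NULL, blob_sigma_um = 60) {
  y0 <- y0 %||% (ny / 2)
  ys <- (seq_len(ny) - y0) * spacing[2]
  m <- matrix(rep(contrast * exp(-ys^2 / (2 * tube_sigma_um^2)), each = nx), nx, ny)
  if (!is.null(blob_at)) {
    xs <- (seq_len(nx) - blob_at[1]) * spacing[1]
    ys2 <- (seq_len(ny) - blob_at[2]) * spacing[2]
    m <- m + contrast * exp(-outer(xs^2, ys2^2, "+") / (2 * blob_sigma_um^2))
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
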