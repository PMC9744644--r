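# Internal numerics shared across image stages. All 2-D arrays are indexed
# (x = fast axis, y = slow axis); depth is the third axis of volumes.

# Sampled, normalized 1-D Gaussian kernel. Radius 4*sigma captures >0.9999
# of the mass; sigma 0 gives the identity kernel.
gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Reflect-pad a matrix by r rows/cols on both ends of one margin.
pad_reflect <- function(m, r, margin) {
  if (r == 0) return(m)
  n <- dim(m)[margin]
  if (r > n) stop("pad radius exceeds matrix extent", call. = FALSE)
  # mirror with edge duplication: m[r]..m[1] | m[1..n] | m[n]..m[n-r+1]
  idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1)
  if (margin == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

# Separable convolution with reflect boundary; kernels may differ per axis
# (anisotropic pixels). Accumulates shifted slabs: O(len(k) * N) vectorized.
conv_sep2d <- function(m, kx, ky = kx) {
  nx <- nrow(m); ny <- ncol(m)
  if (length(kx) > 1) {
    r <- (length(kx) - 1L) %/% 2L
    p <- pad_reflect(m, r, 1L)
    out <- matrix(0, nx, ny)
    for (j in seq_along(kx)) out <- out + kx[j] * p[j:(j + nx - 1L), , drop = FALSE]
    m <- out
  }
  if (length(ky) > 1) {
    r <- (length(ky) - 1L) %/% 2L
    p <- pad_reflect(m, r, 2L)
    out <- matrix(0, nx, ny)
    for (j in seq_along(ky)) out <- out + ky[j] * p[, j:(j + ny - 1L), drop = FALSE]
    m <- out
  }
  m
}

# Gaussian smoothing with physical-unit sigma (micrometres) on a grid with
# per-axis pixel spacing in micrometres.
gauss_smooth_um <- function(m, sigma_um, spacing_um) {
  conv_sep2d(m, gauss_kernel(sigma_um / spacing_um[1]), gauss_kernel(sigma_um / spacing_um[2]))
}

# Vectorized bilinear sampling of matrix m at fractional coordinates
# (xi, yi) in 1-based index units; out-of-frame samples get `fill`.
bilinear_sample <- function(m, xi, yi, fill) {
  nx <- nrow(m); ny <- ncol(m)
  inside <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  # anchor on the lower-left grid point, clamped so xi = nx (exactly on the
  # last sample) interpolates with weight 1 on that sample
  x0 <- pmin(pmax(floor(xi), 1), nx - 1); y0 <- pmin(pmax(floor(yi), 1), ny - 1)
  fx <- pmin(pmax(xi - x0, 0), 1); fy <- pmin(pmax(yi - y0, 0), 1)
  v00 <- m[cbind(x0, y0)];     v10 <- m[cbind(x0 + 1, y0)]
  v01 <- m[cbind(x0, y0 + 1)]; v11 <- m[cbind(x0 + 1, y0 + 1)]
  v <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  v[!inside] <- fill
  attr(v, "n_filled") <- sum(!inside)
  v
}

# Smooth standardized Gaussian random field on an (nx, ny) grid;
# correlation length given in micrometres via per-axis spacing.
gaussian_random_field <- function(nx, ny, corr_um, spacing_um) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  s <- gauss_smooth_um(z, corr_um, spacing_um)
  (s - mean(s)) / stats::sd(s)
}

# Derive a stream-specific 31-bit seed from a master seed and a label,
# so independent stages never share an RNG stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
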