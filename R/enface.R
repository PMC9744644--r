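#' Project a volume to an en-face image between retinal surfaces
#'
#' Reduces each A-scan over the depth voxels between `ILM + offset_top` and
#' `ILM + offset_bottom` (offsets in micrometres, converted to voxels with the
#' axial spacing). The default band, ILM to ILM + 120 um with a mean reducer,
#' targets the superficial vascular slab. The band must lie within
#' `[ILM, RPE]` at every A-scan.
#'
#' @param volume an [oct_volume()].
#' @param surfaces a [surface_pair()] for the same volume.
#' @param band_um numeric `(offset_top, offset_bottom)` below the ILM, um.
#' @param reducer `"mean"` or `"max"`.
#' @return An [enface_image()] with projection provenance.
#' @export
project_enface <- function(volume, surfaces, band_um = c(0, 120), reducer = c("mean", "max")) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "surface_pair"))
  reducer <- match.arg(reducer)
  g <- dim(volume$data)
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  dz_axial <- volume$spacing_um[3]
  z0 <- surfaces$ilm_depth + round(band_um[1] / dz_axial)
  z1 <- surfaces$ilm_depth + round(band_um[2] / dz_axial)
  if (any(z1 < z0)) stop("projection band is inverted", call. = FALSE)
  bad <- which(z0 < 1 | z1 > g[3] | z1 > surfaces$rpe_depth)
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], c(nx, ny))
    stop(sprintf("empty or out-of-slab projection band at A-scan (x=%d, y=%d)",
                 ij[1], ij[2]), call. = FALSE)
  }
  m <- volume$data
  dim(m) <- c(nx * ny, nz)
  idx <- seq_len(nx * ny)
  if (reducer == "mean") {
    # cumulative sums along depth allow per-A-scan bands in O(nz) passes
    cs <- m
    for (z in 2:nz) cs[, z] <- cs[, z - 1] + m[, z]
    top <- as.vector(z0); bot <- as.vector(z1)
    below <- ifelse(top > 1, cs[cbind(idx, pmax(top - 1L, 1L))], 0)
    below[top <= 1] <- 0
    vals <- (cs[cbind(idx, bot)] - below) / (bot - top + 1)
  } else {
    top <- as.vector(z0); bot <- as.vector(z1)
    vals <- rep(-Inf, nx * ny)
    for (z in seq(min(top), max(bot))) {
      sel <- z >= top & z <= bot
      if (any(sel)) vals[sel] <- pmax(vals[sel], m[sel, z])
    }
  }
  enface_image(matrix(vals, nx, ny), spacing_um = volume$spacing_um[1:2],
               provenance = list(band_um = band_um, reducer = reducer,
                                 source = volume$meta$id %||% "volume"))
}

#' Score OCT signal quality on the 0-10 signal-strength scale
#'
#' The underlying SNR estimate is `10 * log10(signal / floor)` where `signal`
#' is the peak of the axially smoothed mean intensity profile (the brightest
#' retinal band) and `floor` is the standard deviation of the top vitreous
#' band (first 5% of depth). The commercial signal-strength metric is
#' proprietary, so the mapping to 0-10 is this package's construction:
#' `score = clamp(round(snr_db / 3), 0, 10)`. A zero noise floor (noise-free
#' input) yields score 10 with a warning. The study's rejection rule
#' (signal strength < 8/10) is applied downstream with threshold 8.
#'
#' @param volume an [oct_volume()].
#' @return A list of class `quality_score` with `score` and `snr_db`.
#' @export
quality_score <- function(volume) {
  stopifnot(inherits(volume, "oct_volume"))
  nz <- dim(volume$data)[3]
  n_noise <- max(3L, round(0.05 * nz))
  noise_band <- volume$data[, , seq_len(n_noise)]
  floor_sd <- stats::sd(as.numeric(noise_band))
  profile <- apply(volume$data, 3, mean)
  k <- gauss_kernel(2)
  r <- (length(k) - 1L) %/% 2L
  prof_s <- as.numeric(stats::filter(c(rev(profile[seq_len(r)]), profile,
                                       rev(rev(profile)[seq_len(r)])), k, sides = 2))
  prof_s <- prof_s[(r + 1):(r + nz)]
  signal <- max(prof_s, na.rm = TRUE)
  if (floor_sd <= .Machine$double.eps) {
    warning("zero noise floor; clamping quality score to 10", call. = FALSE)
    return(structure(list(score = 10, snr_db = Inf), class = "quality_score"))
  }
  snr_db <- 10 * log10(signal / floor_sd)
  structure(list(score = min(max(round(snr_db / 3), 0), 10), snr_db = snr_db),
            class = "quality_score")
}

#' Rigid transform between en-face images
#'
#' `rigid_transform()` builds a transform; [apply_transform()] applies it
#' (rotation about the image centre, then translation, bilinear resampling);
#' [register_rigid()] estimates the transform aligning `moving` to
#' `reference`. [invert_transform()] gives the exact inverse.
#'
#' @param rotation_deg rotation in degrees, in (-180, 180].
#' @param shift_x_px,shift_y_px translation in pixels along x (fast) and y (slow).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, shift_x_px = 0, shift_y_px = 0) {
  if (rotation_deg <= -180 || rotation_deg > 180)
    stop("rotation_deg must lie in (-180, 180]", call. = FALSE)
  structure(list(rotation_deg = rotation_deg, shift_x_px = shift_x_px,
                 shift_y_px = shift_y_px), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  th <- -t$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- -R %*% c(t$shift_x_px, t$shift_y_px)
  rigid_transform(-t$rotation_deg, s[1], s[2])
}

#' Apply a rigid transform to an en-face image
#'
#' Output pixel `(x, y)` samples the input at the inverse-mapped location by
#' bilinear interpolation; out-of-frame samples are filled with the image
#' median, and the number of filled pixels is recorded in provenance.
#'
#' @param image an [enface_image()].
#' @param t a [rigid_transform()].
#' @return A transformed [enface_image()].
#' @export
apply_transform <- function(image, t) {
  stopifnot(inherits(image, "enface_image"), inherits(t, "rigid_transform"))
  m <- image$data
  nx <- nrow(m); ny <- ncol(m)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- t$rotation_deg * pi / 180
  xg <- rep(seq_len(nx), times = ny) - cx - t$shift_x_px
  yg <- rep(seq_len(ny), each = nx) - cy - t$shift_y_px
  # inverse rotation of the output grid into input coordinates
  xi <- cos(th) * xg + sin(th) * yg + cx
  yi <- -sin(th) * xg + cos(th) * yg + cy
  fill <- stats::median(m)
  v <- bilinear_sample(m, xi, yi, fill)
  out <- matrix(v, nx, ny)
  enface_image(out, image$spacing_um,
               provenance = c(image$provenance,
                              list(transform = unclass(t),
                                   n_filled = attr(v, "n_filled"))))
}

#' Estimate the rigid transform aligning one image to another
#'
#' Rotation is searched on a coarse-to-fine grid (default range +/- 12
#' degrees); at each candidate the translation is recovered by phase
#' correlation with subpixel (parabolic) refinement, and the candidate is
#' scored by correlation with the reference. Both images are windowed (Hann)
#' and mean-subtracted before the FFT.
#'
#' @param reference,moving [enface_image()]s of identical shape.
#' @param max_rotation_deg half-range of the rotation search.
#' @param smooth_um low-pass scale applied to both images before scoring;
#'   this keeps the candidate comparison fair (resampling a rotated
#'   candidate smooths speckle and would otherwise inflate its correlation
#'   against the never-resampled zero-rotation candidate).
#' @return A [rigid_transform()] `t` such that `apply_transform(moving, t)`
#'   aligns with `reference`.
#' @export
register_rigid <- function(reference, moving, max_rotation_deg = 12,
                           smooth_um = 25) {
  stopifnot(inherits(reference, "enface_image"), inherits(moving, "enface_image"))
  a <- reference$data; b <- moving$data
  if (!all(dim(a) == dim(b))) stop("images must share a shape", call. = FALSE)
  if (smooth_um > 0) {
    a <- gauss_smooth_um(a, smooth_um, reference$spacing_um)
    b <- gauss_smooth_um(b, smooth_um, moving$spacing_um)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("cannot register a flat (zero-variance) image", call. = FALSE)
  score_at <- function(theta) {
    rot <- rigid_transform(theta)
    bi <- if (theta == 0) enface_image(b, moving$spacing_um) else
      apply_transform(enface_image(b, moving$spacing_um), rot)
    sh <- phase_correlate(a, bi$data)
    shift <- rigid_transform(0, sh[1], sh[2])
    aligned <- apply_transform(bi, shift)
    # score only where both resampling stages sampled real data: the
    # median-filled corners would otherwise bias the correlation
    valid <- transform_valid_mask(theta, sh, nrow(a), ncol(a))
    score <- if (sum(valid) > 0.25 * length(valid))
      stats::cor(a[valid], aligned$data[valid])
    else stats::cor(as.vector(a), as.vector(aligned$data))
    list(theta = theta, shift = sh, score = score)
  }
  best <- NULL
  for (step in c(2, 0.5, 0.1)) {
    centre <- if (is.null(best)) 0 else best$theta
    # refinement windows overlap generously so a mid-level local optimum
    # one step off can still be corrected at the next level
    half <- if (is.null(best)) max_rotation_deg else step * 6
    cands <- unique(pmax(pmin(centre + seq(-half, half, by = step), 179.9), -179.9))
    for (th in cands) {
      sc <- score_at(th)
      if (is.null(best) || (is.finite(sc$score) && sc$score > best$score)) best <- sc
    }
  }
  # translation must compose with the rotation in apply_transform order
  # (rotate then shift): phase correlation was run on the already-rotated
  # image, so the measured shift applies after rotation, as required.
  rigid_transform(best$theta, best$shift[1], best$shift[2])
}

# Phase correlation with Hann windowing and 3-point parabolic subpixel peak.
# Returns (dx, dy) such that shifting `b` by (dx, dy) aligns it with `a`.
phase_correlate <- function(a, b) {
  nx <- nrow(a); ny <- ncol(a)
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  w <- outer(wx, wy)
  fa <- stats::fft((a - mean(a)) * w)
  fb <- stats::fft((b - mean(b)) * w)
  cross <- fa * Conj(fb)
  denom <- Mod(cross)
  denom[denom < .Machine$double.eps] <- 1
  r <- Re(stats::fft(cross / denom, inverse = TRUE)) / (nx * ny)
  pk <- arrayInd(which.max(r), dim(r))
  subpix <- function(rm, r0, rp) {
    den <- r0 * 2 - rm - rp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (rm - rp) / den * -1
  }
  ix <- pk[1]; iy <- pk[2]
  dx <- subpix(r[wrap_idx(ix - 1, nx), iy], r[ix, iy], r[wrap_idx(ix + 1, nx), iy])
  dy <- subpix(r[ix, wrap_idx(iy - 1, ny)], r[ix, iy], r[ix, wrap_idx(iy + 1, ny)])
  sx <- ix - 1 + dx; sy <- iy - 1 + dy
  if (sx > nx / 2) sx <- sx - nx
  if (sy > ny / 2) sy <- sy - ny
  c(sx, sy)
}

wrap_idx <- function(i, n) ((i - 1) %% n) + 1

# Pixels of shift(rotate(img, theta), sh) whose samples never left the frame
# at either resampling stage (mirrors the inverse maps in apply_transform).
transform_valid_mask <- function(theta_deg, sh, nx, ny) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- rep(seq_len(nx), times = ny)
  y <- rep(seq_len(ny), each = nx)
  xi1 <- x - sh[1]; yi1 <- y - sh[2]            # inverse of the shift stage
  ok1 <- xi1 >= 1 & xi1 <= nx & yi1 >= 1 & yi1 <= ny
  th <- theta_deg * pi / 180
  xg <- xi1 - cx; yg <- yi1 - cy                # inverse of the rotation stage
  xs <- cos(th) * xg + sin(th) * yg + cx
  ys <- -sin(th) * xg + cos(th) * yg + cy
  ok2 <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  matrix(ok1 & ok2, nx, ny)
}
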