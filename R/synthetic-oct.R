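#' Scene parameters for the synthetic OCT generator
#'
#' Defines a synthetic macular cube emulating a 6 mm x 6 mm x 2 mm
#' spectral-domain OCT acquisition. The default grid is a half-scale
#' 256 x 128 x 512 cube (the full acquisition grid 512 x 128 x 1024 is
#' available by setting `grid_shape`); physical extent is fixed at the
#' acquisition geometry unless overridden.
#'
#' The generated scene contains, in order of construction: two smooth
#' bounding surfaces (ILM and RPE) drawn as Gaussian random fields; a bright
#' retinal slab between them with a brighter RPE band; a branching
#' superficial vessel network with Gaussian cross-section just below the ILM;
#' additive rank-<=2 vertical/horizontal band artifacts inside the slab;
#' circular Gaussian blob (projection) artifacts in the vessel band; and
#' multiplicative mean-preserving speckle.
#'
#' @param grid_shape integer length-3 `(n_fast, n_slow, n_depth)`.
#' @param extent_mm numeric length-3 physical size, default `c(6, 6, 2)`.
#' @param surface_smoothness correlation length of the random surface fields, mm.
#' @param mean_thickness_um target mean ILM-RPE separation, micrometres.
#' @param vessel_count number of root vessels entering the field.
#' @param vessel_radius_um_range `(min, max)` root vessel radius, micrometres;
#'   must lie in (0, 200].
#' @param vessel_contrast reflectivity multiplier of vessel voxels relative to
#'   the slab ( > 1 bright vessels, < 1 dark vessels).
#' @param speckle_sigma log-scale of the multiplicative speckle.
#' @param band_artifact_amplitude amplitude of the low-rank stripe field,
#'   relative to slab reflectivity.
#' @param blob_artifact_count number of circular projection artifacts.
#' @param target_fraction optional planted en-face vessel area fraction in
#'   (0, 1); vessel radii are rescaled by a monotone search to hit it to
#'   within 0.0005.
#' @param seed RNG seed; a fixed seed makes the volume bit-identical on rerun.
#' @param anatomy_seed seed for the anatomy streams (surfaces and vessel
#'   network); defaults to `seed`. Fixing it while varying `seed` emulates
#'   repeated imaging of the same retina: identical vasculature and surface
#'   shape, fresh speckle and artifacts.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(grid_shape = c(256L, 128L, 512L),
                         extent_mm = c(6, 6, 2),
                         surface_smoothness = 1.5,
                         mean_thickness_um = 300,
                         vessel_count = 4,
                         vessel_radius_um_range = c(35, 70),
                         vessel_contrast = 1.8,
                         speckle_sigma = 0.2,
                         band_artifact_amplitude = 0.06,
                         blob_artifact_count = 3,
                         target_fraction = NULL,
                         seed = 1L,
                         anatomy_seed = NULL) {
  p <- list(grid_shape = as.integer(grid_shape), extent_mm = as.numeric(extent_mm),
            surface_smoothness = surface_smoothness,
            mean_thickness_um = mean_thickness_um, vessel_count = as.integer(vessel_count),
            vessel_radius_um_range = as.numeric(vessel_radius_um_range),
            vessel_contrast = vessel_contrast, speckle_sigma = speckle_sigma,
            band_artifact_amplitude = band_artifact_amplitude,
            blob_artifact_count = as.integer(blob_artifact_count),
            target_fraction = target_fraction, seed = as.integer(seed),
            anatomy_seed = as.integer(anatomy_seed %||% seed))
  if (any(p$grid_shape <= 0) || length(p$grid_shape) != 3)
    stop("grid_shape must be 3 positive counts", call. = FALSE)
  if (any(p$extent_mm <= 0)) stop("extent_mm must be positive", call. = FALSE)
  if (p$vessel_count < 0) stop("vessel_count must be non-negative", call. = FALSE)
  r <- p$vessel_radius_um_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1] || r[2] > 200)
    stop("vessel_radius_um_range must be within (0, 200] um", call. = FALSE)
  if (r[2] > min(p$extent_mm[1:2]) * 1000 / 2)
    stop("vessel radius exceeds half the en-face extent", call. = FALSE)
  if (p$speckle_sigma < 0 || p$band_artifact_amplitude < 0 || p$blob_artifact_count < 0)
    stop("noise/artifact parameters must be non-negative", call. = FALSE)
  if (!is.null(p$target_fraction) &&
      (p$target_fraction <= 0 || p$target_fraction >= 1))
    stop("target_fraction must be in (0, 1)", call. = FALSE)
  if (p$mean_thickness_um <= 0 || p$mean_thickness_um >= p$extent_mm[3] * 1000)
    stop("mean_thickness_um must fit inside the depth extent", call. = FALSE)
  class(p) <- "scene_params"
  p
}

# Reflectivity levels of the synthetic scene (arbitrary units in [0, 1]).
.scene_levels <- list(vitreous = 0.01, slab = 0.45, rpe_band = 0.7, choroid = 0.12)

#' Generate a synthetic OCT volume with known ground truth
#'
#' Builds the scene described in [scene_params()] and records exact ground
#' truth: the planted en-face vessel mask, the ILM/RPE depth maps (1-based
#' voxel indices of the first and last slab voxel per A-scan), the realized
#' vessel area fraction, and the band-artifact field. The vessel network is
#' generated per-root from seeds derived from `(seed, root index)`, so the
#' first `k` roots are identical for any `vessel_count >= k`; adding roots can
#' only add vessel pixels.
#'
#' @param params a [scene_params()] object.
#' @return A list with elements `volume` (an [oct_volume()]) and `truth`
#'   (class `synthetic_truth`: `vessel_mask`, `ilm_depth`, `rpe_depth`,
#'   `true_vessel_fraction`, `artifact_low_rank`, `radius_scale`, `seed`).
#' @export
generate_volume <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  g <- params$grid_shape
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  spacing <- params$extent_mm * 1000 / g
  lv <- .scene_levels

  # --- bounding surfaces (anatomy stream) ------------------------------------
  surf <- withr::with_seed(derive_seed(params$anatomy_seed, "surfaces"), {
    ilm_base_um <- 0.3 * params$extent_mm[3] * 1000
    ilm_um <- ilm_base_um + 30 * gaussian_random_field(nx, ny, params$surface_smoothness * 1000, spacing[1:2])
    th_um <- params$mean_thickness_um + 10 * gaussian_random_field(nx, ny, params$surface_smoothness * 1000, spacing[1:2])
    ilm <- pmin(pmax(round(ilm_um / spacing[3]), 8), nz - 40)
    rpe <- pmin(pmax(ilm + round(th_um / spacing[3]), ilm + 2), nz - 8)
    list(ilm = ilm, rpe = rpe)
  })

  # --- vessel network --------------------------------------------------------
  ves <- rasterize_vessels(params, spacing)

  # --- band artifact field (rank <= 2: vertical + horizontal stripes) --------
  band <- withr::with_seed(derive_seed(params$seed, "bands"), {
    if (params$band_artifact_amplitude > 0) {
      u <- smooth_profile(nx, 3); w <- smooth_profile(ny, 3)
      params$band_artifact_amplitude * lv$slab *
        (outer(u, rep(1, ny)) + outer(rep(1, nx), w))
    } else matrix(0, nx, ny)
  })

  # --- blob (projection) artifacts ------------------------------------------
  blobs <- withr::with_seed(derive_seed(params$seed, "blobs"), {
    b <- matrix(0, nx, ny)
    if (params$blob_artifact_count > 0) {
      xs <- (seq_len(nx) - 0.5) * spacing[1]
      ys <- (seq_len(ny) - 0.5) * spacing[2]
      for (k in seq_len(params$blob_artifact_count)) {
        cx <- stats::runif(1, 0.1, 0.9) * params$extent_mm[1] * 1000
        cy <- stats::runif(1, 0.1, 0.9) * params$extent_mm[2] * 1000
        rad <- stats::runif(1, 80, 200)
        d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
        b <- pmax(b, exp(-d2 / (2 * (rad / 2)^2)))
      }
    }
    b
  })

  # --- assemble volume -------------------------------------------------------
  vol <- array(lv$vitreous, dim = g)
  # depth-slice assembly: one vectorized mask per z keeps memory flat
  vb_top <- surf$ilm + 2L                       # vessel band just below the ILM
  vb_bot <- vb_top + max(1L, ceiling(60 / spacing[3]))
  vessel_gain <- 1 + (params$vessel_contrast - 1) * ves$profile
  for (z in seq_len(nz)) {
    slab <- z >= surf$ilm & z <= surf$rpe
    rpe_band <- abs(z - surf$rpe) <= max(1, round(8 / spacing[3]))
    below <- z > surf$rpe
    slice <- matrix(lv$vitreous, nx, ny)
    slice[slab] <- lv$slab
    slice[below & !rpe_band] <- lv$choroid
    slice[rpe_band] <- lv$rpe_band
    in_vessel_band <- slab & z >= vb_top & z <= vb_bot
    if (any(in_vessel_band)) {
      slice[in_vessel_band] <- (lv$slab * vessel_gain)[in_vessel_band]
      slice[in_vessel_band] <- slice[in_vessel_band] +
        (lv$slab * 0.8 * blobs)[in_vessel_band]
    }
    slice[slab] <- slice[slab] + band[slab]
    vol[, , z] <- slice
  }

  if (params$speckle_sigma > 0) {
    vol <- withr::with_seed(derive_seed(params$seed, "speckle"), {
      s <- params$speckle_sigma
      vol * exp(s * stats::rnorm(length(vol)) - s^2 / 2)
    })
  }
  vol <- pmin(pmax(vol, 0), 1)
  dim(vol) <- g

  truth <- structure(list(
    vessel_mask = ves$mask,
    ilm_depth = surf$ilm,
    rpe_depth = surf$rpe,
    true_vessel_fraction = mean(ves$mask),
    artifact_low_rank = band,
    radius_scale = ves$radius_scale,
    seed = params$seed
  ), class = "synthetic_truth")

  list(volume = oct_volume(vol, spacing_um = spacing,
                           meta = list(generator = "foctr synthetic scene",
                                       seed = params$seed)),
       truth = truth)
}

# Smooth standardized 1-D profile (white noise, Gaussian-smoothed).
smooth_profile <- function(n, sigma_px) {
  z <- stats::rnorm(n)
  k <- gauss_kernel(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  zp <- c(rev(z[seq_len(min(r, n))]), z, rev(z)[seq_len(min(r, n))])
  s <- as.numeric(stats::filter(zp, k, sides = 2))[(r + 1):(r + n)]
  (s - mean(s)) / stats::sd(s)
}

# Random branching walks in the en-face plane, rasterized on an isotropic
# supersampled grid (slow axis upsampled to fast-axis spacing) so Euclidean
# distances to the centerline are correct under anisotropic pixels.
rasterize_vessels <- function(params, spacing) {
  g <- params$grid_shape
  nx <- g[1]; ny <- g[2]
  if (params$vessel_count == 0) {
    return(list(mask = matrix(FALSE, nx, ny), profile = matrix(0, nx, ny),
                radius_scale = 1))
  }
  f <- max(1L, round(spacing[2] / spacing[1]))     # y upsampling factor
  nyu <- ny * f
  sx <- spacing[1]                                 # isotropic work spacing, um
  walkers <- list()
  for (v in seq_len(params$vessel_count)) {
    walkers <- c(walkers, withr::with_seed(
      derive_seed(params$anatomy_seed, paste0("vessel", v)),
      grow_vessel_tree(nx, nyu, params$vessel_radius_um_range, sx)))
  }
  # per-walker normalized distance maps (d / radius) on the native grid
  ycol <- pmin(pmax(round((seq_len(ny) - 0.5) * f + 0.5), 1L), nyu)
  dn_by_walker <- lapply(walkers, function(w) {
    cl <- matrix(0, nx, nyu)
    cl[w$pts] <- 1
    d_um <- as.matrix(EBImage::distmap(1 - cl)) * sx
    (d_um / w$radius_um)[, ycol, drop = FALSE]
  })
  radii <- vapply(walkers, function(w) w$radius_um, numeric(1))
  active <- rep(TRUE, length(walkers))
  dn_native <- Reduce(pmin, dn_by_walker)

  alpha <- 1
  if (!is.null(params$target_fraction)) {
    # radius scale = the order statistic of normalized distance that puts
    # round(target * N) pixels inside the planted mask; distance ties (whole
    # equidistant rings) are broken in index order so the count is exact.
    # If the target would force radii below the pixel pitch, whole walkers
    # are pruned (smallest radius first) — vessel dropout, not sub-pixel
    # tubes, so every planted vessel stays resolvable.
    k <- max(1L, round(params$target_fraction * prod(c(nx, ny))))
    alpha_for <- function(act) {
      dn <- Reduce(pmin, dn_by_walker[act])
      sort(as.numeric(dn), partial = k)[k]
    }
    r_px_min <- 0.8 * max(spacing[1:2])
    repeat {
      alpha <- alpha_for(which(active))
      if (!is.finite(alpha) || alpha > 6) {
        if (sum(active) < length(walkers)) {   # over-pruned: restore one
          active[which(!active)[sum(!active)]] <- TRUE
          alpha <- alpha_for(which(active))
          break
        }
        stop("target_fraction unreachable with this vessel network", call. = FALSE)
      }
      if (sum(active) <= 1 || alpha * min(radii[active]) >= r_px_min) break
      active[which(active)[which.min(radii[active])]] <- FALSE
    }
    dn_native <- Reduce(pmin, dn_by_walker[active])
    mask <- dn_native < alpha
    need <- k - sum(mask)
    if (need > 0) mask[which(dn_native == alpha)[seq_len(need)]] <- TRUE
  } else {
    mask <- dn_native <= alpha
  }
  # flattened (4th-order) radial profile with half-maximum at the planted
  # radius, so the mask footprint coincides with the profile's FWHM support
  prof_native <- exp(-log(2) * (dn_native / alpha)^4)
  prof_native[!is.finite(prof_native)] <- 0
  list(mask = mask, profile = prof_native, radius_scale = alpha)
}

# One root vessel: a random walk with curvature noise, spawning narrower
# branches; returns a list of walkers with centerline pixel indices (on the
# isotropic work grid) and radius in micrometres.
grow_vessel_tree <- function(nx, nyu, radius_range_um, sx) {
  root_radius <- stats::runif(1, radius_range_um[1], radius_range_um[2])
  side <- sample(4, 1)
  start <- switch(side,
    c(1, stats::runif(1, 0.1, 0.9) * nyu),
    c(nx, stats::runif(1, 0.1, 0.9) * nyu),
    c(stats::runif(1, 0.1, 0.9) * nx, 1),
    c(stats::runif(1, 0.1, 0.9) * nx, nyu))
  angle <- atan2(nyu / 2 - start[2], nx / 2 - start[1]) + stats::rnorm(1, 0, 0.3)
  queue <- list(list(pos = start, angle = angle, radius = root_radius, depth = 0))
  walkers <- list()
  max_steps <- round(2.2 * max(nx, nyu))
  while (length(queue) > 0) {
    wk <- queue[[1]]; queue <- queue[-1]
    pts <- matrix(0L, max_steps, 2)
    npts <- 0L
    pos <- wk$pos; ang <- wk$angle
    for (s in seq_len(max_steps)) {
      xi <- round(pos[1]); yi <- round(pos[2])
      if (xi < 1 || xi > nx || yi < 1 || yi > nyu) break
      npts <- npts + 1L
      pts[npts, ] <- c(xi, yi)
      if (wk$depth < 2 && wk$radius > 25 && stats::runif(1) < 0.008 && s > 30) {
        br_ang <- ang + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9)
        queue <- c(queue, list(list(pos = pos, angle = br_ang,
                                    radius = wk$radius * 0.8, depth = wk$depth + 1)))
      }
      ang <- ang + stats::rnorm(1, 0, 0.07)
      pos <- pos + c(cos(ang), sin(ang))
    }
    if (npts > 1)
      walkers <- c(walkers, list(list(pts = pts[seq_len(npts), , drop = FALSE],
                                      radius_um = wk$radius)))
  }
  walkers
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> vessel fraction %.4f (%d px), seed %d\n",
              x$true_vessel_fraction, sum(x$vessel_mask), x$seed))
  invisible(x)
}
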