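#' ILM/RPE surface pair
#'
#' Depth maps (1-based voxel indices on the en-face grid) for the inner
#' limiting membrane and retinal pigment epithelium. The hard smoothness
#' constraint — maximum depth step between adjacent A-scans along the fast
#' axis — is recorded as `smoothness_used`. `ilm_depth < rpe_depth` holds
#' everywhere.
#'
#' @param ilm_depth,rpe_depth integer matrices `(n_fast, n_slow)`.
#' @param smoothness_used max allowed per-step depth change, voxels.
#' @return An object of class `surface_pair`.
#' @export
surface_pair <- function(ilm_depth, rpe_depth, smoothness_used = NA_real_) {
  if (!all(ilm_depth < rpe_depth))
    stop("ilm_depth must be strictly above rpe_depth everywhere", call. = FALSE)
  structure(list(ilm_depth = ilm_depth, rpe_depth = rpe_depth,
                 smoothness_used = smoothness_used), class = "surface_pair")
}

#' Extract ILM and RPE surfaces by dynamic programming
#'
#' Per B-scan, each surface is the minimum-cost depth path across the fast
#' axis under a hard constraint `|z(x+1) - z(x)| <= smoothness`. The ILM cost
#' is the negative positive-going axial gradient (vitreous-to-slab edge); the
#' RPE cost is the negative axially smoothed intensity (brightest band),
#' restricted to depths at least `min_separation_um` below the found ILM.
#' Paths are median-filtered across B-scans (the median preserves the
#' along-x step bound) and the ordering constraint is enforced.
#'
#' This is an in-package surface finder; the graph-search software used
#' clinically is proprietary and is not reproduced here. Accuracy is
#' assessed against synthetic ground truth.
#'
#' @param volume an [oct_volume()].
#' @param smoothness max depth step between adjacent A-scans, voxels.
#' @param min_separation_um minimum ILM-RPE separation for the RPE search.
#' @return A [surface_pair()].
#' @export
extract_surfaces <- function(volume, smoothness = 2L, min_separation_um = 120) {
  stopifnot(inherits(volume, "oct_volume"))
  g <- dim(volume$data)
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  min_sep <- max(2L, round(min_separation_um / volume$spacing_um[3]))
  vol <- volume$data

  # axial smoothing stabilizes both costs against speckle
  kz <- gauss_kernel(max(1, round(6 / volume$spacing_um[3])))
  m <- vol
  dim(m) <- c(nx * ny, nz)
  sm <- m
  if (length(kz) > 1) {
    r <- (length(kz) - 1L) %/% 2L
    idx <- c(rev(seq_len(r)), seq_len(nz), nz + 1 - rev(seq_len(r)))
    p <- m[, idx, drop = FALSE]
    sm <- matrix(0, nx * ny, nz)
    for (j in seq_along(kz)) sm <- sm + kz[j] * p[, j:(j + nz - 1L), drop = FALSE]
  }

  # ILM cost: forward difference of smoothed intensity peaks one voxel above
  # the first slab voxel, so the path is shifted by +1 afterwards. The search
  # window covers the upper 60% of depth (the ILM cannot sit deeper).
  z_hi <- max(4L, ceiling(0.6 * nz))
  grad <- sm[, 2:z_hi, drop = FALSE] - sm[, 1:(z_hi - 1L), drop = FALSE]
  cost_ilm <- -pmax(grad, 0)
  ilm_raw <- dp_surface(cost_ilm, nx, ny, smoothness) + 1L
  ilm <- surface_median_y(ilm_raw)

  # RPE cost: brightest smoothed band below ILM + min separation, searched in
  # a window from just below the shallowest feasible depth to 700 um past the
  # deepest ILM (well beyond any retinal thickness)
  lower <- as.vector(ilm) + min_sep
  z_lo <- min(lower) + 1L
  z_top <- min(nz, max(lower) + round(700 / volume$spacing_um[3]))
  if (z_lo >= nz - 1 || any(lower >= nz - 1)) {
    bad <- which(lower >= nz - 1)[1] %||% 1L
    ij <- arrayInd(bad, c(nx, ny))
    stop(sprintf("no feasible RPE path below the ILM at B-scan y=%d (x=%d)",
                 ij[2], ij[1]), call. = FALSE)
  }
  cost_rpe <- -sm[, z_lo:z_top, drop = FALSE]
  for (z in seq_len(max(lower) - z_lo + 1L)) {
    sel <- lower >= z + z_lo - 1L
    if (any(sel)) cost_rpe[sel, z] <- 1e6   # infeasible region, finite sentinel
  }
  rpe_raw <- dp_surface(cost_rpe, nx, ny, smoothness) + z_lo - 1L
  rpe <- surface_median_y(rpe_raw)
  rpe <- pmax(rpe, ilm + 1L)

  surface_pair(ilm, rpe, smoothness_used = smoothness)
}

matrixStat_rowmin <- function(m) do.call(pmin, as.data.frame(m))

# Min-cost path DP over the fast axis, vectorized across all B-scans.
# cost: (nx*ny, nzc) matrix (rows ordered x-fastest). Returns (nx, ny)
# integer matrix of 1-based depth indices into the cost's z axis.
dp_surface <- function(cost, nx, ny, smoothness) {
  nzc <- ncol(cost)
  s <- as.integer(smoothness)
  row_x <- function(x) cost[seq.int(x, by = nx, length.out = ny), , drop = FALSE]
  D <- row_x(1L)
  ptr <- array(0L, dim = c(ny, nzc, nx))   # x last: contiguous slab writes
  zin <- seq_len(nzc)
  for (x in 2:nx) {
    best <- D
    arg <- matrix(0L, ny, nzc)
    if (s > 0) {
      for (k in seq_len(s)) {
        # candidate from z - k (shift right) and z + k (shift left)
        sel <- D[, pmax(zin - k, 1L), drop = FALSE] < best
        sel[, seq_len(k)] <- FALSE
        if (any(sel)) {
          cand <- D[, pmax(zin - k, 1L), drop = FALSE]
          best[sel] <- cand[sel]; arg[sel] <- -k
        }
        sel <- D[, pmin(zin + k, nzc), drop = FALSE] < best
        sel[, (nzc - k + 1L):nzc] <- FALSE
        if (any(sel)) {
          cand <- D[, pmin(zin + k, nzc), drop = FALSE]
          best[sel] <- cand[sel]; arg[sel] <- k
        }
      }
    }
    D <- best + row_x(x)
    ptr[, , x] <- arg
  }
  # backtrack, vectorized over B-scans
  z <- max.col(-D, ties.method = "first")
  path <- matrix(0L, nx, ny)
  path[nx, ] <- z
  ys <- seq_len(ny)
  for (x in nx:2) {
    z <- z + ptr[cbind(ys, z, x)]
    path[x - 1L, ] <- z
  }
  path
}

# k=3 running median along the slow axis; endpoints kept.
surface_median_y <- function(m) {
  ny <- ncol(m)
  if (ny < 3) return(m)
  a <- m[, 1:(ny - 2), drop = FALSE]
  b <- m[, 2:(ny - 1), drop = FALSE]
  c_ <- m[, 3:ny, drop = FALSE]
  out <- m
  # median of three: max(min(a,b), min(max(a,b), c))
  out[, 2:(ny - 1)] <- pmax(pmin(a, b), pmin(pmax(a, b), c_))
  out
}

#' Thickness map from a surface pair
#'
#' Pointwise `(rpe - ilm) * axial_spacing` in micrometres, with the mean over
#' the analysis region (default: the full scan square; a centred circular
#' region is available via `region_radius_mm`).
#'
#' @param surfaces a [surface_pair()].
#' @param spacing_um length-3 voxel spacing of the source volume (axial = 3rd).
#' @param region_radius_mm optional radius of a centred circular analysis
#'   region; `NULL` uses the full scan area.
#' @return A list of class `thickness_map`: `data` (um), `mean_rt_um`, `region`.
#' @export
thickness_from_surfaces <- function(surfaces, spacing_um, region_radius_mm = NULL) {
  stopifnot(inherits(surfaces, "surface_pair"))
  d_um <- (surfaces$rpe_depth - surfaces$ilm_depth) * spacing_um[3]
  nx <- nrow(d_um); ny <- ncol(d_um)
  region <- matrix(TRUE, nx, ny)
  if (!is.null(region_radius_mm)) {
    xs <- (seq_len(nx) - (nx + 1) / 2) * spacing_um[1] / 1000
    ys <- (seq_len(ny) - (ny + 1) / 2) * spacing_um[2] / 1000
    region <- outer(xs^2, ys^2, "+") <= region_radius_mm^2
  }
  structure(list(data = d_um, mean_rt_um = mean(d_um[region]), region = region),
            class = "thickness_map")
}

#' Aggregate retinal thickness over the top-quality images
#'
#' Mean of `mean_rt_um` over the `k` highest-quality maps (ties broken by
#' acquisition order; `k` capped at the number available).
#'
#' @param maps list of [thickness_from_surfaces()] results.
#' @param quality numeric quality scores, one per map.
#' @param k number of top images to average (study rule: 2-3).
#' @return A list with `mean_rt_um`, `n_used`, `used` (indices).
#' @export
aggregate_rt <- function(maps, quality, k = 3) {
  stopifnot(length(maps) >= 1, length(quality) == length(maps))
  ord <- order(-quality, seq_along(maps))
  use <- ord[seq_len(min(k, length(maps)))]
  list(mean_rt_um = mean(vapply(maps[use], function(m) m$mean_rt_um, numeric(1))),
       n_used = length(use), used = sort(use))
}
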