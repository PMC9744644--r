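# ---- denoise / enhance -----------------------------------------------------

test_that("denoise with sigma zero is the identity and reduces noise otherwise", {
  withr::with_seed(1, img <- enface_image(matrix(runif(48 * 40), 48, 40), c(20, 20)))
  expect_identical(denoise(img, 0)$data, img$data)
  expect_lt(var(as.vector(denoise(img, 20)$data)), var(as.vector(img$data)))
  const <- enface_image(matrix(0.4, 30, 30), c(20, 20))
  expect_equal(denoise(const, 25)$data, const$data, tolerance = 1e-12)
})

test_that("contrast enhancement stays in [0,1] and leaves flat fields flat", {
  const <- enface_image(matrix(0.4, 40, 40), c(20, 20))
  out <- enhance_contrast(const)
  expect_equal(max(out$data) - min(out$data), 0)
  withr::with_seed(2, img <- enface_image(matrix(runif(64 * 64, 0.2, 0.3), 64, 64), c(20, 20)))
  out2 <- enhance_contrast(img, 2)
  expect_gte(min(out2$data), 0)
  expect_lte(max(out2$data), 1)
})

test_that("CLAHE increases tube/background separation on a low-contrast tube", {
  tube <- make_tube_image(64, 64, c(20, 20), tube_sigma_um = 40, contrast = 0.08)
  withr::with_seed(3, img <- enface_image(0.4 + tube + matrix(rnorm(64 * 64, 0, 0.01), 64, 64), c(20, 20)))
  on_tube <- abs(seq_len(64) - 32) <= 2
  sep <- function(m) median(m[, on_tube]) - median(m[, !on_tube])
  expect_gt(sep(enhance_contrast(img, 4)$data), sep(img$data))
})

# ---- robust PCA ------------------------------------------------------------

test_that("RPCA of the zero matrix is zero and always meets its tolerance", {
  z <- rpca_decompose(matrix(0, 20, 15))
  expect_equal(z$L, matrix(0, 20, 15))
  expect_equal(z$S, matrix(0, 20, 15))
  expect_true(z$converged)
})

test_that("RPCA recovers a planted rank-1 + sparse decomposition", {
  withr::with_seed(11, {
    u <- rnorm(80); v <- rnorm(60)
    L0 <- u %*% t(v) / 4
    S0 <- matrix(0, 80, 60)
    idx <- sample(80 * 60, round(0.01 * 80 * 60))
    S0[idx] <- runif(length(idx), 2, 4) * sample(c(-1, 1), length(idx), TRUE)
  })
  M <- L0 + S0
  r <- rpca_decompose(M, tol = 1e-8, max_iter = 400)
  expect_true(r$converged)
  expect_lt(norm(r$L - L0, "F") / norm(L0, "F"), 1e-3)
  # stopping rule: reconstruction within tolerance
  expect_lte(norm(M - r$L - r$S, "F") / norm(M, "F"), 1e-8)
})

test_that("RPCA separates low-rank stripes from a sparse diagonal vessel", {
  withr::with_seed(12, {
    stripes <- outer(rnorm(64), rep(1, 64)) * 0.05 + outer(rep(1, 64), rnorm(64)) * 0.05
  })
  # a diagonal tube is high-rank (unlike an axis-aligned one) and sparse
  d <- abs(outer(seq_len(64), seq_len(64), "-"))
  tube <- 0.5 * exp(-log(2) * (d / 2)^4)
  r <- rpca_decompose(stripes + tube, tol = 1e-7, max_iter = 300)
  on_tube <- d <= 1
  expect_gt(mean(r$S[on_tube]), 5 * abs(mean(r$S[!on_tube])))
})

# ---- Frangi ----------------------------------------------------------------

test_that("a constant image has zero vesselness everywhere", {
  img <- enface_image(matrix(0.7, 48, 48), c(20, 20))
  expect_equal(frangi_vesselness(img)$data, matrix(0, 48, 48))
})

test_that("vesselness is bounded in [0,1] for arbitrary input", {
  withr::with_seed(5, img <- enface_image(matrix(rnorm(50 * 40), 50, 40), c(20, 20)))
  v <- frangi_vesselness(img)$data
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
})

test_that("the tube centerline outscores an equal-contrast isotropic blob", {
  m <- make_tube_image(64, 64, c(20, 20), tube_sigma_um = 30, y0 = 20,
                       contrast = 1, blob_at = c(32, 48), blob_sigma_um = 30)
  v <- frangi_vesselness(enface_image(m, c(20, 20)),
                         frangi_params(scales_um = c(20, 30, 45)))$data
  centerline <- v[32, 20]
  blob_centre <- v[32, 48]
  expect_gt(centerline, blob_centre)
  # argmax of the tube rows lies on the centerline
  expect_equal(which.max(v[32, 1:40]), 20, tolerance = 1)
})

test_that("empty scale lists are rejected", {
  expect_error(frangi_params(scales_um = numeric(0)), "scale")
})

test_that("vesselness matches the brute-force Hessian oracle to 1e-6", {
  withr::with_seed(13, {
    m <- make_tube_image(64, 64, c(20, 20), tube_sigma_um = 35, y0 = 28) +
      0.02 * matrix(rnorm(64 * 64), 64, 64)
  })
  fast <- frangi_vesselness(enface_image(m, c(20, 25)),
                            frangi_params(scales_um = c(25, 40)))$data
  slow <- frangi_bruteforce(m, c(20, 25), c(25, 40))
  expect_lt(max(abs(fast - slow)), 1e-6)
})

# ---- circular artifact suppression ----------------------------------------

test_that("a disc is removed while an equal-intensity tube is retained", {
  m <- matrix(0, 80, 80)
  m[10:70, 38:42] <- 0.8                       # tube, elongation ~12
  xs <- seq_len(80)
  d2 <- outer((xs - 40)^2, (xs - 65)^2, "+")
  m[d2 <= 49] <- 0.8                           # disc of radius 7 at (40, 65)
  prob <- structure(list(data = m, spacing_um = c(20, 20), params = NULL),
                    class = "vessel_prob")
  out <- suppress_circular_artifacts(prob, min_elongation = 2.5,
                                     support_threshold = 0.4)
  expect_equal(max(out$data[d2 <= 16]), 0)          # disc core zeroed
  expect_gt(max(out$data[30:50, 38:42]), 0.7)       # tube survives
})

test_that("zero maps and unit elongation are identities", {
  z <- structure(list(data = matrix(0, 20, 20), spacing_um = c(20, 20),
                      params = NULL), class = "vessel_prob")
  expect_identical(suppress_circular_artifacts(z)$data, z$data)
  withr::with_seed(6, p <- structure(list(data = matrix(runif(400), 20, 20),
                                          spacing_um = c(20, 20), params = NULL),
                                     class = "vessel_prob"))
  expect_identical(suppress_circular_artifacts(p, min_elongation = 1)$data, p$data)
})

# ---- thresholding and rVPD -------------------------------------------------

test_that("extreme thresholds produce full and empty masks", {
  withr::with_seed(7, p <- structure(list(data = matrix(runif(100, 0.01, 0.99), 10, 10),
                                          spacing_um = c(20, 20), params = NULL),
                                     class = "vessel_prob"))
  expect_true(all(global_threshold(p, "fixed", t = 0)$data))
  expect_false(any(global_threshold(p, "fixed", t = 1)$data))
  expect_error(global_threshold(p, "fixed", t = 1.4), "\\[0, 1\\]")
})

test_that("rVPD is an exact pixel ratio", {
  m <- matrix(FALSE, 10, 10); m[1:5] <- TRUE
  r <- compute_rvpd(vessel_mask(m))
  expect_identical(r$rvpd_pct, 5)
  expect_identical(compute_rvpd(vessel_mask(matrix(FALSE, 4, 4)))$rvpd_pct, 0)
})

test_that("rVPD of the planted truth mask equals the stored fraction exactly", {
  sim <- generate_volume(scene_params(grid_shape = c(96L, 48L, 128L), seed = 7))
  r <- compute_rvpd(vessel_mask(sim$truth$vessel_mask))
  expect_identical(r$rvpd_pct, 100 * sim$truth$true_vessel_fraction)
})

test_that("segmentation of a noise-free scene recovers the planted mask support", {
  # wide vessels only: partial-volume dilution of sub-pixel tubes would
  # otherwise dominate the comparison
  sim <- generate_volume(scene_params(grid_shape = c(128L, 64L, 192L), seed = 9,
                                      vessel_count = 3,
                                      vessel_radius_um_range = c(60, 90),
                                      speckle_sigma = 0,
                                      band_artifact_amplitude = 0,
                                      blob_artifact_count = 0))
  ef <- project_enface(sim$volume, surface_pair(sim$truth$ilm_depth,
                                                sim$truth$rpe_depth))
  seg <- segment_vessels(ef, threshold_method = "fixed", threshold = 0.5)
  truth <- sim$truth$vessel_mask
  kern <- matrix(1, 3, 3)
  dil <- function(m) as.matrix(EBImage::dilate(EBImage::Image(m * 1), kern)) > 0
  frac_outside <- mean(seg$mask$data & !dil(truth))
  frac_missed <- mean(truth & !dil(seg$mask$data))
  expect_lt(frac_outside, 0.005)
  expect_lt(frac_missed, 0.005)
})

# ---- aggregation -----------------------------------------------------------

test_that("top-k aggregation averages the highest-quality images", {
  res <- lapply(c(4, 5, 6, 9.9), function(v)
    structure(list(rvpd_pct = v, n_vessel_px = NA, n_total_px = NA,
                   threshold_used = 0.4), class = "perfusion_result"))
  agg <- aggregate_subject(res, quality = c(9, 9, 9, 2), k = 3)
  expect_equal(agg$rvpd_pct, 5)
  expect_equal(agg$used, 1:3)
  one <- aggregate_subject(res[2], quality = 8, k = 3)
  expect_equal(one$rvpd_pct, 5)
  same <- aggregate_subject(res[c(1, 1, 1)], quality = c(7, 7, 7), k = 2)
  expect_equal(same$rvpd_pct, 4)
})

test_that("quality ties break towards earlier acquisitions", {
  res <- lapply(c(2, 4, 6), function(v)
    structure(list(rvpd_pct = v, n_vessel_px = NA, n_total_px = NA,
                   threshold_used = 0.4), class = "perfusion_result"))
  agg <- aggregate_subject(res, quality = c(8, 8, 8), k = 2)
  expect_equal(agg$used, 1:2)
  expect_equal(agg$rvpd_pct, 3)
})

# ---- end-to-end properties -------------------------------------------------

test_that("planted fraction and pipeline rVPD are rank-correlated across seeds", {
  fr <- seq(0.03, 0.075, length.out = 6)
  est <- numeric(6); tru <- numeric(6)
  for (i in seq_along(fr)) {
    sim <- generate_volume(scene_params(grid_shape = c(160L, 80L, 192L),
                                        target_fraction = fr[i], seed = 40 + i))
    surf <- extract_surfaces(sim$volume)
    seg <- segment_vessels(project_enface(sim$volume, surf))
    est[i] <- seg$result$rvpd_pct
    tru[i] <- 100 * sim$truth$true_vessel_fraction
  }
  expect_gte(cor(est, tru, method = "spearman"), 0.8)
})

test_that("RPCA cleanup mostly cancels the band-artifact perturbation", {
  base_p <- scene_params(grid_shape = c(160L, 80L, 192L), target_fraction = 0.05,
                         seed = 14, band_artifact_amplitude = 0)
  band_p <- scene_params(grid_shape = c(160L, 80L, 192L), target_fraction = 0.05,
                         seed = 14, band_artifact_amplitude = 0.12)
  run1 <- function(p, rpca) {
    sim <- generate_volume(p)
    surf <- extract_surfaces(sim$volume)
    segment_vessels(project_enface(sim$volume, surf),
                    use_rpca = rpca)$result$rvpd_pct
  }
  clean <- run1(base_p, TRUE)
  with_band <- run1(band_p, TRUE)
  without_rpca <- run1(band_p, FALSE)
  shift_with <- abs(with_band - clean)
  shift_without <- abs(without_rpca - clean)
  expect_lte(shift_with, shift_without / 3 + 0.15)
})
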