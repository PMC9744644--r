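# ---- projection ------------------------------------------------------------

flat_surfaces <- function(nx, ny, ilm, rpe) {
  surface_pair(matrix(ilm, nx, ny), matrix(rpe, nx, ny), smoothness_used = 2)
}

test_that("projection of a constant slab is constant for both reducers", {
  vol <- oct_volume(array(0.37, c(12, 10, 60)), spacing_um = c(10, 10, 4))
  s <- flat_surfaces(12, 10, 10, 50)
  for (red in c("mean", "max")) {
    ef <- project_enface(vol, s, band_um = c(0, 80), reducer = red)
    expect_equal(ef$data, matrix(0.37, 12, 10), tolerance = 1e-12)
  }
})

test_that("max reducer picks a single bright voxel inside the band", {
  a <- array(0.1, c(6, 5, 40))
  a[3, 2, 15] <- 0.93
  vol <- oct_volume(a, spacing_um = c(10, 10, 4))
  s <- flat_surfaces(6, 5, 10, 35)
  ef <- project_enface(vol, s, band_um = c(0, 40), reducer = "max")
  expect_equal(ef$data[3, 2], 0.93)
  expect_equal(ef$data[1, 1], 0.1)
})

test_that("mean projection is linear in the volume intensities", {
  withr::with_seed(4, a <- array(runif(6 * 5 * 40) * 0.4, c(6, 5, 40)))
  s <- flat_surfaces(6, 5, 8, 36)
  v1 <- oct_volume(a, spacing_um = c(10, 10, 4))
  v2 <- oct_volume(a * 0.5, spacing_um = c(10, 10, 4))
  e1 <- project_enface(v1, s, band_um = c(0, 60))
  e2 <- project_enface(v2, s, band_um = c(0, 60))
  expect_equal(e2$data, 0.5 * e1$data, tolerance = 1e-12)
})

test_that("a band leaving the slab names the offending A-scan", {
  vol <- oct_volume(array(0.3, c(6, 5, 40)), spacing_um = c(10, 10, 4))
  s <- flat_surfaces(6, 5, 10, 20)
  expect_error(project_enface(vol, s, band_um = c(0, 200)), "A-scan")
})

test_that("projected tube positions match the planted mask (noise off)", {
  sim <- generate_volume(scene_params(grid_shape = c(96L, 48L, 128L), seed = 7,
                                      speckle_sigma = 0, band_artifact_amplitude = 0,
                                      blob_artifact_count = 0))
  ef <- project_enface(sim$volume, surface_pair(sim$truth$ilm_depth,
                                                sim$truth$rpe_depth))
  truth <- sim$truth$vessel_mask
  expect_gt(mean(ef$data[truth]), mean(ef$data[!truth]) + 0.05)
})

# ---- quality ---------------------------------------------------------------

test_that("a noise-free slab clamps to score 10 with a warning", {
  sim <- generate_volume(scene_params(grid_shape = c(96L, 48L, 128L), seed = 2,
                                      speckle_sigma = 0))
  expect_warning(q <- quality_score(sim$volume), "noise floor")
  expect_equal(q$score, 10)
})

test_that("a structureless noise volume scores at most 2", {
  withr::with_seed(6, {
    z <- rnorm(40 * 30 * 64)
    a <- 0.01 * exp(0.5 * z - 0.125)
  })
  vol <- oct_volume(array(pmin(a, 1), c(40, 30, 64)), spacing_um = c(60, 60, 15))
  q <- quality_score(vol)
  expect_lte(q$score, 2)
})

test_that("lower speckle yields strictly higher SNR and no lower score", {
  qs <- lapply(c(0.5, 0.25, 0.1), function(s)
    quality_score(generate_volume(scene_params(grid_shape = c(96L, 48L, 128L),
                                               speckle_sigma = s, seed = 5))$volume))
  snr <- vapply(qs, function(q) q$snr_db, numeric(1))
  sc <- vapply(qs, function(q) q$score, numeric(1))
  expect_true(all(diff(snr) > 0))
  expect_true(all(diff(sc) >= 0))
})

# ---- rigid transforms ------------------------------------------------------

tube_scene <- function(seed = 1, nx = 96, ny = 96) {
  withr::with_seed(seed, {
    m <- matrix(0, nx, ny)
    for (i in 1:4) {
      x0 <- runif(1, 20, nx - 20); y0 <- runif(1, 20, ny - 20); th <- runif(1, 0, pi)
      for (s in seq(-34, 34, by = 0.5)) {
        x <- round(x0 + s * cos(th)); y <- round(y0 + s * sin(th))
        if (x > 1 && x < nx && y > 1 && y < ny) m[(x - 1):(x + 1), (y - 1):(y + 1)] <- 1
      }
    }
    enface_image(m + matrix(rnorm(nx * ny, 0, 0.04), nx, ny), c(20, 20))
  })
}

test_that("identity transform reproduces the image to interpolation precision", {
  img <- tube_scene(2)
  out <- apply_transform(img, rigid_transform(0, 0, 0))
  expect_lt(max(abs(out$data - img$data)), 1e-7)
})

test_that("a transform composed with its inverse is the identity map", {
  t1 <- rigid_transform(7.5, 3.2, -1.4)
  ti <- invert_transform(t1)
  # compose on a grid of points: y = R2 (R1 x + s1) + s2 must equal x
  th1 <- t1$rotation_deg * pi / 180; th2 <- ti$rotation_deg * pi / 180
  R1 <- matrix(c(cos(th1), sin(th1), -sin(th1), cos(th1)), 2, 2)
  R2 <- matrix(c(cos(th2), sin(th2), -sin(th2), cos(th2)), 2, 2)
  pts <- matrix(rnorm(20), 2)
  out <- R2 %*% (R1 %*% pts + c(t1$shift_x_px, t1$shift_y_px)) +
    c(ti$shift_x_px, ti$shift_y_px)
  expect_lt(max(abs(out - pts)), 1e-9)
})

test_that("shift followed by inverse shift round-trips within 1e-3 RMS", {
  # band-limited unit-range field: interpolation error is the only residual
  withr::with_seed(3, z <- matrix(rnorm(96 * 96), 96, 96))
  g <- foctr:::gauss_smooth_um(z, 160, c(20, 20))
  img <- enface_image((g - min(g)) / diff(range(g)), c(20, 20))
  fwd <- apply_transform(img, rigid_transform(0, 4.3, -2.7))
  back <- apply_transform(fwd, rigid_transform(0, -4.3, 2.7))
  interior <- img$data[11:86, 11:86]
  expect_lt(sqrt(mean((interior - back$data[11:86, 11:86])^2)), 1e-3)
})

test_that("rotating a symmetric cross by 90 degrees reproduces it", {
  m <- matrix(0, 41, 41)
  m[19:23, ] <- 1; m[, 19:23] <- 1
  img <- enface_image(m, c(10, 10))
  out <- apply_transform(img, rigid_transform(90, 0, 0))
  expect_lt(max(abs(out$data[3:39, 3:39] - m[3:39, 3:39])), 1e-6)
})

# ---- registration ----------------------------------------------------------

test_that("registering an image to itself gives the identity transform", {
  img <- tube_scene(4)
  t <- register_rigid(img, img)
  expect_equal(t$rotation_deg, 0)
  expect_lt(abs(t$shift_x_px), 0.1)
  expect_lt(abs(t$shift_y_px), 0.1)
})

test_that("integer translations are recovered within half a pixel", {
  img <- tube_scene(5)
  mov <- enface_image(img$data[c(4:96, 1:3), c(95:96, 1:94)], img$spacing_um)
  # moving = reference rolled by (-3, +2): aligning it back needs (+3, -2)
  t <- register_rigid(img, mov)
  expect_equal(t$rotation_deg, 0)
  expect_lt(abs(t$shift_x_px - 3), 0.5)
  expect_lt(abs(t$shift_y_px + 2), 0.5)
})

test_that("a 4-degree rotation is recovered within half a degree", {
  img <- tube_scene(6)
  mov <- apply_transform(img, rigid_transform(4, 0, 0))
  t <- register_rigid(img, mov)
  expect_lt(abs(t$rotation_deg + 4), 0.5)
})

test_that("registration is consistent for random transforms within range", {
  img <- tube_scene(7)
  cases <- list(c(2, 5, -3), c(-6, -8, 4), c(9, 2, 9))
  for (cs in cases) {
    tr <- rigid_transform(cs[1], cs[2], cs[3])
    mov <- apply_transform(img, tr)
    est <- register_rigid(img, mov)
    inv <- invert_transform(tr)
    expect_lt(abs(est$rotation_deg - inv$rotation_deg), 0.5)
    expect_lt(abs(est$shift_x_px - inv$shift_x_px), 0.5)
    expect_lt(abs(est$shift_y_px - inv$shift_y_px), 0.5)
  }
})

test_that("flat images cannot be registered", {
  flat <- enface_image(matrix(0.5, 32, 32), c(20, 20))
  expect_error(register_rigid(flat, flat), "flat")
})
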