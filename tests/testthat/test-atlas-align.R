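rot <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

test_that("fit_transform recovers identity and known similarity transforms", {
  set.seed(2)
  P <- cbind(runif(30, 0, 2000), runif(30, 0, 2000))
  id <- fit_transform(P, P)
  expect_equal(id$A, diag(2), tolerance = 1e-12)
  expect_equal(id$t, c(0, 0), tolerance = 1e-9)
  expect_lt(id$rms_residual_um, 1e-9)

  # rotation 10 deg + translation (30, -20), unit scale
  R <- rot(10 * pi / 180)
  M <- sweep(P %*% t(solve(R)), 2, c(30, -20) %*% t(solve(R)))
  fit <- fit_transform(P, M)
  expect_equal(fit$A, R, tolerance = 1e-9)
  expect_equal(fit$t, c(30, -20), tolerance = 1e-6)
  expect_lt(fit$rms_residual_um, 1e-6)
})

test_that("round-trip through noiseless synthetic landmarks is exact", {
  truth <- structure(list(model = "similarity", A = 1.05 * rot(0.2),
                          t = c(120, -60)), class = "transform2d")
  lm <- perturb_landmarks(truth, n_pairs = 40, noise_sd_um = 0, seed = 3)
  fit <- fit_transform(lm[, c("fixed_x_um", "fixed_y_um")],
                       lm[, c("moving_x_um", "moving_y_um")])
  expect_equal(fit$A, truth$A, tolerance = 1e-9)
  expect_equal(fit$t, truth$t, tolerance = 1e-6)
  expect_lt(fit$rms_residual_um, 1e-6)
})

test_that("fit residual scales with landmark noise (Monte Carlo)", {
  truth <- structure(list(model = "similarity", A = rot(0.1), t = c(50, 10)),
                     class = "transform2d")
  rms <- vapply(1:20, function(s) {
    lm <- perturb_landmarks(truth, 60, 5, seed = s)
    fit_transform(lm[, c("fixed_x_um", "fixed_y_um")],
                  lm[, c("moving_x_um", "moving_y_um")])$rms_residual_um
  }, numeric(1))
  expect_true(all(rms > 2.5 & rms < 7.5))
})

test_that("degenerate landmark geometry is rejected", {
  P <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_error(fit_transform(P, P), "degenerate")
  col <- cbind(1:3, 2 * (1:3))       # collinear
  expect_error(fit_transform(col, col, model = "affine"), "degenerate")
  expect_error(fit_transform(cbind(1, 1), cbind(2, 2), model = "affine"),
               ">= 3")
})

test_that("displacement QC: identity, pure translation, rotation", {
  b <- c(0, 3500, 0, 2100)
  qc0 <- displacement_qc(identity_transform(), b)
  expect_equal(qc0$n_points, 11 * 7)
  expect_true(all(qc0$displacements_um == 0))
  expect_equal(qc0$mean_um, 0)
  expect_equal(qc0$sd_um, 0)

  tr <- structure(list(model = "similarity", A = diag(2), t = c(100, 0)),
                  class = "transform2d")
  qc1 <- displacement_qc(tr, b)
  expect_true(all(abs(qc1$displacements_um - 100) < 1e-12))
  expect_equal(qc1$mean_um, 100)
  expect_equal(qc1$sd_um, 0)

  # rotation about the grid center: |T(p) - p| = 2 sin(theta/2) |p - c|
  theta <- 0.05
  ctr <- c(mean(b[1:2]), mean(b[3:4]))
  A <- rot(theta)
  trr <- structure(list(model = "similarity", A = A,
                        t = as.numeric(ctr - A %*% ctr)),
                   class = "transform2d")
  qc2 <- displacement_qc(trr, b)
  r <- sqrt(rowSums(sweep(qc2$grid_points_um, 2, ctr)^2))
  expect_equal(qc2$displacements_um, 2 * sin(theta / 2) * r,
               tolerance = 1e-9)
  expect_true(all(diff(qc2$displacements_um[order(r)]) > -1e-9))
})

test_that("region assignment: interior, out-of-bounds, and bulk oracle", {
  lay <- data.frame(region_id = c(1L, 2L), name = c("a", "b"),
                    x0_um = c(0, 60), y0_um = c(0, 0),
                    width_um = c(50, 40), height_um = c(100, 100))
  map <- generate_region_map(lay, c(300, 300), c(0.5, 0.5))
  expect_equal(assign_regions(cbind(25, 50), map), 1L)
  expect_equal(assign_regions(cbind(80, 50), map), 2L)
  expect_equal(assign_regions(cbind(55, 50), map), 0L)   # gap
  expect_equal(assign_regions(cbind(-5, 50), map), 0L)
  expect_equal(assign_regions(cbind(25, 1e4), map), 0L)

  # bulk: points in section coordinates under a known transform
  tr <- structure(list(model = "similarity", A = diag(2), t = c(12, -7)),
                  class = "transform2d")
  set.seed(4)
  atlas_pts <- cbind(runif(1000, 0, 150), runif(1000, 0, 150))
  section_pts <- sweep(atlas_pts, 2, tr$t)
  truth_id <- integer(1000)
  for (r in 1:2) {
    inside <- atlas_pts[, 1] >= lay$x0_um[r] &
      atlas_pts[, 1] < lay$x0_um[r] + lay$width_um[r] &
      atlas_pts[, 2] >= lay$y0_um[r] &
      atlas_pts[, 2] < lay$y0_um[r] + lay$height_um[r]
    truth_id[inside] <- lay$region_id[r]
  }
  got <- assign_regions(section_pts, map, tr)
  # disagreement only within one pixel of a region border
  border <- pmin(abs(atlas_pts[, 1] - 50), abs(atlas_pts[, 1] - 60),
                 abs(atlas_pts[, 1] - 100)) < 0.5 + 1e-9
  expect_true(all(got[!border] == truth_id[!border]))
})
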