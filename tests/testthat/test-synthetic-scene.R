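test_that("generate_region_map handles identity, disjoint and empty layouts", {
  vs <- c(0.3611, 0.3611)
  # full-frame single region
  lay <- data.frame(region_id = 1L, name = "all", x0_um = 0, y0_um = 0,
                    width_um = 64 * vs[1], height_um = 64 * vs[2])
  map <- generate_region_map(lay, c(64, 64), vs)
  expect_true(all(map$labels == 1L))
  expect_equal(map$id_to_area_um2$area_um2, 64 * 64 * prod(vs))

  # two disjoint rectangles, 100x100 and 50x50 um -> 4:1 areas
  lay2 <- data.frame(region_id = c(1L, 2L), name = c("big", "small"),
                     x0_um = c(5, 120), y0_um = c(5, 5),
                     width_um = c(100, 50), height_um = c(100, 50))
  map2 <- generate_region_map(lay2, c(512, 512), vs)
  a <- map2$id_to_area_um2
  expect_equal(a$area_um2[a$region_id == 1] / a$area_um2[a$region_id == 2],
               4, tolerance = 0.03)

  # empty layout -> all background
  map3 <- generate_region_map(lay2[0, ], c(32, 32), vs)
  expect_true(all(map3$labels == 0L))
  expect_equal(nrow(map3$id_to_area_um2), 0L)
})

test_that("overlapping rectangles are rejected naming both regions", {
  lay <- data.frame(region_id = c(3L, 7L), name = c("a", "b"),
                    x0_um = c(0, 10), y0_um = c(0, 10),
                    width_um = c(20, 20), height_um = c(20, 20))
  expect_error(generate_region_map(lay, c(128, 128), c(0.3611, 0.3611)),
               "3 and 7")
})

test_that("render_scene with zero densities yields empty truth and flat channels", {
  cfg <- small_scene_config(seed = 3,
                            vgat_density_per_region = c(0, 0),
                            pc_fraction_per_region = c(0, 0),
                            axon_clutter_density = 0)
  scene <- render_scene(cfg)
  expect_equal(nrow(scene$truth$boutons), 0L)
  # channel 0 mean ~ illumination amplitude; channel 1 near zero
  expect_lt(abs(mean(scene$stack$channels$vGAT) -
                  cfg$illumination_amplitude), 10)
  expect_lt(mean(scene$stack$channels$tdt), 2)
})

test_that("bouton counts follow the Poisson expectation of area x density", {
  # one 100 x 100 um region at 0.01 / um^2 -> E[count] = 100
  counts <- vapply(1:20, function(s) {
    cfg <- scene_config(
      shape_voxels = c(300, 300, 3),
      region_layout = data.frame(region_id = 1L, name = "r",
                                 x0_um = 4, y0_um = 4,
                                 width_um = 100, height_um = 100),
      vgat_density_per_region = 0.01, pc_fraction_per_region = 0.5,
      seed = s)
    nrow(render_scene(cfg)$truth$boutons)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100) / sqrt(20))
})

test_that("ground-truth PC fraction follows binomial sampling", {
  cfg <- scene_config(
    shape_voxels = c(400, 400, 3),
    region_layout = data.frame(region_id = 1L, name = "r", x0_um = 4,
                               y0_um = 4, width_um = 130, height_um = 130),
    vgat_density_per_region = 0.02, pc_fraction_per_region = 0.5, seed = 11)
  tr <- render_scene(cfg)$truth$boutons
  n <- nrow(tr)
  expect_gte(n, 200)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(tr$is_pc) - 0.5), 3 * se)
})

test_that("identical config and seed reproduce the scene bit for bit", {
  s1 <- render_scene(small_scene_config(seed = 9))
  s2 <- render_scene(small_scene_config(seed = 9))
  expect_identical(s1$stack$channels, s2$stack$channels)
  expect_identical(s1$truth, s2$truth)
})

test_that("per-region ground-truth counts are consistent with the bouton list", {
  scene <- render_scene(small_scene_config(seed = 4))
  tr <- scene$truth
  expect_equal(sum(tr$per_region$n_vgat), nrow(tr$boutons))
  for (r in tr$per_region$region_id) {
    expect_equal(tr$per_region$n_pc[tr$per_region$region_id == r],
                 sum(tr$boutons$is_pc & tr$boutons$region_id == r))
  }
  # centroids inside bounds
  fld <- scene$stack$voxel_size_um * dim(scene$stack$channels$vGAT)[c(2, 1, 3)]
  expect_true(all(tr$boutons$x_um >= 0 & tr$boutons$x_um <= fld[1]))
  expect_true(all(tr$boutons$y_um >= 0 & tr$boutons$y_um <= fld[2]))
  expect_true(all(tr$boutons$z_um >= 0 & tr$boutons$z_um <= fld[3]))
})

test_that("default reporter intensity modes overlap by < 2%", {
  scene <- render_scene(scene_config(seed = 5))
  tr <- scene$truth$boutons
  # midpoint of the default log-modes (10 and 100 a.u.)
  cut <- exp(mean(log(c(10, 100))))
  overlap <- (sum(tr$tdt_peak[tr$is_pc] < cut) +
                sum(tr$tdt_peak[!tr$is_pc] >= cut)) / nrow(tr)
  expect_lt(overlap, 0.02)
})

test_that("scene validation rejects out-of-range parameters", {
  expect_error(small_scene_config(pc_fraction_per_region = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(small_scene_config(vgat_density_per_region = c(-0.01, 0)),
               ">= 0")
  expect_error(small_scene_config(tdt_signal_dist = c(log(5), 0.3)),
               "exceed")
  # desk-scale guard on expected count
  cfg <- scene_config(vgat_density_per_region = c(1e4, 1e4, 1e4))
  expect_error(render_scene(cfg), "guard")
})

test_that("generate_ephys_cells follows the logistic density link", {
  grid <- bin_to_grid(cbind(runif(50, 0, 720), runif(50, 0, 720), 1),
                      extent_um = c(720, 720, 4))
  # beta1 = 0, beta0 = 0 -> fraction ~ 0.5
  cells <- generate_ephys_cells(grid, ephys_link_params(
    beta0 = 0, beta1 = 0, n_cells = 2000, seed = 1))
  expect_lt(abs(mean(cells$responded) - 0.5), 3 * sqrt(0.25 / 2000))
  # nonresponders have amplitude exactly 0, responders > 0
  expect_true(all(cells$amplitude_pa[!cells$responded] == 0))
  expect_true(all(cells$amplitude_pa[cells$responded] > 0))

  # beta1 > 0 -> responding fraction non-decreasing across density terciles
  grid2 <- bin_to_grid(cbind(runif(4000, 0, 720) * runif(4000),
                             runif(4000, 0, 720), 1),
                       extent_um = c(720, 720, 4))
  cells2 <- generate_ephys_cells(grid2, ephys_link_params(
    beta0 = -1, beta1 = 2000, n_cells = 2000, seed = 2))
  d <- local_density(cells2, grid2)
  ter <- cut(d, stats::quantile(d, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  fr <- tapply(cells2$responded, ter, mean)
  expect_true(all(diff(fr) >= 0))
})

test_that("perturb_landmarks is seeded and respects its precondition", {
  tr <- fit_transform(cbind(c(0, 10, 0), c(0, 0, 10)),
                      cbind(c(1, 11, 1), c(2, 2, 12)))
  expect_error(perturb_landmarks(tr, n_pairs = 2, noise_sd_um = 0), ">= 3")
  lm1 <- perturb_landmarks(tr, 20, 1, seed = 7)
  lm2 <- perturb_landmarks(tr, 20, 1, seed = 7)
  expect_identical(lm1, lm2)
})
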