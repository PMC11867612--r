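vs3 <- c(0.3611, 0.3611, 0.3)

test_that("an all-zero image yields no seeds", {
  expect_equal(nrow(find_seed_maxima(array(0, c(16, 16, 3)), vs3, 0)), 0L)
  # constant plateaus yield none either
  expect_equal(nrow(find_seed_maxima(array(5, c(16, 16, 3)), vs3, 0)), 0L)
})

test_that("well-separated rendered spots produce one seed each, near truth", {
  ctr <- rbind(c(5, 6, 0.7), c(7, 6, 0.7))        # 2.0 um apart
  img <- render_spots(c(40, 40, 5), ctr, peaks = c(100, 80))
  seeds <- find_seed_maxima(img, vs3, threshold = 20)
  expect_equal(nrow(seeds), 2L)
  for (b in 1:2) {
    d <- sqrt((seeds$x_um - ctr[b, 1])^2 + (seeds$y_um - ctr[b, 2])^2)
    expect_lt(min(d), 0.3611 * 1.5)
  }
})

test_that("spots closer than the bouton diameter are merged at seed stage", {
  ctr <- rbind(c(5, 5, 0.7), c(5.5, 5, 0.7))      # 0.5 um apart
  img <- render_spots(c(32, 32, 5), ctr, peaks = c(100, 90))
  seeds <- find_seed_maxima(img, vs3, threshold = 20, min_separation_um = 1)
  expect_equal(nrow(seeds), 1L)
})

test_that("compiled maxima + suppression agree with the exhaustive R oracle", {
  set.seed(42)
  for (rep in 1:5) {
    arr <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
    pk <- boutonmap:::detect_peaks(arr, vs3, threshold = 1,
                                   min_separation_um = 0)
    got <- sort(pk$i + 1000L * pk$j + 1000000L * pk$k)
    idx <- boutonmap:::local_maxima_3d(arr)
    idx <- idx[arr[idx] >= 1]
    d <- dim(arr)
    kk <- (idx - 1L) %/% (d[1] * d[2]) + 1L
    rem <- (idx - 1L) %% (d[1] * d[2])
    jj <- rem %/% d[1] + 1L
    ii <- rem %% d[1] + 1L
    expect_setequal(got, sort(ii + 1000L * jj + 1000000L * kk))
  }
})

test_that("greedy suppression matches the plain-R oracle, anisotropy in um", {
  set.seed(7)
  coords <- cbind(runif(300, 0, 30), runif(300, 0, 30), runif(300, 0, 1.5))
  keep_cpp <- boutonmap:::.cpp_suppress_min_sep(coords, 1.0)
  expect_identical(as.logical(keep_cpp), suppress_oracle(coords, 1.0))

  # separation measured physically: 0.8 um along z (many voxels) still merges
  ctr_z <- rbind(c(5, 5, 0.3), c(5, 5, 1.1))
  img_z <- render_spots(c(32, 32, 5), ctr_z, peaks = c(100, 90))
  expect_equal(nrow(find_seed_maxima(img_z, vs3, 20, 1)), 1L)
})

test_that("a single rendered spot segments into one accurate bouton", {
  ctr <- rbind(c(6, 6, 0.7))
  img <- render_spots(c(40, 40, 5), ctr, peaks = 200)
  thr <- 20
  seeds <- find_seed_maxima(img, vs3, thr)
  bs <- segment_boutons(img, vs3, seeds, thr)
  expect_equal(nrow(bs$table), 1L)
  expect_lt(abs(bs$table$x_um - 6), 0.3611)
  expect_lt(abs(bs$table$y_um - 6), 0.3611)
  # integrated intensity ~ rendered mass above threshold
  expect_equal(bs$table$integrated_vgat, sum(img[img >= thr]),
               tolerance = 0.05)
  expect_gte(bs$table$peak_vgat, thr)
})

test_that("watershed splits touching spots along the brute-force boundary", {
  ctr <- rbind(c(5, 6, 0.7), c(7, 6, 0.7))
  img <- render_spots(c(36, 36, 5), ctr, peaks = c(120, 100))
  thr <- 10
  seeds <- find_seed_maxima(img, vs3, thr)
  bs <- segment_boutons(img, vs3, seeds, thr)
  expect_equal(nrow(bs$table), 2L)
  # nearest-peak partition oracle over the suprathreshold mask
  pos <- which(bs$labels > 0L)
  d <- dim(img)
  kk <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  rem <- (pos - 1L) %% (d[1] * d[2])
  jj <- rem %/% d[1] + 1L
  ii <- rem %% d[1] + 1L
  x <- (jj - 0.5) * vs3[1]; y <- (ii - 0.5) * vs3[2]; z <- (kk - 0.5) * vs3[3]
  near1 <- (x - 5)^2 + (y - 6)^2 < (x - 7)^2 + (y - 6)^2
  oracle_lab <- ifelse(near1, which.min(abs(bs$table$x_um - 5)),
                       which.min(abs(bs$table$x_um - 7)))
  expect_gte(mean(oracle_lab == bs$labels[pos]), 0.95)
})

test_that("no seeds gives an empty table, and labels partition the mask", {
  img <- render_spots(c(32, 32, 5), rbind(c(5, 5, 0.7)), peaks = 50)
  empty <- segment_boutons(img, vs3, find_seed_maxima(img, vs3, 1000), 1000)
  expect_equal(nrow(empty$table), 0L)

  seeds <- find_seed_maxima(img, vs3, 10)
  bs <- segment_boutons(img, vs3, seeds, 10)
  expect_equal(nrow(bs$table), nrow(seeds))
  expect_true(all(img[bs$labels > 0L] >= 10))
})

test_that("raising the threshold never increases the object count", {
  scene <- render_scene(small_scene_config(seed = 6))
  vs <- scene$stack$voxel_size_um
  bg <- estimate_background(scene$stack$channels$vGAT, vs, 50)
  cv <- boutonmap:::smooth_3d(subtract_background(scene$stack$channels$vGAT, bg),
                              vs, 0.25)
  counts <- vapply(c(10, 20, 40, 80), function(thr) {
    nrow(segment_boutons(cv, vs, find_seed_maxima(cv, vs, thr), thr)$table)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
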