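test_that("pooled LC responding percentage matches the printed value", {
  st <- region_response_stats(lc_fixture(), grouping = NULL)
  expect_equal(st$n, 67L)
  expect_equal(st$n_responding, 2L)
  expect_equal(round(100 * st$fraction), 3)
})

test_that("amplitude summaries follow the all-cells / responders convention", {
  cells <- data.frame(region_id = "x",
                      responded = c(FALSE, FALSE, TRUE, TRUE),
                      amplitude_pa = c(0, 0, 100, 300))
  st <- region_response_stats(cells)
  expect_equal(st$mean_amplitude_all, 100)
  expect_equal(st$mean_amplitude_responders, 200)
  # identity: mean_all = fraction x mean_responders
  expect_equal(st$mean_amplitude_all, st$fraction * st$mean_amplitude_responders)

  none <- data.frame(region_id = "y", responded = FALSE, amplitude_pa = 0)
  st0 <- region_response_stats(none)
  expect_equal(st0$fraction, 0)
  expect_true(is.na(st0$mean_amplitude_responders))

  bad <- data.frame(region_id = "z", responded = FALSE, amplitude_pa = 3)
  expect_error(region_response_stats(bad), "amplitude 0")
})

test_that("pooled fraction equals the count-weighted mean of section fractions", {
  cells <- lc_fixture()
  per_sec <- region_response_stats(cells, "section_id")
  pooled <- region_response_stats(cells, NULL)
  expect_equal(pooled$fraction,
               sum(per_sec$fraction * per_sec$n) / sum(per_sec$n))
})

test_that("local density is a voxel lookup with half-open edges", {
  P <- cbind(rep(72, 12), rep(72, 12), rep(1, 12))   # 12 points in bin (1,1,1)
  grid <- bin_to_grid(P, extent_um = c(432, 432, 4))
  cells <- data.frame(x_um = c(72, 144, 300, 500), y_um = c(72, 10, 10, 10),
                      z_um = 1)
  expect_message(d <- local_density(cells, grid), "outside")
  expect_equal(d[1], 12 / (144 * 144))
  expect_equal(d[2], 0)          # x = 144 belongs to the second bin
  expect_equal(d[3], 0)
  expect_true(is.na(d[4]))       # outside the grid

  # bulk lookup agrees with direct indexing
  set.seed(3)
  cells2 <- data.frame(x_um = runif(200, 0, 432), y_um = runif(200, 0, 432),
                       z_um = runif(200, 0, 4))
  d2 <- local_density(cells2, grid)
  ix <- floor(cells2$x_um / 144) + 1
  iy <- floor(cells2$y_um / 144) + 1
  expect_equal(d2, grid$density[cbind(ix, iy, 1)])
})

test_that("probability-vs-density curve: trivial and consistency cases", {
  cells <- data.frame(responded = rep(TRUE, 40))
  dens <- runif(40, 0, 0.01)
  cv <- probability_vs_density(cells, dens, bin_edges = c(0, 0.005, 0.01))
  expect_true(all(cv$probability == 1))
  expect_true(all(cv$ci_upper > 1 - 1e-9))

  # a single bin reduces to the pooled fraction
  cells2 <- data.frame(responded = c(rep(TRUE, 3), rep(FALSE, 7)),
                       amplitude_pa = c(rep(40, 3), rep(0, 7)),
                       region_id = "r")
  cv2 <- probability_vs_density(cells2, rep(0.002, 10),
                                bin_edges = c(0, 0.01))
  expect_equal(cv2$probability, region_response_stats(cells2)$fraction)
  expect_equal(cv2$n_cells, 10L)
})

test_that("Wilson CIs cover a generating logistic link", {
  # gradient grid so local densities span 0 .. ~0.02 boutons/um^2
  nx <- 10
  counts <- array(0L, c(nx, 10, 1))
  for (i in seq_len(nx)) counts[i, , 1] <- as.integer((i - 1) * 46)
  grid <- boutonmap:::new_voxel_grid(c(0, 0, 0), c(144, 144, 4), counts, 1L)
  dmax <- max(grid$density)
  beta0 <- -2
  beta1 <- (log(0.8 / 0.2) - beta0) / dmax   # top-of-range p = 0.8
  cells <- generate_ephys_cells(grid, ephys_link_params(
    beta0 = beta0, beta1 = beta1, n_cells = 2000, seed = 42))
  dens <- local_density(cells, grid)
  cv <- probability_vs_density(cells, dens)
  truep <- stats::plogis(beta0 + beta1 * cv$mean_density)
  covered <- sum(truep >= cv$ci_lower & truep <= cv$ci_upper)
  expect_gte(covered, 4)
  expect_equal(nrow(cv), 5L)
})

test_that("rank-sum test matches enumeration and handles ties", {
  x <- c(6, 7, 8, 9, 10); y <- c(1, 2, 3, 4, 5)
  r1 <- compare_density_distributions(x, y, method = "permutation")
  expect_equal(r1$U, 25)
  expect_equal(r1$U, u_stat_oracle(x, y))
  expect_equal(r1$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  r2 <- compare_density_distributions(x, y, method = "normal")
  expect_equal(r2$U, 25)
  expect_lt(r2$p_value, 0.01)

  # identical multisets: tie-corrected variance vanishes -> p = 1
  z <- rep(2, 6)
  expect_equal(compare_density_distributions(z, z)$p_value, 1)

  # U agrees with the brute-force oracle on tied data
  set.seed(6)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(2:6, 25, replace = TRUE)
  expect_equal(compare_density_distributions(a, b)$U, u_stat_oracle(a, b))
  expect_error(compare_density_distributions(numeric(), 1:3), "non-empty")
})

test_that("rank-sum test has power against a 1-SD shift", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(2000 + s)
    x <- rnorm(100, 1, 1)
    y <- rnorm(100, 0, 1)
    if (compare_density_distributions(x, y)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})
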