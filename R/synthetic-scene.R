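#' Configuration of a synthetic two-channel bouton scene
#'
#' Describes a synthetic confocal field: rectangular anatomical regions,
#' each with its own GABAergic (vGAT) bouton density and PC-positive
#' fraction; log-normal per-bouton intensities with well-separated reporter
#' signal and noise modes; a smooth illumination field; dim reporter axon
#' clutter; and Poisson + Gaussian camera noise. The defaults emulate a
#' 512 x 512 x 5 voxel stack (~185 x 185 x 1.5 um at 0.3611 um XY pixels and
#' 0.3 um z steps) with three regions spanning the dense / intermediate /
#' sparse density regimes seen across brainstem regions (~0.002-0.02
#' boutons/um^2, PC fractions 0.05-0.7).
#'
#' @param shape_voxels `(nx, ny, nz)` image size in voxels.
#' @param voxel_size_um `(x, y, z)` voxel size in um.
#' @param region_layout data.frame with columns `region_id`, `name`,
#'   `x0_um`, `y0_um`, `width_um`, `height_um`; rectangles must lie inside
#'   the field and not overlap.
#' @param vgat_density_per_region boutons/um^2 per layout row, `>= 0`.
#' @param pc_fraction_per_region PC-positive fraction per layout row, in
#'   `[0, 1]`.
#' @param bouton_fwhm_um rendered spot full width at half maximum (um).
#' @param vgat_intensity_dist `(meanlog, sdlog)` of per-bouton vGAT peak
#'   amplitudes (a.u.).
#' @param tdt_signal_dist,tdt_noise_dist `(meanlog, sdlog)` of reporter peak
#'   amplitudes for PC and non-PC boutons; the signal-mode median must
#'   exceed the noise-mode median.
#' @param illumination_amplitude mean level of the smooth channel-0
#'   illumination field (a.u.).
#' @param illumination_scale_um correlation length of the illumination field.
#' @param axon_clutter_density density (per um^2) of dim reporter-channel
#'   clutter spots, drawn from `tdt_noise_dist`.
#' @param noise `(poisson_gain, read_sd)`: intensities are Poisson-sampled
#'   as `rpois(signal / gain) * gain` then read noise of SD `read_sd` a.u.
#'   is added.
#' @param seed RNG seed; identical configs render bit-identical scenes.
#' @return A validated `scene_config`.
#' @export
scene_config <- function(shape_voxels = c(512, 512, 5),
                         voxel_size_um = c(0.3611, 0.3611, 0.3),
                         region_layout = NULL,
                         vgat_density_per_region = c(0.02, 0.01, 0.002),
                         pc_fraction_per_region = c(0.7, 0.25, 0.05),
                         bouton_fwhm_um = 1.0,
                         vgat_intensity_dist = c(meanlog = log(300), sdlog = 0.3),
                         tdt_signal_dist = c(meanlog = log(100), sdlog = 0.35),
                         tdt_noise_dist = c(meanlog = log(10), sdlog = 0.4),
                         illumination_amplitude = 30,
                         illumination_scale_um = 50,
                         axon_clutter_density = 0.005,
                         noise = c(poisson_gain = 0.5, read_sd = 1.5),
                         seed = 0L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 1L)) {
    stopf("'shape_voxels' must be three positive integers (nx, ny, nz)")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    stopf("'voxel_size_um' must be three positive numbers")
  }
  field_um <- shape_voxels * voxel_size_um
  if (is.null(region_layout)) {
    m <- 4; gap <- 4                       # um margins between default bands
    wband <- (field_um[1] - 2 * m - 2 * gap) / 3
    region_layout <- data.frame(
      region_id = 1:3,
      name = c("dense", "intermediate", "sparse"),
      x0_um = m + (0:2) * (wband + gap),
      y0_um = m,
      width_um = wband,
      height_um = field_um[2] - 2 * m,
      stringsAsFactors = FALSE)
  }
  need <- c("region_id", "x0_um", "y0_um", "width_um", "height_um")
  if (!all(need %in% names(region_layout))) {
    stopf("region_layout needs columns %s", paste(need, collapse = ", "))
  }
  if (is.null(region_layout$name)) {
    region_layout$name <- as.character(region_layout$region_id)
  }
  nr <- nrow(region_layout)
  if (length(vgat_density_per_region) != nr ||
      length(pc_fraction_per_region) != nr) {
    stopf("densities and fractions must have one value per layout row")
  }
  if (!all(is.finite(vgat_density_per_region)) ||
      any(vgat_density_per_region < 0)) {
    stopf("vgat densities must be finite and >= 0")
  }
  if (!all(is.finite(pc_fraction_per_region)) ||
      any(pc_fraction_per_region < 0 | pc_fraction_per_region > 1)) {
    stopf("pc fractions must lie in [0, 1]")
  }
  check_scalar_num(bouton_fwhm_um, "bouton_fwhm_um", lower = 0,
                   strict_lower = TRUE)
  if (exp(tdt_signal_dist[[1]]) <= exp(tdt_noise_dist[[1]])) {
    stopf("tdt signal-mode median must exceed the noise-mode median")
  }
  structure(list(shape_voxels = shape_voxels, voxel_size_um = voxel_size_um,
                 region_layout = region_layout,
                 vgat_density_per_region = as.numeric(vgat_density_per_region),
                 pc_fraction_per_region = as.numeric(pc_fraction_per_region),
                 bouton_fwhm_um = bouton_fwhm_um,
                 vgat_intensity_dist = vgat_intensity_dist,
                 tdt_signal_dist = tdt_signal_dist,
                 tdt_noise_dist = tdt_noise_dist,
                 illumination_amplitude = illumination_amplitude,
                 illumination_scale_um = illumination_scale_um,
                 axon_clutter_density = axon_clutter_density,
                 noise = noise, seed = as.integer(seed)),
            class = "scene_config")
}

#' Rasterize a rectangle layout into a region label map
#'
#' A pixel belongs to a rectangle when its center does; uncovered pixels
#' keep the background label 0. Overlapping rectangles are an error naming
#' the offending region ids.
#'
#' @param layout rectangle table as in [scene_config()].
#' @param shape_voxels `(nx, ny)` (a third entry is ignored).
#' @param voxel_size_um `(x, y)` pixel size in um.
#' @return A [region_map()].
#' @export
generate_region_map <- function(layout, shape_voxels, voxel_size_um) {
  nx <- shape_voxels[1]; ny <- shape_voxels[2]
  vx <- voxel_size_um[1]; vy <- voxel_size_um[2]
  if (anyDuplicated(layout$region_id)) stopf("region ids must be unique")
  if (nrow(layout) && any(layout$region_id <= 0)) stopf("region ids must be > 0")
  labels <- matrix(0L, nrow = ny, ncol = nx)
  for (r in seq_len(nrow(layout))) {
    x0 <- layout$x0_um[r]; y0 <- layout$y0_um[r]
    x1 <- x0 + layout$width_um[r]; y1 <- y0 + layout$height_um[r]
    if (x0 < 0 || y0 < 0 || x1 > nx * vx + 1e-9 || y1 > ny * vy + 1e-9) {
      stopf("rectangle for region %d exceeds the field bounds",
            layout$region_id[r])
    }
    jj <- which((seq_len(nx) - 0.5) * vx >= x0 & (seq_len(nx) - 0.5) * vx < x1)
    ii <- which((seq_len(ny) - 0.5) * vy >= y0 & (seq_len(ny) - 0.5) * vy < y1)
    if (length(ii) && length(jj)) {
      prev <- labels[ii, jj]
      hit <- prev[prev != 0L]
      if (length(hit)) {
        stopf("regions %d and %d overlap", hit[1], layout$region_id[r])
      }
      labels[ii, jj] <- as.integer(layout$region_id[r])
    }
  }
  region_map(labels, c(vx, vy),
             id_to_name = data.frame(region_id = as.integer(layout$region_id),
                                     name = as.character(layout$name),
                                     stringsAsFactors = FALSE))
}

#' Render a synthetic two-channel scene with ground truth
#'
#' Channel `vGAT` is a smooth illumination field plus an anisotropic
#' Gaussian spot (FWHM `bouton_fwhm_um`, in physical um) for every bouton,
#' at Poisson-sampled per-region counts, plus camera noise. Channel `tdt`
#' carries bright reporter spots at PC boutons (peaks from
#' `tdt_signal_dist`), dim spots at non-PC boutons (`tdt_noise_dist`), dim
#' axon clutter, and the same noise model. The returned ground truth lists
#' every bouton's true centroid, region and PC label, with per-region count
#' summaries. Identical config + seed reproduce the scene bit for bit.
#'
#' @param config a [scene_config()].
#' @return list with `stack` ([image_stack()], channels `vGAT`, `tdt`),
#'   `truth` (list: `boutons` data.frame, `per_region` data.frame) and
#'   `region_map`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  shp <- config$shape_voxels; vs <- config$voxel_size_um
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  field_um <- shp * vs
  lay <- config$region_layout
  areas <- lay$width_um * lay$height_um
  expected <- sum(areas * config$vgat_density_per_region)
  if (expected > 1e6) {
    stopf("expected bouton count %.3g exceeds the desk-scale guard (1e6)",
          expected)
  }
  with_seed(config$seed, {
    # --- ground-truth boutons ------------------------------------------
    parts <- lapply(seq_len(nrow(lay)), function(r) {
      n <- rpois(1, areas[r] * config$vgat_density_per_region[r])
      if (n == 0L) return(NULL)
      data.frame(
        x_um = runif(n, lay$x0_um[r], lay$x0_um[r] + lay$width_um[r]),
        y_um = runif(n, lay$y0_um[r], lay$y0_um[r] + lay$height_um[r]),
        z_um = runif(n, 0, field_um[3]),
        region_id = as.integer(lay$region_id[r]),
        is_pc = runif(n) < config$pc_fraction_per_region[r])
    })
    parts <- Filter(Negate(is.null), parts)
    if (length(parts)) {
      boutons <- do.call(rbind, parts)
      rownames(boutons) <- NULL
    } else {
      boutons <- data.frame(x_um = numeric(), y_um = numeric(),
                            z_um = numeric(), region_id = integer(),
                            is_pc = logical())
    }
    n_b <- nrow(boutons)
    boutons$id <- seq_len(n_b)
    boutons$vgat_peak <- rlnorm(n_b, config$vgat_intensity_dist[[1]],
                                config$vgat_intensity_dist[[2]])
    boutons$tdt_peak <- ifelse(
      boutons$is_pc,
      rlnorm(n_b, config$tdt_signal_dist[[1]], config$tdt_signal_dist[[2]]),
      rlnorm(n_b, config$tdt_noise_dist[[1]], config$tdt_noise_dist[[2]]))
    boutons <- boutons[c("id", "x_um", "y_um", "z_um", "region_id", "is_pc",
                         "vgat_peak", "tdt_peak")]

    # --- deterministic rendering ---------------------------------------
    sigma_um <- rep(config$bouton_fwhm_um / (2 * sqrt(2 * log(2))), 3)
    ctr <- cbind(boutons$x_um, boutons$y_um, boutons$z_um)
    ch_vgat <- add_spots(array(0, c(ny, nx, nz)), ctr, boutons$vgat_peak,
                         sigma_um, vs)
    ch_tdt <- add_spots(array(0, c(ny, nx, nz)), ctr, boutons$tdt_peak,
                        sigma_um, vs)

    # smooth illumination on channel 0
    illum <- illumination_field(nx, ny, vs, config$illumination_scale_um,
                                config$illumination_amplitude)
    for (k in seq_len(nz)) ch_vgat[, , k] <- ch_vgat[, , k] + illum

    # dim reporter axon clutter
    n_cl <- rpois(1, config$axon_clutter_density * field_um[1] * field_um[2])
    if (n_cl > 0) {
      cl <- data.frame(x = runif(n_cl, 0, field_um[1]),
                       y = runif(n_cl, 0, field_um[2]),
                       z = runif(n_cl, 0, field_um[3]),
                       a = rlnorm(n_cl, config$tdt_noise_dist[[1]],
                                  config$tdt_noise_dist[[2]]))
      ch_tdt <- add_spots(ch_tdt, cbind(cl$x, cl$y, cl$z), cl$a, sigma_um,
                          vs)
    }

    # camera noise: Poisson on (signal / gain), then Gaussian read noise
    gain <- config$noise[[1]]; read_sd <- config$noise[[2]]
    apply_noise <- function(ch) {
      lam <- pmax(ch, 0) / gain
      out <- rpois(length(lam), lam) * gain +
        rnorm(length(lam), 0, read_sd)
      out[out < 0] <- 0
      array(out, dim(ch))
    }
    ch_vgat <- apply_noise(ch_vgat)
    ch_tdt <- apply_noise(ch_tdt)

    per_region <- data.frame(
      region_id = as.integer(lay$region_id),
      n_vgat = vapply(lay$region_id, function(id) {
        sum(boutons$region_id == id)
      }, integer(1)),
      n_pc = vapply(lay$region_id, function(id) {
        sum(boutons$is_pc & boutons$region_id == id)
      }, integer(1)))

    list(stack = image_stack(list(vGAT = ch_vgat, tdt = ch_tdt), vs),
         truth = list(boutons = boutons, per_region = per_region),
         region_map = generate_region_map(lay, shp, vs))
  })
}

# Add anisotropic Gaussian spots (peak amplitudes, per-axis sigma in um)
# centered at physical coordinates, evaluated at voxel centers within
# +/- 3.5 sigma.
add_spots <- function(arr, centers_um, peaks, sigma_um, voxel_size_um) {
  if (!nrow(centers_um)) return(arr)
  array(.cpp_add_spots(as.numeric(arr), as.integer(dim(arr)),
                       as.matrix(centers_um), as.numeric(peaks),
                       as.numeric(sigma_um), as.numeric(voxel_size_um)),
        dim(arr))
}

# Smooth illumination field: standard-normal values on a coarse grid with
# node spacing `scale_um`, bilinearly interpolated, scaled to
# amplitude * (1 + 0.3 * field) and floored at 10% of the amplitude.
illumination_field <- function(nx, ny, voxel_size_um, scale_um, amplitude) {
  ngx <- max(2L, ceiling(nx * voxel_size_um[1] / scale_um) + 2L)
  ngy <- max(2L, ceiling(ny * voxel_size_um[2] / scale_um) + 2L)
  coarse <- matrix(rnorm(ngy * ngx), nrow = ngy, ncol = ngx)
  gx <- ((seq_len(nx) - 0.5) * voxel_size_um[1]) / scale_um
  gy <- ((seq_len(ny) - 0.5) * voxel_size_um[2]) / scale_um
  vals <- bilinear_at(coarse,
                      gx = rep(gx, each = ny),
                      gy = rep(gy, times = nx))
  f <- amplitude * (1 + 0.3 * matrix(vals, nrow = ny, ncol = nx))
  pmax(f, 0.1 * amplitude)
}

#' Parameters linking bouton density to evoked-IPSC probability
#'
#' Logistic link: `P(responded) = plogis(beta0 + beta1 * density)` with the
#' local density in boutons/um^2 of the voxel containing the cell.
#' Responder amplitudes are log-normal in pA (default median 50 pA, the
#' scale of small evoked PC-IPSCs); nonresponders have amplitude exactly 0.
#'
#' @param beta0 logit intercept.
#' @param beta1 logit slope per (boutons/um^2).
#' @param amplitude_dist `(meanlog, sdlog)` of responder amplitudes (pA).
#' @param n_cells number of cells to simulate, `> 0`.
#' @param seed RNG seed.
#' @return A validated `ephys_link_params`.
#' @export
ephys_link_params <- function(beta0 = -2, beta1 = 200,
                              amplitude_dist = c(meanlog = log(50), sdlog = 0.8),
                              n_cells = 200L, seed = 0L) {
  check_scalar_num(beta0, "beta0")
  check_scalar_num(beta1, "beta1")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells <= 0L) stopf("'n_cells' must be > 0")
  structure(list(beta0 = beta0, beta1 = beta1,
                 amplitude_dist = amplitude_dist,
                 n_cells = n_cells, seed = as.integer(seed)),
            class = "ephys_link_params")
}

#' Simulate recorded cells whose response probability follows local density
#'
#' Cells are placed uniformly over the grid extent; each cell responds with
#' probability `plogis(beta0 + beta1 * d)` where `d` is the density of the
#' voxel containing it, and responders draw a log-normal IPSC amplitude.
#'
#' @param density_field a `voxel_grid` (e.g. from [bin_to_grid()] or
#'   [average_grids()]); densities must be non-negative.
#' @param params an [ephys_link_params()].
#' @return data.frame: `cell_id`, `section_id`, `x_um`, `y_um`, `z_um`,
#'   `region_id` (`NA`), `responded`, `amplitude_pa`.
#' @export
generate_ephys_cells <- function(density_field, params) {
  stopifnot(inherits(params, "ephys_link_params"))
  if (any(density_field$density < 0)) stopf("density field must be non-negative")
  d <- dim(density_field$counts)
  o <- density_field$origin_um; w <- density_field$bin_size_um
  with_seed(params$seed, {
    n <- params$n_cells
    cells <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n)),
      section_id = "s1",
      x_um = runif(n, o[1], o[1] + d[1] * w[1]),
      y_um = runif(n, o[2], o[2] + d[2] * w[2]),
      z_um = runif(n, o[3], o[3] + d[3] * w[3]),
      region_id = NA_integer_,
      stringsAsFactors = FALSE)
    dens <- local_density(cells, density_field)
    p <- plogis(params$beta0 + params$beta1 * dens)
    cells$responded <- runif(n) < p
    amp <- rlnorm(n, params$amplitude_dist[[1]], params$amplitude_dist[[2]])
    cells$amplitude_pa <- ifelse(cells$responded, amp, 0)
    cells
  })
}

#' Generate noisy landmark pairs under a known transform
#'
#' Fixed (atlas) points are drawn uniformly in `bounds_um`; moving points
#' are `T^{-1}(fixed)` plus isotropic Gaussian noise, so that refitting with
#' [fit_transform()] should recover `true_transform`.
#'
#' @param true_transform a `transform2d`.
#' @param n_pairs number of landmark pairs, `>= 3`.
#' @param noise_sd_um per-coordinate Gaussian noise SD (um).
#' @param bounds_um `(xmin, xmax, ymin, ymax)` for the fixed points.
#' @param seed RNG seed.
#' @return data.frame with `fixed_x_um`, `fixed_y_um`, `moving_x_um`,
#'   `moving_y_um`.
#' @export
perturb_landmarks <- function(true_transform, n_pairs, noise_sd_um,
                              bounds_um = c(0, 5000, 0, 5000), seed = 0L) {
  if (n_pairs < 3L) stopf("'n_pairs' must be >= 3")
  with_seed(seed, {
    fx <- runif(n_pairs, bounds_um[1], bounds_um[2])
    fy <- runif(n_pairs, bounds_um[3], bounds_um[4])
    Minv <- apply_transform(invert_transform(true_transform), cbind(fx, fy))
    data.frame(fixed_x_um = fx, fixed_y_um = fy,
               moving_x_um = Minv[, 1] + rnorm(n_pairs, 0, noise_sd_um),
               moving_y_um = Minv[, 2] + rnorm(n_pairs, 0, noise_sd_um))
  })
}
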