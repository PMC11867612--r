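#' Pipeline parameters
#'
#' Flat, validated container for every numeric procedure constant of the
#' anatomy pipeline: background-kernel FWHM (50 um), threshold rule
#' (median + k x SD over three 50-px reference squares), bouton diameter
#' (1 um, used as the seed separation), colocalization radius (0.7 um),
#' density-map bin size (144 x 144 x 4 um^3), registration QC grid spacing
#' (350 um) and the acquisition geometry (0.3611 um XY pixels, 0.3 um z
#' steps, 1.5 um stacks). Unknown keys in a config file are errors — silent
#' default drift is the main reproducibility hazard.
#'
#' @param background_diameter_um Gaussian background FWHM (um).
#' @param threshold_k SD multiplier of the intensity threshold.
#' @param roi_side_px side of the threshold reference squares (px).
#' @param n_rois number of default reference squares.
#' @param bouton_diameter_um nominal bouton diameter (um); sets both the
#'   seed separation and, via `bouton_smooth_sigma_um`, the matched-filter
#'   scale of punctum isolation.
#' @param bouton_smooth_sigma_um Gaussian sigma (um) of the bouton-scale
#'   matched filter applied to the corrected vGAT channel before
#'   thresholding, seeding and watershed; default `bouton_diameter_um / 4`.
#'   Set to 0 to threshold the unsmoothed corrected channel (the
#'   seed-distance-only interpretation of the bouton-diameter parameter).
#' @param tdt_min_separation_um reporter regional-maximum separation (um).
#' @param tdt_smooth_sigma_um reporter pre-smoothing sigma (um).
#' @param match_radius_um colocalization center-to-center radius (um).
#' @param min_object_voxels watershed object size floor (voxels).
#' @param bin_size_um density-map voxel `(x, y, z)` (um).
#' @param qc_grid_spacing_um displacement-QC grid spacing (um).
#' @param voxel_size_um acquisition voxel size `(x, y, z)` (um).
#' @param stack_depth_um nominal stack depth (um).
#' @param seed RNG seed for stages that draw (the anatomy run itself is
#'   deterministic).
#' @return A validated `pipeline_params` list.
#' @export
pipeline_params <- function(background_diameter_um = 50,
                            threshold_k = 1,
                            roi_side_px = 50,
                            n_rois = 3,
                            bouton_diameter_um = 1.0,
                            bouton_smooth_sigma_um = bouton_diameter_um / 4,
                            tdt_min_separation_um = 0.5,
                            tdt_smooth_sigma_um = 0.25,
                            match_radius_um = 0.7,
                            min_object_voxels = 2,
                            bin_size_um = c(144, 144, 4),
                            qc_grid_spacing_um = 350,
                            voxel_size_um = c(0.3611, 0.3611, 0.3),
                            stack_depth_um = 1.5,
                            seed = 0L) {
  check_scalar_num(background_diameter_um, "background_diameter_um",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(threshold_k, "threshold_k")
  check_scalar_num(roi_side_px, "roi_side_px", lower = 1)
  check_scalar_num(bouton_diameter_um, "bouton_diameter_um", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(bouton_smooth_sigma_um, "bouton_smooth_sigma_um", lower = 0)
  check_scalar_num(match_radius_um, "match_radius_um", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(qc_grid_spacing_um, "qc_grid_spacing_um", lower = 0,
                   strict_lower = TRUE)
  bin_size_um <- as.numeric(bin_size_um)
  if (length(bin_size_um) != 3L || any(bin_size_um <= 0)) {
    stopf("'bin_size_um' must be three positive numbers")
  }
  if (match_radius_um >= min(bin_size_um)) {
    stopf("'match_radius_um' must be smaller than every bin dimension")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    stopf("'voxel_size_um' must be three positive numbers")
  }
  check_scalar_num(stack_depth_um, "stack_depth_um", lower = 0,
                   strict_lower = TRUE)
  structure(list(background_diameter_um = background_diameter_um,
                 threshold_k = threshold_k, roi_side_px = roi_side_px,
                 n_rois = n_rois, bouton_diameter_um = bouton_diameter_um,
                 bouton_smooth_sigma_um = bouton_smooth_sigma_um,
                 tdt_min_separation_um = tdt_min_separation_um,
                 tdt_smooth_sigma_um = tdt_smooth_sigma_um,
                 match_radius_um = match_radius_um,
                 min_object_voxels = min_object_voxels,
                 bin_size_um = bin_size_um,
                 qc_grid_spacing_um = qc_grid_spacing_um,
                 voxel_size_um = voxel_size_um,
                 stack_depth_um = stack_depth_um,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

#' Load pipeline parameters from a flat JSON config file
#'
#' Keys must match [pipeline_params()] arguments exactly; unknown keys are
#' an error.
#'
#' @param path JSON file of key-value pairs.
#' @return A `pipeline_params`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(pipeline_params)), "...")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  }
  do.call(pipeline_params, cfg)
}

#' Run the anatomy pipeline on one section
#'
#' End-to-end quantification of one two-channel stack: per-channel
#' background correction, ROI-based intensity threshold, watershed bouton
#' isolation on the vGAT channel, reporter regional-maximum colocalization,
#' bimodal valley classification, atlas registration (from landmarks when
#' supplied, identity otherwise) with displacement QC, region assignment,
#' per-region summaries and the coarse density grid of PC boutons. The run
#' is deterministic for a given config and inputs; per-stage counts are
#' collected in the returned log.
#'
#' @param stack an [image_stack()] with channels `vGAT` and `tdt`.
#' @param map a [region_map()] in atlas coordinates.
#' @param params a [pipeline_params()].
#' @param landmarks optional data.frame (`fixed_x_um`, `fixed_y_um`,
#'   `moving_x_um`, `moving_y_um`) used to fit the section-to-atlas
#'   transform; `NULL` means the section is already in atlas coordinates.
#' @param section_id label for output rows.
#' @param out_dir optional directory; when given, writes `boutons_<id>.csv`,
#'   `region_summary_<id>.csv`, `pc_grid_<id>.tif` (+ JSON geometry
#'   sidecar), `threshold_<id>.json`, `valley_<id>.json`,
#'   `registration_qc_<id>.json` and `run_log_<id>.json`.
#' @return list: `boutons` (`bouton_set`), `summary`, `grid`,
#'   `threshold_report`, `valley_report`, `transform`, `qc`, `log`.
#' @export
run_anatomy <- function(stack, map, params = pipeline_params(),
                        landmarks = NULL, section_id = "s1",
                        out_dir = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  if (!inherits(stack, "image_stack")) stopf("'stack' must be an image_stack")
  for (ch in c("vGAT", "tdt")) {
    if (!ch %in% names(stack$channels)) stopf("missing channel '%s'", ch)
  }
  if (!inherits(map, "region_map")) stopf("'map' must be a region_map")
  vs <- stack$voxel_size_um

  bg_v <- estimate_background(stack$channels$vGAT, vs,
                              params$background_diameter_um)
  corr_v <- subtract_background(stack$channels$vGAT, bg_v)
  # matched filter at the bouton scale: stabilizes the ROI threshold and
  # suppresses single-voxel noise before seeding and watershed
  corr_v <- smooth_3d(corr_v, vs, params$bouton_smooth_sigma_um)
  bg_t <- estimate_background(stack$channels$tdt, vs,
                              params$background_diameter_um)
  corr_t <- subtract_background(stack$channels$tdt, bg_t)

  thr <- compute_intensity_threshold(corr_v, vs, rois = NULL,
                                     k = params$threshold_k,
                                     roi_side_px = params$roi_side_px)
  seeds <- find_seed_maxima(corr_v, vs, thr$threshold,
                            min_separation_um = params$bouton_diameter_um)
  boutons <- segment_boutons(corr_v, vs, seeds, thr$threshold,
                             min_voxels = params$min_object_voxels,
                             section_id = section_id)
  maxima <- detect_tdt_maxima(corr_t, vs,
                              min_separation_um = params$tdt_min_separation_um,
                              smooth_sigma_um = params$tdt_smooth_sigma_um)
  boutons <- assign_tdt_intensity(boutons, maxima, corr_t,
                                  max_center_distance_um = params$match_radius_um)
  valley <- find_bimodal_threshold(boutons$table$tdt_intensity)
  boutons <- classify_pc(boutons, valley)

  if (!is.null(landmarks)) {
    transform <- fit_transform(landmarks[, c("fixed_x_um", "fixed_y_um")],
                               landmarks[, c("moving_x_um", "moving_y_um")])
  } else {
    transform <- identity_transform()
  }
  atlas_xy <- apply_transform(transform,
                              cbind(boutons$table$x_um, boutons$table$y_um))
  boutons$table$region_id <- assign_regions(
    cbind(boutons$table$x_um, boutons$table$y_um), map, transform)
  boutons$table$x_atlas_um <- atlas_xy[, 1]
  boutons$table$y_atlas_um <- atlas_xy[, 2]

  bounds <- c(0, ncol(map$labels) * map$pixel_size_um[1],
              0, nrow(map$labels) * map$pixel_size_um[2])
  qc <- displacement_qc(transform, bounds, params$qc_grid_spacing_um)

  summary <- summarize_regions(boutons$table, map)
  pc <- boutons$table[boutons$table$is_pc, , drop = FALSE]
  in_atlas <- pc$x_atlas_um >= 0 & pc$x_atlas_um < bounds[2] &
    pc$y_atlas_um >= 0 & pc$y_atlas_um < bounds[4]
  n_pc_outside <- sum(!in_atlas)
  if (n_pc_outside > 0) {
    message(sprintf("run_anatomy: %d PC bouton(s) map outside the atlas",
                    n_pc_outside))
  }
  pc <- pc[in_atlas, , drop = FALSE]
  grid <- bin_to_grid(cbind(pc$x_atlas_um, pc$y_atlas_um, pc$z_um),
                      bin_size_um = params$bin_size_um,
                      extent_um = c(bounds[2], bounds[4],
                                    max(params$stack_depth_um,
                                        params$bin_size_um[3])))

  log <- list(section_id = section_id, params = unclass(params),
              n_seeds = nrow(seeds), n_boutons = nrow(boutons$table),
              n_matched = sum(boutons$table$tdt_matched),
              n_pc_outside_atlas = n_pc_outside,
              n_pc = sum(boutons$table$is_pc),
              threshold = thr$threshold, valley = valley$valley,
              valley_fallback = valley$fallback_used,
              registration_rms_um = transform$rms_residual_um,
              qc_mean_um = qc$mean_um)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(stem, ext) file.path(out_dir,
                                        sprintf("%s_%s.%s", stem, section_id, ext))
    write.csv(boutons$table, fp("boutons", "csv"), row.names = FALSE)
    write.csv(summary, fp("region_summary", "csv"), row.names = FALSE)
    write_tiff(lapply(seq_len(dim(grid$counts)[3]), function(k) {
      t(grid$counts[, , k])      # pages as [y = iy, x = ix]
    }), fp("pc_grid", "tif"), format = "float32")
    write_json_file(list(origin_um = grid$origin_um,
                         bin_size_um = grid$bin_size_um,
                         n_sections_averaged = grid$n_sections_averaged),
                    fp("pc_grid_geometry", "json"))
    write_json_file(list(pooled_median = thr$pooled_median,
                         pooled_sd = thr$pooled_sd, k = thr$k,
                         threshold = thr$threshold,
                         roi_specs = thr$roi_specs), fp("threshold", "json"))
    write_json_file(unclass(valley), fp("valley", "json"))
    write_json_file(list(n_points = qc$n_points,
                         grid_spacing_um = qc$grid_spacing_um,
                         mean_um = qc$mean_um, sd_um = qc$sd_um,
                         displacements_um = qc$displacements_um),
                    fp("registration_qc", "json"))
    write_json_file(log, fp("run_log", "json"))
  }

  list(boutons = boutons, summary = summary, grid = grid,
       threshold_report = thr, valley_report = valley,
       transform = transform, qc = qc, log = log)
}

#' Run the electrophysiology linkage analysis
#'
#' Validates the cell table schema, summarizes responses per region and per
#' section, looks up each cell's local bouton density on the averaged grid,
#' builds the probability-vs-density curve and compares the density
#' distributions of responding vs nonresponding cells.
#'
#' @param cells data.frame with columns `cell_id`, `section_id`, `x_um`,
#'   `y_um`, `region_id`, `responded` (logical), `amplitude_pa` (0 for
#'   nonresponders). Extra columns pass through.
#' @param grid a `voxel_grid` of averaged PC-bouton counts, or `NULL` to
#'   skip the density analyses.
#' @param params a [pipeline_params()] (seed only; the analysis itself is
#'   deterministic).
#' @param out_dir optional output directory (`ephys_region_summary.csv`,
#'   `density_curve.json`, `ephys_run_log.json`).
#' @return list: `region_stats`, `section_stats`, `densities`, `curve`,
#'   `comparison`, `log`.
#' @export
run_ephys <- function(cells, grid = NULL, params = pipeline_params(),
                      out_dir = NULL) {
  required <- c("cell_id", "section_id", "x_um", "y_um", "region_id",
                "responded", "amplitude_pa")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stopf("cell table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!nrow(cells)) stopf("cell table is empty")
  if (!is.logical(cells$responded)) stopf("column 'responded' must be logical")
  if (!is.numeric(cells$amplitude_pa) || any(cells$amplitude_pa < 0)) {
    stopf("column 'amplitude_pa' must be numeric and >= 0")
  }
  if (any(cells$amplitude_pa[!cells$responded] != 0)) {
    stopf("column 'amplitude_pa' must be 0 for nonresponding cells")
  }

  region_stats <- region_response_stats(cells, "region_id")
  section_stats <- region_response_stats(cells, "section_id")

  densities <- curve <- comparison <- NULL
  if (!is.null(grid)) {
    densities <- local_density(cells, grid)
    curve <- probability_vs_density(cells, densities)
    ok <- !is.na(densities)
    dr <- densities[ok & cells$responded]
    dn <- densities[ok & !cells$responded]
    if (length(dr) && length(dn)) {
      comparison <- compare_density_distributions(dr, dn)
    }
  }

  log <- list(n_cells = nrow(cells), n_responding = sum(cells$responded),
              fraction = mean(cells$responded),
              mean_amplitude_all = mean(cells$amplitude_pa),
              test = if (!is.null(comparison)) comparison$method else NA,
              p_value = if (!is.null(comparison)) comparison$p_value else NA)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(region_stats, file.path(out_dir, "ephys_region_summary.csv"),
              row.names = FALSE)
    if (!is.null(curve)) {
      write_json_file(as.data.frame(curve),
                      file.path(out_dir, "density_curve.json"))
    }
    write_json_file(log, file.path(out_dir, "ephys_run_log.json"))
  }

  list(region_stats = region_stats, section_stats = section_stats,
       densities = densities, curve = curve, comparison = comparison,
       log = log)
}
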