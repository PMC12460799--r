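# End-to-end pipeline: simulation -> AO -> calibration -> multi-plane
# acquisition with feedback drift correction -> localization ->
# reconstruction -> metrics.

#' Synthetic cell scene for the demo pipeline
#'
#' Builds a scaled-down acquisition scene: docking sites on a spherical
#' shell (a membrane-like structure) spanning the planned volume, plus
#' fiducial beads at fixed positions outside a central well region so that
#' adjacent planes share beads for tracking and registration.
#'
#' @param config [default_config()]-style configuration.
#' @return List with `molecules`, `fiducials` (emitter data.frames with
#'   absolute `z_um`), `well_box_nm`, and scene geometry.
#' @export
synthetic_cell_scene <- function(config = default_config()) {
  px <- config$optical$pixel_size_camera_nm
  fov <- config$scene$fov_px
  side_nm <- fov * px
  plan <- config$plan
  z0 <- plan$first_plane_z_um
  z1 <- z0 + (plan$n_planes - 1) * plan$dz_nm / 1000
  photons <- config$scene$signal_adu * config$camera$electrons_per_adu /
    config$camera$quantum_efficiency
  # docking sites on a shell centred in the FOV, radius spanning the planes
  set.seed(config$seed)
  r_nm <- max((z1 - z0) * 1000 / 2 + 200, 900)
  ctr <- c(side_nm / 2, side_nm / 2, (z0 + z1) / 2 * 1000)
  n_sites <- config$scene$n_sites %||% 120
  u <- matrix(stats::rnorm(3 * n_sites), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- sweep(u * r_nm, 2, ctr, `+`)
  # keep sites laterally inside the central well region
  well_half <- side_nm * 0.22
  ok <- abs(pos[, 1] - ctr[1]) < well_half & abs(pos[, 2] - ctr[2]) < well_half
  pos <- pos[ok, , drop = FALSE]
  mol <- emitters(pos[, 1], pos[, 2], pos[, 3] / 1000, photons, "molecule")
  # beads in the polymer outside the well, between the planes so adjacent
  # planes share them; kept a tracking-window margin away from the border
  margin <- max(side_nm * 0.12, 10 * px)
  bead_xy <- rbind(c(margin, margin), c(side_nm - margin, margin),
                   c(margin, side_nm - margin),
                   c(side_nm - margin, side_nm - margin))
  bead_z <- z0 + (seq_len(nrow(bead_xy)) - 1) %% 2 * 0.1 +
    (z1 - z0) * (seq_len(nrow(bead_xy)) - 1) / max(1, nrow(bead_xy) - 1)
  bead_z <- pmin(pmax(bead_z, z0 + 0.05), max(z1 - 0.05, z0 + 0.05))
  fid <- emitters(bead_xy[, 1], bead_xy[, 2], bead_z,
                  config$scene$bead_photons, "fiducial")
  well_box_nm <- list(x = ctr[1] + c(-well_half, well_half),
                      y = ctr[2] + c(-well_half, well_half))
  list(molecules = mol, fiducials = fid, well_box_nm = well_box_nm,
       center_nm = ctr, radius_nm = r_nm, side_nm = side_nm)
}

#' Extract per-plane bead positions from a localization table
#'
#' Beads are photostable and ON in (almost) every frame, so their
#' localizations pile up at fixed lateral positions. Localizations are
#' linked laterally; components present in at least `min_fraction` of the
#' plane's frames are reported with their mean position.
#'
#' @param locs One plane's localization data.frame.
#' @param n_frames Number of frames in the plane.
#' @param min_fraction Minimum fraction of frames a bead must appear in
#'   (default 0.5).
#' @param link_nm Lateral linking distance (default 150 nm).
#' @return data.frame of bead positions (`x_nm`, `y_nm`, `z_um`, `n_loc`).
#' @export
extract_bead_positions <- function(locs, n_frames, min_fraction = 0.5,
                                   link_nm = 150) {
  if (!nrow(locs))
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_um = numeric(0), n_loc = integer(0)))
  comp <- .linkage_components(cbind(locs$x_nm, locs$y_nm), link_nm)
  out <- list()
  for (g in unique(comp)) {
    sel <- comp == g
    if (length(unique(locs$frame[sel])) < min_fraction * n_frames) next
    out[[length(out) + 1]] <- data.frame(
      x_nm = mean(locs$x_nm[sel]), y_nm = mean(locs$y_nm[sel]),
      z_um = mean(locs$z_um[sel], na.rm = TRUE), n_loc = sum(sel))
  }
  if (!length(out))
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_um = numeric(0), n_loc = integer(0)))
  do.call(rbind, out)
}

#' Run the full demo pipeline
#'
#' Executes, with one seed: (1) sensorless AO correction of the
#' depth-dependent aberration on a simulated bead; (2) astigmatism
#' calibration; (3) automatic multi-plane acquisition with feedback-loop
#' drift correction; (4) per-plane localization, quality filtering and
#' offline residual drift correction; (5) plane registration and volume
#' assembly; (6) rendering (optionally grid-filtered), axial homogeneity
#' and FRC resolution. All intermediate artifacts are written to
#' `out_dir`.
#'
#' @param config [default_config()] or [read_config()] result.
#' @param out_dir Output directory (created if needed).
#' @param write_frames Also write the raw frame stacks as TIFF (default
#'   FALSE; they are the largest artifact).
#' @return List of stage results (correction state, calibration,
#'   acquisition, localization tables, volume, metrics, manifest), invisibly
#'   also written to `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("smlm3d_"),
                         write_frames = FALSE) {
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cfg <- do.call(optical_config, config$optical)
  camera <- do.call(camera_model, config$camera)
  kinetics <- do.call(blink_kinetics, config$kinetics)
  depth <- config$aberration$depth_um
  # ---- stage 1: adaptive optics ----
  set.seed(seed)
  system_fn <- make_bead_system(zernike_coeffs(), cfg, depth_um = depth,
                                photons = config$scene$bead_photons * 10,
                                camera = NULL)
  ao <- suppressWarnings(
    run_3n(system_fn, modes = zernike_modes(config$ao$n_modes),
           alpha_nm = config$ao$alpha_nm,
           iterations = config$ao$iterations))
  jsonlite::write_json(
    list(correction_nm = as.list(unclass(ao$correction)),
         merit_history = ao$merit_history, log = ao$log),
    file.path(out_dir, "ao_correction.json"), auto_unbox = TRUE, digits = NA)
  # imaging wavefront: induced astigmatism + AO-corrected depth aberration
  imaging_coeffs <- zernike_coeffs(coefficients =
    unclass(ao$correction) +
    unclass(zernike_coeffs(astig_v = config$aberration$astigmatism_nm)))
  # ---- stage 2: astigmatism calibration ----
  zs <- seq(-0.8, 0.8, by = 0.025)
  zstack <- simulate_bead_zstack(zs, imaging_coeffs, camera,
                                 photons = config$scene$bead_photons * 10,
                                 cfg = cfg, seed = seed + 1,
                                 depth_um = depth, shot_noise = FALSE)
  cal <- calibrate_astigmatism(zstack, zs, camera, cfg)
  # ---- stage 3: acquisition ----
  scene <- synthetic_cell_scene(config)
  plan <- acquisition_plan(config$plan$first_plane_z_um, config$plan$n_planes,
                           config$plan$dz_nm, config$plan$frames_per_plane,
                           well_box_nm = scene$well_box_nm,
                           drift_threshold_nm = config$plan$drift_threshold_nm,
                           W = config$plan$W)
  sim_scene <- list(molecules = scene$molecules,
                    fiducials = scene$fiducials,
                    coeffs = imaging_coeffs, camera = camera, cfg = cfg,
                    kinetics = kinetics, cal = cal,
                    fov_px = c(config$scene$fov_px, config$scene$fov_px),
                    background_photons = config$scene$background_photons,
                    depth_um = depth,
                    drift_rate_nm = config$scene$drift_rate_nm)
  acq <- run_volume_acquisition(plan, sim_scene, seed = seed + 2)
  # ---- stage 4: localization per plane ----
  loc_cfg <- config$localization
  plane_locs <- list(); plane_beads <- list()
  for (p in acq$planes) {
    locs <- localize_stack(p$stack, cal, camera, cfg,
                           threshold_factor = loc_cfg$threshold_factor,
                           roi_halfwidth = loc_cfg$roi_halfwidth,
                           plane_index = p$plane_index)
    locs <- correct_residual_drift(locs, p$track, W = plan$W)
    locs <- filter_localizations(locs, loc_cfg$chi2_range, loc_cfg$z_range_um)
    beads <- extract_bead_positions(locs, plan$frames_per_plane)
    # molecule table: localizations not at a bead position
    if (nrow(beads)) {
      nn <- RANN::nn2(cbind(beads$x_nm, beads$y_nm),
                      cbind(locs$x_nm, locs$y_nm), k = 1)
      mol_locs <- locs[nn$nn.dists[, 1] > 200, , drop = FALSE]
    } else mol_locs <- locs
    plane_locs[[length(plane_locs) + 1]] <- mol_locs
    plane_beads[[length(plane_beads) + 1]] <- beads
    write_localizations(locs, file.path(out_dir,
      sprintf("localizations_plane%02d.csv", p$plane_index)))
    if (write_frames)
      write_stack_tiff(p$stack, file.path(out_dir,
        sprintf("frames_plane%02d.tif", p$plane_index)))
    utils::write.csv(data.frame(frame = p$track$frames,
                                x_nm = p$track$positions[, 1],
                                y_nm = p$track$positions[, 2],
                                z_nm = p$track$positions[, 3],
                                d_nm = p$track$drifts),
                     file.path(out_dir, sprintf("beadtrack_plane%02d.csv",
                                                p$plane_index)),
                     row.names = FALSE)
  }
  # ---- stage 5: registration + assembly ----
  shifts <- list()
  if (length(plane_locs) > 1) {
    for (i in seq_len(length(plane_locs) - 1)) {
      reg <- tryCatch(
        register_planes(plane_beads[[i]], plane_beads[[i + 1]],
                        plane_locs[[i + 1]]),
        error = function(e) NULL)
      if (!is.null(reg)) {
        plane_locs[[i + 1]] <- reg$locs
        bs <- plane_beads[[i + 1]]
        bs$x_nm <- bs$x_nm + reg$shift_nm[1]
        bs$y_nm <- bs$y_nm + reg$shift_nm[2]
        plane_beads[[i + 1]] <- bs
        shifts[[i]] <- reg$shift_nm
      } else shifts[[i]] <- c(NA_real_, NA_real_)
    }
  }
  volume <- assemble_volume(plane_locs, plan$dz_nm)
  write_localizations(volume, file.path(out_dir, "volume.csv"))
  # ---- stage 6: rendering + metrics ----
  rcfg <- render_config(config$render$sr_pixel_nm,
                        config$render$plane_spacing_nm,
                        config$render$blur_lateral_nm,
                        config$render$blur_axial_nm,
                        cfg$pixel_size_camera_nm)
  rendered <- render_volume(volume, rcfg)
  if (isTRUE(config$grid_filter$enabled)) {
    for (p in seq_len(dim(rendered)[3]))
      rendered[, , p] <- remove_grid_artifact(rendered[, , p],
                                              cfg$pixel_size_camera_nm,
                                              rcfg$zoom)
  }
  write_render_tiff(rendered, file.path(out_dir, "render.tif"))
  cv <- tryCatch(axial_cv(volume, rcfg$plane_spacing_nm),
                 error = function(e) NA_real_)
  frc <- tryCatch(frc_resolution(volume, rcfg,
                                 criterion = config$resolution$frc_criterion,
                                 min_per_plane = 50),
                  error = function(e) NULL)
  manifest <- list(
    package_version = as.character(utils::packageVersion("smlm3d")),
    seed = seed,
    config = unclass(config),
    n_planes_acquired = length(acq$planes),
    skipped_planes = acq$skipped,
    n_localizations = nrow(volume),
    registration_shifts_nm = shifts,
    axial_cv = as.numeric(cv),
    frc_mean_nm = if (!is.null(frc)) frc$mean_nm else NA,
    ao_final_merit = ao$merit_history[length(ao$merit_history)])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ao = ao, calibration = cal, acquisition = acq,
                 plane_locs = plane_locs, plane_beads = plane_beads,
                 volume = volume, rendered = rendered, axial_cv = cv,
                 frc = frc, manifest = manifest, out_dir = out_dir))
}
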