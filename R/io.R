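# File formats: ThunderSTORM-compatible localization CSV, multi-page TIFF
# stacks, YAML configuration.

# internal column name <-> CSV header mapping (ThunderSTORM dialect)
.loc_columns <- data.frame(
  internal = c("loc_id", "frame", "x_nm", "y_nm", "z_nm", "sigma_x_nm",
               "sigma_y_nm", "intensity_adu", "chi2", "plane_index"),
  header = c("id", "frame", "x [nm]", "y [nm]", "z [nm]", "sigma1 [nm]",
             "sigma2 [nm]", "intensity [photon]", "chi2", "plane"),
  stringsAsFactors = FALSE
)

#' Write a localization table to CSV
#'
#' ThunderSTORM-compatible headers: `id, frame, x [nm], y [nm], z [nm],
#' sigma1 [nm], sigma2 [nm], intensity [photon], chi2, plane`. A missing
#' `z_nm` column is derived from `z_um * 1000`. Extra columns are appended
#' unchanged, so foreign annotations survive a round trip.
#'
#' @param locs Localization data.frame.
#' @param path Output file.
#' @export
write_localizations <- function(locs, path) {
  if (is.null(locs$z_nm) && !is.null(locs$z_um)) locs$z_nm <- locs$z_um * 1000
  if (is.null(locs$loc_id)) locs$loc_id <- seq_len(nrow(locs))
  missing_cols <- setdiff(.loc_columns$internal, names(locs))
  for (mc in missing_cols) locs[[mc]] <- NA
  extra <- setdiff(names(locs), c(.loc_columns$internal, "z_um"))
  out <- locs[, .loc_columns$internal, drop = FALSE]
  names(out) <- .loc_columns$header
  for (e in extra) out[[e]] <- locs[[e]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Inverse of [write_localizations()]. Mandatory columns are checked by
#' name (missing ones are reported); malformed (non-numeric) rows are
#' rejected with their line number; extra columns are preserved.
#'
#' @param path CSV file.
#' @return Localization data.frame (internal column names, plus `z_um`).
#' @export
read_localizations <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mandatory <- c("id", "frame", "x [nm]", "y [nm]")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  present <- .loc_columns[.loc_columns$header %in% names(raw), ]
  out <- raw
  for (i in seq_len(nrow(present))) {
    v <- raw[[present$header[i]]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "" & v != "NA")
      if (length(bad))
        stop(sprintf("malformed value in column '%s' at data line %d",
                     present$header[i], bad[1]))
      v <- num
    }
    out[[present$header[i]]] <- v
  }
  names(out)[match(present$header, names(out))] <- present$internal
  if (!is.null(out$z_nm)) out$z_um <- out$z_nm / 1000
  out
}

#' Write a frame stack as multi-page 16-bit TIFF
#'
#' @param stack `frame_stack` or 3-D array (frame x y x x) of counts.
#' @param path Output file.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  pages <- lapply(seq_len(dim(frames)[1]),
                  function(f) frames[f, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF into a frame array
#'
#' @param path TIFF file written by [write_stack_tiff()] (16-bit counts).
#' @return 3-D integer array (frame x y x x).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0L, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) out[f, , ] <- as.integer(pages[[f]])
  out
}

#' Write a rendered volume as 32-bit float multi-page TIFF
#'
#' @param vol 3-D array (y, x, plane) from [render_volume()].
#' @param path Output file.
#' @export
write_render_tiff <- function(vol, path) {
  vol <- pmax(vol, 0)            # filtered renders can dip slightly negative
  mx <- max(vol)
  pages <- lapply(seq_len(dim(vol)[3]),
                  function(p) if (mx > 0) vol[, , p] / mx else vol[, , p])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

# ---- configuration --------------------------------------------------------

.default_config <- function() {
  list(
    seed = 1L,
    optical = list(numerical_aperture = 1.27, wavelength_nm = 580,
                   pixel_size_camera_nm = 108, pupil_grid_size = 64,
                   depth_spherical_slope_rad_per_um = 0.031,
                   refractive_index = 1.33, extra_blur_nm = 100),
    camera = list(baseline_adu = 100, electrons_per_adu = 0.46,
                  quantum_efficiency = 0.82, read_noise_e = 1.4),
    kinetics = list(on_rate_per_frame = 0.01, mean_on_frames = 3),
    aberration = list(astigmatism_nm = 60, depth_um = 14),
    ao = list(alpha_nm = 60, iterations = 3, n_modes = 7),
    plan = list(first_plane_z_um = 0, n_planes = 2, dz_nm = 350,
                frames_per_plane = 300, drift_threshold_nm = 0, W = 10),
    scene = list(fov_px = 48, signal_adu = 3500, background_photons = 2,
                 bead_photons = 2000, n_sites = 150,
                 drift_rate_nm = c(0.05, 0.02, -0.05)),
    localization = list(threshold_factor = 1.5, roi_halfwidth = 5,
                        chi2_range = c(0.6, 1), z_range_um = c(-0.5, 0.5),
                        fiducial_sigma_range_nm = c(130, 300),
                        fiducial_chi2_min = 0.65),
    render = list(sr_pixel_nm = 10, plane_spacing_nm = 200,
                  blur_lateral_nm = 10, blur_axial_nm = 50),
    resolution = list(frc_criterion = 0.142857142857143,
                      bead_min_loc = 30),
    cluster = list(min_loc = 10, cut_nm = 50),
    grid_filter = list(enabled = FALSE)
  )
}

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: alpha = 60 nm RMS for
#' the AO probe, chi2 filters 0.6 (localizations) and 0.65 (fiducial
#' selection), sigma bounds 130-300 nm, axial range +/-0.5 um, temporal
#' averaging W = 10, cluster minimum 10 localizations and 50 nm cutting
#' distance, FRC criterion 1/7, rendering at 10 nm pixels with 10/50 nm
#' blur, camera 100 ADU baseline / 0.46 e-/ADU / QE 0.82.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(.default_config(), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values are merged over [default_config()]; unknown keys (at any nesting
#' level present in the defaults) are rejected.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- .default_config()
  merge <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(user[[k]]))
        base[[k]] <- merge(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  structure(merge(base, user), class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config `pipeline_config` (or plain list).
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
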