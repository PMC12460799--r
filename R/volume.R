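# Offline reconstruction: residual drift correction, plane registration
# from shared fiducials, volume assembly, rendering, axial homogeneity and
# Fourier grid-artifact removal.

# Centred moving average with window w (sliding), edges shrink.
.moving_average <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Correct residual drift within a plane from its bead track
#'
#' The reference bead trajectory (in sample coordinates, i.e. what the
#' feedback loop could not remove) is smoothed with a moving average of
#' window `W`, interpolated at each localization's frame, and subtracted
#' from the localization coordinates. The smoothed trajectory is centred on
#' its own mean so the correction removes displacement, not absolute
#' position; the bead's corrected trajectory then has zero mean
#' displacement.
#'
#' @param locs Localization data.frame (one plane).
#' @param track Either a [bead_track()] or a data.frame with columns
#'   `frame`, `x_nm`, `y_nm`, `z_nm` of the bead positions.
#' @param W Smoothing window in frames (default 10, the feedback averaging
#'   window).
#' @return `locs` with corrected `x_nm`, `y_nm`, `z_um`; pass-through with
#'   a warning when the track is missing.
#' @export
correct_residual_drift <- function(locs, track, W = 10L) {
  if (is.null(track)) {
    warning("no bead track available: localizations passed through")
    return(locs)
  }
  if (inherits(track, "bead_track")) {
    if (!nrow(track$positions)) {
      warning("empty bead track: localizations passed through")
      return(locs)
    }
    tr <- data.frame(frame = track$frames,
                     x_nm = track$positions[, 1],
                     y_nm = track$positions[, 2],
                     z_nm = track$positions[, 3])
  } else tr <- track
  if (!nrow(locs)) return(locs)
  sm <- data.frame(frame = tr$frame,
                   x = .moving_average(tr$x_nm, W),
                   y = .moving_average(tr$y_nm, W),
                   z = .moving_average(tr$z_nm, W))
  corr <- function(col) {
    v <- sm[[col]] - mean(sm[[col]])
    stats::approx(sm$frame, v, xout = locs$frame, rule = 2)$y
  }
  locs$x_nm <- locs$x_nm - corr("x")
  locs$y_nm <- locs$y_nm - corr("y")
  locs$z_um <- locs$z_um - corr("z") / 1000
  locs
}

#' Measure and apply the lateral shift between adjacent planes
#'
#' Fiducials visible in both planes are matched by lateral nearest
#' neighbour (within `match_radius_nm`); the shift is the mean over shared
#' beads of (position in plane i - position in plane i+1), lateral only.
#' Plane i+1 localizations are translated by the shift.
#'
#' @param beads_i,beads_j data.frames of bead positions (`x_nm`, `y_nm`,
#'   one row per bead, averaged over the plane acquisition) for plane i and
#'   plane i+1.
#' @param locs_j Localizations of plane i+1 to translate (optional).
#' @param match_radius_nm Maximum lateral distance for a bead match
#'   (default 500).
#' @return List with `shift_nm` (length-2 dx, dy), `n_shared`, and
#'   `locs` (translated plane i+1 localizations, when supplied).
#' @export
register_planes <- function(beads_i, beads_j, locs_j = NULL,
                            match_radius_nm = 500) {
  stopifnot(nrow(beads_i) >= 1, nrow(beads_j) >= 1)
  nn <- RANN::nn2(cbind(beads_j$x_nm, beads_j$y_nm),
                  cbind(beads_i$x_nm, beads_i$y_nm), k = 1)
  ok <- nn$nn.dists[, 1] <= match_radius_nm
  if (sum(ok) < 2)
    stop("registration impossible: fewer than 2 shared fiducials")
  j <- nn$nn.idx[ok, 1]
  dx <- beads_i$x_nm[ok] - beads_j$x_nm[j]
  dy <- beads_i$y_nm[ok] - beads_j$y_nm[j]
  shift <- c(mean(dx), mean(dy))
  if (!is.null(locs_j)) {
    locs_j$x_nm <- locs_j$x_nm + shift[1]
    locs_j$y_nm <- locs_j$y_nm + shift[2]
  }
  list(shift_nm = shift, n_shared = sum(ok), locs = locs_j)
}

#' Assemble registered planes into a volume
#'
#' Adds the vertical offset `(plane_index - 1) * dz_nm` to each plane's
#' localizations and concatenates them with globally unique sequential
#' `loc_id`s.
#'
#' @param planes List of localization data.frames, each with a constant
#'   `plane_index` column (1-based).
#' @param dz_nm Plane spacing, nm.
#' @return Merged localization data.frame with `z_nm` = `z_um * 1000 +
#'   (plane_index - 1) * dz_nm` (total axial position in nm).
#' @export
assemble_volume <- function(planes, dz_nm) {
  out <- list()
  for (p in planes) {
    if (!nrow(p)) next
    p$z_nm <- p$z_um * 1000 + (p$plane_index - 1) * dz_nm
    out[[length(out) + 1]] <- p
  }
  vol <- do.call(rbind, out)
  vol$loc_id <- seq_len(nrow(vol))
  rownames(vol) <- NULL
  vol
}

#' Axial homogeneity of a reconstructed volume
#'
#' Histograms the localization counts along z and reports the coefficient
#' of variation of the counts: population standard deviation divided by
#' the mean.
#'
#' @param volume Assembled localization data.frame (`z_nm` column).
#' @param bin_nm Bin width, nm (default 200, the rendering plane spacing).
#' @return CV (dimensionless; multiply by 100 for percent), with attribute
#'   `counts`.
#' @export
axial_cv <- function(volume, bin_nm = 200) {
  if (!nrow(volume)) stop("empty volume")
  z <- volume$z_nm
  breaks <- seq(floor(min(z) / bin_nm) * bin_nm,
                ceiling(max(z) / bin_nm) * bin_nm + bin_nm, by = bin_nm)
  counts <- graphics::hist(z, breaks = breaks, plot = FALSE)$counts
  counts <- counts[seq_len(max(which(counts > 0)))]
  counts <- counts[min(which(counts > 0)):length(counts)]
  if (length(counts) < 2) stop("need at least 2 populated bins")
  pop_sd <- sqrt(mean((counts - mean(counts))^2))
  structure(pop_sd / mean(counts), counts = counts)
}

#' Rendering configuration
#'
#' @param sr_pixel_nm Super-resolution pixel size, nm (default 10).
#' @param plane_spacing_nm Rendered plane spacing, nm (default 200).
#' @param blur_lateral_nm Fixed lateral Gaussian blur sigma, nm (default 10).
#' @param blur_axial_nm Fixed axial Gaussian blur sigma, nm (default 50).
#' @param camera_pixel_nm Camera pixel size Delta used for the grid-filter
#'   frequency (default 108); the zoom factor is
#'   `z_sr = camera_pixel_nm / sr_pixel_nm`.
#' @return Object of class `render_config`.
#' @export
render_config <- function(sr_pixel_nm = 10, plane_spacing_nm = 200,
                          blur_lateral_nm = 10, blur_axial_nm = 50,
                          camera_pixel_nm = 108) {
  stopifnot(sr_pixel_nm > 0, plane_spacing_nm > 0)
  zoom <- camera_pixel_nm / sr_pixel_nm
  if (zoom <= 1) stop("zoom factor z_sr must exceed 1")
  structure(list(sr_pixel_nm = sr_pixel_nm,
                 plane_spacing_nm = plane_spacing_nm,
                 blur_lateral_nm = blur_lateral_nm,
                 blur_axial_nm = blur_axial_nm,
                 camera_pixel_nm = camera_pixel_nm, zoom = zoom),
            class = "render_config")
}

#' Render a localization volume as a Gaussian-blurred image stack
#'
#' Each localization deposits a separable 3-D Gaussian (fixed sigma
#' `blur_lateral_nm` laterally and `blur_axial_nm` axially, integral 1) on
#' a grid of `sr_pixel_nm` laterally and `plane_spacing_nm` axially, so the
#' integrated intensity is proportional to the localization count.
#'
#' @param volume Localization data.frame with `x_nm`, `y_nm` and `z_nm`
#'   columns (use [assemble_volume()]; a missing `z_nm` falls back to
#'   `z_um * 1000`).
#' @param cfg [render_config()].
#' @param extent Optional list with `x`, `y`, `z` ranges (nm) fixing the
#'   grid; defaults to the data range padded by 3 blur sigmas.
#' @return 3-D array (y, x, plane) with attributes `origin_nm` and config.
#' @export
render_volume <- function(volume, cfg = render_config(), extent = NULL) {
  if (is.null(volume$z_nm)) volume$z_nm <- volume$z_um * 1000
  px <- cfg$sr_pixel_nm; pz <- cfg$plane_spacing_nm
  sl <- cfg$blur_lateral_nm; sa <- cfg$blur_axial_nm
  if (is.null(extent)) {
    pad_l <- 3 * sl; pad_a <- max(3 * sa, pz)
    extent <- list(x = range(volume$x_nm) + c(-pad_l, pad_l),
                   y = range(volume$y_nm) + c(-pad_l, pad_l),
                   z = range(volume$z_nm) + c(-pad_a, pad_a))
  }
  nx <- max(2L, ceiling(diff(extent$x) / px))
  ny <- max(2L, ceiling(diff(extent$y) / px))
  nz <- max(1L, ceiling(diff(extent$z) / pz))
  img <- array(0, dim = c(ny, nx, nz))
  if (!nrow(volume)) {
    attr(img, "origin_nm") <- c(extent$x[1], extent$y[1], extent$z[1])
    attr(img, "config") <- cfg
    return(img)
  }
  hw_l <- ceiling(3 * sl / px)
  hw_a <- max(0L, ceiling(3 * sa / pz))
  for (i in seq_len(nrow(volume))) {
    cx <- (volume$x_nm[i] - extent$x[1]) / px + 0.5   # grid coordinates
    cy <- (volume$y_nm[i] - extent$y[1]) / px + 0.5
    cz <- (volume$z_nm[i] - extent$z[1]) / pz + 0.5
    ix <- round(cx); iy <- round(cy); iz <- round(cz)
    xr <- max(1, ix - hw_l):min(nx, ix + hw_l)
    yr <- max(1, iy - hw_l):min(ny, iy + hw_l)
    zr <- max(1, iz - hw_a):min(nz, iz + hw_a)
    if (!length(xr) || !length(yr) || !length(zr)) next
    gx <- exp(-((xr - 0.5) * px - (volume$x_nm[i] - extent$x[1]))^2 / (2 * sl^2))
    gy <- exp(-((yr - 0.5) * px - (volume$y_nm[i] - extent$y[1]))^2 / (2 * sl^2))
    gz <- exp(-((zr - 0.5) * pz - (volume$z_nm[i] - extent$z[1]))^2 / (2 * sa^2))
    gx <- gx / sum(gx); gy <- gy / sum(gy)
    if (sum(gz) > 0) gz <- gz / sum(gz)
    patch <- outer(gy, gx)
    for (k in seq_along(zr))
      img[yr, xr, zr[k]] <- img[yr, xr, zr[k]] + patch * gz[k]
  }
  attr(img, "origin_nm") <- c(extent$x[1], extent$y[1], extent$z[1])
  attr(img, "config") <- cfg
  img
}

#' Remove the camera-pixel grid artifact by Fourier filtering
#'
#' High-density reconstructions can carry a periodic artifact at the camera
#' pixel frequency. The filter zeroes the discrete Fourier bins at integer
#' non-zero multiples of `N / z_sr` (spatial frequency `1/Delta` and its
#' harmonics) along both axes, preserving DC, and returns the real part of
#' the inverse transform. Whole frequency lines (rows/columns) at the
#' targeted harmonics are cleared so the grid is removed regardless of its
#' orientation along the axes.
#'
#' @param image 2-D matrix (a rendered plane) whose pixel pitch is
#'   `Delta / z_sr`.
#' @param camera_pixel_nm Camera pixel size Delta, nm.
#' @param zoom Zoom factor `z_sr = Delta / sr_pixel`.
#' @return Filtered image (same dimensions).
#' @export
remove_grid_artifact <- function(image, camera_pixel_nm = 108, zoom = 10.8) {
  stopifnot(is.matrix(image))
  if (zoom <= 1) stop("zoom factor must exceed 1")
  ny <- nrow(image); nx <- ncol(image)
  if (nx / zoom < 1 || ny / zoom < 1)
    stop("image too small: the grid frequency is beyond Nyquist")
  F <- stats::fft(image)
  target_bins <- function(n) {
    step <- n / zoom                     # bins per harmonic of 1/Delta
    m <- seq_len(floor(zoom / 2))        # harmonics up to Nyquist
    k <- round(m * step)
    k <- k[k >= 1 & k <= floor(n / 2)]
    unique(c(k + 1, n - k + 1))          # positive and negative frequencies
  }
  F[target_bins(ny), ] <- 0
  F[, target_bins(nx)] <- 0
  Re(stats::fft(F, inverse = TRUE)) / (nx * ny)
}
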