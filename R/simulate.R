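# Synthetic acquisition forward model: emitters + blinking + drift ->
# photon images -> sCMOS counts.

#' sCMOS camera model
#'
#' @param baseline_adu Camera baseline offset in A/D counts (default 100).
#' @param electrons_per_adu Conversion gain, photo-electrons per count
#'   (default 0.46).
#' @param quantum_efficiency Detection quantum efficiency in (0, 1]
#'   (default 0.82).
#' @param read_noise_e Gaussian read noise, e- RMS (default 1.4; set 0 for a
#'   noiseless detector).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(baseline_adu = 100, electrons_per_adu = 0.46,
                         quantum_efficiency = 0.82, read_noise_e = 1.4) {
  stopifnot(baseline_adu >= 0, electrons_per_adu > 0,
            quantum_efficiency > 0, quantum_efficiency <= 1,
            read_noise_e >= 0)
  structure(list(baseline_adu = baseline_adu,
                 electrons_per_adu = electrons_per_adu,
                 quantum_efficiency = quantum_efficiency,
                 read_noise_e = read_noise_e),
            class = "camera_model")
}

#' Apply the camera model to an expected-photon image
#'
#' Photons are thinned by the quantum efficiency and shot-noised (Poisson),
#' converted to electrons, read noise added, divided by the conversion gain
#' and offset by the baseline; the result is the integer count image clipped
#' to the 16-bit range.
#'
#' @param photon_img Matrix of expected photons per pixel.
#' @param camera [camera_model()].
#' @param shot_noise If `FALSE`, the expectation is propagated without
#'   Poisson noise (used for deterministic tests and merit landscapes).
#' @return Integer count matrix.
#' @export
apply_camera <- function(photon_img, camera, shot_noise = TRUE) {
  lambda <- photon_img * camera$quantum_efficiency
  e <- if (shot_noise) {
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  } else lambda
  if (camera$read_noise_e > 0)
    e <- e + matrix(stats::rnorm(length(e), 0, camera$read_noise_e),
                    nrow(e), ncol(e))
  adu <- e / camera$electrons_per_adu + camera$baseline_adu
  adu <- round(adu)
  adu[adu < 0] <- 0
  adu[adu > 65535] <- 65535
  storage.mode(adu) <- "integer"
  adu
}

#' DNA-PAINT blinking kinetics
#'
#' Two-state discrete-time Markov chain per docking site: OFF -> ON with
#' probability `on_rate_per_frame` (proportional to imager concentration),
#' ON -> OFF with probability `1/mean_on_frames`. The steady-state ON
#' fraction is `on_rate / (on_rate + 1/mean_on_frames)`.
#'
#' @param on_rate_per_frame Binding probability per frame (> 0).
#' @param mean_on_frames Mean bright-time in frames (> 0).
#' @return Object of class `blink_kinetics`.
#' @export
blink_kinetics <- function(on_rate_per_frame = 0.002, mean_on_frames = 3) {
  stopifnot(on_rate_per_frame > 0, mean_on_frames > 0)
  structure(list(on_rate_per_frame = on_rate_per_frame,
                 mean_on_frames = mean_on_frames),
            class = "blink_kinetics")
}

#' Steady-state ON fraction of a blinking model
#' @param kinetics [blink_kinetics()].
#' @return Probability that a site is ON in any frame at equilibrium.
#' @export
on_fraction <- function(kinetics) {
  koff <- 1 / kinetics$mean_on_frames
  kinetics$on_rate_per_frame / (kinetics$on_rate_per_frame + koff)
}

#' Emitter table constructor
#'
#' @param x_nm,y_nm Lateral positions, nm.
#' @param z_um Axial positions relative to the nominal focal plane of the
#'   acquisition plane, um.
#' @param photons_mean Expected photons per frame while ON (> 0).
#' @param kind `"molecule"` or `"fiducial"`. Fiducials are always ON.
#' @return data.frame with one row per emitter.
#' @export
emitters <- function(x_nm, y_nm, z_um, photons_mean, kind = "molecule") {
  stopifnot(all(photons_mean > 0), all(kind %in% c("molecule", "fiducial")))
  n <- length(x_nm)
  data.frame(id = seq_len(n), x_nm = x_nm, y_nm = y_nm, z_um = z_um,
             photons_mean = rep_len(photons_mean, n),
             kind = rep_len(kind, n), stringsAsFactors = FALSE)
}

#' Linear 3-axis drift trajectory
#'
#' @param n_frames Number of frames.
#' @param rate_nm_per_frame Length-3 drift rate (dx, dy, dz) in nm/frame.
#' @param random_walk_nm Optional per-axis random-walk step sd, nm.
#' @param seed Optional seed for the random-walk component.
#' @return data.frame with columns `dx_nm`, `dy_nm`, `dz_nm`, one row per
#'   frame (frame 0 has zero drift).
#' @export
drift_trajectory <- function(n_frames, rate_nm_per_frame = c(0, 0, 0),
                             random_walk_nm = 0, seed = NULL) {
  stopifnot(n_frames >= 1, length(rate_nm_per_frame) == 3)
  t <- seq_len(n_frames) - 1
  d <- outer(t, rate_nm_per_frame)
  if (random_walk_nm > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (a in 1:3)
      d[, a] <- d[, a] + cumsum(c(0, stats::rnorm(n_frames - 1, 0, random_walk_nm)))
  }
  out <- as.data.frame(d)
  names(out) <- c("dx_nm", "dy_nm", "dz_nm")
  out
}

#' Place fiducial beads around a well
#'
#' Draws a Poisson number of beads with mean `density_per_um3` times the
#' volume outside the excluded well box, uniformly distributed in the
#' remaining volume (beads are embedded in the polymer surrounding the
#' sample well, never inside it).
#'
#' @param density_per_um3 Bead density, um^-3 (>= 0; default 4.5e-3).
#' @param volume_um3 Length-3 extent (Lx, Ly, Lz) of the volume, um.
#' @param well_box Excluded region: list with `x`, `y`, `z` ranges in um
#'   (each length-2), fully inside the volume; or `NULL` for none.
#' @param photons_mean Bead brightness, expected photons per frame.
#' @param seed RNG seed.
#' @return Emitter data.frame (`kind = "fiducial"`), positions in nm (x, y)
#'   and um (z, absolute within the volume).
#' @export
place_fiducials <- function(density_per_um3 = 4.5e-3,
                            volume_um3 = c(50, 50, 40),
                            well_box = NULL, photons_mean = 2000,
                            seed = NULL) {
  if (density_per_um3 < 0) stop("density must be >= 0")
  stopifnot(length(volume_um3) == 3, all(volume_um3 > 0))
  vol <- prod(volume_um3)
  wvol <- 0
  if (!is.null(well_box)) {
    stopifnot(all(c("x", "y", "z") %in% names(well_box)))
    for (a in c("x", "y", "z")) stopifnot(length(well_box[[a]]) == 2)
    if (well_box$x[1] < 0 || well_box$y[1] < 0 || well_box$z[1] < 0 ||
        well_box$x[2] > volume_um3[1] || well_box$y[2] > volume_um3[2] ||
        well_box$z[2] > volume_um3[3])
      stop("well_box must lie inside the volume")
    wvol <- prod(vapply(well_box, diff, numeric(1)))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, density_per_um3 * (vol - wvol))
  if (n == 0)
    return(emitters(numeric(0), numeric(0), numeric(0), photons_mean,
                    "fiducial"))
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    m <- max(2 * (n - nrow(pts)), 16)
    cand <- cbind(stats::runif(m, 0, volume_um3[1]),
                  stats::runif(m, 0, volume_um3[2]),
                  stats::runif(m, 0, volume_um3[3]))
    if (!is.null(well_box)) {
      inside <- cand[, 1] > well_box$x[1] & cand[, 1] < well_box$x[2] &
        cand[, 2] > well_box$y[1] & cand[, 2] < well_box$y[2] &
        cand[, 3] > well_box$z[1] & cand[, 3] < well_box$z[2]
      cand <- cand[!inside, , drop = FALSE]
    }
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  emitters(pts[, 1] * 1000, pts[, 2] * 1000, pts[, 3], photons_mean,
           "fiducial")
}

# Add an expected-photon PSF patch for one emitter to a photon image.
# x/y in nm in frame coordinates (pixel-centre convention, origin at the
# corner pixel centre).
.add_emitter_patch <- function(img, x_nm, y_nm, z_um, photons, coeffs,
                               depth_um, cfg, halfwin = 31L) {
  px <- cfg$pixel_size_camera_nm
  cx <- round(x_nm / px)                 # nearest pixel (0-based)
  cy <- round(y_nm / px)
  frac_x <- x_nm - cx * px
  frac_y <- y_nm - cy * px
  psf <- render_psf(coeffs, z_um = z_um, depth_um = depth_um, cfg = cfg,
                    dx_nm = frac_x, dy_nm = frac_y)
  N <- nrow(psf); c0 <- N / 2 + 1
  w <- min(halfwin, N / 2 - 1)
  patch <- psf[(c0 - w):(c0 + w), (c0 - w):(c0 + w)]
  rows <- (cy - w):(cy + w) + 1          # 1-based matrix rows (y)
  cols <- (cx - w):(cx + w) + 1
  ok_r <- rows >= 1 & rows <= nrow(img)
  ok_c <- cols >= 1 & cols <= ncol(img)
  if (!any(ok_r) || !any(ok_c)) return(img)
  img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] +
    photons * patch[ok_r, ok_c]
  img
}

#' Simulate a single-plane blinking acquisition
#'
#' Renders `n_frames` camera frames of the given emitters: molecules blink
#' according to the two-state kinetics, fiducials are always ON, the stage
#' drift is applied to the emitters in the sample frame, and the expected
#' photon image is passed through the sCMOS camera model. Ground truth (ON
#' emitters with drifted positions per frame, and the drift itself) is
#' recorded.
#'
#' @param em Emitter data.frame (see [emitters()]); `x_nm`, `y_nm` are frame
#'   coordinates, `z_um` is relative to the focal plane of this acquisition.
#' @param kinetics [blink_kinetics()] for molecules.
#' @param drift Drift data.frame from [drift_trajectory()] (`n_frames` rows)
#'   or `NULL` for no drift.
#' @param coeffs [zernike_coeffs()] wavefront (include the induced
#'   astigmatism here).
#' @param camera [camera_model()].
#' @param n_frames Number of frames (>= 1).
#' @param cfg [optical_config()].
#' @param fov_px Length-2 frame size (nx, ny) in pixels.
#' @param seed RNG seed (required for reproducibility).
#' @param depth_um Imaging depth above the coverslip, um.
#' @param background_photons Flat background, expected photons per pixel per
#'   frame; optionally length 2 `c(base, gradient)` for a smooth left-right
#'   linear gradient.
#' @param shot_noise Apply Poisson shot noise (default `TRUE`).
#' @param frame_rate_hz Nominal frame rate stored with the stack.
#' @param plane_index 1-based acquisition-plane index stored with the stack.
#' @return Object of class `frame_stack`: list with `frames` (3-D integer
#'   array frame x y x x), `frame_rate_hz`, `plane_index`, and
#'   `ground_truth` (per-frame ON emitter table and the drift trajectory).
#' @export
simulate_acquisition <- function(em, kinetics = blink_kinetics(),
                                 drift = NULL, coeffs = zernike_coeffs(),
                                 camera = camera_model(), n_frames,
                                 cfg = optical_config(),
                                 fov_px = c(64, 64), seed,
                                 depth_um = 0, background_photons = 0,
                                 shot_noise = TRUE, frame_rate_hz = 10,
                                 plane_index = 1L) {
  stopifnot(n_frames >= 1)
  if (any(fov_px < 8)) stop("frame geometry too small")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  if (is.null(drift)) drift <- drift_trajectory(n_frames)
  if (nrow(drift) != n_frames) stop("drift length must equal n_frames")
  nx <- fov_px[1]; ny <- fov_px[2]
  frames <- array(0L, dim = c(n_frames, ny, nx))
  is_mol <- em$kind == "molecule"
  state <- stats::runif(nrow(em)) < on_fraction(kinetics)
  state[!is_mol] <- TRUE
  p_on <- kinetics$on_rate_per_frame
  p_off <- 1 / kinetics$mean_on_frames
  bg <- matrix(background_photons[1], ny, nx)
  if (length(background_photons) > 1 && background_photons[2] != 0)
    bg <- bg + matrix(rep(seq(0, background_photons[2], length.out = nx),
                          each = ny), ny, nx)
  gt <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      u <- stats::runif(nrow(em))
      state <- ifelse(state, u >= p_off, u < p_on)
      state[!is_mol] <- TRUE
    }
    img <- bg
    on_idx <- which(state)
    for (i in on_idx) {
      img <- .add_emitter_patch(img,
                                em$x_nm[i] + drift$dx_nm[f],
                                em$y_nm[i] + drift$dy_nm[f],
                                em$z_um[i] + drift$dz_nm[f] / 1000,
                                em$photons_mean[i], coeffs, depth_um, cfg)
    }
    frames[f, , ] <- apply_camera(img, camera, shot_noise = shot_noise)
    if (!length(on_idx)) next
    gt[[f]] <- data.frame(frame = f - 1L, id = em$id[on_idx],
                          kind = em$kind[on_idx],
                          x_nm = em$x_nm[on_idx] + drift$dx_nm[f],
                          y_nm = em$y_nm[on_idx] + drift$dy_nm[f],
                          z_um = em$z_um[on_idx] + drift$dz_nm[f] / 1000,
                          photons = em$photons_mean[on_idx])
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 plane_index = as.integer(plane_index),
                 ground_truth = list(on = do.call(rbind, gt), drift = drift)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stack: %d frames of %d x %d px (plane %d, %.2f Hz)\n",
              d[1], d[3], d[2], x$plane_index, x$frame_rate_hz))
  invisible(x)
}

#' Simulate a fiducial bead z-stack for PSF calibration
#'
#' One frame per z position of a single bead held at the frame centre,
#' mirroring the calibration protocol (an epifluorescence z-stack of a
#' stationary bead with the induced astigmatism applied).
#'
#' @param z_um Ascending axial positions, um (e.g. `seq(-1, 1, by = 0.025)`).
#' @param coeffs Wavefront including the induced astigmatism.
#' @param camera [camera_model()].
#' @param photons Expected photons per frame.
#' @param cfg [optical_config()].
#' @param fov_px Frame size (nx, ny).
#' @param seed RNG seed.
#' @param depth_um Imaging depth, um.
#' @param shot_noise Apply Poisson noise.
#' @return `frame_stack` with one frame per z position.
#' @export
simulate_bead_zstack <- function(z_um, coeffs, camera = camera_model(),
                                 photons = 20000, cfg = optical_config(),
                                 fov_px = c(32, 32), seed = 1,
                                 depth_um = 0, shot_noise = TRUE) {
  set.seed(seed)
  nx <- fov_px[1]; ny <- fov_px[2]
  px <- cfg$pixel_size_camera_nm
  cx <- (round(nx / 2) - 1) * px; cy <- (round(ny / 2) - 1) * px
  frames <- array(0L, dim = c(length(z_um), ny, nx))
  for (f in seq_along(z_um)) {
    img <- .add_emitter_patch(matrix(0, ny, nx), cx, cy, z_um[f], photons,
                              coeffs, depth_um, cfg)
    frames[f, , ] <- apply_camera(img, camera, shot_noise = shot_noise)
  }
  structure(list(frames = frames, frame_rate_hz = NA_real_,
                 plane_index = 1L,
                 ground_truth = list(z_um = z_um)),
            class = "frame_stack")
}
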