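# Real-time fiducial tracking and feedback-loop drift correction with
# automatic multi-plane sequencing.

#' Select the reference fiducial for a plane
#'
#' Candidates must be axially close to the imaged plane
#' (130 nm <= sigma_x, sigma_y <= 300 nm), well fitted (chi2 > 0.65), and
#' lie outside the sample well. Among candidates the bead closest to focus
#' (minimal |sigma_x - sigma_y|) is selected, ties broken by the highest
#' chi2; this operationalizes "axially closest to the imaging plane with
#' the best localization accuracy".
#'
#' @param locs Localization data.frame of bead candidates.
#' @param well_box_nm Optional lateral exclusion region: list with `x` and
#'   `y` ranges in nm; candidates inside it are rejected.
#' @param sigma_range_nm Acceptable sigma range (default `c(130, 300)`).
#' @param chi2_min Minimum goodness of fit (default 0.65).
#' @return The selected localization row (data.frame), or `NULL` when no
#'   candidate qualifies.
#' @export
select_fiduciary <- function(locs, well_box_nm = NULL,
                             sigma_range_nm = c(130, 300),
                             chi2_min = 0.65) {
  if (is.null(locs) || !nrow(locs)) return(NULL)
  ok <- locs$sigma_x_nm >= sigma_range_nm[1] &
    locs$sigma_x_nm <= sigma_range_nm[2] &
    locs$sigma_y_nm >= sigma_range_nm[1] &
    locs$sigma_y_nm <= sigma_range_nm[2] &
    locs$chi2 > chi2_min
  if (!is.null(well_box_nm)) {
    inside <- locs$x_nm > well_box_nm$x[1] & locs$x_nm < well_box_nm$x[2] &
      locs$y_nm > well_box_nm$y[1] & locs$y_nm < well_box_nm$y[2]
    ok <- ok & !inside
  }
  cand <- locs[which(ok), , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  an <- abs(cand$sigma_x_nm - cand$sigma_y_nm)
  best <- which(an == min(an))
  if (length(best) > 1) best <- best[which.max(cand$chi2[best])]
  cand[best, , drop = FALSE]
}

#' Drift metric: Euclidean distance to the reference position
#'
#' `d_i = sqrt((x_i - x_0)^2 + (y_i - y_0)^2 + (z_i - z_0)^2)`, the 3-D
#' distance between the fiducial position at frame i and its position at
#' the beginning of the acquisition.
#'
#' @param p0 Reference position `(x0, y0, z0)` in nm.
#' @param pi Current position `(xi, yi, zi)` in nm.
#' @return Non-negative scalar distance in nm.
#' @export
compute_drift <- function(p0, pi) {
  stopifnot(length(p0) == 3, length(pi) == 3,
            all(is.finite(p0)), all(is.finite(pi)))
  sqrt(sum((pi - p0)^2))
}

#' Initialize a bead track
#'
#' @param reference Length-3 reference position (x0, y0, z0), nm.
#' @param bead_id Identifier.
#' @param W Temporal averaging window in frames (sliding; default 10).
#' @param threshold_nm Drift threshold above which a correction is issued
#'   (default 0: correct whenever d > 0).
#' @param max_misses Consecutive lost-bead frames tolerated before the
#'   plane is aborted (default 50).
#' @return Object of class `bead_track`.
#' @export
bead_track <- function(reference, bead_id = 1L, W = 10L, threshold_nm = 0,
                       max_misses = 50L) {
  stopifnot(length(reference) == 3, all(is.finite(reference)))
  structure(list(bead_id = bead_id, reference = as.numeric(reference),
                 W = as.integer(W), threshold_nm = threshold_nm,
                 max_misses = as.integer(max_misses),
                 positions = matrix(numeric(0), 0, 3),
                 frames = integer(0), drifts = numeric(0),
                 corrections = matrix(numeric(0), 0, 4,
                                      dimnames = list(NULL, c("frame", "dx", "dy", "dz"))),
                 misses = 0L, aborted = FALSE),
            class = "bead_track")
}

#' One feedback-loop step
#'
#' Appends the new bead localization to the track, estimates the current
#' position as the sliding mean of the last <= W localizations, computes
#' the drift metric to the reference, and when it exceeds the threshold
#' emits the stage correction `-(estimate - reference)`. A missing
#' localization (`NULL`) counts as a lost-bead frame; after `max_misses`
#' consecutive misses the track is marked aborted.
#'
#' @param track [bead_track()].
#' @param new_loc Length-3 position (x, y, z) nm of the bead this frame, or
#'   `NULL` if the bead was not localized.
#' @param frame Frame index (0-based).
#' @return List with `track` (updated) and `correction` (length-3 nm vector
#'   or `NULL` when no correction was issued).
#' @export
feedback_step <- function(track, new_loc, frame = NA_integer_) {
  stopifnot(inherits(track, "bead_track"))
  if (is.null(new_loc)) {
    track$misses <- track$misses + 1L
    if (track$misses >= track$max_misses) track$aborted <- TRUE
    return(list(track = track, correction = NULL))
  }
  stopifnot(length(new_loc) == 3)
  track$misses <- 0L
  track$positions <- rbind(track$positions, as.numeric(new_loc))
  track$frames <- c(track$frames, as.integer(frame))
  n <- nrow(track$positions)
  w <- min(track$W, n)
  est <- colMeans(track$positions[(n - w + 1):n, , drop = FALSE])
  d <- compute_drift(track$reference, est)
  track$drifts <- c(track$drifts, d)
  corr <- NULL
  if (d > track$threshold_nm) {
    corr <- -(est - track$reference)
    track$corrections <- rbind(track$corrections,
                               c(frame, corr[1], corr[2], corr[3]))
    # re-reference the stored window to the commanded stage position:
    # past localizations were measured before this correction, so they are
    # translated by it to stay comparable with future measurements
    # (otherwise the averaged feedback acts on stale coordinates and the
    # loop is unstable for W > 1)
    track$positions <- sweep(track$positions, 2, corr, "+")
  }
  list(track = track, correction = corr)
}

#' @export
print.bead_track <- function(x, ...) {
  cat(sprintf("Bead track %s: %d localizations, %d corrections (W = %d)\n",
              x$bead_id, nrow(x$positions), nrow(x$corrections), x$W))
  if (length(x$drifts))
    cat(sprintf("  drift metric: last %.2f nm, max %.2f nm\n",
                x$drifts[length(x$drifts)], max(x$drifts)))
  invisible(x)
}

#' Closed-loop drift-correction simulation (localization level)
#'
#' Simulates the feedback loop on one bead without rendering images: the
#' measured bead position each frame is the reference plus the injected
#' drift, plus the accumulated stage offset, plus white localization noise.
#' Issued corrections move the stage (optionally with a one-frame latency
#' and actuator noise). Used for loop-stability characterization.
#'
#' @param drift data.frame from [drift_trajectory()] (per-frame sample
#'   drift, nm).
#' @param precision_nm Length-3 per-axis localization noise sd, nm (a
#'   scalar is recycled).
#' @param W Averaging window.
#' @param threshold_nm Correction threshold.
#' @param latency_frames Frames between issuing a correction and the stage
#'   moving (default 1).
#' @param stage_noise_nm Actuator positioning noise sd per applied
#'   correction, nm (default 2).
#' @param seed RNG seed.
#' @return List with `track`, `residual` (matrix of per-frame true residual
#'   sample displacement = drift + stage, nm), `stage` (final stage offset)
#'   and `residual_rms` (per-axis RMS of the residual).
#' @export
simulate_feedback_loop <- function(drift, precision_nm = 6, W = 10L,
                                   threshold_nm = 0, latency_frames = 1L,
                                   stage_noise_nm = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(drift)
  prec <- rep_len(precision_nm, 3)
  ref <- c(0, 0, 0)
  track <- bead_track(ref, W = W, threshold_nm = threshold_nm)
  stage <- c(0, 0, 0)
  pending <- list()                     # corrections waiting for latency
  residual <- matrix(0, n, 3)
  stage_at_frame <- matrix(0, n, 3)
  for (f in seq_len(n)) {
    # apply corrections whose latency has elapsed
    if (length(pending)) {
      due <- vapply(pending, function(p) p$frame + latency_frames <= f - 1L,
                    logical(1))
      for (p in pending[due]) {
        corr <- p$corr
        if (stage_noise_nm > 0)
          corr <- corr + stats::rnorm(3, 0, stage_noise_nm)
        stage <- stage + corr
      }
      pending <- pending[!due]
    }
    true_disp <- c(drift$dx_nm[f], drift$dy_nm[f], drift$dz_nm[f]) + stage
    residual[f, ] <- true_disp
    stage_at_frame[f, ] <- stage
    meas <- ref + true_disp + stats::rnorm(3, 0, prec)
    st <- feedback_step(track, meas, frame = f - 1L)
    track <- st$track
    if (!is.null(st$correction))
      pending[[length(pending) + 1]] <- list(frame = f - 1L,
                                             corr = st$correction)
  }
  list(track = track, residual = residual, stage = stage,
       stage_at_frame = stage_at_frame,
       residual_rms = sqrt(colMeans(residual^2)))
}

#' Acquisition plan for automatic multi-plane volumes
#'
#' @param first_plane_z_um Absolute z of the first acquisition plane, um.
#' @param n_planes Number of planes (>= 1).
#' @param dz_nm Plane spacing, nm (> 0).
#' @param frames_per_plane Frames acquired per plane.
#' @param well_box_nm Lateral well region excluded from bead selection
#'   (list with `x`, `y` ranges in nm), or `NULL`.
#' @param drift_threshold_nm Feedback threshold (default 0).
#' @param W Temporal averaging window (default 10).
#' @return Object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(first_plane_z_um, n_planes, dz_nm,
                             frames_per_plane, well_box_nm = NULL,
                             drift_threshold_nm = 0, W = 10L) {
  stopifnot(n_planes >= 1, dz_nm > 0, frames_per_plane >= 1)
  structure(list(first_plane_z_um = first_plane_z_um,
                 n_planes = as.integer(n_planes), dz_nm = dz_nm,
                 frames_per_plane = as.integer(frames_per_plane),
                 well_box_nm = well_box_nm,
                 drift_threshold_nm = drift_threshold_nm, W = as.integer(W)),
            class = "acquisition_plan")
}

#' Run an automatic multi-plane volume acquisition
#'
#' For each plane of the plan: a pre-acquisition bead image is taken, the
#' fiducials near the plane are localized and the reference bead selected
#' ([select_fiduciary()]); the plane is then acquired frame by frame with
#' feedback-loop drift correction on the simulated stage, after which both
#' the imaging and the excitation plane advance by the plane spacing.
#' Planes without an eligible bead are skipped with a logged gap; if no
#' plane has a bead, an error is raised.
#'
#' @param plan [acquisition_plan()].
#' @param scene List describing the simulated sample: `molecules` (emitter
#'   data.frame with absolute z_um), `fiducials` (same), `coeffs`, `camera`,
#'   `cfg`, `kinetics`, `cal` (astigmatism calibration),
#'   `fov_px`, `background_photons`, `depth_um` and `drift_rate_nm`
#'   (length-3 nm/frame, continuing across planes).
#' @param seed RNG seed.
#' @return Object of class `volume_acquisition`: list with `planes` (per
#'   acquired plane: `frame_stack`, `bead_track`, `plane_index`,
#'   `plane_z_um`, per-frame stage offsets), `skipped` (plane indices
#'   without bead) and the plan.
#' @export
run_volume_acquisition <- function(plan, scene, seed = 1) {
  stopifnot(inherits(plan, "acquisition_plan"))
  set.seed(seed)
  cfg <- scene$cfg; camera <- scene$camera
  fov <- scene$fov_px
  px <- cfg$pixel_size_camera_nm
  planes <- list(); skipped <- integer(0)
  drift_rate <- scene$drift_rate_nm %||% c(0, 0, 0)
  frame_global <- 0L
  stage <- c(0, 0, 0)
  for (p in seq_len(plan$n_planes)) {
    plane_z <- plan$first_plane_z_um + (p - 1) * plan$dz_nm / 1000
    total_drift <- function() frame_global * drift_rate
    # --- pre-acquisition bead image: fiducials near this plane, no blinking
    fid <- scene$fiducials
    rel_z <- fid$z_um - plane_z
    near <- abs(rel_z) <= 0.45
    sel <- NULL
    if (any(near)) {
      fid_near <- fid[near, , drop = FALSE]
      fid_near$z_um <- rel_z[near]
      pre <- simulate_acquisition(fid_near, drift = NULL,
                                  coeffs = scene$coeffs, camera = camera,
                                  n_frames = 1, cfg = cfg, fov_px = fov,
                                  seed = sample.int(2^31 - 1, 1),
                                  depth_um = scene$depth_um %||% 0,
                                  background_photons = scene$background_photons %||% 0)
      locs <- localize_stack(pre, scene$cal, camera, cfg)
      sel <- select_fiduciary(locs, plan$well_box_nm)
    }
    if (is.null(sel)) {
      skipped <- c(skipped, p)
      frame_global <- frame_global + plan$frames_per_plane
      next
    }
    ref <- c(sel$x_nm, sel$y_nm, sel$z_um * 1000)
    # re-measure the reference on fresh frames with the tracking estimator:
    # the bead was selected for its minimal measured anisotropy, so its
    # fitted z in the selection frame is biased toward focus (winner's
    # curse); averaging independent re-measurements gives an unbiased
    # feedback target
    ref_stack <- simulate_acquisition(fid_near, drift = NULL,
                                      coeffs = scene$coeffs, camera = camera,
                                      n_frames = plan$W, cfg = cfg,
                                      fov_px = fov,
                                      seed = sample.int(2^31 - 1, 1),
                                      depth_um = scene$depth_um %||% 0,
                                      background_photons = scene$background_photons %||% 0)
    remeas <- vapply(seq_len(plan$W), function(f) {
      m <- .track_bead(ref_stack$frames[f, , ], ref, camera, cfg, scene$cal)
      if (is.null(m)) rep(NA_real_, 3) else m
    }, numeric(3))
    if (any(stats::complete.cases(t(remeas))))
      ref <- rowMeans(remeas, na.rm = TRUE)
    track <- bead_track(ref, bead_id = p, W = plan$W,
                        threshold_nm = plan$drift_threshold_nm)
    mol <- scene$molecules
    mol_rel <- mol; mol_rel$z_um <- mol$z_um - plane_z
    frames <- array(0L, dim = c(plan$frames_per_plane, fov[2], fov[1]))
    stage_log <- matrix(0, plan$frames_per_plane, 3)
    gt_drift <- matrix(0, plan$frames_per_plane, 3)
    state <- NULL
    for (f in seq_len(plan$frames_per_plane)) {
      dr <- total_drift()
      gt_drift[f, ] <- dr
      disp <- dr + stage
      stage_log[f, ] <- stage
      # blinking states evolve across the plane
      if (is.null(state))
        state <- stats::runif(nrow(mol_rel)) < on_fraction(scene$kinetics)
      else {
        u <- stats::runif(nrow(mol_rel))
        state <- ifelse(state, u >= 1 / scene$kinetics$mean_on_frames,
                        u < scene$kinetics$on_rate_per_frame)
      }
      img <- matrix(scene$background_photons %||% 0, fov[2], fov[1])
      # optical sectioning: only molecules inside the excitation window
      # around the plane fluoresce (the sheet profile itself is not
      # modelled, just its axial extent)
      exc <- scene$excitation_halfwidth_um %||% 0.6
      for (i in which(state)) {
        z_eff <- mol_rel$z_um[i] + disp[3] / 1000
        if (abs(z_eff) > exc) next
        img <- .add_emitter_patch(img, mol_rel$x_nm[i] + disp[1],
                                  mol_rel$y_nm[i] + disp[2], z_eff,
                                  mol_rel$photons_mean[i], scene$coeffs,
                                  scene$depth_um %||% 0, cfg)
      }
      # beads near the plane are imaged together with the molecules
      for (i in which(near)) {
        img <- .add_emitter_patch(img, fid$x_nm[i] + disp[1],
                                  fid$y_nm[i] + disp[2],
                                  fid$z_um[i] - plane_z + disp[3] / 1000,
                                  fid$photons_mean[i], scene$coeffs,
                                  scene$depth_um %||% 0, cfg)
      }
      frame <- apply_camera(img, camera)
      frames[f, , ] <- frame
      # real-time bead localization in an ROI around the predicted position
      meas <- .track_bead(frame, ref, camera, cfg, scene$cal)
      st <- feedback_step(track, meas, frame = frame_global)
      track <- st$track
      if (track$aborted) break
      if (!is.null(st$correction)) stage <- stage + st$correction
      frame_global <- frame_global + 1L
    }
    stk <- structure(list(frames = frames, frame_rate_hz = NA_real_,
                          plane_index = p,
                          ground_truth = list(drift = gt_drift,
                                              stage = stage_log)),
                     class = "frame_stack")
    planes[[length(planes) + 1]] <- list(stack = stk, track = track,
                                         plane_index = p,
                                         plane_z_um = plane_z)
  }
  if (!length(planes)) stop("no plane contained an eligible fiducial")
  structure(list(planes = planes, skipped = skipped, plan = plan),
            class = "volume_acquisition")
}

# Localize the tracked bead in a window around its reference position.
.track_bead <- function(frame, ref_nm, camera, cfg, cal, halfwin = 7L) {
  px <- cfg$pixel_size_camera_nm
  c0 <- round(ref_nm[1] / px) + 1L
  r0 <- round(ref_nm[2] / px) + 1L
  # clamp the window inside the frame (beads can sit near the border)
  r0 <- min(max(r0, halfwin + 1L), nrow(frame) - halfwin)
  c0 <- min(max(c0, halfwin + 1L), ncol(frame) - halfwin)
  if (r0 - halfwin < 1 || r0 + halfwin > nrow(frame) ||
      c0 - halfwin < 1 || c0 + halfwin > ncol(frame)) return(NULL)
  roi <- frame[(r0 - halfwin):(r0 + halfwin), (c0 - halfwin):(c0 + halfwin)] -
    camera$baseline_adu
  fit <- fit_gaussian(roi, px)
  if (!fit$ok) return(NULL)
  z <- assign_z(fit$sigma_x_nm, fit$sigma_y_nm, cal)
  if (!attr(z, "in_range")[1]) return(NULL)
  c((c0 - 1L - halfwin) * px + fit$x_nm,
    (r0 - 1L - halfwin) * px + fit$y_nm,
    as.numeric(z) * 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.volume_acquisition <- function(x, ...) {
  cat(sprintf("Volume acquisition: %d/%d planes acquired (dz = %g nm)\n",
              length(x$planes), x$plan$n_planes, x$plan$dz_nm))
  if (length(x$skipped))
    cat("  skipped planes (no fiducial):", paste(x$skipped, collapse = ", "),
        "\n")
  invisible(x)
}
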