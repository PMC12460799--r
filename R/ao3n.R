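# Sensorless modal adaptive optics: the 3N algorithm.
#
# Each Zernike mode is probed at (+alpha, 0, -alpha) around the current
# correction, an image-quality merit factor is measured at the three
# samples, a parabola is fitted and the correction jumps to its vertex.
# The merit factor is the inverse of the maximum pixel intensity of a
# point-source image: sharper (less aberrated) PSFs concentrate photons
# into fewer pixels, so lower merit is better.

#' Image-quality merit factor (inverse maximum intensity)
#'
#' @param image Intensity image (matrix).
#' @param baseline Offset subtracted before taking the maximum (camera
#'   baseline in counts); the merit must reflect signal, not offset.
#' @return `1 / max(image - baseline)`; lower is better.
#' @export
evaluate_merit <- function(image, baseline = 0) {
  if (length(image) == 0) stop("empty image")
  m <- max(image) - baseline
  if (!is.finite(m) || m <= 0) stop("merit undefined: image maximum <= baseline")
  1 / m
}

#' Parabola vertex of a 3-point merit sample
#'
#' Fits a second-order polynomial through the merit values measured at
#' coefficients (-alpha, 0, +alpha) and returns the abscissa of its
#' extremum, clamped to `[-alpha, alpha]`. If the sampled triplet is not
#' convex (curvature <= 0) the best sampled coefficient is returned instead
#' and flagged, which keeps the search robust on noisy merits.
#'
#' @param merits Length-3 numeric `(m_minus, m_zero, m_plus)`.
#' @param alpha_nm Probe amplitude, nm RMS (> 0).
#' @return `alpha_opt_nm` with attribute `convex` (logical).
#' @export
parabola_vertex <- function(merits, alpha_nm) {
  stopifnot(length(merits) == 3, alpha_nm > 0)
  if (any(!is.finite(merits))) stop("non-finite merit values")
  curv <- merits[1] - 2 * merits[2] + merits[3]
  if (curv > 0) {
    a_opt <- alpha_nm * (merits[1] - merits[3]) / (2 * curv)
    a_opt <- max(-alpha_nm, min(alpha_nm, a_opt))
    return(structure(a_opt, convex = TRUE))
  }
  samples <- c(-alpha_nm, 0, alpha_nm)
  structure(samples[which.min(merits)], convex = FALSE)
}

#' Run the 3N sensorless correction loop
#'
#' Sequentially optimizes each mode in `modes` for `iterations` passes.
#' For every mode the system is imaged with the current correction plus
#' (+alpha, 0, -alpha) on that mode, the merit parabola vertex is computed,
#' and the correction is moved to the vertex (the merit minimizer).
#'
#' @param system Callable `function(coeffs)` returning an image of a point
#'   source under the given correction coefficients; deterministic systems
#'   give deterministic corrections.
#' @param modes Character vector of mode labels (default the 7-mode set;
#'   see [zernike_modes()]).
#' @param alpha_nm Probe amplitude, nm RMS (default 60).
#' @param iterations Number of full passes (default 3; two to three are
#'   typically sufficient).
#' @param initial Starting correction ([zernike_coeffs()]).
#' @param baseline Camera baseline subtracted in [evaluate_merit()].
#' @param n_average Number of images averaged per merit evaluation (for
#'   noisy systems; default 1).
#' @return Object of class `correction_state`: list with `correction`
#'   (final [zernike_coeffs()]), `log` (one row per mode per iteration:
#'   sampled merits, alpha_opt, convexity flag) and `merit_history` (merit
#'   of the current correction before and after each iteration).
#' @export
run_3n <- function(system, modes = zernike_modes(7), alpha_nm = 60,
                   iterations = 3, initial = zernike_coeffs(),
                   baseline = 0, n_average = 1) {
  stopifnot(length(modes) >= 1, alpha_nm > 0, iterations >= 1)
  bad <- setdiff(modes, .zernike_table$label)
  if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  correction <- zernike_coeffs(coefficients = unclass(initial))
  measure <- function(co) {
    m <- 0
    for (i in seq_len(n_average)) m <- m + evaluate_merit(system(co), baseline)
    m / n_average
  }
  log_rows <- list()
  merit_hist <- measure(correction)
  for (it in seq_len(iterations)) {
    for (mode in modes) {
      probe <- function(da) {
        co <- unclass(correction)
        co[mode] <- co[mode] + da
        zernike_coeffs(coefficients = co)
      }
      merits <- c(measure(probe(-alpha_nm)), measure(probe(0)),
                  measure(probe(alpha_nm)))
      a_opt <- parabola_vertex(merits, alpha_nm)
      if (!attr(a_opt, "convex"))
        warning(sprintf("non-convex merit triplet for mode %s (iteration %d)",
                        mode, it), call. = FALSE)
      co <- unclass(correction)
      co[mode] <- co[mode] + as.numeric(a_opt)
      correction <- zernike_coeffs(coefficients = co)
      log_rows[[length(log_rows) + 1]] <- data.frame(
        iteration = it, mode = mode,
        merit_minus = merits[1], merit_zero = merits[2],
        merit_plus = merits[3], alpha_opt_nm = as.numeric(a_opt),
        convex = attr(a_opt, "convex"), stringsAsFactors = FALSE)
    }
    merit_hist <- c(merit_hist, measure(correction))
  }
  structure(list(correction = correction,
                 log = do.call(rbind, log_rows),
                 merit_history = merit_hist,
                 alpha_nm = alpha_nm, modes = modes),
            class = "correction_state")
}

#' @export
print.correction_state <- function(x, ...) {
  cat(sprintf("3N correction: %d modes, %d iterations (alpha = %g nm RMS)\n",
              length(x$modes), max(x$log$iteration), x$alpha_nm))
  cat(sprintf("  merit %.4g -> %.4g\n", x$merit_history[1],
              x$merit_history[length(x$merit_history)]))
  print(x$correction)
  invisible(x)
}

#' Simulated point-source system for AO correction
#'
#' Builds the callable consumed by [run_3n()]: a fiducial bead imaged under
#' a fixed (unknown to the loop) aberration plus the candidate correction,
#' optionally through the camera model with shot noise.
#'
#' @param aberration True system aberration ([zernike_coeffs()]).
#' @param cfg [optical_config()].
#' @param depth_um Imaging depth (adds depth-proportional spherical).
#' @param photons Expected photons per exposure.
#' @param camera Optional [camera_model()]; `NULL` returns noiseless
#'   expected-photon images.
#' @param shot_noise Shot noise flag when a camera is given.
#' @return `function(correction)` returning an image.
#' @export
make_bead_system <- function(aberration, cfg = optical_config(),
                             depth_um = 0, photons = 2000, camera = NULL,
                             shot_noise = TRUE) {
  force(aberration); force(cfg); force(depth_um); force(photons)
  function(correction) {
    total <- zernike_coeffs(coefficients =
      unclass(aberration) + unclass(correction))
    img <- photons * render_psf(total, z_um = 0, depth_um = depth_um,
                                cfg = cfg)
    if (is.null(camera)) img
    else apply_camera(img, camera, shot_noise = shot_noise)
  }
}
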