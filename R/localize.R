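# Spot detection (a-trous wavelet), anisotropic Gaussian fitting, astigmatic
# z assignment and quality filtering.

# Separable convolution with the B3-spline kernel [1,4,6,4,1]/16 dilated by
# `step` (holes between taps), replicated edges.
.b3_smooth <- function(img, step) {
  h <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * step
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  idx <- function(i, len) pmin(pmax(i, 1L), len)  # clamp (edge replication)
  for (k in seq_along(h)) out <- out + h[k] * img[idx(seq_len(n) + off[k], n), ]
  img2 <- out; out <- matrix(0, n, m)
  for (k in seq_along(h)) out <- out + h[k] * img2[, idx(seq_len(m) + off[k], m)]
  out
}

#' A-trous B3-spline wavelet planes
#'
#' @param img Image matrix.
#' @param levels Number of decomposition levels (default 3).
#' @return List with `planes` (detail planes W1..Wk) and `residual`
#'   (final smooth approximation).
#' @export
atrous_decompose <- function(img, levels = 3) {
  A <- img
  planes <- vector("list", levels)
  for (k in seq_len(levels)) {
    Ak <- .b3_smooth(A, 2L^(k - 1L))
    planes[[k]] <- A - Ak
    A <- Ak
  }
  list(planes = planes, residual = A)
}

#' Detect candidate single-molecule spots
#'
#' Decomposes the frame with the a-trous B3-spline wavelet and thresholds
#' the second detail plane at `threshold_factor` times a robust (MAD-based)
#' noise estimate of that plane. Each connected component above threshold
#' yields one candidate ROI centred on its intensity-weighted centroid.
#'
#' @param frame Baseline-subtracted image matrix.
#' @param threshold_factor Multiplier on the robust noise scale (default 1.5).
#' @param roi_halfwidth Half-width of the square fitting window in pixels
#'   (default 5, i.e. 11 x 11 windows).
#' @param min_area Minimum component area in pixels (default 4).
#' @return data.frame with columns `row`, `col` (1-based centre pixel) and
#'   `peak` (wavelet amplitude); zero rows when nothing is detected.
#'   ROIs whose window would leave the frame are dropped.
#' @export
detect_spots <- function(frame, threshold_factor = 1.5, roi_halfwidth = 5L,
                         min_area = 4L) {
  dec <- atrous_decompose(frame, 3)
  w2 <- dec$planes[[2]]
  noise <- stats::mad(w2)
  thr <- threshold_factor * noise
  bin <- w2 > thr & w2 > 0
  if (!any(bin))
    return(data.frame(row = integer(0), col = integer(0), peak = numeric(0)))
  lab <- EBImage::bwlabel(bin * 1)
  n <- max(lab)
  rows <- integer(0); cols <- integer(0); peaks <- numeric(0)
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    wgt <- w2[px]
    r <- round(sum(px[, 1] * wgt) / sum(wgt))
    c <- round(sum(px[, 2] * wgt) / sum(wgt))
    if (r - roi_halfwidth < 1 || r + roi_halfwidth > nrow(frame) ||
        c - roi_halfwidth < 1 || c + roi_halfwidth > ncol(frame)) next
    rows <- c(rows, r); cols <- c(cols, c); peaks <- c(peaks, max(wgt))
  }
  out <- data.frame(row = rows, col = cols, peak = peaks)
  # non-maximum suppression: wavelet side lobes of a bright PSF can form
  # separate components; keep only the strongest candidate within a window
  if (nrow(out) > 1) {
    out <- out[order(-out$peak), ]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      d <- pmax(abs(out$row[seq_len(i - 1)] - out$row[i]),
                abs(out$col[seq_len(i - 1)] - out$col[i]))
      if (any(keep[seq_len(i - 1)] & d <= 2L * roi_halfwidth - 1L))
        keep[i] <- FALSE
    }
    out <- out[keep, ]
    rownames(out) <- NULL
  }
  out
}

#' Fit an anisotropic 2D Gaussian to an ROI
#'
#' Least-squares fit of
#' `I(x, y) = A * exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2)) + b`
#' by Levenberg-Marquardt. The goodness of fit is reported as the
#' coefficient of determination `chi2 = 1 - SS_res / SS_tot`, clamped to
#' [0, 1], so that 1 is a perfect fit (this is the convention used by the
#' quality filters; it is not the classical chi-square statistic).
#'
#' @param roi Square ROI matrix (>= 9 x 9), baseline-subtracted counts.
#' @param pixel_nm Pixel size in nm.
#' @return List with `x_nm`, `y_nm` (position relative to the centre of the
#'   ROI corner pixel), `sigma_x_nm`, `sigma_y_nm`, `intensity_adu`
#'   (integrated amplitude above offset), `offset`, `chi2`, and `ok`
#'   (FALSE when the fit failed or hit bounds).
#' @export
fit_gaussian <- function(roi, pixel_nm) {
  if (nrow(roi) < 9 || ncol(roi) < 9) stop("ROI must be at least 9 x 9 px")
  ny <- nrow(roi); nx <- ncol(roi)
  xs <- (seq_len(nx) - 1)                 # pixel units
  ys <- (seq_len(ny) - 1)
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  b0 <- min(roi); A0 <- max(roi) - b0
  if (A0 <= 0)
    return(list(x_nm = NA_real_, y_nm = NA_real_, sigma_x_nm = NA_real_,
                sigma_y_nm = NA_real_, intensity_adu = NA_real_,
                offset = b0, chi2 = 0, ok = FALSE))
  w <- pmax(roi - b0, 0)
  x0 <- sum(X * w) / sum(w); y0 <- sum(Y * w) / sum(w)
  sx0 <- sqrt(max(sum(w * (X - x0)^2) / sum(w), 0.25))
  sy0 <- sqrt(max(sum(w * (Y - y0)^2) / sum(w), 0.25))
  resid_fn <- function(p) {
    A <- p[1]; x0 <- p[2]; y0 <- p[3]
    sx <- abs(p[4]); sy <- abs(p[5]); b <- p[6]
    model <- A * exp(-((X - x0)^2) / (2 * sx^2) - ((Y - y0)^2) / (2 * sy^2)) + b
    as.vector(model - roi)
  }
  # non-convergence is reported through the ok flag, not as a warning
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = c(A0, x0, y0, sx0, sy0, b0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(x_nm = NA_real_, y_nm = NA_real_, sigma_x_nm = NA_real_,
                sigma_y_nm = NA_real_, intensity_adu = NA_real_,
                offset = b0, chi2 = 0, ok = FALSE))
  p <- fit$par
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((roi - mean(roi))^2)
  chi2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
  sx <- abs(p[4]); sy <- abs(p[5])
  ok <- is.finite(p[1]) && p[1] > 0 && sx > 0.1 && sy > 0.1 &&
    sx < max(nx, ny) && sy < max(nx, ny) &&
    p[2] > -1 && p[2] < nx && p[3] > -1 && p[3] < ny
  list(x_nm = p[2] * pixel_nm, y_nm = p[3] * pixel_nm,
       sigma_x_nm = sx * pixel_nm, sigma_y_nm = sy * pixel_nm,
       intensity_adu = 2 * pi * p[1] * sx * sy, offset = p[6],
       chi2 = chi2, ok = ok)
}

#' Localize all spots in a frame stack
#'
#' Runs [detect_spots()] and [fit_gaussian()] on every frame, optionally
#' assigns z from an astigmatism calibration, and returns a localization
#' table. Failed (non-converged) fits are dropped.
#'
#' @param stack `frame_stack` from [simulate_acquisition()], or a 3-D array
#'   (frame x y x x) of counts.
#' @param cal Optional [calibrate_astigmatism()] result; when supplied a
#'   `z_um` column is filled via [assign_z()] (NA when out of range).
#' @param camera [camera_model()] whose baseline is subtracted before
#'   detection.
#' @param cfg [optical_config()] (pixel size).
#' @param threshold_factor,roi_halfwidth Passed to [detect_spots()].
#' @param plane_index Plane index stored in the table (defaults to the
#'   stack's own).
#' @return data.frame with columns `loc_id`, `frame` (0-based), `x_nm`,
#'   `y_nm`, `z_um`, `sigma_x_nm`, `sigma_y_nm`, `intensity_adu`, `chi2`,
#'   `plane_index`.
#' @export
localize_stack <- function(stack, cal = NULL, camera = camera_model(),
                           cfg = optical_config(), threshold_factor = 1.5,
                           roi_halfwidth = 5L, plane_index = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (is.null(plane_index))
    plane_index <- if (inherits(stack, "frame_stack")) stack$plane_index else 1L
  px <- cfg$pixel_size_camera_nm
  out <- list()
  for (f in seq_len(dim(frames)[1])) {
    img <- frames[f, , ] - camera$baseline_adu
    spots <- detect_spots(img, threshold_factor, roi_halfwidth)
    if (!nrow(spots)) next
    for (s in seq_len(nrow(spots))) {
      r <- spots$row[s]; c <- spots$col[s]
      roi <- img[(r - roi_halfwidth):(r + roi_halfwidth),
                 (c - roi_halfwidth):(c + roi_halfwidth)]
      fit <- fit_gaussian(roi, px)
      if (!fit$ok) next
      out[[length(out) + 1]] <- data.frame(
        frame = f - 1L,
        x_nm = (c - 1 - roi_halfwidth) * px + fit$x_nm,
        y_nm = (r - 1 - roi_halfwidth) * px + fit$y_nm,
        z_um = NA_real_,
        sigma_x_nm = fit$sigma_x_nm, sigma_y_nm = fit$sigma_y_nm,
        intensity_adu = fit$intensity_adu, chi2 = fit$chi2,
        plane_index = as.integer(plane_index))
    }
  }
  locs <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               z_um = numeric(0), sigma_x_nm = numeric(0),
               sigma_y_nm = numeric(0), intensity_adu = numeric(0),
               chi2 = numeric(0), plane_index = integer(0))
  if (!is.null(cal) && nrow(locs)) {
    z <- assign_z(locs$sigma_x_nm, locs$sigma_y_nm, cal)
    locs$z_um <- as.numeric(z)
    locs$z_um[!attr(z, "in_range")] <- NA_real_
  }
  locs <- cbind(loc_id = seq_len(nrow(locs)), locs)
  rownames(locs) <- NULL
  locs
}

#' Calibrate the astigmatic sigma-z relationship
#'
#' Fits the central bead in every plane of a z-stack acquired with known z
#' steps and builds interpolants sigma_x(z), sigma_y(z). The focus origin
#' z* is defined as the crossing sigma_x(z*) = sigma_y(z*) and subtracted,
#' so that z = 0 is the symmetric focus. sigma_x - sigma_y must be strictly
#' monotone on the usable range, otherwise the calibration is rejected.
#' A symmetry score (normalized L2 distance between sigma_x(z) and
#' sigma_y(-z) about z*) quantifies calibration quality: 0 is perfectly
#' symmetric; spherical aberration degrades it.
#'
#' @param zstack 3-D array (plane x y x x) of counts, one plane per z step,
#'   containing a single bead, or a `frame_stack`.
#' @param z_um Axial position of each plane, um (ascending, spanning at
#'   least +/-0.5 um with steps <= 50 nm).
#' @param camera,cfg As in [localize_stack()].
#' @param usable_range_um Range over which monotonicity is enforced
#'   (default 0.4).
#' @return Object of class `astig_calibration`: z grid, sigma samples,
#'   spline interpolants, `z_star` (raw focus position), `symmetry_score`.
#' @export
calibrate_astigmatism <- function(zstack, z_um, camera = camera_model(),
                                  cfg = optical_config(),
                                  usable_range_um = 0.4) {
  frames <- if (inherits(zstack, "frame_stack")) zstack$frames else zstack
  stopifnot(dim(frames)[1] == length(z_um))
  if (min(z_um) > -0.5 || max(z_um) < 0.5)
    stop("z range must cover at least +/-0.5 um")
  if (max(diff(z_um)) > 0.0501) stop("z step must be <= 50 nm")
  px <- cfg$pixel_size_camera_nm
  sx <- sy <- rep(NA_real_, length(z_um))
  for (f in seq_along(z_um)) {
    img <- frames[f, , ] - camera$baseline_adu
    # bead held at the frame centre: fit a fixed central window
    r <- round(nrow(img) / 2); c <- round(ncol(img) / 2)
    hw <- min(8L, r - 1L, c - 1L, nrow(img) - r - 1L, ncol(img) - c - 1L)
    roi <- img[(r - hw):(r + hw), (c - hw):(c + hw)]
    fit <- fit_gaussian(roi, px)
    if (fit$ok) { sx[f] <- fit$sigma_x_nm; sy[f] <- fit$sigma_y_nm }
  }
  ok <- is.finite(sx) & is.finite(sy)
  if (sum(ok) < 5) stop("too few usable calibration planes")
  z <- z_um[ok]; sx <- sx[ok]; sy <- sy[ok]
  fx_raw <- stats::splinefun(z, sx, method = "natural")
  fy_raw <- stats::splinefun(z, sy, method = "natural")
  d <- function(zz) fx_raw(zz) - fy_raw(zz)
  zg <- seq(min(z), max(z), by = 0.001)
  dz <- d(zg)
  sgn <- sign(dz)
  cross <- which(diff(sgn) != 0)
  if (!length(cross)) stop("calibration rejected: sigma_x - sigma_y never crosses zero")
  i <- cross[which.min(abs(zg[cross]))]
  z_star <- stats::uniroot(d, c(zg[i], zg[i + 1]))$root
  zc <- z - z_star
  usable <- abs(zg - z_star) <= usable_range_um
  dd <- diff(dz[usable])
  if (!(all(dd > 0) || all(dd < 0)))
    stop("calibration rejected: sigma_x - sigma_y not strictly monotone on the usable range")
  # symmetry: compare sigma_x at +dz with sigma_y at -dz about focus
  zs <- seq(-usable_range_um, usable_range_um, by = 0.01)
  a <- fx_raw(z_star + zs); b <- fy_raw(z_star - zs)
  sym <- sqrt(mean((a - b)^2)) / mean(c(a, b))
  structure(list(z_um = zc, sigma_x_nm = sx, sigma_y_nm = sy,
                 fx = stats::splinefun(zc, sx, method = "natural"),
                 fy = stats::splinefun(zc, sy, method = "natural"),
                 z_star = z_star, symmetry_score = sym,
                 usable_range_um = usable_range_um,
                 z_range = range(zc)),
            class = "astig_calibration")
}

#' @export
print.astig_calibration <- function(x, ...) {
  cat(sprintf("Astigmatism calibration: %d planes, z in [%.2f, %.2f] um\n",
              length(x$z_um), x$z_range[1], x$z_range[2]))
  cat(sprintf("  focus at raw z* = %.3f um, symmetry score %.4f\n",
              x$z_star, x$symmetry_score))
  invisible(x)
}

#' Assign axial positions from fitted PSF widths
#'
#' For each (sigma_x, sigma_y) pair, z is the minimizer over a 1 nm grid of
#' the squared distance to the calibration curves,
#' `(sigma_x - sigma_x_cal(z))^2 + (sigma_y - sigma_y_cal(z))^2`,
#' restricted to `|z| <= range_um`. Least squares in sigma space is robust
#' to correlated sigma errors. Minima on the range boundary are flagged
#' out-of-range.
#'
#' @param sigma_x_nm,sigma_y_nm Fitted widths, nm (vectors).
#' @param cal [calibrate_astigmatism()] result.
#' @param range_um Search half-range, um (default 0.5).
#' @return Numeric vector of z (um) with logical attribute `in_range`.
#' @export
assign_z <- function(sigma_x_nm, sigma_y_nm, cal, range_um = 0.5) {
  stopifnot(inherits(cal, "astig_calibration"))
  lo <- max(-range_um, cal$z_range[1])
  hi <- min(range_um, cal$z_range[2])
  zg <- seq(lo, hi, by = 0.001)
  sxg <- cal$fx(zg); syg <- cal$fy(zg)
  n <- length(sigma_x_nm)
  z <- numeric(n); inr <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (sigma_x_nm[i] - sxg)^2 + (sigma_y_nm[i] - syg)^2
    j <- which.min(d2)
    z[i] <- zg[j]
    inr[i] <- j > 1 && j < length(zg)
  }
  structure(z, in_range = inr)
}

#' Filter localizations by quality
#'
#' Keeps localizations with goodness of fit `chi2` in \[0.6, 1\] and axial
#' position `z_um` in \[-0.5, 0.5\] (bounds inclusive). Rows with missing z
#' are removed.
#'
#' @param locs Localization data.frame.
#' @param chi2_range,z_range_um Override the default bounds.
#' @return Filtered data.frame.
#' @export
filter_localizations <- function(locs, chi2_range = c(0.6, 1),
                                 z_range_um = c(-0.5, 0.5)) {
  keep <- locs$chi2 >= chi2_range[1] & locs$chi2 <= chi2_range[2] &
    !is.na(locs$z_um) &
    locs$z_um >= z_range_um[1] & locs$z_um <= z_range_um[2]
  locs[keep, , drop = FALSE]
}
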