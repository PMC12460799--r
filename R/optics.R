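# Scalar Fourier-optics forward model: Zernike-aberrated pupil -> intensity PSF.
#
# Conventions used throughout the package:
#   * lateral coordinates in nm, right handed, origin at the centre of the
#     corner pixel, pixel-centre convention; axial coordinate z in um,
#     positive away from the coverslip; frames are 0-based.
#   * Zernike amplitudes are stored in nm RMS of wavefront error using
#     unit-RMS (Noll-normalized) polynomials, converted to phase radians
#     via 2*pi/lambda.

#' Optical configuration
#'
#' Describes the imaging system used by the PSF forward model: objective NA,
#' emission wavelength, effective camera pixel size in sample space, the
#' pupil grid used for the scalar diffraction computation, and the rate at
#' which first-order spherical aberration grows with imaging depth
#' (refractive-index mismatch).
#'
#' @param numerical_aperture Objective numerical aperture (default 1.27,
#'   water-immersion).
#' @param wavelength_nm Emission wavelength in nm (default 580, Cy3B-like).
#' @param pixel_size_camera_nm Effective camera pixel size in sample space,
#'   nm (default 108 = 6.5 um sCMOS pixel / 60x magnification).
#' @param pupil_grid_size Side of the square pupil grid (even, >= 64).
#' @param depth_spherical_slope_rad_per_um Increase of the first-order
#'   spherical phase term with imaging depth, rad RMS per um (default 0.031).
#' @param refractive_index Immersion/sample refractive index used for the
#'   defocus phase (default 1.33).
#' @param extra_blur_nm Gaussian blur sigma applied to the intensity PSF,
#'   nm (default 100). Accounts for everything the ideal scalar pupil model
#'   omits: the finite size of the 0.1 um fiducial markers, the camera
#'   pixel response, and residual uncorrected system aberrations. The
#'   default places near-focus astigmatic PSF widths in the 130-300 nm
#'   band used for fiducial selection, as observed on real calibrations;
#'   set 0 for the bare diffraction model.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(numerical_aperture = 1.27,
                           wavelength_nm = 580,
                           pixel_size_camera_nm = 108,
                           pupil_grid_size = 64,
                           depth_spherical_slope_rad_per_um = 0.031,
                           refractive_index = 1.33,
                           extra_blur_nm = 100) {
  stopifnot(numerical_aperture > 0, wavelength_nm > 0,
            pixel_size_camera_nm > 0, extra_blur_nm >= 0)
  if (pupil_grid_size < 64 || pupil_grid_size %% 2 != 0)
    stop("pupil_grid_size must be even and >= 64")
  if (numerical_aperture >= refractive_index)
    stop("numerical_aperture must be below the refractive index")
  cfg <- list(numerical_aperture = numerical_aperture,
              wavelength_nm = wavelength_nm,
              pixel_size_camera_nm = pixel_size_camera_nm,
              pupil_grid_size = as.integer(pupil_grid_size),
              depth_spherical_slope_rad_per_um = depth_spherical_slope_rad_per_um,
              refractive_index = refractive_index,
              extra_blur_nm = extra_blur_nm)
  class(cfg) <- "optical_config"
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  NA %.2f, lambda %.0f nm, pixel %.0f nm, pupil grid %d\n",
              x$numerical_aperture, x$wavelength_nm, x$pixel_size_camera_nm,
              x$pupil_grid_size))
  cat(sprintf("  depth spherical slope %.3f rad/um, n = %.2f\n",
              x$depth_spherical_slope_rad_per_um, x$refractive_index))
  invisible(x)
}

# Correctable Zernike modes (piston/tip/tilt/defocus excluded).  (n, m) in
# the standard double-index convention; m < 0 denotes the sin(|m| theta)
# harmonic.  The default 7-mode correction set is the first seven entries.
.zernike_table <- data.frame(
  label = c("astig_v", "astig_o", "coma_v", "coma_h", "spherical",
            "trefoil_v", "trefoil_h", "astig2_v", "astig2_o"),
  n = c(2L, 2L, 3L, 3L, 4L, 3L, 3L, 4L, 4L),
  m = c(2L, -2L, -1L, 1L, 0L, -3L, 3L, 2L, -2L),
  stringsAsFactors = FALSE
)

#' Zernike mode labels
#'
#' @param n_modes Number of modes (7 or 9). The 7-mode set is vertical and
#'   oblique astigmatism, vertical and horizontal coma, first-order
#'   spherical, and vertical and horizontal trefoil; the 9-mode set appends
#'   secondary astigmatism.
#' @return Character vector of mode labels.
#' @export
zernike_modes <- function(n_modes = 7) {
  stopifnot(n_modes %in% c(7, 9))
  .zernike_table$label[seq_len(n_modes)]
}

#' Zernike coefficient set
#'
#' A named wavefront description in nm RMS per mode. Unspecified modes are
#' zero. Amplitudes must be finite; piston/tip/tilt/defocus are not part of
#' the correctable set and are not representable.
#'
#' @param ... Named amplitudes in nm RMS, e.g. `astig_v = 60`.
#' @param coefficients Alternatively, a named numeric vector.
#' @return Object of class `zernike_coeffs` (named numeric over all modes).
#' @export
zernike_coeffs <- function(..., coefficients = NULL) {
  vals <- if (is.null(coefficients)) unlist(list(...)) else coefficients
  out <- stats::setNames(numeric(nrow(.zernike_table)), .zernike_table$label)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals))))
      stop("Zernike amplitudes must be named")
    bad <- setdiff(names(vals), .zernike_table$label)
    if (length(bad))
      stop("unknown Zernike mode(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(vals)))
      stop("Zernike amplitudes must be finite")
    out[names(vals)] <- vals
  }
  class(out) <- "zernike_coeffs"
  out
}

#' @export
print.zernike_coeffs <- function(x, ...) {
  nz <- x[abs(unclass(x)) > 1e-12]
  cat("Zernike coefficients (nm RMS):\n")
  if (!length(nz)) cat("  all zero\n")
  else for (nm in names(nz)) cat(sprintf("  %-10s %8.2f\n", nm, nz[[nm]]))
  invisible(x)
}

# Radial Zernike polynomial R_n^|m|(rho).
.zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

# Unit-RMS (Noll-normalized) Zernike polynomial on (rho, theta).
.zernike_poly <- function(n, m, rho, theta) {
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  rad <- .zernike_radial(n, m, rho)
  if (m > 0) norm * rad * cos(m * theta)
  else if (m < 0) norm * rad * sin(-m * theta)
  else norm * rad
}

.fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr / 2 + 1):nr, 1:(nr / 2)), c((nc / 2 + 1):nc, 1:(nc / 2))]
}

# Pupil context cache: frequency grids, aperture mask, per-mode phase maps
# and the defocus kernel, keyed by the optical configuration.
.pupil_cache <- new.env(parent = emptyenv())

.pupil_context <- function(cfg) {
  key <- paste(cfg$numerical_aperture, cfg$wavelength_nm,
               cfg$pixel_size_camera_nm, cfg$pupil_grid_size,
               cfg$refractive_index, cfg$extra_blur_nm %||% 0, sep = "|")
  ctx <- .pupil_cache[[key]]
  if (!is.null(ctx)) return(ctx)
  N <- cfg$pupil_grid_size
  # FFT-bin frequency step chosen so that the image pixel equals the camera
  # pixel: dk = 1 / (N * pixel).
  dk <- 1 / (N * cfg$pixel_size_camera_nm)
  k1 <- dk * (seq_len(N) - 1 - N / 2)             # centred frequency axis
  KXv <- matrix(rep(k1, each = N), N, N)           # column index -> kx
  KYv <- matrix(rep(k1, times = N), N, N)          # row index -> ky
  KR <- sqrt(KXv^2 + KYv^2)
  kmax <- cfg$numerical_aperture / cfg$wavelength_nm
  mask <- KR <= kmax
  rho <- ifelse(mask, KR / kmax, 0)
  theta <- atan2(KYv, KXv)
  n_med <- cfg$refractive_index
  kz <- sqrt(pmax((n_med / cfg$wavelength_nm)^2 - KR^2, 0))  # cycles/nm
  modes <- vector("list", nrow(.zernike_table))
  names(modes) <- .zernike_table$label
  for (i in seq_len(nrow(.zernike_table))) {
    z <- .zernike_poly(.zernike_table$n[i], .zernike_table$m[i], rho, theta)
    modes[[i]] <- ifelse(mask, z, 0)
  }
  blur <- cfg$extra_blur_nm %||% 0
  otf_blur <- NULL
  if (blur > 0) {
    # Gaussian blur of the intensity PSF applied in the frequency domain
    # (frequencies of the *intensity* image, in fft bin order)
    fgrid <- c(0:(N / 2), (N / 2 - 1):1) / (N * cfg$pixel_size_camera_nm)
    fx <- matrix(rep(fgrid, each = N), N, N)
    fy <- matrix(rep(fgrid, times = N), N, N)
    otf_blur <- exp(-2 * pi^2 * blur^2 * (fx^2 + fy^2))
  }
  ctx <- list(N = N, mask = mask, kx = KXv, ky = KYv, kz = kz,
              modes = modes, n_in_pupil = sum(mask), otf_blur = otf_blur)
  .pupil_cache[[key]] <- ctx
  ctx
}

#' Render an aberrated astigmatic PSF
#'
#' Computes the intensity PSF of a point emitter through a scalar
#' Fourier-optics pupil model `|FT(pupil)|^2`. The wavefront is the sum of
#' the supplied Zernike coefficients plus a first-order spherical term
#' proportional to the imaging depth (slope `cfg$depth_spherical_slope_rad_per_um`,
#' converted from rad RMS to nm RMS via lambda/(2*pi)). Defocus for the
#' emitter's axial offset `z_um` enters through the angular-spectrum
#' propagation phase.
#'
#' @param coeffs [zernike_coeffs()] wavefront (nm RMS per mode).
#' @param z_um Axial offset of the emitter from the nominal focal plane, um
#'   (|z| <= 2).
#' @param depth_um Imaging depth above the coverslip, um (>= 0).
#' @param cfg [optical_config()].
#' @param dx_nm,dy_nm Lateral sub-pixel offset of the emitter from the image
#'   centre pixel, nm.
#' @return Square intensity image (matrix, rows = y) normalized to unit sum,
#'   centred at pixel (N/2+1, N/2+1) for zero offset.
#' @export
render_psf <- function(coeffs, z_um = 0, depth_um = 0, cfg = optical_config(),
                       dx_nm = 0, dy_nm = 0) {
  if (!inherits(coeffs, "zernike_coeffs")) coeffs <- zernike_coeffs(coefficients = coeffs)
  if (any(!is.finite(unclass(coeffs)))) stop("non-finite Zernike coefficients")
  if (abs(z_um) > 2) stop("|z_um| must be <= 2 um")
  if (depth_um < 0) stop("depth_um must be >= 0")
  ctx <- .pupil_context(cfg)
  eff <- unclass(coeffs)
  eff["spherical"] <- eff["spherical"] +
    depth_um * cfg$depth_spherical_slope_rad_per_um *
      cfg$wavelength_nm / (2 * pi)
  phase <- matrix(0, ctx$N, ctx$N)
  k2rad <- 2 * pi / cfg$wavelength_nm
  for (nm in names(eff)) {
    a <- eff[[nm]]
    if (a != 0) phase <- phase + a * k2rad * ctx$modes[[nm]]
  }
  # defocus (angular spectrum) + lateral shift ramps
  phase <- phase + 2 * pi * (z_um * 1000 * ctx$kz +
                             dx_nm * ctx$kx + dy_nm * ctx$ky)
  pupil <- ifelse(ctx$mask, exp(1i * phase), 0 + 0i)
  amp <- stats::fft(.fftshift2(pupil))
  psf <- Re(amp * Conj(amp))
  if (!is.null(ctx$otf_blur))
    psf <- pmax(Re(stats::fft(stats::fft(psf) * ctx$otf_blur,
                              inverse = TRUE)) / length(psf), 0)
  psf <- .fftshift2(psf)
  psf / sum(psf)
}

#' Effective first-order spherical amplitude at depth
#'
#' Bookkeeping helper: the spherical wavefront amplitude seen at a given
#' imaging depth, i.e. the coefficient's own value plus depth times the
#' configured slope (converted rad -> nm RMS via lambda/(2*pi)).
#'
#' @inheritParams render_psf
#' @param unit `"nm"` (RMS wavefront) or `"rad"` (RMS phase).
#' @return Scalar amplitude.
#' @export
effective_spherical <- function(coeffs, depth_um, cfg = optical_config(),
                                unit = c("nm", "rad")) {
  unit <- match.arg(unit)
  nm <- unclass(coeffs)[["spherical"]] +
    depth_um * cfg$depth_spherical_slope_rad_per_um * cfg$wavelength_nm / (2 * pi)
  if (unit == "nm") nm else nm * 2 * pi / cfg$wavelength_nm
}
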