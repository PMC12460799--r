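# Spatial resolution estimation: Fourier ring correlation on even/odd
# localization splits, and FWHM of fiducial localization clusters via
# principal-axis (ellipsoid) projection.

#' Fourier ring correlation curve of two images
#'
#' Correlation of the discrete Fourier transforms of two equally sized 2-D
#' images over concentric single-bin frequency rings.
#'
#' @param img1,img2 Matrices of identical dimensions.
#' @return List with `freq_per_px` (ring frequency, cycles/pixel) and
#'   `frc` (correlation per ring; ring 0 is DC).
#' @export
frc_curve <- function(img1, img2) {
  stopifnot(all(dim(img1) == dim(img2)))
  n <- min(dim(img1))
  F1 <- stats::fft(img1); F2 <- stats::fft(img2)
  ny <- nrow(img1); nx <- ncol(img1)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  FR <- sqrt(outer(fy^2, fx^2, `+`))
  ring <- pmin(round(FR * n), n %/% 2)           # ring index 0..n/2
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2; d2 <- Mod(F2)^2
  idx <- ring + 1L
  s_num <- tapply(num, idx, sum)
  s_d1 <- tapply(d1, idx, sum)
  s_d2 <- tapply(d2, idx, sum)
  k <- as.integer(names(s_num)) - 1L
  frc <- as.numeric(s_num) / sqrt(as.numeric(s_d1) * as.numeric(s_d2))
  frc[!is.finite(frc)] <- 0
  ord <- order(k)
  list(freq_per_px = k[ord] / n, frc = frc[ord])
}

.smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

#' Fourier ring correlation resolution of a reconstruction
#'
#' Splits the localizations into halves by the parity of `loc_id`, renders
#' both halves with identical settings, and computes the FRC per lateral
#' plane of the rendered stack over single-bin frequency rings. The curve
#' is smoothed with a 3-bin moving average and the resolution read as the
#' inverse of the first frequency at which it drops below the criterion
#' (1/7). Curves that never drop below the criterion report the Nyquist
#' floor (2 super-resolution pixels); planes whose curve never rises above
#' it are reported unresolved and excluded from the aggregate.
#'
#' @param volume Assembled localization data.frame (`x_nm`, `y_nm`, `z_nm`,
#'   `loc_id`).
#' @param cfg [render_config()].
#' @param criterion FRC threshold (default 1/7).
#' @param min_per_plane Planes with fewer localizations (per half) than
#'   this are skipped (default 100).
#' @return Object of class `frc_result`: per-plane resolutions (nm), mean,
#'   s.e.m., and the FRC curves.
#' @export
frc_resolution <- function(volume, cfg = render_config(), criterion = 1 / 7,
                           min_per_plane = 100) {
  if (is.null(volume$z_nm)) volume$z_nm <- volume$z_um * 1000
  even <- volume[volume$loc_id %% 2 == 0, , drop = FALSE]
  odd <- volume[volume$loc_id %% 2 == 1, , drop = FALSE]
  pad <- 3 * cfg$blur_lateral_nm
  extent <- list(x = range(volume$x_nm) + c(-pad, pad),
                 y = range(volume$y_nm) + c(-pad, pad),
                 z = range(volume$z_nm) + c(-1, 1) * max(3 * cfg$blur_axial_nm,
                                                         cfg$plane_spacing_nm))
  s_even <- render_volume(even, cfg, extent)
  s_odd <- render_volume(odd, cfg, extent)
  nz <- dim(s_even)[3]
  z_lo <- extent$z[1] + (seq_len(nz) - 1) * cfg$plane_spacing_nm
  res <- rep(NA_real_, nz); status <- character(nz)
  curves <- vector("list", nz)
  floor_nm <- 2 * cfg$sr_pixel_nm
  for (p in seq_len(nz)) {
    n_even <- sum(even$z_nm >= z_lo[p] & even$z_nm < z_lo[p] + cfg$plane_spacing_nm)
    n_odd <- sum(odd$z_nm >= z_lo[p] & odd$z_nm < z_lo[p] + cfg$plane_spacing_nm)
    if (min(n_even, n_odd) < min_per_plane) { status[p] <- "skipped"; next }
    cv <- frc_curve(s_even[, , p], s_odd[, , p])
    curves[[p]] <- cv
    sm <- .smooth3(cv$frc)
    above <- sm[-1] > criterion              # exclude DC ring
    # resolved curves hold above the criterion over a run of rings; an
    # isolated noise spike in a sparse low-frequency ring does not count
    run3 <- above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE)
    if (!any(run3)) { status[p] <- "unresolved"; next }
    below <- which(sm[-1] < criterion)
    first_above <- min(which(run3))
    below <- below[below > first_above]
    if (!length(below)) { res[p] <- floor_nm; status[p] <- "floor"; next }
    k <- below[1] + 1L                       # index into cv (with DC)
    # linear interpolation of the crossing between bins k-1 and k
    f1 <- cv$freq_per_px[k - 1]; f2 <- cv$freq_per_px[k]
    v1 <- sm[k - 1]; v2 <- sm[k]
    fc <- f1 + (criterion - v1) / (v2 - v1) * (f2 - f1)
    res[p] <- max(cfg$sr_pixel_nm / fc, floor_nm)
    status[p] <- "resolved"
  }
  vals <- res[!is.na(res)]
  structure(list(per_plane_nm = res, status = status,
                 mean_nm = if (length(vals)) mean(vals) else NA_real_,
                 sem_nm = if (length(vals) > 1)
                   stats::sd(vals) / sqrt(length(vals)) else NA_real_,
                 n_planes = length(vals), curves = curves,
                 criterion = criterion),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  cat(sprintf("FRC resolution: %.1f +/- %.1f nm (mean +/- s.e.m., n = %d planes)\n",
              x$mean_nm, x$sem_nm, x$n_planes))
  invisible(x)
}

#' Fiducial-cluster FWHM resolution
#'
#' Groups bead localizations into physical beads, fits the principal axes
#' (3-D ellipsoid) of each cloud of at least `min_loc` localizations, and
#' reports the FWHM along each axis as 2.35 times the standard deviation
#' of the projections. The two short axes are lateral, the long axis
#' axial (astigmatic localization is least precise along z); beads whose
#' long axis deviates more than 30 degrees from z are flagged.
#'
#' @param locs Bead localizations (`x_nm`, `y_nm` and `z_nm` or `z_um`).
#' @param group Optional integer vector assigning each row to a bead;
#'   when `NULL`, beads are separated by single linkage at `link_nm`
#'   followed by a second-level density clustering (points above the mean
#'   Voronoi local density, re-linked at `cut_nm`) of any component that
#'   appears multi-modal.
#' @param min_loc Minimum localizations per bead (default 30); smaller
#'   clusters are skipped.
#' @param link_nm,cut_nm Grouping parameters (defaults 150 and 50 nm).
#' @param fwhm_factor FWHM/sigma ratio (default 2.35).
#' @return Object of class `bead_resolution`: per-bead lateral and axial
#'   FWHM, ellipsoid axes, tilt flags, and mean +/- s.e.m. aggregates.
#' @export
bead_fwhm_resolution <- function(locs, group = NULL, min_loc = 30,
                                 link_nm = 150, cut_nm = 50,
                                 fwhm_factor = 2.35) {
  z <- if (!is.null(locs$z_nm)) locs$z_nm else locs$z_um * 1000
  pts <- cbind(locs$x_nm, locs$y_nm, z)
  if (is.null(group)) {
    group <- .linkage_components(pts, link_nm)
    # second-level split: inside each component, high-density cores
    # (above the component mean local density) relinked at the cutting
    # distance separate beads that merged at the first level
    if (nrow(pts) >= 8) {
      ids <- unique(group)
      next_id <- max(group) + 1L
      for (g in ids) {
        sel <- which(group == g)
        if (length(sel) < 2 * min_loc) next
        dens <- tryCatch(voronoi_density(pts[sel, , drop = FALSE])$density,
                         error = function(e) NULL)
        if (is.null(dens)) next
        core <- sel[dens > mean(dens)]
        if (length(core) < 2 * min_loc / 3) next
        sub <- .linkage_components(pts[core, , drop = FALSE], cut_nm)
        if (max(sub) < 2) next
        # reassign all points of the component to the nearest core cluster
        centers <- do.call(rbind, lapply(seq_len(max(sub)), function(s)
          colMeans(pts[core[sub == s], , drop = FALSE])))
        nn <- RANN::nn2(centers, pts[sel, , drop = FALSE], k = 1)
        group[sel] <- next_id + nn$nn.idx[, 1] - 1L
        next_id <- next_id + max(sub)
      }
    }
  }
  rows <- list()
  for (g in unique(group)) {
    p <- pts[group == g, , drop = FALSE]
    if (nrow(p) < min_loc) next
    ctr <- colMeans(p)
    ev <- eigen(stats::cov(p), symmetric = TRUE)
    sdev <- sqrt(pmax(ev$values, 0))          # descending
    fwhm <- fwhm_factor * sdev
    long_axis <- ev$vectors[, 1]
    tilt_deg <- acos(min(1, abs(long_axis[3]))) * 180 / pi
    rows[[length(rows) + 1]] <- data.frame(
      bead = g, n_loc = nrow(p),
      x_nm = ctr[1], y_nm = ctr[2], z_nm = ctr[3],
      fwhm_lateral_nm = mean(fwhm[2:3]),
      fwhm_axial_nm = fwhm[1],
      fwhm_1 = fwhm[1], fwhm_2 = fwhm[2], fwhm_3 = fwhm[3],
      tilt_deg = tilt_deg, tilted = tilt_deg > 30)
  }
  if (!length(rows)) stop("no bead cluster with enough localizations")
  tab <- do.call(rbind, rows)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(beads = tab,
                 lateral_mean_nm = mean(tab$fwhm_lateral_nm),
                 lateral_sem_nm = sem(tab$fwhm_lateral_nm),
                 axial_mean_nm = mean(tab$fwhm_axial_nm),
                 axial_sem_nm = sem(tab$fwhm_axial_nm),
                 n_beads = nrow(tab), fwhm_factor = fwhm_factor),
            class = "bead_resolution")
}

#' @export
print.bead_resolution <- function(x, ...) {
  cat(sprintf("Bead FWHM resolution (n = %d beads):\n", x$n_beads))
  cat(sprintf("  lateral %.1f +/- %.1f nm, axial %.1f +/- %.1f nm (mean +/- s.e.m.)\n",
              x$lateral_mean_nm, x$lateral_sem_nm,
              x$axial_mean_nm, x$axial_sem_nm))
  invisible(x)
}
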