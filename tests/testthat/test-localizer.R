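px <- fix_cfg$pixel_size_camera_nm

test_that("spot detection finds isolated PSFs and nothing on flat frames", {
  expect_equal(nrow(detect_spots(matrix(5, 48, 48))), 0)
  em <- emitters(20 * px, 28 * px, 0, fix_photons_3500adu, kind = "fiducial")
  stk <- simulate_acquisition(em, drift = NULL, coeffs = fix_astig,
                              camera = fix_cam, n_frames = 1, cfg = fix_cfg,
                              fov_px = c(48, 48), seed = 11,
                              background_photons = 2)
  sp <- detect_spots(stk$frames[1, , ] - fix_cam$baseline_adu)
  sp <- sp[order(-sp$peak), ]
  expect_gte(nrow(sp), 1)
  expect_lte(max(abs(c(sp$col[1] - 1 - 20, sp$row[1] - 1 - 28))), 1)
  # two emitters 20 px apart give two distinct candidates
  em2 <- emitters(c(14, 34) * px, c(24, 24) * px, c(0, 0),
                  fix_photons_3500adu, kind = "fiducial")
  stk2 <- simulate_acquisition(em2, drift = NULL, coeffs = fix_astig,
                               camera = fix_cam, n_frames = 1, cfg = fix_cfg,
                               fov_px = c(48, 48), seed = 12,
                               background_photons = 2)
  sp2 <- detect_spots(stk2$frames[1, , ] - fix_cam$baseline_adu)
  sp2 <- sp2[order(-sp2$peak), ]
  expect_gte(nrow(sp2), 2)
  cols <- sort(sp2$col[1:2])
  expect_lte(max(abs(cols - 1 - c(14, 34))), 1)
})

test_that("Gaussian fit recovers noiseless parameters to sub-nm accuracy", {
  xs <- (0:14) * px
  X <- outer(rep(1, 15), xs); Y <- outer(xs, rep(1, 15))
  truth <- list(A = 500, x0 = 7.3 * px, y0 = 6.8 * px, sx = 150, sy = 200,
                b = 10)
  roi <- truth$A * exp(-(X - truth$x0)^2 / (2 * truth$sx^2) -
                         (Y - truth$y0)^2 / (2 * truth$sy^2)) + truth$b
  fit <- fit_gaussian(roi, px)
  expect_true(fit$ok)
  expect_lt(abs(fit$x_nm - truth$x0), 0.5)
  expect_lt(abs(fit$y_nm - truth$y0), 0.5)
  expect_lt(abs(fit$sigma_x_nm - truth$sx), 0.5)
  expect_lt(abs(fit$sigma_y_nm - truth$sy), 0.5)
  expect_gt(fit$chi2, 0.999)
  # isotropic input stays isotropic
  roi_iso <- 500 * exp(-((X - 7 * px)^2 + (Y - 7 * px)^2) / (2 * 160^2))
  fit_iso <- fit_gaussian(roi_iso, px)
  expect_lt(abs(fit_iso$sigma_x_nm - fit_iso$sigma_y_nm), 2)
  # structureless noise has chi2 near zero
  set.seed(1)
  fit_noise <- suppressWarnings(fit_gaussian(matrix(rnorm(225, 0, 5), 15, 15), px))
  expect_lt(fit_noise$chi2, 0.5)
  expect_error(fit_gaussian(matrix(1, 5, 5), px))
})

test_that("astigmatism calibration is symmetric, monotone, and rejects bad stacks", {
  cal <- fix_calibration
  expect_lt(abs(cal$z_star), 0.026)        # focus at stack centre +/- one step
  expect_lt(cal$symmetry_score, 0.02)
  # added spherical aberration degrades the symmetry score (strong
  # spherical destroys monotonicity outright and is rejected)
  zs <- seq(-0.8, 0.8, by = 0.025)
  stk_sph <- simulate_bead_zstack(zs, zernike_coeffs(astig_v = 60,
                                                     spherical = 25),
                                  fix_cam, photons = 20000, cfg = fix_cfg,
                                  seed = 1, shot_noise = FALSE)
  cal_sph <- calibrate_astigmatism(stk_sph, zs, fix_cam, fix_cfg)
  expect_gt(cal_sph$symmetry_score, cal$symmetry_score)
  # the 25 nm step protocol over +/- 1 um is accepted
  zs_fine <- seq(-1, 1, by = 0.025)
  stk_fine <- simulate_bead_zstack(zs_fine, fix_astig, fix_cam,
                                   photons = 20000, cfg = fix_cfg, seed = 1,
                                   shot_noise = FALSE)
  expect_s3_class(calibrate_astigmatism(stk_fine, zs_fine, fix_cam, fix_cfg),
                  "astig_calibration")
  # without astigmatism the width difference never crosses: rejected
  stk_none <- simulate_bead_zstack(zs, zernike_coeffs(), fix_cam,
                                   photons = 20000, cfg = fix_cfg, seed = 1,
                                   shot_noise = FALSE)
  expect_error(calibrate_astigmatism(stk_none, zs, fix_cam, fix_cfg))
})

test_that("z assignment inverts the calibration curves", {
  cal <- fix_calibration
  s0 <- cal$fx(0)
  z0 <- assign_z(s0, cal$fy(0), cal)
  expect_lt(abs(as.numeric(z0)), 0.002)
  z3 <- assign_z(cal$fx(0.3), cal$fy(0.3), cal)
  expect_equal(as.numeric(z3), 0.3, tolerance = 0.002 / 0.3)
  # widths beyond the usable range land on the boundary and are flagged
  zbig <- assign_z(cal$fx(0.49) + 200, cal$fy(0.49) + 300, cal)
  expect_false(attr(zbig, "in_range")[1])
})

test_that("quality filters keep chi2 in [0.6, 1] and |z| <= 0.5 um", {
  locs <- data.frame(chi2 = c(0.7, 0.5, 0.9, 0.6, 1.0),
                     z_um = c(0.3, 0.0, 0.6, -0.5, 0.5))
  kept <- filter_localizations(locs)
  expect_equal(kept$chi2, c(0.7, 0.6, 1.0))
  expect_equal(kept$z_um, c(0.3, -0.5, 0.5))
})

test_that("axial accuracy is below 60 nm across the usable range", {
  cal <- fix_calibration
  set.seed(31)
  n <- 25
  ztrue <- stats::runif(n, -0.4, 0.4)
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- stats::runif(1, 18, 30) * px; y <- stats::runif(1, 18, 30) * px
    em <- emitters(x, y, ztrue[i], fix_photons_3500adu, kind = "fiducial")
    stk <- simulate_acquisition(em, drift = NULL, coeffs = fix_astig,
                                camera = fix_cam, n_frames = 1,
                                cfg = fix_cfg, fov_px = c(48, 48),
                                seed = 500 + i, background_photons = 2)
    locs <- localize_stack(stk, cal, fix_cam, fix_cfg)
    if (!nrow(locs)) next
    j <- which.min((locs$x_nm - x)^2 + (locs$y_nm - y)^2)
    err[i] <- locs$z_um[j] - ztrue[i]
  }
  expect_gt(sum(!is.na(err)), 0.9 * n)
  expect_lt(1000 * sqrt(mean(err^2, na.rm = TRUE)), 60)
})

test_that("localization precision scales as one over root photons", {
  set.seed(41)
  levels <- c(600, 2400, 9600)
  x0 <- 7.35 * px; y0 <- 7.5 * px
  prec <- vapply(levels, function(ph) {
    psf <- ph * render_psf(fix_astig, 0, 0, fix_cfg,
                           dx_nm = x0 - 7 * px, dy_nm = y0 - 7 * px)
    c0 <- nrow(psf) / 2 + 1
    patch <- psf[(c0 - 7):(c0 + 7), (c0 - 7):(c0 + 7)]
    xs <- vapply(1:40, function(r) {
      img <- apply_camera(patch, fix_cam)
      fit <- fit_gaussian(img - fix_cam$baseline_adu, px)
      if (fit$ok) fit$x_nm else NA_real_
    }, numeric(1))
    stats::sd(xs, na.rm = TRUE)
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(log(prec) ~ log(levels)))[2])
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("in-focus localization is unbiased below 2 nm", {
  set.seed(43)
  x0 <- 7.35 * px; y0 <- 7.52 * px
  psf <- fix_photons_3500adu *
    render_psf(fix_astig, 0, 0, fix_cfg, dx_nm = x0 - 7 * px,
               dy_nm = y0 - 7 * px)
  c0 <- nrow(psf) / 2 + 1
  patch <- psf[(c0 - 7):(c0 + 7), (c0 - 7):(c0 + 7)]
  err <- vapply(1:300, function(r) {
    img <- apply_camera(patch, fix_cam)
    fit <- fit_gaussian(img - fix_cam$baseline_adu, px)
    if (fit$ok) fit$x_nm - (x0 - 7 * px + 7 * px) else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(err, na.rm = TRUE)), 2)
})

test_that("detection yield drops beyond the astigmatic axial range", {
  yield <- function(z) {
    hits <- vapply(1:15, function(i) {
      em <- emitters(24 * px, 24 * px, z, fix_photons_3500adu,
                     kind = "fiducial")
      stk <- simulate_acquisition(em, drift = NULL, coeffs = fix_astig,
                                  camera = fix_cam, n_frames = 1,
                                  cfg = fix_cfg, fov_px = c(48, 48),
                                  seed = 900 + i, background_photons = 2)
      locs <- localize_stack(stk, fix_calibration, fix_cam, fix_cfg)
      locs <- filter_localizations(locs)
      any(nrow(locs) > 0 &
            (locs$x_nm - 24 * px)^2 + (locs$y_nm - 24 * px)^2 < 200^2)
    }, logical(1))
    mean(hits)
  }
  expect_lt(yield(0.45), yield(0))
})
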