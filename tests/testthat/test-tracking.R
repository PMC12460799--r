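test_that("fiducial selection applies the width, fit and well filters", {
  locs <- data.frame(loc_id = 1:4, x_nm = c(100, 200, 5000, 300),
                     y_nm = c(100, 200, 5000, 300),
                     z_um = 0, sigma_x_nm = c(200, 120, 210, 190),
                     sigma_y_nm = c(200, 180, 200, 250),
                     chi2 = c(0.8, 0.9, 0.9, 0.9), intensity_adu = 1000,
                     frame = 0, plane_index = 1)
  # bead 2 fails the 130 nm lower bound; bead 3 sits inside the well
  well <- list(x = c(4000, 6000), y = c(4000, 6000))
  sel <- select_fiduciary(locs, well)
  expect_equal(sel$loc_id, 1)
  # between two in-band candidates, the one closest to focus wins
  locs2 <- data.frame(loc_id = 1:2, x_nm = c(100, 200), y_nm = c(100, 200),
                      z_um = 0, sigma_x_nm = c(200, 160),
                      sigma_y_nm = c(210, 220),
                      chi2 = c(0.7, 0.95), intensity_adu = 1000,
                      frame = 0, plane_index = 1)
  an <- abs(locs2$sigma_x_nm - locs2$sigma_y_nm)
  expect_equal(select_fiduciary(locs2)$loc_id, locs2$loc_id[which.min(an)])
  # no candidate -> NULL
  expect_null(select_fiduciary(locs[2, , drop = FALSE]))
})

test_that("drift metric is the Euclidean distance to the reference", {
  expect_equal(compute_drift(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(compute_drift(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_drift(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_error(compute_drift(c(0, 0), c(1, 2, 2)))
})

test_that("feedback step averages, thresholds and re-references", {
  tr <- bead_track(c(0, 0, 0), W = 1, threshold_nm = 0)
  st <- feedback_step(tr, c(0, 0, 0), frame = 0)
  expect_null(st$correction)              # d = 0 is not > 0
  st2 <- feedback_step(st$track, c(10, 0, 0), frame = 1)
  expect_equal(st2$correction, c(-10, 0, 0))
  # a displaced estimate below the threshold issues nothing
  tr3 <- bead_track(c(0, 0, 0), W = 1, threshold_nm = 20)
  st3 <- feedback_step(tr3, c(10, 0, 0), frame = 0)
  expect_null(st3$correction)
  # lost bead accounting
  tr4 <- bead_track(c(0, 0, 0), W = 1, max_misses = 2)
  s <- feedback_step(tr4, NULL, 0)
  expect_false(s$track$aborted)
  s <- feedback_step(s$track, NULL, 1)
  expect_true(s$track$aborted)
})

test_that("closed loop cancels linear drift within the noise floor", {
  drift <- drift_trajectory(1000, rate_nm_per_frame = c(0.1, 0, 0))
  sim <- simulate_feedback_loop(drift, precision_nm = 6, W = 10, seed = 3)
  # analytic floor: 2 sigma / sqrt(W) plus the per-window tracking lag
  bound <- 2 * 6 / sqrt(10) + 0.1 * 10
  expect_lt(max(sim$residual_rms), bound)
  # bookkeeping: residual minus applied stage equals the injected drift
  recon <- sim$residual - sim$stage_at_frame
  expect_lt(max(abs(recon - as.matrix(drift))), 1e-9)
})

test_that("longer averaging windows reduce the residual under white noise", {
  drift <- drift_trajectory(1000, rate_nm_per_frame = c(0.1, 0, 0))
  rms <- vapply(c(1, 5, 10), function(W)
    sqrt(mean(simulate_feedback_loop(drift, precision_nm = 6, W = W,
                                     seed = 5)$residual^2)),
    numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("the loop stays bounded over long acquisitions", {
  drift <- drift_trajectory(10000, rate_nm_per_frame = c(1, 0.5, -1))
  sim <- simulate_feedback_loop(drift, precision_nm = 10, W = 10, seed = 7)
  expect_lt(max(abs(sim$residual)), 100)
})

test_that("multi-plane acquisition sequences planes and skips bead-less ones", {
  config <- default_config()
  config$plan$n_planes <- 3
  config$plan$frames_per_plane <- 15
  config$scene$n_sites <- 30
  scene <- synthetic_cell_scene(config)
  cfg <- do.call(optical_config, config$optical)
  camera <- do.call(camera_model, config$camera)
  coeffs <- zernike_coeffs(astig_v = 60)
  sim_scene <- list(molecules = scene$molecules, fiducials = scene$fiducials,
                    coeffs = coeffs, camera = camera, cfg = cfg,
                    kinetics = blink_kinetics(0.01, 3),
                    cal = fix_calibration,
                    fov_px = c(config$scene$fov_px, config$scene$fov_px),
                    background_photons = 2, depth_um = 0,
                    drift_rate_nm = c(0, 0, 0))
  plan <- acquisition_plan(0, 3, 350, 15, well_box_nm = scene$well_box_nm)
  acq <- run_volume_acquisition(plan, sim_scene, seed = 9)
  expect_equal(length(acq$planes), 3)
  expect_equal(vapply(acq$planes, `[[`, numeric(1), "plane_z_um"),
               c(0, 0.35, 0.70))
  for (p in acq$planes) expect_gt(nrow(p$track$positions), 10)
  # beads in focus at planes 1 and 3 only: at plane 2 (0.35 um away) the
  # wide astigmatic arm exceeds the 300 nm bound, so no candidate remains
  sim_scene2 <- sim_scene
  sim_scene2$fiducials$z_um <- c(0, 0, 0.70, 0.70)
  acq2 <- run_volume_acquisition(plan, sim_scene2, seed = 9)
  expect_equal(acq2$skipped, 2L)
  expect_equal(length(acq2$planes), 2)
})

test_that("image-level closed loop leaves small per-plane residual drift", {
  config <- default_config()
  config$plan$n_planes <- 1
  config$plan$frames_per_plane <- 120
  config$scene$n_sites <- 20
  scene <- synthetic_cell_scene(config)
  cfg <- do.call(optical_config, config$optical)
  camera <- do.call(camera_model, config$camera)
  sim_scene <- list(molecules = scene$molecules, fiducials = scene$fiducials,
                    coeffs = zernike_coeffs(astig_v = 60), camera = camera,
                    cfg = cfg, kinetics = blink_kinetics(0.005, 3),
                    cal = fix_calibration,
                    fov_px = c(config$scene$fov_px, config$scene$fov_px),
                    background_photons = 2, depth_um = 0,
                    drift_rate_nm = c(0.3, 0.1, -0.3))
  plan <- acquisition_plan(0, 1, 350, 120, well_box_nm = scene$well_box_nm)
  acq <- run_volume_acquisition(plan, sim_scene, seed = 13)
  p <- acq$planes[[1]]
  resid <- p$stack$ground_truth$drift + p$stack$ground_truth$stage
  # discard the start-up transient of the first averaging window
  resid <- resid[-(1:20), , drop = FALSE]
  # analytic noise floor from the measured per-frame bead precision:
  # 2 sigma / sqrt(W) plus the tracking lag over one averaging window
  tr <- p$track$positions
  sm <- apply(tr, 2, function(v) stats::filter(v, rep(1 / 10, 10),
                                               sides = 1))
  prec <- apply(tr[11:nrow(tr), ] - sm[10:(nrow(tr) - 1), ], 2, stats::sd)
  lag <- abs(sim_scene$drift_rate_nm) * (plan$W + 1) / 2
  bound <- 2 * prec / sqrt(plan$W) + lag + 2
  expect_lt(sqrt(mean(resid[, 3]^2)), bound[3])    # axial
  expect_lt(sqrt(mean(resid[, 1]^2)), bound[1])    # lateral
  expect_lt(sqrt(mean(resid[, 2]^2)), bound[2])
  expect_lt(max(abs(resid)), 100)                  # loop never diverges
})
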