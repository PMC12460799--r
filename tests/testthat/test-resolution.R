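# simulated filament field: points along random 3-D line segments with
# localization noise, duplicated so even/odd halves sample one structure
make_filament_volume <- function(n_per_fil = 400, n_fil = 6, noise_nm = 10,
                                 seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(n_fil), function(i) {
    a <- runif(2, 500, 3500); b <- runif(2, 500, 3500)
    t <- runif(n_per_fil)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
          runif(1, 80, 120))
  }))
  pts <- pts[rep(seq_len(nrow(pts)), each = 2), ]
  pts[, 1:2] <- pts[, 1:2] + rnorm(length(pts[, 1:2]), 0, noise_nm)
  data.frame(loc_id = seq_len(nrow(pts)), x_nm = pts[, 1], y_nm = pts[, 2],
             z_nm = pts[, 3])
}

test_that("FRC of identical halves sits at the Nyquist floor", {
  set.seed(2)
  base <- data.frame(x_nm = runif(800, 0, 3000), y_nm = runif(800, 0, 3000),
                     z_nm = 100)
  # duplicate every localization with consecutive ids: parity halves equal
  vol <- base[rep(1:800, each = 2), ]
  vol$loc_id <- seq_len(nrow(vol))
  r <- frc_resolution(vol, render_config())
  expect_equal(r$mean_nm, 2 * 10)
  expect_true(all(r$status[!is.na(r$per_plane_nm)] == "floor"))
})

test_that("halves without shared structure are reported unresolved", {
  # two independent pure-noise images never hold above the criterion
  set.seed(3)
  cv <- frc_curve(matrix(rnorm(200 * 200), 200), matrix(rnorm(200 * 200), 200))
  above <- cv$frc[-1] > 1 / 7
  run3 <- above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE)
  expect_false(any(run3))
  # localization halves drawn from disjoint regions share no structure
  vol <- data.frame(loc_id = 1:2000,
                    x_nm = c(runif(1000, 0, 900), runif(1000, 1100, 2000)),
                    y_nm = runif(2000, 0, 2000), z_nm = 100)
  vol$loc_id <- c(seq(2, 2000, 2), seq(1, 1999, 2))  # even left, odd right
  r <- frc_resolution(vol, render_config())
  expect_true(all(r$status %in% c("unresolved", "skipped")))
  expect_equal(r$n_planes, 0)
})

test_that("FRC resolution matches the total smoothing kernel on filaments", {
  vol <- make_filament_volume(noise_nm = 10, seed = 4)
  r <- frc_resolution(vol, render_config())
  expect_gte(r$n_planes, 1)
  expected <- 2.35 * sqrt(10^2 + 10^2)    # localization noise (+) render blur
  expect_lt(abs(r$mean_nm - expected) / expected, 0.3)
})

test_that("FRC resolution degrades monotonically with localization noise", {
  res <- vapply(c(5, 15, 30), function(s) {
    frc_resolution(make_filament_volume(noise_nm = s, seed = 7),
                   render_config())$mean_nm
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("parity split is balanced", {
  vol <- data.frame(loc_id = 1:1001, x_nm = 0, y_nm = 0, z_nm = 0)
  expect_lte(abs(sum(vol$loc_id %% 2 == 0) - sum(vol$loc_id %% 2 == 1)), 1)
})

test_that("bead FWHM equals 2.35 times the projection sd", {
  set.seed(11)
  n <- 5000
  cloud <- data.frame(x_nm = rnorm(n, 0, 20), y_nm = rnorm(n, 0, 20),
                      z_nm = rnorm(n, 0, 20))
  r <- bead_fwhm_resolution(cloud, group = rep(1L, n))
  fw <- unlist(r$beads[1, c("fwhm_1", "fwhm_2", "fwhm_3")])
  expect_equal(unname(fw), rep(2.35 * 20, 3), tolerance = 0.05)
  # the reported FWHM over the empirical projection sd is exactly 2.35
  p <- cbind(cloud$x_nm, cloud$y_nm, cloud$z_nm)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  sd1 <- stats::sd(p %*% ev$vectors[, 1])
  expect_equal(r$beads$fwhm_1[1] / sd1, 2.35, tolerance = 1e-9)
})

test_that("anisotropic clouds give the scaled lateral and axial FWHM", {
  set.seed(12)
  n <- 5000
  cloud <- data.frame(x_nm = rnorm(n, 0, 6), y_nm = rnorm(n, 0, 6),
                      z_nm = rnorm(n, 0, 17))
  r <- bead_fwhm_resolution(cloud, group = rep(1L, n))
  expect_equal(r$lateral_mean_nm, 2.35 * 6, tolerance = 0.05)
  expect_equal(r$axial_mean_nm, 2.35 * 17, tolerance = 0.05)
  expect_false(r$beads$tilted[1])
})

test_that("bead FWHM estimator is rotation equivariant", {
  set.seed(13)
  n <- 2000
  p <- cbind(rnorm(n, 0, 5), rnorm(n, 0, 9), rnorm(n, 0, 16))
  # random rotation via QR of a Gaussian matrix
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  pr <- p %*% t(Q)
  r1 <- bead_fwhm_resolution(data.frame(x_nm = p[, 1], y_nm = p[, 2],
                                        z_nm = p[, 3]), group = rep(1L, n))
  r2 <- bead_fwhm_resolution(data.frame(x_nm = pr[, 1], y_nm = pr[, 2],
                                        z_nm = pr[, 3]), group = rep(1L, n))
  f1 <- sort(unlist(r1$beads[1, c("fwhm_1", "fwhm_2", "fwhm_3")]))
  f2 <- sort(unlist(r2$beads[1, c("fwhm_1", "fwhm_2", "fwhm_3")]))
  expect_lt(max(abs(f1 - f2) / f1), 0.01)
})

test_that("beads are separated and small clusters skipped", {
  set.seed(14)
  mk <- function(cx, cy, n) data.frame(x_nm = rnorm(n, cx, 7),
                                       y_nm = rnorm(n, cy, 7),
                                       z_nm = rnorm(n, 0, 20))
  locs <- rbind(mk(0, 0, 80), mk(600, 0, 60), mk(3000, 3000, 10))
  r <- bead_fwhm_resolution(locs, min_loc = 30)
  expect_equal(r$n_beads, 2)
  expect_error(bead_fwhm_resolution(mk(0, 0, 10), min_loc = 30))
})
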