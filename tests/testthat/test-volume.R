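test_that("residual drift correction subtracts the smoothed bead trajectory", {
  # constant bead trajectory: localizations unchanged
  tr <- data.frame(frame = 0:99, x_nm = 5, y_nm = -3, z_nm = 10)
  locs <- data.frame(loc_id = 1:10, frame = seq(0, 99, length.out = 10),
                     x_nm = 100, y_nm = 200, z_um = 0.1, plane_index = 1)
  out <- correct_residual_drift(locs, tr, W = 10)
  expect_equal(out$x_nm, locs$x_nm)
  expect_equal(out$z_um, locs$z_um)
  # linear residual on a static emitter: lateral RMS shrinks >= 4x
  set.seed(8)
  n <- 200
  resid <- seq(0, 20, length.out = n)
  tr2 <- data.frame(frame = 0:(n - 1), x_nm = 1000 + resid,
                    y_nm = 1000, z_nm = 0)
  locs2 <- data.frame(loc_id = 1:n, frame = 0:(n - 1),
                      x_nm = 500 + resid + rnorm(n, 0, 0.5),
                      y_nm = 500, z_um = 0, plane_index = 1)
  out2 <- correct_residual_drift(locs2, tr2, W = 10)
  expect_gt(stats::sd(locs2$x_nm) / stats::sd(out2$x_nm), 4)
  # applied to the bead itself, the trajectory variance strictly decreases
  bead_locs <- data.frame(loc_id = 1:n, frame = 0:(n - 1),
                          x_nm = tr2$x_nm, y_nm = tr2$y_nm,
                          z_um = tr2$z_nm / 1000, plane_index = 1)
  bead_out <- correct_residual_drift(bead_locs, tr2, W = 10)
  expect_lt(stats::var(bead_out$x_nm), stats::var(bead_locs$x_nm))
  expect_warning(correct_residual_drift(locs, NULL), "passed through")
})

test_that("plane registration recovers shifts from shared fiducials", {
  set.seed(2)
  b1 <- data.frame(x_nm = runif(6, 0, 5000), y_nm = runif(6, 0, 5000))
  expect_equal(register_planes(b1, b1)$shift_nm, c(0, 0))
  b2 <- data.frame(x_nm = b1$x_nm - 12, y_nm = b1$y_nm + 7)
  r <- register_planes(b1, b2)
  expect_equal(r$shift_nm, c(12, -7), tolerance = 1e-12)
  expect_equal(r$n_shared, 6)
  expect_error(register_planes(b1[1, , drop = FALSE],
                               b2[4, , drop = FALSE]),
               "fewer than 2")
  # Monte-Carlo: per-bead noise sigma = 6 nm, n = 8 beads -> shift error
  # RMS ~ 6 / sqrt(8) per axis over 100 seeded repeats
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    b <- data.frame(x_nm = runif(8, 0, 5000), y_nm = runif(8, 0, 5000))
    bb <- data.frame(x_nm = b$x_nm + rnorm(8, 0, 6) - 30,
                     y_nm = b$y_nm + rnorm(8, 0, 6) + 15)
    register_planes(b, bb)$shift_nm - c(30, -15)
  }, numeric(2))
  rms <- sqrt(mean(errs^2))
  expect_lt(abs(rms - 6 / sqrt(8)) / (6 / sqrt(8)), 0.25)
})

test_that("volume assembly applies the (i-1) dz vertical offsets", {
  p1 <- data.frame(loc_id = 1, frame = 0, x_nm = 0, y_nm = 0, z_um = 0.2,
                   plane_index = 1)
  p5 <- data.frame(loc_id = 1, frame = 0, x_nm = 0, y_nm = 0, z_um = -0.15,
                   plane_index = 5)
  v <- assemble_volume(list(p1, p5), 350)
  expect_equal(v$z_nm, c(200, -150 + 4 * 350))
  expect_equal(v$loc_id, 1:2)
  # one static emitter seen at +0.2 / -0.15 in consecutive planes is 350 nm
  # apart after assembly
  p2 <- p5; p2$plane_index <- 2
  v2 <- assemble_volume(list(p1, p2), 350)
  expect_equal(diff(v2$z_nm), 350 - 350)  # same physical z
})

test_that("registration and assembly commute with a global translation", {
  set.seed(5)
  beads <- data.frame(x_nm = runif(5, 0, 4000), y_nm = runif(5, 0, 4000))
  mk <- function(dx, dy, plane) {
    locs <- data.frame(loc_id = 1:20, frame = 0:19,
                       x_nm = runif(20, 0, 4000) , y_nm = runif(20, 0, 4000),
                       z_um = runif(20, -0.4, 0.4), plane_index = plane)
    locs
  }
  l1 <- mk(0, 0, 1); l2 <- mk(0, 0, 2)
  b2 <- data.frame(x_nm = beads$x_nm - 9, y_nm = beads$y_nm + 4)
  reg <- register_planes(beads, b2, l2)
  v <- assemble_volume(list(l1, reg$locs), 350)
  shift <- c(123, -77)
  tr <- function(d) { d$x_nm <- d$x_nm + shift[1]; d$y_nm <- d$y_nm + shift[2]; d }
  reg_t <- register_planes(tr(beads), tr(b2), tr(l2))
  v_t <- assemble_volume(list(tr(l1), reg_t$locs), 350)
  expect_equal(v_t$x_nm, v$x_nm + shift[1], tolerance = 1e-9)
  expect_equal(v_t$y_nm, v$y_nm + shift[2], tolerance = 1e-9)
  expect_equal(v_t$z_nm, v$z_nm)
})

test_that("axial CV is the population sd over mean of the bin counts", {
  v <- data.frame(z_nm = c(rep(100, 100), rep(300, 300)))
  expect_equal(as.numeric(axial_cv(v, 200)), 0.5)
  v2 <- data.frame(z_nm = rep(c(100, 300, 500), each = 50))
  expect_equal(as.numeric(axial_cv(v2, 200)), 0)
  expect_error(axial_cv(data.frame(z_nm = numeric(0))))
})

test_that("volume rendering deposits normalized anisotropic Gaussians", {
  cfg <- render_config()
  vol <- data.frame(x_nm = 500, y_nm = 500, z_nm = 100)
  ext <- list(x = c(0, 1000), y = c(0, 1000), z = c(0, 200))
  img <- render_volume(vol, cfg, ext)
  expect_equal(sum(img), 1, tolerance = 1e-9)
  pl <- img[, , 1]
  pk <- which(pl == max(pl), arr.ind = TRUE)[1, ]
  prof <- pl[pk[1], ]
  xs <- (seq_along(prof) - 0.5) * cfg$sr_pixel_nm
  fine <- stats::approx(xs, prof, xout = seq(400, 600, 0.1))
  fwhm <- diff(range(fine$x[fine$y > max(prof) / 2]))
  expect_equal(fwhm, 2.355 * cfg$blur_lateral_nm, tolerance = 0.15)
  # empty input gives a zero stack; doubling localizations doubles intensity
  expect_true(all(render_volume(vol[0, ], cfg, ext) == 0))
  img2 <- render_volume(rbind(vol, vol), cfg, ext)
  expect_equal(sum(img2), 2 * sum(img), tolerance = 1e-9)
})

test_that("grid filter removes the camera-pixel frequency and nothing else", {
  n <- 216; zoom <- 10.8                  # 108 nm camera pixel, 10 nm SR pixel
  xs <- seq_len(n) - 1
  grid <- outer(rep(1, n), cos(2 * pi * xs / zoom))
  img <- 5 + grid
  filt <- remove_grid_artifact(img, 108, zoom)
  expect_lt(sum((filt - 5)^2) / sum(grid^2), 1e-6)
  expect_equal(mean(filt), 5, tolerance = 1e-12)   # DC preserved
  # an image with no energy at the targeted bins passes through unchanged
  set.seed(3)
  clean <- matrix(rnorm(n * n), n, n)
  ref <- remove_grid_artifact(clean, 108, zoom)
  again <- remove_grid_artifact(ref, 108, zoom)
  expect_lt(max(abs(again - ref)) / max(abs(ref)), 1e-10)
  expect_error(remove_grid_artifact(matrix(0, 8, 8), 108, 10.8))
})
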