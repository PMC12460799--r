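test_that("Voronoi density is exact on a cubic lattice and scales correctly", {
  a <- 20
  g <- as.matrix(expand.grid(x = 0:6, y = 0:6, z = 0:6)) * a
  vd <- voronoi_density(g, pad_nm = a / 2)
  interior <- rowSums(g >= 2 * a & g <= 4 * a) == 3
  expect_lt(max(abs(vd$density[interior] * a^3 - 1)), 1e-6)
  expect_lt(max(abs(vd$volume[interior] / a^3 - 1)), 1e-6)
  # doubling all coordinates divides densities by 8
  vd2 <- voronoi_density(g * 2, pad_nm = a)
  expect_equal(vd2$density[interior], vd$density[interior] / 8,
               tolerance = 1e-9)
  expect_error(voronoi_density(cbind(runif(10), runif(10), 0)),
               "coplanar")
})

test_that("mean Voronoi density of a uniform cloud matches n over volume", {
  set.seed(4)
  m <- 600
  pts <- cbind(runif(m, 0, 1000), runif(m, 0, 1000), runif(m, 0, 1000))
  vd <- voronoi_density(pts)
  expect_lt(abs(mean(vd$density) / (m / 1e9) - 1), 0.05)
})

test_that("cluster detection matches the stated thresholds and an oracle", {
  set.seed(21)
  cl <- cbind(rnorm(200, 0, 25), rnorm(200, 0, 25), rnorm(200, 0, 60))
  bg <- cbind(runif(100, -2000, 2000), runif(100, -2000, 2000),
              runif(100, -2000, 2000))
  locs <- data.frame(x_nm = c(cl[, 1], bg[, 1]), y_nm = c(cl[, 2], bg[, 2]),
                     z_nm = c(cl[, 3], bg[, 3]))
  det <- detect_clusters(locs)
  expect_equal(nrow(det$stats), 1)
  expect_gte(det$stats$n_loc, 180)
  # brute-force oracle: connected components of the full <= 50 nm distance
  # graph over the density-filtered points
  ann <- compute_local_density(locs)
  keep <- which(ann$density > nrow(locs) / sum(ann$cell_volume))
  d <- as.matrix(stats::dist(cbind(locs$x_nm, locs$y_nm, locs$z_nm)[keep, ]))
  adj <- d <= 50
  comp <- rep(0L, length(keep)); cid <- 0L
  for (i in seq_along(keep)) {
    if (comp[i] > 0) next
    cid <- cid + 1L; queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  oracle_sizes <- sort(table(comp)[table(comp) >= 10], decreasing = TRUE)
  expect_equal(sort(det$stats$n_loc, decreasing = TRUE),
               as.integer(oracle_sizes))
  # a 9-point blob is below the minimum size
  set.seed(22)
  l9 <- data.frame(x_nm = c(rnorm(9, 0, 10), runif(60, -3000, 3000)),
                   y_nm = c(rnorm(9, 0, 10), runif(60, -3000, 3000)),
                   z_nm = c(rnorm(9, 0, 10), runif(60, -3000, 3000)))
  expect_equal(nrow(detect_clusters(l9)$stats), 0)
  # two blobs 300 nm apart cannot link across 50 nm
  set.seed(23)
  l2 <- data.frame(x_nm = c(rnorm(50, 0, 15), rnorm(50, 300, 15)),
                   y_nm = rnorm(100, 0, 15), z_nm = rnorm(100, 0, 15))
  expect_equal(nrow(detect_clusters(l2)$stats), 2)
})

test_that("cluster detection is invariant to rigid motions", {
  set.seed(24)
  locs <- data.frame(x_nm = c(rnorm(60, 0, 20), runif(80, -1500, 1500)),
                     y_nm = c(rnorm(60, 0, 20), runif(80, -1500, 1500)),
                     z_nm = c(rnorm(60, 0, 20), runif(80, -1500, 1500)))
  d0 <- detect_clusters(locs)
  Q <- qr.Q(qr(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  p <- as.matrix(locs) %*% t(Q)
  locs_r <- data.frame(x_nm = p[, 1] + 5000, y_nm = p[, 2] - 2000,
                       z_nm = p[, 3] + 100)
  d1 <- detect_clusters(locs_r)
  expect_equal(nrow(d1$stats), nrow(d0$stats))
  expect_equal(sort(d1$stats$n_loc), sort(d0$stats$n_loc))
})

test_that("sphere fitting recovers exact and noisy spheres", {
  set.seed(3)
  u <- matrix(rnorm(1500), 500, 3); u <- u / sqrt(rowSums(u^2))
  ctr <- c(1000, 2000, 3000)
  exact <- sweep(u * 5000, 2, ctr, `+`)
  sf <- fit_sphere(exact)
  expect_lt(max(abs(sf$center - ctr)) / 5000, 1e-6)
  expect_lt(abs(sf$radius_nm - 5000) / 5000, 1e-6)
  noisy <- sweep((5000 + rnorm(500, 0, 50)) * u, 2, ctr, `+`)
  sfn <- fit_sphere(noisy)
  expect_lt(sqrt(sum((sfn$center - ctr)^2)), 3 * 50 / sqrt(500))
  expect_equal(sfn$rms_residual_nm, 50, tolerance = 0.15)
  expect_error(fit_sphere(matrix(1, 5, 3)))
})

test_that("spherical Voronoi map partitions the sphere surface", {
  # octahedral symmetry: six equal cells
  cen <- data.frame(x_nm = c(5000, -5000, 0, 0, 0, 0),
                    y_nm = c(0, 0, 5000, -5000, 0, 0),
                    z_nm = c(0, 0, 0, 0, 5000, -5000))
  fit <- structure(list(center = c(0, 0, 0), radius_nm = 5000,
                        rms_residual_nm = 0, n = 6), class = "sphere_fit")
  map <- project_to_sphere_map(cen, fit)
  expect_equal(map$cell_area_um2, rep(4 * pi * 25 / 6, 6), tolerance = 1e-9)
  expect_equal(sum(map$cell_area_um2), 4 * pi * 25, tolerance = 1e-9)
  # density x area integrates back to the cluster count
  expect_equal(sum(map$clusters$surface_density_per_um2 *
                     map$cell_area_um2), 6, tolerance = 1e-9)
  # uniformly spread clusters have lower surface-density CV than a
  # clumped arrangement of the same size
  set.seed(31)
  n <- 60
  uu <- matrix(rnorm(3 * n), n, 3); uu <- uu / sqrt(rowSums(uu^2))
  even_map <- project_to_sphere_map(
    data.frame(x_nm = 5000 * uu[, 1], y_nm = 5000 * uu[, 2],
               z_nm = 5000 * uu[, 3]), fit)
  clump <- uu
  clump[1:40, ] <- clump[1:40, ] / 4 +
    matrix(rep(c(1, 0, 0), each = 40), 40, 3)
  clump <- clump / sqrt(rowSums(clump^2))
  clump_map <- project_to_sphere_map(
    data.frame(x_nm = 5000 * clump[, 1], y_nm = 5000 * clump[, 2],
               z_nm = 5000 * clump[, 3]), fit)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(even_map$clusters$surface_density_per_um2),
            cv(clump_map$clusters$surface_density_per_um2))
})

test_that("property-vs-z regression reports slope and R squared", {
  z <- seq(100, 5000, length.out = 50)
  tab <- data.frame(z_nm = z, d_r_nm = 2 * z, d_z_nm = 7,
                    n_loc = rep(5L, 50), volume_nm3 = 1)
  r <- props_vs_z_regression(tab)
  expect_equal(r$slope[r$property == "d_r_nm"], 2, tolerance = 1e-12)
  expect_equal(r$r_squared[r$property == "d_r_nm"], 1, tolerance = 1e-12)
  expect_equal(r$slope[r$property == "d_z_nm"], 0)
  expect_equal(r$r_squared[r$property == "d_z_nm"], 0)
  # a z-independent property over many clusters stays below the
  # homogeneity criterion R^2 <= 0.03 (E[R^2] = 1/(n-1) under the null)
  set.seed(41)
  tab2 <- data.frame(z_nm = runif(1000, 0, 10000),
                     d_r_nm = rnorm(1000, 50, 5),
                     d_z_nm = rnorm(1000, 120, 10),
                     n_loc = rpois(1000, 30),
                     volume_nm3 = rnorm(1000, 1e5, 1e4))
  r2 <- props_vs_z_regression(tab2)
  expect_true(all(r2$r_squared < 0.03))
  expect_error(props_vs_z_regression(tab2[1:5, ]))
  tab3 <- tab2; tab3$z_nm <- 7
  expect_error(props_vs_z_regression(tab3))
})
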