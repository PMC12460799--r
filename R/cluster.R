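# Voronoi-density clustering of 3-D localization clouds, per-cluster
# quantification, best-fit-sphere membrane projection, and property-vs-z
# homogeneity regression.

# Single-linkage connected components with link distance <= cut (grid-based
# neighbor search, no full distance matrix).
.linkage_components <- function(pts, cut) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  k <- min(n, 16)
  repeat {
    nn <- RANN::nn2(pts, pts, k = k, searchtype = "radius", radius = cut)
    # the radius query caps at k results: grow k until no list saturates,
    # so the link graph is the exact <= cut neighborhood graph
    if (k >= n || !any(nn$nn.idx[, k] > 0)) break
    k <- min(n, 2 * k)
  }
  from <- integer(0); to <- integer(0)
  idx <- nn$nn.idx
  for (j in 2:ncol(idx)) {
    hit <- idx[, j] > 0
    if (!any(hit)) break
    from <- c(from, which(hit)); to <- c(to, idx[hit, j])
  }
  if (!length(from)) return(seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Annotate localizations with Voronoi local density
#'
#' Thin wrapper over [voronoi_density()] returning the localization table
#' with `density` (nm^-3) and `cell_volume` (nm^3) columns.
#'
#' @param locs Localization data.frame (`x_nm`, `y_nm`, `z_nm` or `z_um`).
#' @param ... Passed to [voronoi_density()].
#' @return `locs` with density annotations (class keeps data.frame).
#' @export
compute_local_density <- function(locs, ...) {
  z <- if (!is.null(locs$z_nm)) locs$z_nm else locs$z_um * 1000
  vd <- voronoi_density(cbind(locs$x_nm, locs$y_nm, z), ...)
  locs$density <- vd$density
  locs$cell_volume <- vd$volume
  locs$boundary_cell <- vd$boundary
  locs
}

# Per-cluster descriptors from a point cloud (nm).
.cluster_stats <- function(p, id, dens, fwhm_factor = 2.35) {
  ctr <- colMeans(p)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  sdev <- sqrt(pmax(ev$values, 0))
  fwhm <- fwhm_factor * sdev                 # descending: long, mid, short
  d_z <- fwhm[1]
  d_r <- mean(fwhm[2:3])
  data.frame(cluster = id, n_loc = nrow(p),
             x_nm = ctr[1], y_nm = ctr[2], z_nm = ctr[3],
             d_r_nm = d_r, d_z_nm = d_z,
             volume_nm3 = (4 / 3) * pi * (d_r / 2)^2 * (d_z / 2),
             mean_density = mean(dens))
}

#' Detect clusters by Voronoi density thresholding and single linkage
#'
#' Keeps localizations whose local density exceeds the average density of
#' the whole cloud (the localization count divided by the total
#' tessellated volume), links the survivors by single linkage with a maximum
#' link (cutting) distance, discards components below the minimum size,
#' and quantifies each cluster: principal-axes (ellipsoid) projections,
#' FWHM = 2.35 sigma along each axis (`d_z` = long axis, `d_r` = mean of
#' the two short axes), and the FWHM-ellipsoid volume
#' `V = (4/3) pi (d_r/2)^2 (d_z/2)`.
#'
#' @param locs Density-annotated localizations ([compute_local_density()]
#'   is applied if the `density` column is absent).
#' @param min_loc Minimum localizations per cluster (default 10).
#' @param cut_nm Cutting distance, nm (default 50).
#' @param fwhm_factor FWHM/sigma conversion (default 2.35).
#' @return Object of class `smlm_clusters`: list with `stats` (data.frame,
#'   one row per cluster), `assignment` (per input row: cluster id or NA)
#'   and the thresholds used.
#' @export
detect_clusters <- function(locs, min_loc = 10, cut_nm = 50,
                            fwhm_factor = 2.35) {
  if (is.null(locs$density)) locs <- compute_local_density(locs)
  z <- if (!is.null(locs$z_nm)) locs$z_nm else locs$z_um * 1000
  pts <- cbind(locs$x_nm, locs$y_nm, z)
  # average density of the cloud = localization count per tessellated
  # volume (not the mean of the heavy-tailed per-point densities, which a
  # few very dense clusters would dominate)
  thr <- if (!is.null(locs$cell_volume))
    nrow(locs) / sum(locs$cell_volume) else mean(locs$density)
  keep <- which(locs$density > thr)
  assignment <- rep(NA_integer_, nrow(locs))
  stats_rows <- list()
  if (length(keep) >= min_loc) {
    comp <- .linkage_components(pts[keep, , drop = FALSE], cut_nm)
    cid <- 0L
    for (g in seq_len(max(comp))) {
      sel <- keep[comp == g]
      if (length(sel) < min_loc) next
      cid <- cid + 1L
      assignment[sel] <- cid
      stats_rows[[cid]] <- .cluster_stats(pts[sel, , drop = FALSE], cid,
                                          locs$density[sel], fwhm_factor)
    }
  }
  stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    data.frame(cluster = integer(0), n_loc = integer(0), x_nm = numeric(0),
               y_nm = numeric(0), z_nm = numeric(0), d_r_nm = numeric(0),
               d_z_nm = numeric(0), volume_nm3 = numeric(0),
               mean_density = numeric(0))
  structure(list(stats = stats, assignment = assignment,
                 density_threshold = thr, min_loc = min_loc,
                 cut_nm = cut_nm),
            class = "smlm_clusters")
}

#' @export
print.smlm_clusters <- function(x, ...) {
  cat(sprintf("%d clusters (>= %d locs, density > mean, cut %g nm)\n",
              nrow(x$stats), x$min_loc, x$cut_nm))
  if (nrow(x$stats))
    cat(sprintf("  median d_r %.1f nm, d_z %.1f nm, n_loc %d\n",
                stats::median(x$stats$d_r_nm), stats::median(x$stats$d_z_nm),
                round(stats::median(x$stats$n_loc))))
  invisible(x)
}

#' Best-fit sphere through cluster centroids
#'
#' Algebraic least-squares sphere fit (linear in center and radius^2)
#' refined by geometric residual minimization (Gauss-Newton on
#' `|p - c| - r`). Used to approximate the cell membrane from surface
#' receptor cluster centroids.
#'
#' @param centroids n x 3 matrix or data.frame with `x_nm`, `y_nm`, `z_nm`
#'   (n >= 4, non-coplanar).
#' @return Object of class `sphere_fit`: `center` (nm), `radius_nm`,
#'   `rms_residual_nm`.
#' @export
fit_sphere <- function(centroids) {
  p <- if (is.data.frame(centroids))
    cbind(centroids$x_nm, centroids$y_nm, centroids$z_nm)
  else as.matrix(centroids)
  n <- nrow(p)
  if (n < 4) stop("need at least 4 centroids")
  if (qr(sweep(p, 2, colMeans(p)))$rank < 3)
    stop("degenerate input: centroids are coplanar or collinear")
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- unname(stats::lm.fit(A, b)$coefficients)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  # geometric refinement
  par <- c(ctr, r)
  for (it in 1:50) {
    d <- sqrt(rowSums(sweep(p, 2, par[1:3])^2))
    res <- d - par[4]
    J <- cbind(-sweep(p, 2, par[1:3]) / d, -1)
    step <- tryCatch(unname(stats::lm.fit(J, -res)$coefficients),
                     error = function(e) rep(0, 4))
    step[!is.finite(step)] <- 0
    par <- unname(par + step)
    if (sqrt(sum(step^2)) < 1e-9 * max(par[4], 1)) break
  }
  d <- sqrt(rowSums(sweep(p, 2, par[1:3])^2))
  structure(list(center = par[1:3], radius_nm = par[4],
                 rms_residual_nm = sqrt(mean((d - par[4])^2)), n = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("Sphere fit (n = %d): center (%.0f, %.0f, %.0f) nm, radius %.0f nm, RMS residual %.1f nm\n",
              x$n, x$center[1], x$center[2], x$center[3], x$radius_nm,
              x$rms_residual_nm))
  invisible(x)
}

#' Project cluster centroids onto the membrane sphere and map densities
#'
#' Each centroid is mapped radially onto the best-fit sphere; the spherical
#' Voronoi diagram of the projected points partitions the surface, and the
#' local surface cluster density is the inverse cell area (clusters per
#' um^2). Any cluster property can then be visualized per Voronoi polygon.
#'
#' @param clusters `smlm_clusters` object or a centroid data.frame
#'   (`x_nm`, `y_nm`, `z_nm`).
#' @param fit [fit_sphere()] result.
#' @param jitter_nm Jitter applied (with a warning) when two centroids
#'   project to the same surface point (default 1).
#' @return Object of class `sphere_map`: data.frame `clusters` with
#'   spherical coordinates and `surface_density_per_um2`, list `polygons`
#'   (cell vertices on the sphere, nm), `cell_area_um2`, and the fit.
#' @export
project_to_sphere_map <- function(clusters, fit, jitter_nm = 1) {
  cen <- if (inherits(clusters, "smlm_clusters")) clusters$stats else clusters
  if (nrow(cen) < 4) stop("need at least 4 clusters")
  p <- cbind(cen$x_nm, cen$y_nm, cen$z_nm)
  rel <- sweep(p, 2, fit$center)
  rr <- sqrt(rowSums(rel^2))
  if (any(rr == 0)) stop("cluster centroid at the sphere center")
  u <- rel / rr
  # coincident projections: jitter tangentially
  dup <- duplicated(round(u, 9))
  if (any(dup)) {
    warning(sum(dup), " coincident surface projection(s) jittered")
    for (i in which(dup)) {
      t1 <- c(-u[i, 2], u[i, 1], 0)
      if (sum(t1^2) < 1e-12) t1 <- c(1, 0, 0)
      t1 <- t1 / sqrt(sum(t1^2))
      u[i, ] <- u[i, ] + t1 * (jitter_nm / fit$radius_nm)
      u[i, ] <- u[i, ] / sqrt(sum(u[i, ]^2))
    }
  }
  sv <- spherical_voronoi(u)
  area_nm2 <- sv$area * fit$radius_nm^2
  area_um2 <- area_nm2 / 1e6
  cen$theta <- acos(pmin(1, pmax(-1, u[, 3])))
  cen$phi <- atan2(u[, 2], u[, 1])
  cen$cell_area_um2 <- area_um2
  cen$surface_density_per_um2 <- 1 / area_um2
  polygons <- lapply(sv$cells, function(v)
    sweep(v * fit$radius_nm, 2, fit$center, `+`))
  structure(list(clusters = cen, polygons = polygons,
                 cell_area_um2 = area_um2, fit = fit),
            class = "sphere_map")
}

#' @export
print.sphere_map <- function(x, ...) {
  cat(sprintf("Spherical cluster map: %d clusters on a %.2f um radius sphere\n",
              nrow(x$clusters), x$fit$radius_nm / 1000))
  cat(sprintf("  surface density %.2f +/- %.2f clusters/um^2 (mean +/- sd)\n",
              mean(x$clusters$surface_density_per_um2),
              stats::sd(x$clusters$surface_density_per_um2)))
  invisible(x)
}

#' Regression of cluster properties against axial position
#'
#' Ordinary least squares of each cluster property (`d_r_nm`, `d_z_nm`,
#' `n_loc`, `volume_nm3`) on the centroid z. Near-zero slopes and R^2
#' indicate axially homogeneous reconstruction quality.
#'
#' @param clusters `smlm_clusters` object or its `stats` data.frame
#'   (>= 10 clusters, non-constant z).
#' @param properties Property columns to regress.
#' @return data.frame with `property`, `slope`, `intercept`, `r_squared`.
#' @export
props_vs_z_regression <- function(clusters,
                                  properties = c("d_r_nm", "d_z_nm",
                                                 "n_loc", "volume_nm3")) {
  tab <- if (inherits(clusters, "smlm_clusters")) clusters$stats else clusters
  if (nrow(tab) < 10) stop("need at least 10 clusters")
  if (stats::var(tab$z_nm) == 0) stop("zero variance in z")
  out <- lapply(properties, function(pr) {
    y <- tab[[pr]]
    if (stats::var(y) == 0)
      return(data.frame(property = pr, slope = 0, intercept = y[1],
                        r_squared = 0))
    fit <- stats::lm(y ~ z_nm, data = tab)
    r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits are fine
    data.frame(property = pr,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2)
  })
  do.call(rbind, out)
}
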