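# Exact 3-D Voronoi cells by half-space clipping, and an incremental 3-D
# convex hull. These primitives back the tessellation-based local density
# used for cluster segmentation and the spherical Voronoi surface map.

#' Voronoi tessellation local density of a 3-D point cloud
#'
#' Computes, for every point, the exact volume of its Voronoi cell clipped
#' to a padded bounding box, its first-rank Voronoi neighbors, and the
#' first-rank local density
#' `density_i = (1 + |N1(i)|) / (V_i + sum_{j in N1(i)} V_j)`,
#' i.e. the point plus its natural neighbors divided by their pooled cell
#' volume. Cells touching the bounding box ("boundary" cells, whose true
#' Voronoi cell is unbounded) are assigned the average density of their
#' interior neighbors instead of their own truncated-volume estimate.
#'
#' @param pts n x 3 matrix of coordinates (nm).
#' @param pad_nm Bounding-box padding; defaults to half the mean
#'   nearest-neighbor spacing estimate `(V/n)^(1/3) / 2`.
#' @param k_neighbors Initial number of candidate neighbors considered per
#'   point (grown automatically when insufficient; the clip is exact).
#' @return List (class `voronoi_density`) with `volume` (nm^3), `density`
#'   (nm^-3), `neighbors` (list of first-rank neighbor indices),
#'   `boundary` (logical: cell touches the box).
#' @export
voronoi_density <- function(pts, pad_nm = NULL, k_neighbors = 24) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points")
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 3)
    stop("degenerate input: points are coplanar")
  rng <- apply(pts, 2, range)
  if (is.null(pad_nm)) {
    vol_box <- prod(pmax(rng[2, ] - rng[1, ], 1e-9))
    pad_nm <- max((vol_box / n)^(1 / 3) / 2, 1e-6)
  }
  lo <- rng[1, ] - pad_nm; hi <- rng[2, ] + pad_nm
  kmax <- n - 1
  volume <- numeric(n)
  neighbors <- vector("list", n)
  boundary <- logical(n)
  store <- function(i, res) {
    volume[i] <<- res$volume
    neighbors[[i]] <<- res$neighbors
    boundary[i] <<- res$boundary
  }
  # phase 1: clip against the nearest neighbors; most cells are proven
  # complete by the early-stop rule (a point farther than twice the max
  # vertex distance from the generator cannot cut its cell)
  k0 <- min(k_neighbors, kmax)
  nn <- RANN::nn2(pts, pts, k = k0 + 1)
  pending <- integer(0)
  for (i in seq_len(n)) {
    res <- .vor_cell_cpp(i, nn$nn.idx[i, -1], nn$nn.dists[i, -1], pts,
                         lo, hi)
    if (res$complete || k0 >= kmax) store(i, res)
    else pending <- c(pending, i)
  }
  # widen the candidate ring in bulk for the cells still open (sparse
  # regions, hull cells); recomputing the few open cells from scratch is
  # cheaper than per-point neighbor queries
  k_wide <- k0
  while (length(pending)) {
    k_wide <- min(kmax, max(8L * k_wide, 256L))
    nnw <- RANN::nn2(pts, pts[pending, , drop = FALSE], k = k_wide + 1)
    still <- integer(0)
    for (m in seq_along(pending)) {
      i <- pending[m]
      res <- .vor_cell_cpp(i, nnw$nn.idx[m, -1], nnw$nn.dists[m, -1], pts,
                           lo, hi)
      if (res$complete || k_wide >= kmax) store(i, res)
      else still <- c(still, i)
    }
    pending <- still
  }
  # first-rank density; cells truncated by the bounding box carry a
  # volume artifact, so they are excluded from the pooled sums and later
  # assigned their interior neighbors' average instead
  density <- numeric(n)
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    nb <- nb[!boundary[nb]]
    density[i] <- (1 + length(nb)) / (volume[i] + sum(volume[nb]))
  }
  interior_density <- density
  for (i in which(boundary)) {
    nb <- neighbors[[i]]
    nb <- nb[!boundary[nb]]
    if (length(nb)) density[i] <- mean(interior_density[nb])
  }
  structure(list(volume = volume, density = density, neighbors = neighbors,
                 boundary = boundary, pad_nm = pad_nm),
            class = "voronoi_density")
}

# ---- incremental 3-D convex hull ------------------------------------------
# Returns triangle faces (m x 3 vertex indices) with outward orientation.
.convex_hull3 <- function(pts, tol = 1e-10) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points for a 3-D hull")
  scale <- max(abs(pts))
  eps <- tol * max(scale, 1)
  # initial simplex: spread points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) stop("degenerate input")
  d2 <- rowSums((pts - matrix(pts[i1, ], n, 3, byrow = TRUE))^2)
  e <- pts[i2, ] - pts[i1, ]
  # third point: farthest from the line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * e[3] - rel[, 3] * e[2],
              rel[, 3] * e[1] - rel[, 1] * e[3],
              rel[, 1] * e[2] - rel[, 2] * e[1])
  i3 <- which.max(rowSums(cr^2))
  nrm <- cr[i3, ]
  if (sqrt(sum(nrm^2)) <= eps) stop("degenerate input: collinear points")
  h <- as.numeric(rel %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) <= eps * sqrt(sum(nrm^2)))
    stop("degenerate input: coplanar points")
  tet <- c(i1, i2, i3, i4)
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(pts[tet, ])
  orient <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; c <- pts[f[3], ]
    nn <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
            (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
            (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (sum(nn * (ctr - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_normal <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; c <- pts[f[3], ]
    c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
      (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  for (p in setdiff(seq_len(n), tet)) {
    x <- pts[p, ]
    vis <- logical(nrow(faces))
    for (f in seq_len(nrow(faces))) {
      nrm <- face_normal(faces[f, ])
      vis[f] <- sum(nrm * (x - pts[faces[f, 1], ])) >
        eps * sqrt(sum(nrm^2))
    }
    if (!any(vis)) next
    # horizon = edges shared by exactly one visible face
    edges <- list()
    for (f in which(vis)) {
      tri <- faces[f, ]
      for (e in list(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)]))
        edges[[length(edges) + 1]] <- e
    }
    em <- do.call(rbind, edges)
    key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    horizon <- em[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    new_faces <- cbind(horizon, p)
    # orientation: keep interior ctr below each new face
    new_faces <- t(apply(new_faces, 1, orient))
    faces <- rbind(faces, new_faces)
  }
  faces
}

# Spherical triangle area (unit sphere) via L'Huilier.
.sph_tri_area <- function(a, b, c) {
  ang <- function(u, v) 2 * asin(pmin(1, sqrt(sum((u - v)^2)) / 2))
  A <- ang(b, c); B <- ang(a, c); C <- ang(a, b)
  s <- (A + B + C) / 2
  t <- sqrt(max(0, tan(s / 2) * tan((s - A) / 2) * tan((s - B) / 2) *
                  tan((s - C) / 2)))
  4 * atan(t)
}

#' Spherical Voronoi diagram of points on a sphere
#'
#' Given unit vectors on the sphere, computes the spherical Voronoi cell of
#' each generator (vertices = circumcenters of the Delaunay triangles
#' incident to it, i.e. of the convex hull facets) and its area.
#'
#' @param u n x 3 matrix of unit vectors (n >= 4, not all coplanar).
#' @return List with `cells` (per generator: matrix of unit-vector cell
#'   vertices in counter-clockwise order) and `area` (steradians; areas
#'   sum to 4 pi).
#' @export
spherical_voronoi <- function(u) {
  u <- as.matrix(u)
  n <- nrow(u)
  if (n < 4) stop("need at least 4 generators")
  faces <- .convex_hull3(u)
  # circumcenter of each facet = normalized normal, oriented outward
  cc <- t(apply(faces, 1, function(f) {
    a <- u[f[1], ]; b <- u[f[2], ]; c <- u[f[3], ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nrm <- nrm / sqrt(sum(nrm^2))
    if (sum(nrm * (a + b + c)) < 0) -nrm else nrm
  }))
  cells <- vector("list", n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    fi <- which(apply(faces, 1, function(f) i %in% f))
    if (length(fi) < 3) stop("generator ", i, " has a degenerate cell")
    verts <- cc[fi, , drop = FALSE]
    # order around the generator
    g <- u[i, ]
    a1 <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a1 - sum(a1 * g) * g; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(g[2] * e1[3] - g[3] * e1[2], g[3] * e1[1] - g[1] * e1[3],
            g[1] * e1[2] - g[2] * e1[1])
    ang <- atan2(verts %*% e2, verts %*% e1)
    verts <- verts[order(ang), , drop = FALSE]
    cells[[i]] <- verts
    s <- 0
    for (k in seq_len(nrow(verts))) {
      k2 <- if (k == nrow(verts)) 1 else k + 1
      s <- s + .sph_tri_area(g, verts[k, ], verts[k2, ])
    }
    area[i] <- s
  }
  list(cells = cells, area = area)
}
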