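#' Triangular surface mesh with outward normals and region labels
#'
#' @param vertices N x 3 matrix of vertex positions (mm, world frame).
#' @param triangles M x 3 integer matrix of vertex indices (1-based).
#' @param normals N x 3 matrix of outward unit normals; computed by
#'   area-weighted triangle-normal averaging when omitted.
#' @param labels Character vector of per-vertex region labels
#'   (`"body"` or `"posterior"`); defaults to all `"body"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, normals = NULL, labels = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3L) stop("surface_mesh: vertices must be N x 3")
  n <- nrow(vertices)
  if (min(triangles) < 1L || max(triangles) > n)
    stop("surface_mesh: triangle indices out of range")
  if (is.null(normals)) normals <- vertex_normals(vertices, triangles)
  normals <- as.matrix(normals)
  len <- sqrt(rowSums(normals^2))
  if (any(len < 1e-12)) stop("surface_mesh: degenerate normals")
  normals <- normals / len
  if (is.null(labels)) labels <- rep("body", n)
  if (length(labels) != n) stop("surface_mesh: labels must cover all vertices")
  if (!all(labels %in% c("body", "posterior")))
    stop("surface_mesh: labels must be 'body' or 'posterior'")
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles (%d posterior-labeled)\n",
              nrow(x$vertices), nrow(x$triangles),
              sum(x$labels == "posterior")))
  invisible(x)
}

vertex_normals <- function(vertices, triangles) {
  e1 <- vertices[triangles[, 2], ] - vertices[triangles[, 1], ]
  e2 <- vertices[triangles[, 3], ] - vertices[triangles[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  nrm <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (c in 1:3)
      nrm[, c] <- nrm[, c] +
        unname(tapply(fn[, c], factor(triangles[, k], levels = seq_len(nrow(vertices))),
                      sum, default = 0))
  }
  nrm[is.na(nrm)] <- 0
  nrm
}

#' Unique undirected edges of a mesh
#'
#' @param mesh A [surface_mesh()].
#' @return Two-column matrix of vertex index pairs.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Moller-Trumbore ray/triangle intersection of one ray against all
# triangles; returns the smallest positive hit distance (Inf if none).
ray_mesh_distance <- function(origin, dir, vertices, triangles,
                              t_min = 1e-6) {
  v0 <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - v0
  e2 <- vertices[triangles[, 3], , drop = FALSE] - v0
  cross_d <- function(a, d) cbind(a[, 2] * d[3] - a[, 3] * d[2],
                                  a[, 3] * d[1] - a[, 1] * d[3],
                                  a[, 1] * d[2] - a[, 2] * d[1])
  p <- -cross_d(e2, dir)  # dir x e2
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-12
  if (!any(ok)) return(Inf)
  tv <- sweep(v0, 2, origin, "-") * -1  # origin - v0
  u <- rowSums(tv * p) / det
  q <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
             tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
             tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  v <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / det
  t <- rowSums(q * e2) / det
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > t_min
  if (!any(hit)) return(Inf)
  min(t[hit])
}

#' Chord length to the opposing surface along each inward normal
#'
#' For each vertex, casts a ray along the inward normal and returns the
#' distance to the first intersection with the mesh (the opposing
#' cortex). Used to truncate sampled profiles in thin structures such as
#' pedicles and spinous processes.
#'
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of chord lengths (mm); `Inf` when the ray
#'   leaves the mesh without re-intersection.
#' @export
mesh_chord_lengths <- function(mesh) {
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- ray_mesh_distance(mesh$vertices[i, ], -mesh$normals[i, ],
                                mesh$vertices, mesh$triangles,
                                t_min = 1e-4)
  }
  out
}

# Closest point on a triangle mesh: returns for each query point the
# nearest triangle index, barycentric weights and distance.
# Reference: Ericson, Real-Time Collision Detection, closest-point-on-
# triangle, vectorized over triangles per query.
closest_point_on_mesh <- function(points, vertices, triangles) {
  points <- matrix(points, ncol = 3)
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  ab <- b - a; ac <- c - a
  nq <- nrow(points)
  tri <- integer(nq); dist <- numeric(nq)
  bary <- matrix(0, nq, 3)
  for (i in seq_len(nq)) {
    p <- points[i, ]
    ap <- sweep(a, 2, p, "-") * -1
    d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
    bp <- sweep(b, 2, p, "-") * -1
    d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
    cp <- sweep(c, 2, p, "-") * -1
    d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    u <- rep(NA_real_, length(d1)); v <- rep(NA_real_, length(d1))
    # vertex regions
    reg_a <- d1 <= 0 & d2 <= 0
    reg_b <- d3 >= 0 & d4 <= d3
    reg_c <- d6 >= 0 & d5 <= d6
    # edge regions
    t_ab <- d1 / (d1 - d3)
    reg_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
    t_ac <- d2 / (d2 - d6)
    reg_ac <- !reg_a & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
    t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    reg_bc <- !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
    u[reg_a] <- 0; v[reg_a] <- 0
    u[reg_b] <- 1; v[reg_b] <- 0
    u[reg_c] <- 0; v[reg_c] <- 1
    u[reg_ab] <- t_ab[reg_ab]; v[reg_ab] <- 0
    u[reg_ac] <- 0; v[reg_ac] <- t_ac[reg_ac]
    u[reg_bc] <- 1 - t_bc[reg_bc]; v[reg_bc] <- t_bc[reg_bc]
    interior <- is.na(u)
    if (any(interior)) {
      denom <- va + vb + vc
      u[interior] <- (vb / denom)[interior]
      v[interior] <- (vc / denom)[interior]
    }
    q <- a + ab * u + ac * v
    d2q <- rowSums(sweep(q, 2, p, "-")^2)
    j <- which.min(d2q)
    tri[i] <- j
    dist[i] <- sqrt(d2q[j])
    bary[i, ] <- c(1 - u[j] - v[j], u[j], v[j])
  }
  list(triangle = tri, bary = bary, distance = dist)
}

#' Ellipsoid surface mesh
#'
#' Latitude/longitude triangulation of an ellipsoid with analytic
#' outward normals (the normalized gradient of the implicit surface).
#' Used as the phantom body shape and as the canonical template for
#' synthetic cohorts.
#'
#' @param semiaxes Semi-axes (mm), length 3.
#' @param center Centre (mm).
#' @param n_theta Number of latitude bands (>= 3).
#' @param n_phi Number of longitude steps (>= 3).
#' @param posterior_cap Fraction (0 to < 0.5) of vertices at the -y pole
#'   labeled `"posterior"`, emulating the posterior elements; 0 labels
#'   everything `"body"`.
#' @return A [surface_mesh()].
#' @export
ellipsoid_mesh <- function(semiaxes = c(18, 14, 11), center = c(0, 0, 0),
                           n_theta = 16, n_phi = 24, posterior_cap = 0) {
  th <- seq(0, pi, length.out = n_theta + 1)[-c(1, n_theta + 1)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(th = th, ph = ph)
  unit <- rbind(c(0, 0, 1),
                cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th)),
                c(0, 0, -1))
  v <- sweep(sweep(unit, 2, semiaxes, "*"), 2, center, "+")
  nv <- nrow(v)
  idx <- function(i, j) 1L + (((j - 1L) %% n_phi) * (n_theta - 1L)) + i  # ring i, column j
  tris <- list()
  # top fan
  for (j in seq_len(n_phi))
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  # bands
  for (i in seq_len(n_theta - 2L)) for (j in seq_len(n_phi)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    tris[[length(tris) + 1L]] <- c(a, b, c2)
    tris[[length(tris) + 1L]] <- c(a, c2, d)
  }
  # bottom fan
  for (j in seq_len(n_phi))
    tris[[length(tris) + 1L]] <- c(nv, idx(n_theta - 1L, j + 1L), idx(n_theta - 1L, j))
  triangles <- do.call(rbind, tris)
  # analytic outward normal of x^2/a^2 + y^2/b^2 + z^2/c^2 = 1
  nrm <- sweep(sweep(v, 2, center, "-"), 2, semiaxes^2, "/")
  nrm <- nrm / sqrt(rowSums(nrm^2))
  labels <- rep("body", nv)
  if (posterior_cap > 0) {
    stopifnot(posterior_cap < 0.5)
    yrel <- (v[, 2] - center[2]) / semiaxes[2]
    labels[yrel < stats::quantile(yrel, posterior_cap)] <- "posterior"
  }
  surface_mesh(v, triangles, normals = nrm, labels = labels)
}
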