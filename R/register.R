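#' Registration configuration
#'
#' @param icp_iter Maximum rigid ICP iterations.
#' @param icp_tol Relative RMS improvement below which ICP stops.
#' @param rigid_rms_max Abort threshold (mm) on the post-rigid RMS
#'   nearest-neighbor distance (shapes too dissimilar).
#' @param tps_lambda Thin-plate-spline regularization weight.
#' @param tps_points Maximum number of mutual-nearest-neighbor control
#'   points driving the warp.
#' @param identity If `TRUE`, skip registration and use same-index
#'   correspondence (phantom cohorts share mesh topology with known
#'   true correspondence, so downstream stages can be isolated).
#' @return A list of class `register_config`.
#' @export
register_config <- function(icp_iter = 50, icp_tol = 1e-7,
                            rigid_rms_max = 10, tps_lambda = 0.1,
                            tps_points = 250, identity = FALSE) {
  structure(list(icp_iter = icp_iter, icp_tol = icp_tol,
                 rigid_rms_max = rigid_rms_max, tps_lambda = tps_lambda,
                 tps_points = tps_points, identity = identity),
            class = "register_config")
}

nearest_indices <- function(from, to) {
  # for each row of `from`, index of nearest row of `to` (brute force)
  n <- nrow(from)
  out <- integer(n)
  t2 <- rowSums(to^2)
  for (i in seq_len(n)) {
    d <- t2 - 2 * (to %*% from[i, ])[, 1]
    out[i] <- which.min(d)
  }
  out
}

kabsch <- function(src, dst) {
  # least-squares rigid transform mapping src -> dst
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cd - as.vector(R %*% cs))
}

apply_rigid <- function(points, tf) sweep(points %*% t(tf$R), 2, tf$t, "+")

# Principal-axes initialization: aligns centroid and covariance
# eigenvectors, trying the four proper-rotation sign combinations and
# keeping the one with the lowest nearest-neighbor RMS. Plain
# nearest-neighbor ICP from identity is prone to tangential local
# minima on smooth, nearly symmetric shapes.
pca_inits <- function(subject, canonical) {
  cs <- colMeans(subject); cc <- colMeans(canonical)
  es <- eigen(stats::cov(subject))$vectors
  ec <- eigen(stats::cov(canonical))$vectors
  inits <- list(list(R = diag(3), t = c(0, 0, 0)))
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))   # proper rotations only
    R <- ec %*% S %*% t(es)
    if (det(R) < 0) R <- ec %*% (S * -1) %*% t(es)
    inits[[length(inits) + 1L]] <- list(R = R, t = cc - as.vector(R %*% cs))
  }
  inits
}

icp_rigid <- function(subject, canonical, config) {
  nn_rms <- function(pts) {
    nn <- nearest_indices(pts, canonical)
    sqrt(mean(rowSums((pts - canonical[nn, , drop = FALSE])^2)))
  }
  inits <- pca_inits(subject, canonical)
  rms0 <- vapply(inits, function(tf) nn_rms(apply_rigid(subject, tf)),
                 numeric(1))
  # near-ties arise on (near-)symmetric shapes, where several
  # alignments are geometrically equivalent; prefer the earliest
  # candidate (identity first) so correspondence is not flipped
  tf <- inits[[which(rms0 <= min(rms0) + 1e-6 * (1 + min(rms0)))[1]]]
  pts <- apply_rigid(subject, tf)
  rms_prev <- Inf
  for (it in seq_len(config$icp_iter)) {
    nn <- nearest_indices(pts, canonical)
    step <- kabsch(pts, canonical[nn, , drop = FALSE])
    pts <- apply_rigid(pts, step)
    tf <- list(R = step$R %*% tf$R,
               t = as.vector(step$R %*% tf$t) + step$t)
    rms <- sqrt(mean(rowSums((pts - canonical[nn, , drop = FALSE])^2)))
    if (is.finite(rms_prev) && rms_prev - rms < config$icp_tol * max(rms, 1e-12))
      break
    rms_prev <- rms
  }
  nn <- nearest_indices(pts, canonical)
  rms <- sqrt(mean(rowSums((pts - canonical[nn, , drop = FALSE])^2)))
  list(points = pts, transform = tf, rms = rms)
}

# Thin-plate spline in 3D (kernel U(r) = r) fitted from control points
# `src` to displacements `dst - src`, with ridge regularization lambda.
tps_fit <- function(src, dst, lambda) {
  n <- nrow(src)
  K <- as.matrix(stats::dist(src))
  P <- cbind(1, src)
  L <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst - src, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  list(src = src, w = sol[seq_len(n), , drop = FALSE],
       a = sol[(n + 1):(n + 4), , drop = FALSE])
}

tps_apply <- function(tps, points) {
  D2 <- outer(rowSums(points^2), rep(1, nrow(tps$src))) +
    outer(rep(1, nrow(points)), rowSums(tps$src^2)) -
    2 * points %*% t(tps$src)
  U <- sqrt(pmax(D2, 0))
  disp <- U %*% tps$w + cbind(1, points) %*% tps$a
  points + disp
}

#' Register a subject mesh onto the canonical shape
#'
#' Correspondence-free rigid alignment (iterative closest point) of the
#' subject onto the canonical mesh, followed by a nonrigid thin-plate
#' spline refinement driven by mutual-nearest-neighbor matches.
#' Correspondences are then assigned by closest-point projection of each
#' canonical vertex onto the warped subject surface, expressed as a
#' subject triangle plus barycentric weights.
#'
#' @param subject,canonical [surface_mesh()]es of the same anatomy
#'   class.
#' @param config A [register_config()].
#' @return An object of class `atlas_entry`: `triangle` and `bary`
#'   (per canonical vertex, on the subject mesh), `residual` (mm),
#'   `miss` flags, `rigid_rms`, and the transforms used.
#' @export
register_mesh <- function(subject, canonical, config = register_config()) {
  stopifnot(inherits(subject, "surface_mesh"), inherits(canonical, "surface_mesh"))
  if (config$identity) {
    if (nrow(subject$vertices) != nrow(canonical$vertices))
      stop("register_mesh: identity mode requires shared mesh topology")
    return(identity_atlas_entry(subject, canonical))
  }
  sv <- subject$vertices
  cv <- canonical$vertices
  rigid <- icp_rigid(sv, cv, config)
  if (rigid$rms > config$rigid_rms_max)
    stop("register_mesh: post-rigid RMS ", signif(rigid$rms, 4),
         " mm exceeds threshold ", config$rigid_rms_max,
         " mm; shapes too dissimilar")
  # mutual nearest neighbors between rigidly aligned subject and canonical
  s2c <- nearest_indices(rigid$points, cv)
  c2s <- nearest_indices(cv, rigid$points)
  mutual <- which(c2s[s2c] == seq_len(nrow(sv)))
  if (length(mutual) >= 10) {
    if (length(mutual) > config$tps_points)
      mutual <- mutual[round(seq(1, length(mutual),
                                 length.out = config$tps_points))]
    tps <- tps_fit(rigid$points[mutual, , drop = FALSE],
                   cv[s2c[mutual], , drop = FALSE], config$tps_lambda)
    warped <- tps_apply(tps, rigid$points)
  } else {
    tps <- NULL
    warped <- rigid$points
  }
  cp <- closest_point_on_mesh(cv, warped, subject$triangles)
  structure(list(triangle = cp$triangle, bary = cp$bary,
                 residual = cp$distance,
                 miss = rep(FALSE, nrow(cv)),
                 rigid_rms = rigid$rms,
                 rigid = rigid$transform, tps = tps,
                 subject = subject, canonical = canonical),
            class = "atlas_entry")
}

identity_atlas_entry <- function(subject, canonical) {
  nv <- nrow(canonical$vertices)
  tri_of <- integer(nv)
  bary <- matrix(0, nv, 3)
  tr <- subject$triangles
  for (k in 1:3) {
    hit <- match(seq_len(nv), tr[, k])
    take <- is.na(tri_of) | tri_of == 0L
    use <- take & !is.na(hit)
    tri_of[use] <- hit[use]
    bary[cbind(which(use), k)] <- 1
  }
  if (any(tri_of == 0L))
    stop("register_mesh: identity mode found vertices absent from every triangle")
  structure(list(triangle = tri_of, bary = bary,
                 residual = rep(0, nv), miss = rep(FALSE, nv),
                 rigid_rms = 0, rigid = NULL, tps = NULL,
                 subject = subject, canonical = canonical),
            class = "atlas_entry")
}

#' Transfer a subject vertex map onto the canonical mesh
#'
#' Barycentric interpolation of subject values at each canonical
#' vertex. A canonical vertex is invalid when its correspondence is
#' miss-flagged or any supporting subject vertex is invalid; region
#' labels are inherited from the dominant (largest total barycentric
#' weight) label of the supporting vertices.
#'
#' @param atlas_entry Result of [register_mesh()].
#' @param map A [vertex_map()] on the subject mesh.
#' @return A [vertex_map()] on the canonical mesh.
#' @export
transfer_map <- function(atlas_entry, map) {
  stopifnot(inherits(atlas_entry, "atlas_entry"), inherits(map, "vertex_map"))
  if (!same_mesh(map$mesh, atlas_entry$subject))
    stop("transfer_map: map does not live on the registered subject mesh")
  tr <- atlas_entry$subject$triangles[atlas_entry$triangle, , drop = FALSE]
  vals <- matrix(map$values[tr], ncol = 3)
  vals[is.na(vals)] <- 0  # masked by validity below
  values <- rowSums(vals * atlas_entry$bary)
  support_valid <- matrix(map$valid[tr], ncol = 3)
  # vertices with negligible weight do not constrain validity
  relevant <- atlas_entry$bary > 1e-8
  valid <- apply(support_valid | !relevant, 1, all) & !atlas_entry$miss
  values[!valid] <- NA_real_
  canon <- atlas_entry$canonical
  vertex_map(map$metric, values, valid, canon)
}

#' Majority-vote label transfer onto the canonical mesh
#'
#' @param atlas_entry Result of [register_mesh()].
#' @return Character vector of per-canonical-vertex labels, each the
#'   label with the largest total barycentric weight among the
#'   supporting subject vertices.
#' @export
transfer_labels <- function(atlas_entry) {
  stopifnot(inherits(atlas_entry, "atlas_entry"))
  tr <- atlas_entry$subject$triangles[atlas_entry$triangle, , drop = FALSE]
  labs <- matrix(atlas_entry$subject$labels[tr], ncol = 3)
  w_post <- rowSums(atlas_entry$bary * (labs == "posterior"))
  ifelse(w_post > 0.5, "posterior", "body")
}
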