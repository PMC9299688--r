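#' Per-vertex scalar map on a surface mesh
#'
#' @param metric Metric name (one of [cortical_metrics()], or any
#'   scalar field name).
#' @param values Per-vertex values (one per mesh vertex).
#' @param valid Logical per-vertex validity flags.
#' @param mesh The [surface_mesh()] the map lives on.
#' @return An object of class `vertex_map`.
#' @export
vertex_map <- function(metric, values, valid = NULL, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  if (length(values) != n)
    stop("vertex_map: values must match the mesh vertex count")
  if (is.null(valid)) valid <- !is.na(values)
  if (length(valid) != n) stop("vertex_map: valid flags must match vertex count")
  valid <- valid & !is.na(values)
  structure(list(metric = metric, values = as.numeric(values),
                 valid = as.logical(valid), mesh = mesh),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("vertex_map '%s': %d vertices (%d valid), median %.4g\n",
              x$metric, length(x$values), sum(x$valid),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

same_mesh <- function(a, b) {
  nrow(a$vertices) == nrow(b$vertices) &&
    nrow(a$triangles) == nrow(b$triangles) &&
    isTRUE(all.equal(a$vertices, b$vertices, tolerance = 1e-8,
                     check.attributes = FALSE))
}

#' Gaussian smoothing of a vertex map across the surface
#'
#' Gaussian-weighted averaging over geodesic neighborhoods, with
#' geodesic distance approximated by shortest paths on the mesh edge
#' graph (edge weight = Euclidean edge length). Weights are renormalized
#' over valid vertices only, so invalid vertices are filled with the
#' weighted average of their valid neighbors — this both removes noise
#' and supplies a value where the model failed to fit.
#'
#' @param map A [vertex_map()].
#' @param fwhm Kernel full width at half maximum (mm). The kernel is
#'   truncated at 3 x FWHM.
#' @param scope Optional logical vector restricting smoothing support
#'   and output to a vertex subset (e.g. the vertebral body).
#' @return A smoothed [vertex_map()]. Vertices with no valid neighbor
#'   within 3 x FWHM remain invalid (and are reported via a message).
#' @export
smooth_vertex_map <- function(map, fwhm = 5, scope = NULL) {
  stopifnot(inherits(map, "vertex_map"), fwhm > 0)
  mesh <- map$mesh
  n <- nrow(mesh$vertices)
  if (is.null(scope)) scope <- rep(TRUE, n)
  D <- mesh_geodesic_distances(mesh)
  sd_k <- fwhm / (2 * sqrt(2 * log(2)))
  W <- exp(-D^2 / (2 * sd_k^2))
  W[D > 3 * fwhm] <- 0
  src <- map$valid & scope
  W[, !src] <- 0
  wsum <- rowSums(W)
  values <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  idx <- scope & wsum > 0
  vals <- ifelse(src, map$values, 0)
  values[idx] <- (W[idx, , drop = FALSE] %*% vals)[, 1] / wsum[idx]
  valid[idx] <- TRUE
  orpham <- scope & !idx
  if (any(orpham))
    message("smooth_vertex_map: ", sum(orpham),
            " vertex/vertices with no valid neighbor within 3 x FWHM remain invalid")
  vertex_map(map$metric, values, valid, mesh)
}

# Cached-per-call all-pairs geodesic (graph) distances.
mesh_geodesic_distances <- function(mesh) {
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- len
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  igraph::distances(g)
}

#' Restrict a map of an interior metric to the vertebral body
#'
#' Endocortical and cancellous measures (Ec.Th, Cn.BMD) cannot be
#' computed within the spinous processes and pedicles, where the
#' opposing cortices are too close; their maps and summaries use
#' body-labeled vertices only. Cortical metrics are returned unchanged.
#'
#' @param map A [vertex_map()].
#' @return A [vertex_map()] with posterior-labeled vertices invalidated
#'   (values set to `NA`) for body-only metrics.
#' @export
restrict_to_body <- function(map) {
  stopifnot(inherits(map, "vertex_map"))
  if (!is_body_only_metric(map$metric)) return(map)
  labels <- map$mesh$labels
  if (is.null(labels) || !length(labels))
    stop("restrict_to_body: mesh has no region labels")
  keep <- labels == "body"
  values <- ifelse(keep, map$values, NA_real_)
  vertex_map(map$metric, values, map$valid & keep, map$mesh)
}

# In-scope vertex mask for a metric (body-only metrics exclude the
# posterior elements).
metric_scope <- function(metric, mesh) {
  if (is_body_only_metric(metric)) mesh$labels == "body"
  else rep(TRUE, nrow(mesh$vertices))
}

# Denominator floors guarding percentage changes against near-zero
# baselines (Ec.Th baselines of ~0.09 mm make ratios unstable).
percent_change_floor <- function(metric) {
  switch(metric,
         ec_th = 0.02,    # mm
         ct_th = 0.05,    # mm
         cmsd = 0.5,      # mg/cm^2
         10)              # densities, mg/cm^3
}

#' Per-vertex percentage-change map between two timepoints
#'
#' @param baseline,followup [vertex_map()]s of the same metric on the
#'   same (canonical) mesh.
#' @return A [vertex_map()] of 100 x (follow - base) / base. Vertices
#'   invalid in either input, or with baseline below the metric-specific
#'   floor ([percent_change_floor()]), are flagged invalid.
#' @export
percent_change_map <- function(baseline, followup) {
  check_change_pair(baseline, followup)
  floor_v <- percent_change_floor(baseline$metric)
  ok <- baseline$valid & followup$valid & !is.na(baseline$values) &
    baseline$values >= floor_v
  values <- rep(NA_real_, length(baseline$values))
  values[ok] <- 100 * (followup$values[ok] - baseline$values[ok]) /
    baseline$values[ok]
  vertex_map(baseline$metric, values, ok, baseline$mesh)
}

#' Per-vertex absolute-change map between two timepoints
#'
#' @inheritParams percent_change_map
#' @return A [vertex_map()] of follow - base in the metric's units.
#' @export
absolute_change_map <- function(baseline, followup) {
  check_change_pair(baseline, followup)
  ok <- baseline$valid & followup$valid
  values <- rep(NA_real_, length(baseline$values))
  values[ok] <- followup$values[ok] - baseline$values[ok]
  vertex_map(baseline$metric, values, ok, baseline$mesh)
}

check_change_pair <- function(baseline, followup) {
  stopifnot(inherits(baseline, "vertex_map"), inherits(followup, "vertex_map"))
  if (baseline$metric != followup$metric)
    stop("change map: metrics differ (", baseline$metric, " vs ",
         followup$metric, ")")
  if (!same_mesh(baseline$mesh, followup$mesh))
    stop("change map: maps live on different meshes; register them onto ",
         "the canonical shape first")
  invisible(TRUE)
}
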