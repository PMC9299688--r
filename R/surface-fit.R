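#' Sample density profiles perpendicular to the surface
#'
#' For each mesh vertex, samples trilinear-interpolated density along
#' the inward normal from `-depth_out` (outside the bone) to `depth_in`
#' (inside). Samples beyond half the local chord length to the opposing
#' surface are marked missing, so profiles in thin structures (pedicles,
#' processes) are not contaminated by the far cortex.
#'
#' @param volume A [calibrated_volume()] in mg/cm^3.
#' @param mesh A [surface_mesh()] inside the volume (world frame).
#' @param depth_out Sampling depth outside the surface (mm).
#' @param depth_in Sampling depth inside the surface (mm).
#' @param step Sample spacing (mm); at most half the smallest voxel
#'   spacing is recommended.
#' @param truncate_chord If `TRUE` (default) truncate at half the local
#'   chord length.
#' @param max_missing Profiles with more than this fraction of missing
#'   samples are flagged unusable (attribute `usable`).
#' @return A list of [density_profile()]s, one per vertex, each with a
#'   logical attribute `usable`.
#' @export
sample_profiles <- function(volume, mesh, depth_out = 4, depth_in = 8,
                            step = 0.2, truncate_chord = TRUE,
                            max_missing = 0.3) {
  stopifnot(inherits(volume, "calibrated_volume"), inherits(mesh, "surface_mesh"))
  if (volume$unit != "BMD")
    stop("sample_profiles: volume must be calibrated (unit BMD); ",
         "apply calibrate_volume() first")
  if (depth_out <= 0 || depth_in <= 0 || step <= 0)
    stop("sample_profiles: depths and step must be positive")
  t_seq <- seq(-depth_out, depth_in, by = step)
  nv <- nrow(mesh$vertices)
  np <- length(t_seq)
  # all sample points at once: vertex + t * inward normal
  pts <- matrix(0, nv * np, 3)
  for (c in 1:3)
    pts[, c] <- rep(mesh$vertices[, c], each = np) -
      rep(mesh$normals[, c], each = np) * rep(t_seq, nv)
  vals <- interp_trilinear(volume, pts)
  chord <- if (truncate_chord) mesh_chord_lengths(mesh) else rep(Inf, nv)
  out <- vector("list", nv)
  for (i in seq_len(nv)) {
    v <- vals[((i - 1L) * np + 1L):(i * np)]
    v[t_seq > chord[i] / 2] <- NA_real_
    pr <- density_profile(t_seq, v, vertex_id = i)
    attr(pr, "usable") <- mean(is.na(v)) <= max_missing
    out[[i]] <- pr
  }
  out
}

#' Fit the cortical model over an entire surface
#'
#' Samples a profile at every vertex, fixes the per-scan PSF width
#' (policy-dependent), fits each profile independently, and returns one
#' [vertex_map()] per cortical metric with failed fits flagged invalid
#' (to be filled in by [smooth_vertex_map()]).
#'
#' @param volume A [calibrated_volume()] in mg/cm^3.
#' @param mesh A [surface_mesh()].
#' @param config A [fit_config()]. With `sigma_policy = "fixed"` the
#'   per-scan sigma is taken from `sigma_scan` when given, otherwise
#'   estimated by [estimate_global_sigma()]. A non-`NULL`
#'   `config$y_c_fixed` anchors the cortical plateau density.
#' @param sigma_scan Optional known PSF standard deviation (mm):
#'   a scalar, or a per-vertex vector for anisotropic PSFs
#'   ([psf_sigma_along_normals()]); skips the global estimate.
#' @param depth_out,depth_in,step Sampling geometry, see
#'   [sample_profiles()].
#' @param max_invalid Abort when the fraction of invalid fits exceeds
#'   this (default 0.5).
#' @return A named list of [vertex_map()]s (`ct_th`, `ec_th`, `ct_bmd`,
#'   `cn_bmd`, `cmsd`) with attributes `sigma` (per-scan sigma used) and
#'   `fits` (per-vertex [fit_profile()] results).
#' @export
fit_surface <- function(volume, mesh, config = fit_config(),
                        sigma_scan = NULL,
                        depth_out = 4, depth_in = 8, step = 0.2,
                        max_invalid = 0.5) {
  profiles <- sample_profiles(volume, mesh, depth_out, depth_in, step)
  usable <- vapply(profiles, function(p) isTRUE(attr(p, "usable")), logical(1))
  if (config$sigma_policy == "fixed" && is.null(sigma_scan)) {
    sigma_scan <- estimate_global_sigma(profiles[usable], config)
  }
  sigma_by_profile <- NULL
  if (!is.null(sigma_scan)) {
    if (length(sigma_scan) == 1L) config$sigma <- sigma_scan
    else sigma_by_profile <- sigma_scan
  }
  fits <- fit_profile_set(profiles, config, usable, sigma_by_profile)
  maps <- fits_to_maps(fits, mesh)
  n_invalid <- sum(!vapply(fits, `[[`, logical(1), "valid"))
  if (n_invalid > max_invalid * length(fits))
    stop("fit_surface: ", n_invalid, "/", length(fits),
         " fits invalid (limit ", max_invalid * length(fits),
         "); check calibration, mesh placement and sigma policy")
  attr(maps, "sigma") <- if (is.null(sigma_by_profile)) config$sigma else sigma_by_profile
  attr(maps, "fits") <- fits
  maps
}

#' Fit a list of profiles with a shared configuration
#'
#' Fitting is independent per profile, so results are exchangeable under
#' reordering of the input.
#'
#' @param profiles List of [density_profile()]s.
#' @param config A [fit_config()].
#' @param usable Optional logical vector; profiles marked unusable are
#'   given failed results without fitting.
#' @param sigma_by_profile Optional numeric vector of per-profile PSF
#'   standard deviations (mm), e.g. the direction-dependent effective
#'   blur of an anisotropic PSF ([psf_sigma_along_normals()]).
#' @return List of `fit_result`s.
#' @export
fit_profile_set <- function(profiles, config = fit_config(), usable = NULL,
                            sigma_by_profile = NULL) {
  if (is.null(usable))
    usable <- vapply(profiles, function(p) !isFALSE(attr(p, "usable")),
                     logical(1))
  if (!is.null(sigma_by_profile) &&
      length(sigma_by_profile) != length(profiles))
    stop("fit_profile_set: sigma_by_profile must match profiles")
  lapply(seq_along(profiles), function(i) {
    if (!usable[i]) return(fit_failure(profiles[[i]], "profile unusable"))
    cfg <- config
    if (!is.null(sigma_by_profile)) cfg$sigma <- sigma_by_profile[i]
    fit_profile(profiles[[i]], cfg)
  })
}

#' Effective along-normal PSF width for an anisotropic scanner blur
#'
#' A CT point spread function with in-plane standard deviation
#' `sigma_inplane` and through-slice standard deviation `sigma_slice`
#' blurs a profile sampled along unit direction n with an effective 1D
#' Gaussian of standard deviation
#' sqrt((n_x^2 + n_y^2) sigma_inplane^2 + n_z^2 sigma_slice^2).
#'
#' When fitting profiles sampled from a voxel grid, the sampling chain
#' itself blurs: trilinear interpolation is a convolution with a
#' triangle kernel (variance h^2/6 per axis for voxel size h), and a
#' box rasterization averaged over s^3 sub-samples adds h^2/(12 s^2).
#' Supplying `spacing` (and `supersample` for synthetic volumes) adds
#' these variances, which matters when the cortex is near or below the
#' PSF width: ignoring them slides the fit along the
#' thickness/density trade-off.
#'
#' @param mesh A [surface_mesh()] (slice axis = z).
#' @param sigma_inplane,sigma_slice PSF standard deviations (mm).
#' @param spacing Optional voxel spacing (mm, length 3) to include
#'   interpolation blur.
#' @param supersample Rasterization sub-sampling factor of a synthetic
#'   volume (see [phantom_spec()]); ignored unless `spacing` is given.
#' @return Numeric vector of per-vertex effective sigmas (mm).
#' @export
psf_sigma_along_normals <- function(mesh, sigma_inplane, sigma_slice,
                                    spacing = NULL, supersample = 1) {
  n <- mesh$normals
  s2 <- c(sigma_inplane^2, sigma_inplane^2, sigma_slice^2)
  if (!is.null(spacing)) {
    stopifnot(length(spacing) == 3L)
    s2 <- s2 + spacing^2 / 6 + spacing^2 / (12 * supersample^2)
  }
  sqrt(n[, 1]^2 * s2[1] + n[, 2]^2 * s2[2] + n[, 3]^2 * s2[3])
}

# Per-vertex metric maps from a list of fit results.
fits_to_maps <- function(fits, mesh) {
  metrics <- cortical_metrics()
  valid <- vapply(fits, `[[`, logical(1), "valid")
  out <- lapply(metrics, function(m) {
    vals <- vapply(fits, function(f) {
      if (is.null(f$metrics)) NA_real_ else f$metrics[[m]]
    }, numeric(1))
    vertex_map(m, vals, valid, mesh)
  })
  names(out) <- metrics
  out
}
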