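#' Density profile along a surface normal
#'
#' @param positions Regularly spaced sample positions (mm) along the
#'   inward normal (negative = outside the bone).
#' @param values Calibrated density samples (mg/cm^3); `NA` marks samples
#'   outside the volume or truncated at the opposing cortex.
#' @param vertex_id Index of the originating mesh vertex.
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(positions, values, vertex_id = NA_integer_) {
  if (length(positions) != length(values))
    stop("density_profile: positions and values differ in length")
  if (length(positions) < 15L)
    stop("density_profile: at least 15 samples are required")
  d <- diff(positions)
  if (any(d <= 0)) stop("density_profile: positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("density_profile: positions must be regularly spaced")
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 spacing = mean(d),
                 vertex_id = as.integer(vertex_id)),
            class = "density_profile")
}

#' Fitting configuration for profile deconvolution
#'
#' @param sigma_policy `"fixed"` uses `sigma` for every profile (typically
#'   the output of [estimate_global_sigma()]); `"fitted"` fits sigma per
#'   profile within `sigma_bounds`.
#' @param sigma Default / fixed PSF standard deviation (mm).
#' @param sigma_bounds Bounds for a fitted sigma (mm).
#' @param ct_th_bounds Plausibility bounds on cortical thickness (mm);
#'   fits outside are flagged invalid.
#' @param ec_th_max Upper bound on the endocortical slope width (mm).
#' @param density_bounds Plausibility bounds on fitted densities
#'   (mg/cm^3).
#' @param min_contrast Minimum `y_c - y_t` (mg/cm^3) for a fit to be
#'   considered valid.
#' @param residual_factor Fits whose RMS residual exceeds
#'   `residual_factor` times the estimated noise SD are flagged invalid.
#' @param y_c_fixed Optional per-scan cortical plateau density
#'   (mg/cm^3) to hold fixed during per-vertex fits (typically the
#'   output of [estimate_scan_density()]). When the cortex is thinner
#'   than the PSF width, per-vertex thickness and density are nearly
#'   interchangeable; anchoring the slowly varying tissue density at a
#'   per-scan value removes that degeneracy. `NULL` fits y_c freely.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(sigma_policy = c("fixed", "fitted"),
                       sigma = 1.0,
                       sigma_bounds = c(0.2, 3),
                       ct_th_bounds = c(0.05, 5),
                       ec_th_max = 5,
                       density_bounds = c(0, 2000),
                       min_contrast = 50,
                       residual_factor = 3,
                       y_c_fixed = NULL,
                       max_iter = 150L) {
  structure(list(sigma_policy = match.arg(sigma_policy),
                 sigma = sigma, sigma_bounds = sigma_bounds,
                 ct_th_bounds = ct_th_bounds, ec_th_max = ec_th_max,
                 density_bounds = density_bounds,
                 min_contrast = min_contrast,
                 residual_factor = residual_factor,
                 y_c_fixed = y_c_fixed,
                 max_iter = as.integer(max_iter)),
            class = "fit_config")
}

#' Robust per-profile noise estimate
#'
#' Estimates the sample noise SD from first differences of the profile,
#' which cancel the smooth (PSF-blurred) signal component.
#'
#' @param profile A [density_profile()].
#' @return Estimated noise SD (mg/cm^3).
#' @export
estimate_profile_noise <- function(profile) {
  v <- profile$values[!is.na(profile$values)]
  if (length(v) < 3L) return(NA_real_)
  stats::mad(diff(v)) / sqrt(2)
}

#' Heuristic initialization for a profile fit
#'
#' Places the periosteal edge at the maximum positive gradient and the
#' endocortical midpoint at the maximum negative gradient beyond it;
#' plateau densities start from the profile maximum and the tail medians.
#'
#' @param profile A [density_profile()].
#' @param sigma Starting PSF standard deviation (mm).
#' @return A [cortical_params()] start, or `NULL` (with attribute
#'   `reason`) when no cortical edge structure is detectable (flat or
#'   contrast-inverted profile).
#' @export
initialize_params <- function(profile, sigma = 1.0) {
  pos <- profile$positions
  val <- profile$values
  ok <- !is.na(val)
  if (sum(ok) < 15L) return(failed_init("too few usable samples"))
  pos <- pos[ok]; val <- val[ok]
  noise <- stats::mad(diff(val)) / sqrt(2)
  rng <- max(val) - min(val)
  if (rng < max(6 * noise, 1e-9))
    return(failed_init("flat profile: range below noise floor"))

  g <- diff(val) / diff(pos)
  gx <- (pos[-1] + pos[-length(pos)]) / 2
  i_up <- which.max(g)
  x0 <- gx[i_up]
  # endocortical descent must lie inside the bone, beyond the rise
  after <- which(gx > x0)
  if (length(after) == 0L) return(failed_init("no interior descent"))
  i_dn <- after[which.min(g[after])]
  if (g[i_dn] >= 0) return(failed_init("no descending endocortical edge"))
  x1 <- gx[i_dn]

  y_c <- max(val)
  n <- length(val)
  k <- max(3L, floor(n / 4))
  y_bg <- stats::median(val[seq_len(k)])
  y_t <- stats::median(val[seq.int(n - k + 1L, n)])
  if (y_t >= y_c - 1e-9 || y_c <= y_bg + 1e-9)
    return(failed_init("inverted contrast: no cortical peak"))

  if (x1 < x0 + profile$spacing) x1 <- x0 + profile$spacing
  x2 <- x1 + 2 * profile$spacing
  y_t <- max(y_t, 0)
  cortical_params(x0 = x0, x1 = x1, x2 = x2,
                  y_bg = min(y_bg, y_c - 1), y_c = y_c, y_t = y_t,
                  sigma = sigma)
}

failed_init <- function(reason) structure(list(), reason = reason)

init_failed <- function(init) length(init) == 0L

# The three plateau densities enter the blurred model linearly:
# model = y_bg (1 - Phi0) + y_c (Phi0 - R) + y_t R, with Phi0 the blurred
# periosteal step and R the blurred endocortical ramp. Fitting therefore
# uses variable projection: the optimizer searches only the nonlinear
# geometry (x0, d1 = x1 - x0, w = x2 - x1[, sigma]) while the densities
# are recovered by an inner linear least-squares solve. This keeps the
# search low-dimensional and well conditioned even when the cortex is
# well below the PSF width.
varpro_basis <- function(theta, pos, sigma_fixed) {
  s <- if (is.null(sigma_fixed)) theta[["sigma"]] else sigma_fixed
  x0 <- theta[["x0"]]
  x1 <- x0 + theta[["d1"]]
  x2 <- x1 + theta[["w"]]
  Phi0 <- stats::pnorm((pos - x0) / s)
  R <- blurred_ramp(pos, x1, x2, s)
  cbind(1 - Phi0, Phi0 - R, R)
}

varpro_residuals <- function(theta, pos, val, sigma_fixed,
                             y_c_fixed = NULL) {
  B <- varpro_basis(theta, pos, sigma_fixed)
  if (!is.null(y_c_fixed)) {
    val <- val - y_c_fixed * B[, 2]
    B <- B[, c(1, 3), drop = FALSE]
  }
  f <- tryCatch(stats::.lm.fit(B, val), error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f$coefficients)))
    return(rep(1e6, length(val)))
  f$residuals
}

# Densities at the optimum, with nonnegativity repaired by re-solving on
# the active set (a negative cancellous or background density is set to
# zero and the remaining columns refitted).
varpro_densities <- function(theta, pos, val, sigma_fixed,
                             y_c_fixed = NULL) {
  B <- varpro_basis(theta, pos, sigma_fixed)
  fixed <- !is.null(y_c_fixed)
  if (fixed) {
    val <- val - y_c_fixed * B[, 2]
    B <- B[, c(1, 3), drop = FALSE]
  }
  f <- tryCatch(stats::.lm.fit(B, val), error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f$coefficients))) return(NULL)
  y <- f$coefficients
  nonneg <- if (fixed) c(TRUE, TRUE) else c(TRUE, FALSE, TRUE)
  free <- rep(TRUE, length(y))
  for (pass in seq_len(sum(nonneg))) {
    neg <- which(free & y < 0 & nonneg)
    if (!length(neg)) break
    free[neg] <- FALSE
    y[neg] <- 0
    if (!any(free)) break
    f2 <- tryCatch(stats::.lm.fit(B[, free, drop = FALSE], val),
                   error = function(e) NULL)
    if (is.null(f2) || any(!is.finite(f2$coefficients))) return(NULL)
    y[free] <- f2$coefficients
  }
  if (fixed) list(y_bg = y[1], y_c = y_c_fixed, y_t = y[2])
  else list(y_bg = y[1], y_c = y[2], y_t = y[3])
}

#' Fit the blurred cortical model to one density profile
#'
#' Bounded Levenberg-Marquardt least squares from the heuristic start of
#' [initialize_params()], with one multi-start retry (endocortical edge
#' perturbed by +/- 2 samples) when the first attempt fails to converge.
#' A fit is `valid` only when it converged and passes plausibility
#' screens: Ct.Th within `config$ct_th_bounds`, densities within
#' `config$density_bounds`, cortical-cancellous contrast of at least
#' `config$min_contrast`, and RMS residual within
#' `config$residual_factor` times the estimated noise SD.
#'
#' @param profile A [density_profile()].
#' @param config A [fit_config()].
#' @return A list of class `fit_result`: `params`, `metrics`,
#'   `residual_rms`, `converged`, `valid`, `reason`.
#' @export
fit_profile <- function(profile, config = fit_config()) {
  stopifnot(inherits(profile, "density_profile"))
  ok <- !is.na(profile$values)
  pos <- profile$positions[ok]
  val <- profile$values[ok]
  if (length(val) < 15L)
    return(fit_failure(profile, "too few usable samples"))

  init <- initialize_params(profile, sigma = config$sigma)
  if (init_failed(init))
    return(fit_failure(profile, attr(init, "reason")))

  noise <- estimate_profile_noise(profile)
  fitted_sigma <- config$sigma_policy == "fitted"
  sigma_fixed <- if (fitted_sigma) NULL else config$sigma

  theta0 <- c(x0 = init$x0, d1 = init$x1 - init$x0,
              w = init$x2 - init$x1)
  lower <- c(x0 = min(pos), d1 = 0, w = 0)
  upper <- c(x0 = max(pos), d1 = diff(range(pos)), w = config$ec_th_max)
  if (fitted_sigma) {
    theta0 <- c(theta0, sigma = config$sigma)
    lower <- c(lower, sigma = config$sigma_bounds[1])
    upper <- c(upper, sigma = config$sigma_bounds[2])
  }
  theta0 <- pmin(pmax(theta0, lower), upper)

  run <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = varpro_residuals, pos = pos, val = val,
                         sigma_fixed = sigma_fixed,
                         y_c_fixed = config$y_c_fixed,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter, ptol = 1e-10,
                           ftol = 1e-10)),
      error = function(e) NULL)
  }
  # Start list: the heuristic gradient start, then starts over a grid of
  # candidate thicknesses T anchored at the blurred peak (a
  # sub-resolution cortex attenuates the peak and drags the gradient
  # landmarks, so the heuristic start can sit in the wrong basin), then
  # the endocortical edge shifted by +/- 2 samples.
  x_pk <- pos[which.max(val)]
  sp <- profile$spacing
  starts <- list(theta0)
  for (T in c(0.3, 0.5, 0.8, 1.2, 2.0)) {
    st <- theta0
    st[["x0"]] <- x_pk - T / 2
    st[["d1"]] <- max(T - sp, sp)
    st[["w"]] <- sp
    starts[[length(starts) + 1L]] <- pmin(pmax(st, lower), upper)
  }
  for (shift in c(-2, 2) * sp) {
    st <- theta0
    st[["d1"]] <- max(sp, st[["d1"]] + shift)
    starts[[length(starts) + 1L]] <- pmin(pmax(st, lower), upper)
  }
  # Rank starts by initial deviance (one projected residual evaluation
  # each) and refine the three most promising; stop early only when a
  # start reaches a near-exact fit, which no other basin can beat.
  start_dev <- vapply(starts, function(st)
    sum(varpro_residuals(st, pos, val, sigma_fixed,
                         config$y_c_fixed)^2), numeric(1))
  starts <- starts[order(start_dev)][seq_len(min(3L, length(starts)))]
  dev_exact <- length(val) * (1e-4 * diff(range(val)))^2
  best <- NULL
  for (st in starts) {
    alt <- run(st)
    if (!is.null(alt) && (is.null(best) || alt$deviance < best$deviance))
      best <- alt
    if (!is.null(best) && best$deviance <= dev_exact) break
  }
  if (is.null(best)) return(fit_failure(profile, "optimizer failure"))

  converged <- best$info %in% 1:4
  th <- best$par
  dens <- varpro_densities(th, pos, val, sigma_fixed, config$y_c_fixed)
  if (is.null(dens)) return(fit_failure(profile, "degenerate basis"))
  s_hat <- if (fitted_sigma) th[["sigma"]] else sigma_fixed
  params <- tryCatch(
    cortical_params(th[["x0"]], th[["x0"]] + th[["d1"]],
                    th[["x0"]] + th[["d1"]] + th[["w"]],
                    dens$y_bg, dens$y_c, dens$y_t, s_hat),
    error = function(e) NULL)
  if (is.null(params)) return(fit_failure(profile, "implausible optimum"))
  metrics <- derived_metrics(params)
  rms <- sqrt(best$deviance / length(val))

  reason <- NULL
  if (!converged) reason <- "did not converge"
  else if (metrics$ct_th < config$ct_th_bounds[1] ||
           metrics$ct_th > config$ct_th_bounds[2]) reason <- "ct_th out of bounds"
  else if (params$y_c > config$density_bounds[2] ||
           params$y_t > config$density_bounds[2]) reason <- "density out of bounds"
  else if (params$y_c - params$y_t < config$min_contrast) reason <- "insufficient contrast"
  else if (is.finite(noise) && noise > 0 &&
           rms > config$residual_factor * noise) reason <- "residual exceeds noise budget"

  structure(list(params = params, metrics = metrics,
                 residual_rms = rms, converged = converged,
                 valid = is.null(reason),
                 reason = if (is.null(reason)) NA_character_ else reason,
                 vertex_id = profile$vertex_id),
            class = "fit_result")
}

fit_failure <- function(profile, reason) {
  structure(list(params = NULL, metrics = NULL, residual_rms = NA_real_,
                 converged = FALSE, valid = FALSE, reason = reason,
                 vertex_id = profile$vertex_id),
            class = "fit_result")
}

#' Estimate the per-scan cortical plateau density
#'
#' When the cortex is thinner than the PSF width, per-profile thickness
#' and plateau density trade off almost freely, so their individual
#' per-vertex estimates are heavy-tailed even though their product
#' (mass) is stable. The tissue-level cortical density varies slowly
#' across a bone, which licenses a per-scan constraint: this estimator
#' averages the sampled profiles of a scan vertex-wise (profiles share
#' the sampling grid, aligned at the periosteal surface), which
#' suppresses the sample noise by \eqn{1/\sqrt{n}}, and performs one
#' free fit of the averaged profile. The fitted plateau density is then
#' held fixed in the per-vertex fits via `fit_config(y_c_fixed = )`.
#'
#' @param profiles A list of [density_profile()]s on a common grid.
#' @param config A [fit_config()] (sigma policy and bounds are
#'   honored; `y_c_fixed` is ignored).
#' @return A list: `y_c` (mg/cm^3), `fit` (the reference
#'   [fit_profile()] result on the averaged profile), `n_used`.
#' @export
estimate_scan_density <- function(profiles, config = fit_config()) {
  usable <- vapply(profiles, function(p) !isFALSE(attr(p, "usable")),
                   logical(1))
  profiles <- profiles[usable]
  if (!length(profiles)) stop("estimate_scan_density: no usable profiles")
  pos0 <- profiles[[1]]$positions
  same <- vapply(profiles, function(p)
    length(p$positions) == length(pos0) &&
      max(abs(p$positions - pos0)) < 1e-9, logical(1))
  profiles <- profiles[same]
  vals <- vapply(profiles, `[[`, numeric(length(pos0)), "values")
  mean_prof <- density_profile(pos0, rowMeans(vals, na.rm = TRUE))
  cfg <- config
  cfg$y_c_fixed <- NULL
  fit <- fit_profile(mean_prof, cfg)
  if (is.null(fit$params) || !fit$converged)
    stop("estimate_scan_density: reference fit failed (",
         fit$reason, ")")
  list(y_c = fit$params$y_c, fit = fit, n_used = length(profiles))
}

#' Estimate a per-scan PSF width from many profiles
#'
#' Jointly fitting sigma and a sub-resolution thickness per profile is
#' ill-posed, so sigma is estimated once per scan: profiles in the top
#' quartile by density range (the thickest, highest-contrast cortices)
#' are fitted with sigma free, fits whose cortex is at least as thick as
#' the fitted sigma are kept, and the median fitted sigma is returned.
#'
#' @param profiles A list of [density_profile()] objects (>= 50).
#' @param config A [fit_config()]; `config$sigma` is the fallback.
#' @return Estimated sigma (mm). Falls back to `config$sigma` with a
#'   warning when fewer than 10 usable free fits are obtained.
#' @export
estimate_global_sigma <- function(profiles, config = fit_config()) {
  if (length(profiles) < 50L)
    stop("estimate_global_sigma: at least 50 profiles required")
  rngs <- vapply(profiles, function(p) {
    v <- p$values[!is.na(p$values)]
    if (length(v) < 2L) return(-Inf)
    diff(range(v))
  }, numeric(1))
  top <- profiles[rngs >= stats::quantile(rngs[is.finite(rngs)], 0.75)]
  cfg <- config
  cfg$sigma_policy <- "fitted"
  sigmas <- numeric(0)
  for (p in top) {
    f <- fit_profile(p, cfg)
    if (f$valid && f$metrics$ct_th >= f$params$sigma)
      sigmas <- c(sigmas, f$params$sigma)
  }
  if (length(sigmas) < 10L) {
    warning("estimate_global_sigma: fewer than 10 usable free fits; ",
            "falling back to config default sigma = ", config$sigma)
    return(config$sigma)
  }
  stats::median(sigmas)
}
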