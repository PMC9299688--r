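#' Piecewise cortical density model parameters
#'
#' Constructs the parameter set of the cortical density model used for
#' model-based deconvolution of CT profiles. Along the inward surface
#' normal (x = 0 near the periosteal surface, increasing into the bone)
#' the unblurred density is piecewise: extra-osseous background `y_bg`
#' for x < `x0`; the cortical plateau `y_c` (Ct.BMD) for `x0` <= x < `x1`;
#' a linear endocortical slope from `y_c` at `x1` down to `y_t` at `x2`;
#' and the cancellous plateau `y_t` (Cn.BMD) for x >= `x2`. `sigma` is the
#' standard deviation of the Gaussian point spread function along the
#' profile; the scanner is assumed to observe this model convolved with
#' that Gaussian.
#'
#' @param x0 Periosteal edge position (mm).
#' @param x1 Start of the endocortical slope (mm), `x1 >= x0`.
#' @param x2 End of the endocortical slope (mm), `x2 >= x1`. `x1 == x2`
#'   degenerates to the classic sharp (two-step) endocortex.
#' @param y_bg Background (soft tissue) density (mg/cm^3).
#' @param y_c Cortical plateau density, Ct.BMD (mg/cm^3).
#' @param y_t Cancellous density adjacent to the endocortex, Cn.BMD
#'   (mg/cm^3).
#' @param sigma Gaussian PSF standard deviation (mm), > 0.
#' @return An object of class `cortical_params`.
#' @export
cortical_params <- function(x0, x1, x2, y_bg, y_c, y_t, sigma) {
  p <- list(x0 = x0, x1 = x1, x2 = x2,
            y_bg = y_bg, y_c = y_c, y_t = y_t, sigma = sigma)
  validate_cortical_params(p)
  structure(p, class = "cortical_params")
}

validate_cortical_params <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in c("x0", "x1", "x2", "y_bg", "y_c", "y_t", "sigma"))
    if (!num1(p[[f]])) stop("cortical_params: '", f, "' must be a finite scalar")
  if (p$x0 > p$x1 || p$x1 > p$x2)
    stop("cortical_params: ordering x0 <= x1 <= x2 violated")
  if (p$sigma <= 0) stop("cortical_params: sigma must be > 0")
  if (p$y_c <= p$y_bg) stop("cortical_params: y_c must exceed y_bg")
  if (p$y_c <= p$y_t) stop("cortical_params: y_c must exceed y_t")
  if (p$y_t < 0) stop("cortical_params: y_t must be >= 0")
  invisible(TRUE)
}

#' @export
print.cortical_params <- function(x, ...) {
  cat(sprintf(
    "cortical_params: x0=%.3f x1=%.3f x2=%.3f mm | y_bg=%.1f y_c=%.1f y_t=%.1f mg/cm3 | sigma=%.3f mm\n",
    x$x0, x$x1, x$x2, x$y_bg, x$y_c, x$y_t, x$sigma))
  invisible(x)
}

#' Evaluate the unblurred cortical model
#'
#' @param params A [cortical_params()] object.
#' @param x Positions along the inward normal (mm); vectorized.
#' @return Densities (mg/cm^3) at `x`.
#' @export
eval_unblurred <- function(params, x) {
  validate_cortical_params(params)
  p <- params
  y <- ifelse(x < p$x0, p$y_bg,
       ifelse(x < p$x1, p$y_c,
       ifelse(x >= p$x2, p$y_t, NA_real_)))
  in_slope <- is.na(y)
  if (any(in_slope)) {
    w <- p$x2 - p$x1
    y[in_slope] <- p$y_c + (p$y_t - p$y_c) * (x[in_slope] - p$x1) / w
  }
  y
}

#' Evaluate the PSF-blurred cortical model
#'
#' Closed-form convolution of the piecewise model with a unit-area
#' Gaussian of standard deviation `params$sigma`. The periosteal step
#' contributes an error-function term; the endocortical ramp contributes
#' the standard closed form for a linear ramp convolved with a Gaussian.
#'
#' @inheritParams eval_unblurred
#' @param sigma Optional PSF standard deviation (mm) overriding
#'   `params$sigma`.
#' @return Blurred densities (mg/cm^3) at `x`.
#' @export
eval_blurred <- function(params, x, sigma = NULL) {
  validate_cortical_params(params)
  p <- params
  s <- if (is.null(sigma)) p$sigma else sigma
  if (s <= 0) stop("eval_blurred: sigma must be > 0")
  step <- (p$y_c - p$y_bg) * stats::pnorm((x - p$x0) / s)
  ramp <- blurred_ramp(x, p$x1, p$x2, s)
  p$y_bg + step - (p$y_c - p$y_t) * ramp
}

# Unit ramp rising 0 -> 1 over [x1, x2], convolved with a Gaussian of SD s.
# Degenerates to the blurred unit step when x2 - x1 is negligible.
blurred_ramp <- function(x, x1, x2, s) {
  w <- x2 - x1
  if (w < 1e-9 * max(s, 1)) return(stats::pnorm((x - x1) / s))
  u1 <- (x - x1) / s
  u2 <- (x - x2) / s
  ((x - x1) * stats::pnorm(u1) - (x - x2) * stats::pnorm(u2) +
      s * (stats::dnorm(u1) - stats::dnorm(u2))) / w
}

#' Metrics derived from fitted model parameters
#'
#' Cortical thickness runs from the periosteal surface to the midpoint of
#' the endocortical slope, so cortex and endocortex overlap by half the
#' endocortical width. CMSD (cortical mass surface density) is
#' 0.1 x Ct.Th x Ct.BMD, converting mm x mg/cm^3 to mg/cm^2.
#'
#' @param params A [cortical_params()] object.
#' @return A list of class `derived_metrics` with elements `ct_th`,
#'   `ec_th` (mm), `ct_bmd`, `cn_bmd` (mg/cm^3) and `cmsd` (mg/cm^2).
#' @export
derived_metrics <- function(params) {
  validate_cortical_params(params)
  p <- params
  ct_th <- (p$x1 + p$x2) / 2 - p$x0
  ec_th <- p$x2 - p$x1
  structure(list(
    ct_th = ct_th,
    ec_th = ec_th,
    ct_bmd = p$y_c,
    cn_bmd = p$y_t,
    cmsd = 0.1 * ct_th * p$y_c
  ), class = "derived_metrics")
}

#' Names of the five cortical metrics
#'
#' @param body_only If `TRUE`, return only the metrics restricted to the
#'   vertebral body (Cn.BMD and Ec.Th).
#' @return Character vector of metric names.
#' @export
cortical_metrics <- function(body_only = FALSE) {
  if (body_only) c("cn_bmd", "ec_th")
  else c("ct_th", "ec_th", "ct_bmd", "cn_bmd", "cmsd")
}

# Metrics whose summaries and maps are restricted to the vertebral body:
# endocortical and cancellous measures are meaningless in the pedicles and
# spinous processes where opposing cortices nearly touch.
is_body_only_metric <- function(metric) metric %in% c("cn_bmd", "ec_th")
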