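#' Calibrated (or raw HU) CT volume
#'
#' A 3D voxel array in world millimetre coordinates. Voxel `[i, j, k]` is
#' centred at `origin + (c(i, j, k) - 1) * spacing`. The `unit` flag
#' tracks whether voxels are raw Hounsfield units (`"HU"`) or calibrated
#' densities in mg/cm^3 (`"BMD"`), so calibration is applied exactly once.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing (mm), length 3 (in-plane x, in-plane y,
#'   slice z); may be anisotropic.
#' @param origin World position (mm) of the centre of voxel `[1, 1, 1]`.
#' @param unit `"BMD"` (mg/cm^3) or `"HU"`.
#' @param calibration Optional list `(slope, intercept)` mapping
#'   HU -> mg/cm^3 (recorded by [calibrate_volume()]).
#' @return An object of class `calibrated_volume`.
#' @export
calibrated_volume <- function(data, spacing, origin = c(0, 0, 0),
                              unit = c("BMD", "HU"), calibration = NULL) {
  unit <- match.arg(unit)
  if (length(dim(data)) != 3L) stop("calibrated_volume: data must be 3D")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("calibrated_volume: spacing must be 3 positive values")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), unit = unit,
                 calibration = calibration),
            class = "calibrated_volume")
}

#' @export
print.calibrated_volume <- function(x, ...) {
  cat(sprintf("calibrated_volume [%s]: %s voxels, spacing %s mm, origin %s mm\n",
              x$unit, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "/"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Trilinear interpolation of a volume at world points
#'
#' @param volume A [calibrated_volume()].
#' @param points N x 3 matrix of world coordinates (mm).
#' @return Numeric vector of interpolated values; `NA` outside the
#'   volume.
#' @export
interp_trilinear <- function(volume, points) {
  points <- matrix(points, ncol = 3)
  d <- dim(volume$data)
  # continuous voxel index (1-based)
  ix <- sweep(sweep(points, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
  i0 <- floor(ix)
  f <- ix - i0
  out <- rep(NA_real_, nrow(points))
  inside <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] + 1 <= d[1] & i0[, 2] + 1 <= d[2] & i0[, 3] + 1 <= d[3]
  # points exactly on the upper boundary
  hi <- ix[, 1] <= d[1] & ix[, 2] <= d[2] & ix[, 3] <= d[3] &
    i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1
  clamp_hi <- hi & !inside
  if (any(clamp_hi)) {
    i0[clamp_hi, ] <- pmin(i0[clamp_hi, , drop = FALSE],
                           matrix(rep(d - 1L, each = sum(clamp_hi)), ncol = 3))
    f[clamp_hi, ] <- ix[clamp_hi, , drop = FALSE] - i0[clamp_hi, , drop = FALSE]
    inside <- inside | clamp_hi
  }
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  fx <- f[inside, 1]; fy <- f[inside, 2]; fz <- f[inside, 3]
  at <- function(di, dj, dk)
    volume$data[cbind(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)]
  v <- at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
       at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
       at(1, 1, 0) * fx       * fy       * (1 - fz) +
       at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
       at(1, 0, 1) * fx       * (1 - fy) * fz +
       at(0, 1, 1) * (1 - fx) * fy       * fz +
       at(1, 1, 1) * fx       * fy       * fz
  out[inside] <- v
  out
}

#' Calibrate a raw HU volume against phantom rods
#'
#' Fits the ordinary least-squares line density = slope x HU + intercept
#' through the calibration rod measurements (in-scan phantom rods of
#' known equivalent density) and applies it voxel-wise.
#'
#' @param raw_volume A [calibrated_volume()] with `unit = "HU"`.
#' @param rod_hu Mean measured HU per rod (>= 3 rods).
#' @param rod_density Known rod densities (mg/cm^3).
#' @return A [calibrated_volume()] in mg/cm^3 with the fitted
#'   `calibration` recorded.
#' @export
calibrate_volume <- function(raw_volume, rod_hu, rod_density) {
  stopifnot(inherits(raw_volume, "calibrated_volume"))
  if (raw_volume$unit != "HU")
    stop("calibrate_volume: volume is already calibrated (unit flag is BMD)")
  if (length(rod_hu) < 3L || length(rod_hu) != length(rod_density))
    stop("calibrate_volume: at least 3 matched rod measurements required")
  fit <- stats::lm(rod_density ~ rod_hu)
  sst <- sum((rod_density - mean(rod_density))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  if (is.na(r2) || r2 < 0.9)
    stop("calibrate_volume: rod fit R^2 = ", signif(r2, 3), " (< 0.9); rejecting")
  if (r2 < 0.99)
    warning("calibrate_volume: rod fit R^2 = ", signif(r2, 3), " (< 0.99)")
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  calibrated_volume(raw_volume$data * slope + intercept,
                    spacing = raw_volume$spacing, origin = raw_volume$origin,
                    unit = "BMD",
                    calibration = list(slope = slope, intercept = intercept))
}
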