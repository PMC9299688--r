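#' Baseline cortical parameter distributions per treatment group
#'
#' Mean and SD of the baseline cortical metrics per treatment group of
#' the 56-woman QCT substudy (vertebral body only for Cn.BMD and
#' Ec.Th), used to draw per-subject ground truths for synthetic
#' cohorts.
#'
#' @return Data frame with columns `group`, `metric`, `mean`, `sd`.
#' @export
baseline_presets <- function() {
  rbind(
    data.frame(group = "placebo", metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th"),
               mean = c(0.93, 787.7, 112.2, 0.091),
               sd = c(0.08, 53.7, 17.7, 0.051)),
    data.frame(group = "teriparatide", metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th"),
               mean = c(0.91, 799.3, 118.4, 0.094),
               sd = c(0.07, 55.0, 20.4, 0.042)),
    data.frame(group = "romosozumab", metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th"),
               mean = c(0.89, 793.6, 113.3, 0.087),
               sd = c(0.07, 51.2, 24.7, 0.050)))
}

#' 12-month percentage-change distributions per treatment group
#'
#' Mean and SD of the per-subject percentage changes from baseline of
#' each cortical metric under placebo, teriparatide and romosozumab,
#' used as the injected group effects of synthetic two-timepoint
#' cohorts. CMSD changes are not drawn independently: they are implied
#' by the joint Ct.Th and Ct.BMD changes.
#'
#' @return Data frame with columns `group`, `metric`, `mean`, `sd`.
#' @export
change_presets <- function() {
  rbind(
    data.frame(group = "placebo", metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th"),
               mean = c(0.6, -0.3, -4.6, 8.2),
               sd = c(3.4, 2.6, 6.1, 29.7)),
    data.frame(group = "teriparatide", metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th"),
               mean = c(4.3, -0.1, 18.1, 47.5),
               sd = c(3.4, 2.8, 14.4, 34.5)),
    data.frame(group = "romosozumab", metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th"),
               mean = c(10.3, 2.1, 22.2, 137.6),
               sd = c(4.9, 3.3, 6.6, 80.5)))
}

#' Generate a noisy blurred density profile from known truth
#'
#' @param truth A [cortical_params()] ground truth.
#' @param spacing Sample spacing (mm).
#' @param depth_out,depth_in Sampling depths (mm) outside/inside the
#'   periosteal position `truth$x0`.
#' @param noise_sd Additive Gaussian noise SD (mg/cm^3).
#' @param seed Optional seed (profile is drawn from the current RNG
#'   stream when `NULL`).
#' @param vertex_id Vertex id recorded on the profile.
#' @return A [density_profile()].
#' @export
gen_profile <- function(truth, spacing = 0.2, depth_out = 4, depth_in = 8,
                        noise_sd = 0, seed = NULL, vertex_id = NA_integer_) {
  validate_cortical_params(truth)
  draw <- function() {
    pos <- seq(truth$x0 - depth_out, truth$x0 + depth_in, by = spacing)
    val <- eval_blurred(truth, pos)
    if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, noise_sd)
    density_profile(pos, val, vertex_id = vertex_id)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Phantom specification for a blurred shell volume
#'
#' Describes an ellipsoidal vertebral-body phantom: a cortical shell of
#' given thickness and plateau density, a linearly decreasing
#' endocortical transition, a cancellous interior and soft-tissue
#' background, imaged with an anisotropic Gaussian PSF (in-plane vs
#' slice), additive noise and a linear HU calibration.
#'
#' Truth fields (`ct_th`, `ec_th`, `y_c`, `y_t`) may be scalars or
#' functions of an N x 3 matrix of unit directions (points on the unit
#' sphere preimage of the ellipsoid), enabling spatially varying truth.
#'
#' @param semiaxes Ellipsoid semi-axes (mm).
#' @param ct_th,ec_th,y_c,y_t Truth fields (mm, mm, mg/cm^3, mg/cm^3).
#' @param y_bg Background density (mg/cm^3).
#' @param sigma_inplane,sigma_slice PSF standard deviations (mm); the
#'   slice presets of the study regime correspond to reconstructed
#'   slice thicknesses of 1.0 or 1.25 mm.
#' @param noise_sd Additive noise SD (mg/cm^3).
#' @param spacing Voxel spacing (mm): in-plane x, in-plane y, slice z.
#' @param hu_slope,hu_intercept Linear calibration density = slope x HU
#'   + intercept used to encode the volume to HU.
#' @param posterior_cap Fraction of mesh vertices labeled posterior.
#' @param n_theta,n_phi Mesh resolution.
#' @param supersample Sub-voxel rasterization factor (>= 1).
#' @param seed Seed for the noise draw.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(semiaxes = c(18, 14, 11),
                         ct_th = 0.9, ec_th = 0.2, y_c = 790, y_t = 112,
                         y_bg = 30,
                         sigma_inplane = 0.8, sigma_slice = 1.0,
                         noise_sd = 25,
                         spacing = c(0.6, 0.6, 1.0),
                         hu_slope = 0.8, hu_intercept = -5,
                         posterior_cap = 0, n_theta = 14, n_phi = 20,
                         supersample = 2L, seed = 1L) {
  structure(list(semiaxes = semiaxes, ct_th = ct_th, ec_th = ec_th,
                 y_c = y_c, y_t = y_t, y_bg = y_bg,
                 sigma_inplane = sigma_inplane, sigma_slice = sigma_slice,
                 noise_sd = noise_sd, spacing = spacing,
                 hu_slope = hu_slope, hu_intercept = hu_intercept,
                 posterior_cap = posterior_cap,
                 n_theta = n_theta, n_phi = n_phi,
                 supersample = as.integer(supersample), seed = seed),
            class = "phantom_spec")
}

truth_at <- function(field, dirs) {
  if (is.function(field)) field(dirs) else rep(field, nrow(dirs))
}

# Signed distance to an ellipsoid (positive inward), via the exact
# closest-point projection: bisection on the Lagrange parameter of
# x_i = a_i^2 q_i / (t + a_i^2), vectorized over query points.
ellipsoid_signed_depth <- function(points, semiaxes, center = c(0, 0, 0),
                                   iter = 60L) {
  q <- sweep(matrix(points, ncol = 3), 2, center, "-")
  a2 <- semiaxes^2
  qa <- abs(q)
  qa <- pmax(qa, 1e-9)  # avoid the degenerate on-axis case
  f_of <- function(t) {
    s <- 0
    for (i in 1:3) s <- s + (semiaxes[i] * qa[, i] / (t + a2[i]))^2
    s - 1
  }
  lo <- rep(-min(a2) * (1 - 1e-9), nrow(q))
  hi <- sqrt(rowSums(qa^2)) * max(semiaxes) + max(a2)
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    pos <- f_of(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t_star <- (lo + hi) / 2
  x <- qa
  for (i in 1:3) x[, i] <- a2[i] * qa[, i] / (t_star + a2[i])
  dist <- sqrt(rowSums((qa - x)^2))
  inside <- rowSums(sweep(q, 2, semiaxes, "/")^2) < 1
  depth <- ifelse(inside, dist, -dist)
  # unit-sphere preimage direction of the closest surface point
  dirs <- sweep(x, 2, semiaxes, "/") * sign(q)
  dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
  list(depth = depth, dirs = dirs)
}

# Separable Gaussian blur of a 3D array (sigma in voxel units per axis).
blur3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    d <- dim(arr)
    out <- array(0, d)
    for (off in seq(-r, r)) {
      idx_src <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])  # edge-replicate
      out <- out + k[off + r + 1L] * switch(ax,
        arr[idx_src, , , drop = FALSE],
        arr[, idx_src, , drop = FALSE],
        arr[, , idx_src, drop = FALSE])
    }
    arr <- out
  }
  arr
}

#' Generate a blurred shell phantom volume, mesh and ground truth
#'
#' Rasterizes the layered density model along the local ellipsoid
#' normal (background outside, cortical plateau, endocortical ramp,
#' cancellous interior), convolves with the anisotropic Gaussian PSF,
#' adds noise, and encodes to HU by the inverse calibration. The
#' periosteal mesh lies on the analytic surface with per-vertex truth
#' maps attached.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `volume` ([calibrated_volume()] in HU), `mesh`
#'   ([surface_mesh()]), `truth` (named list of [vertex_map()]s for the
#'   five metrics), `spec`.
#' @export
gen_shell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mesh <- ellipsoid_mesh(spec$semiaxes, n_theta = spec$n_theta,
                         n_phi = spec$n_phi,
                         posterior_cap = spec$posterior_cap)
  vdirs <- sweep(mesh$vertices, 2, spec$semiaxes, "/")
  vdirs <- vdirs / sqrt(rowSums(vdirs^2))
  v_ct <- truth_at(spec$ct_th, vdirs)
  v_ec <- truth_at(spec$ec_th, vdirs)
  v_yc <- truth_at(spec$y_c, vdirs)
  v_yt <- truth_at(spec$y_t, vdirs)
  fine_step <- min(spec$spacing) / spec$supersample
  if (any(v_ct < fine_step))
    stop("gen_shell_phantom: shell thinner than one fine-rasterization step (",
         signif(fine_step, 3), " mm); refine spacing/supersample")
  if (any(v_ct < v_ec / 2))
    stop("gen_shell_phantom: truth violates ct_th >= ec_th/2")

  margin <- 4 * max(spec$sigma_inplane, spec$sigma_slice) + 2
  lo <- -spec$semiaxes - margin
  hi <- spec$semiaxes + margin
  n_vox <- pmax(ceiling((hi - lo) / spec$spacing) + 1L, 8L)
  origin <- lo
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(n_vox[i]) - 1) * spec$spacing[i])

  ss <- spec$supersample
  offs <- if (ss > 1L) (seq_len(ss) - (ss + 1) / 2) / ss else 0
  acc <- array(0, n_vox)
  grid0 <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  for (ox in offs) for (oy in offs) for (oz in offs) {
    pts <- sweep(grid0, 2, c(ox, oy, oz) * spec$spacing, "+")
    sd3 <- ellipsoid_signed_depth(pts, spec$semiaxes)
    ct <- truth_at(spec$ct_th, sd3$dirs)
    ec <- truth_at(spec$ec_th, sd3$dirs)
    yc <- truth_at(spec$y_c, sd3$dirs)
    yt <- truth_at(spec$y_t, sd3$dirs)
    x1 <- ct - ec / 2
    x2 <- ct + ec / 2
    d <- sd3$depth
    dens <- ifelse(d < 0, spec$y_bg,
            ifelse(d < x1, yc,
            ifelse(d >= x2, yt,
                   yc + (yt - yc) * (d - x1) / pmax(ec, 1e-12))))
    acc <- acc + array(dens, n_vox)
  }
  dens_vol <- acc / length(offs)^3

  sig_vox <- c(spec$sigma_inplane, spec$sigma_inplane, spec$sigma_slice) /
    spec$spacing
  blurred <- blur3d(dens_vol, sig_vox)
  noisy <- if (spec$noise_sd > 0) {
    with_seed(spec$seed,
              blurred + array(stats::rnorm(length(blurred), 0, spec$noise_sd),
                              dim(blurred)))
  } else blurred
  hu <- (noisy - spec$hu_intercept) / spec$hu_slope
  volume <- calibrated_volume(hu, spacing = spec$spacing, origin = origin,
                              unit = "HU")

  truth <- list(
    ct_th = vertex_map("ct_th", v_ct, mesh = mesh),
    ec_th = vertex_map("ec_th", v_ec, mesh = mesh),
    ct_bmd = vertex_map("ct_bmd", v_yc, mesh = mesh),
    cn_bmd = vertex_map("cn_bmd", v_yt, mesh = mesh),
    cmsd = vertex_map("cmsd", 0.1 * v_ct * v_yc, mesh = mesh))
  list(volume = volume, mesh = mesh, truth = truth, spec = spec)
}

#' Two-timepoint cohort specification
#'
#' Groups, sample sizes, baseline truth distributions and per-group
#' 12-month percentage-change distributions for a simulated
#' longitudinal cohort. Defaults reproduce the study arms: n = 20
#' placebo, 19 teriparatide, 17 romosozumab, baselines from
#' [baseline_presets()] and group effects from [change_presets()],
#' applied as spatially uniform multiplicative changes.
#'
#' @param n Named vector of subjects per group.
#' @param baseline Baseline distribution table (`group`, `metric`,
#'   `mean`, `sd`).
#' @param changes Change distribution table (`group`, `metric`, `mean`,
#'   `sd`); set `sd = 0, mean = 0` rows for null cohorts.
#' @param n_vertices Profiles (vertices) per subject.
#' @param sigma PSF standard deviation (mm), identical at both
#'   timepoints of a subject (same scanner at baseline and follow-up).
#' @param noise_sd Profile noise SD (mg/cm^3).
#' @param spacing,depth_out,depth_in Profile sampling geometry (mm).
#' @param y_bg Soft-tissue background density (mg/cm^3).
#' @param ec_th_floor Lower bound (mm) applied when drawing baseline
#'   endocortical thickness.
#' @param seed Cohort seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(placebo = 20, teriparatide = 19,
                              romosozumab = 17),
                        baseline = baseline_presets(),
                        changes = change_presets(),
                        n_vertices = 500, sigma = 1.0, noise_sd = 25,
                        spacing = 0.2, depth_out = 4, depth_in = 8,
                        y_bg = 30, ec_th_floor = 0.02, seed = 1L) {
  structure(list(n = n, baseline = baseline, changes = changes,
                 n_vertices = n_vertices, sigma = sigma,
                 noise_sd = noise_sd, spacing = spacing,
                 depth_out = depth_out, depth_in = depth_in,
                 y_bg = y_bg, ec_th_floor = ec_th_floor, seed = seed),
            class = "cohort_spec")
}

dist_of <- function(tab, g, m) {
  row <- tab[tab$group == g & tab$metric == m, ]
  if (nrow(row) != 1L) stop("cohort_spec tables: missing ", g, "/", m)
  row
}

# Draw one subject's baseline truth and true multiplicative changes,
# redrawing (bounded, counted) when a draw violates the model's
# validity constraints.
draw_subject_truth <- function(spec, g) {
  redraws <- 0L
  repeat {
    b <- vapply(c("ct_th", "ct_bmd", "cn_bmd", "ec_th"), function(m) {
      d <- dist_of(spec$baseline, g, m)
      stats::rnorm(1, d$mean, d$sd)
    }, numeric(1))
    b["ec_th"] <- max(b["ec_th"], spec$ec_th_floor)
    dl <- vapply(c("ct_th", "ct_bmd", "cn_bmd", "ec_th"), function(m) {
      d <- dist_of(spec$changes, g, m)
      stats::rnorm(1, d$mean, d$sd)
    }, numeric(1))
    f <- b * (1 + dl / 100)
    ok <- all(b > 0) && all(f > 0) &&
      b["ct_th"] >= b["ec_th"] / 2 && f["ct_th"] >= f["ec_th"] / 2 &&
      b["ct_bmd"] > b["cn_bmd"] + 50 && f["ct_bmd"] > f["cn_bmd"] + 50
    if (ok) break
    redraws <- redraws + 1L
    if (redraws > 100L) stop("draw_subject_truth: inconsistent cohort spec")
  }
  list(baseline = b, change = dl, followup = f, redraws = redraws)
}

truth_params <- function(tr, y_bg, sigma) {
  cortical_params(x0 = 0,
                  x1 = tr[["ct_th"]] - tr[["ec_th"]] / 2,
                  x2 = tr[["ct_th"]] + tr[["ec_th"]] / 2,
                  y_bg = y_bg, y_c = tr[["ct_bmd"]], y_t = tr[["cn_bmd"]],
                  sigma = sigma)
}

#' Generate a two-timepoint cohort of profile sets with known truth
#'
#' For each subject: baseline truths drawn from the group's baseline
#' distributions, true multiplicative percentage changes drawn from the
#' group's change distributions, and noisy blurred profiles synthesized
#' at both timepoints with the same PSF. Ground truth is recorded for
#' every subject so downstream accuracy checks never read it from the
#' pipeline.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `profile_cohort`: `subjects` (list with
#'   `group`, `baseline_profiles`, `followup_profiles`, `truth`), and
#'   `truth_table` (data frame of per-subject baseline truth and true
#'   change per metric, including the implied CMSD change).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    subjects <- list()
    rows <- list()
    sid <- 0L
    for (g in names(spec$n)) for (k in seq_len(spec$n[[g]])) {
      sid <- sid + 1L
      tr <- draw_subject_truth(spec, g)
      pb <- truth_params(tr$baseline, spec$y_bg, spec$sigma)
      pf <- truth_params(tr$followup, spec$y_bg, spec$sigma)
      base_pr <- lapply(seq_len(spec$n_vertices), function(v)
        gen_profile(pb, spec$spacing, spec$depth_out, spec$depth_in,
                    spec$noise_sd, vertex_id = v))
      fol_pr <- lapply(seq_len(spec$n_vertices), function(v)
        gen_profile(pf, spec$spacing, spec$depth_out, spec$depth_in,
                    spec$noise_sd, vertex_id = v))
      cmsd_change <- 100 * ((1 + tr$change[["ct_th"]] / 100) *
                              (1 + tr$change[["ct_bmd"]] / 100) - 1)
      subjects[[sid]] <- list(id = sid, group = g,
                              baseline_profiles = base_pr,
                              followup_profiles = fol_pr,
                              truth = tr, sigma = spec$sigma)
      rows[[sid]] <- data.frame(
        subject = sid, group = g,
        metric = c("ct_th", "ct_bmd", "cn_bmd", "ec_th", "cmsd"),
        baseline = c(tr$baseline[c("ct_th", "ct_bmd", "cn_bmd", "ec_th")],
                     0.1 * tr$baseline[["ct_th"]] * tr$baseline[["ct_bmd"]]),
        true_change = c(tr$change[c("ct_th", "ct_bmd", "cn_bmd", "ec_th")],
                        cmsd_change),
        redraws = tr$redraws,
        stringsAsFactors = FALSE)
    }
    structure(list(subjects = subjects,
                   truth_table = do.call(rbind, rows),
                   spec = spec),
              class = "profile_cohort")
  })
}
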