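test_that("trilinear interpolation reproduces a linear field exactly", {
  arr <- array(0, c(8, 9, 7))
  sp <- c(0.5, 0.6, 1.0)
  org <- c(-1, 2, 0)
  for (i in 1:8) for (j in 1:9) for (k in 1:7) {
    p <- org + (c(i, j, k) - 1) * sp
    arr[i, j, k] <- 2 * p[1] - 3 * p[2] + 0.5 * p[3] + 7
  }
  vol <- calibrated_volume(arr, sp, org, unit = "BMD")
  set.seed(21)
  pts <- cbind(runif(50, -0.9, 2.4), runif(50, 2.1, 6.7), runif(50, 0.1, 5.9))
  want <- 2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 7
  expect_equal(interp_trilinear(vol, pts), want, tolerance = 1e-12)
  expect_true(is.na(interp_trilinear(vol, cbind(-5, 3, 3))))
})

test_that("HU calibration fits and applies the rod line", {
  arr <- array(runif(60, 0, 1000), c(5, 4, 3))
  raw <- calibrated_volume(arr, c(1, 1, 1), unit = "HU")
  cal <- calibrate_volume(raw, rod_hu = c(0, 100, 200),
                          rod_density = c(0, 100, 200))
  expect_equal(cal$data, arr)                        # identity line
  expect_equal(cal$unit, "BMD")
  # synthetic encoding with slope 0.8, intercept -5
  dens <- array(runif(60, 0, 1200), c(5, 4, 3))
  raw2 <- calibrated_volume((dens + 5) / 0.8, c(1, 1, 1), unit = "HU")
  rod_d <- c(0, 100, 200, 400)
  cal2 <- calibrate_volume(raw2, (rod_d + 5) / 0.8, rod_d)
  expect_equal(cal2$calibration$slope, 0.8, tolerance = 1e-6)
  expect_equal(cal2$calibration$intercept, -5, tolerance = 1e-6)
  expect_equal(cal2$data, dens, tolerance = 1e-9)
  expect_error(calibrate_volume(raw, c(0, 100), c(0, 100)), "at least 3")
  expect_error(calibrate_volume(cal, c(0, 100, 200), c(0, 100, 200)),
               "already calibrated")
  expect_error(
    suppressWarnings(calibrate_volume(raw, c(0, 100, 200), c(50, 20, 300))),
    "R\\^2")
})

test_that("profiles from a uniform volume are constant", {
  vol <- calibrated_volume(array(300, c(40, 40, 30)),
                           c(1, 1, 1), c(-20, -20, -15), unit = "BMD")
  mesh <- small_mesh()
  profs <- sample_profiles(vol, mesh, depth_out = 2, depth_in = 3, step = 0.25,
                           truncate_chord = FALSE)
  for (pr in profs[c(1, 20, 80)])
    expect_true(all(abs(pr$values - 300) < 1e-9))
  expect_true(all(vapply(profs, attr, logical(1), "usable")))
})

test_that("flipping the normal reverses the sampled profile", {
  set.seed(22)
  arr <- array(runif(27000, 0, 500), c(30, 30, 30))
  vol <- calibrated_volume(arr, c(1, 1, 1), c(-15, -15, -15), unit = "BMD")
  mesh <- small_mesh()
  i <- 15
  pr <- sample_profiles(vol, mesh, 3, 3, 0.25, truncate_chord = FALSE)[[i]]
  flipped <- mesh
  flipped$normals <- -mesh$normals
  pf <- sample_profiles(vol, flipped, 3, 3, 0.25, truncate_chord = FALSE)[[i]]
  expect_equal(pf$values, rev(pr$values), tolerance = 1e-10)
})

test_that("profiles are truncated at half the chord to the opposing cortex", {
  mesh <- small_mesh()
  chord <- mesh_chord_lengths(mesh)
  expect_true(all(is.finite(chord)))
  # chord along the shortest axis is about twice the semi-axis
  pole <- which.max(abs(mesh$vertices[, 3]))
  expect_equal(chord[pole], 20, tolerance = 1.5)
  vol <- calibrated_volume(array(300, c(40, 40, 30)), c(1, 1, 1),
                           c(-20, -20, -15), unit = "BMD")
  profs <- sample_profiles(vol, mesh, depth_out = 2, depth_in = 15, step = 0.5)
  pr <- profs[[pole]]
  expect_true(all(is.na(pr$values[pr$positions > chord[pole] / 2])))
  expect_false(attr(pr, "usable"))  # >30% truncated at this depth
})

test_that("out-of-volume vertices yield missing samples, run completes", {
  vol <- calibrated_volume(array(300, c(20, 40, 30)), c(1, 1, 1),
                           c(0, -20, -15), unit = "BMD")  # half the mesh outside
  mesh <- small_mesh()
  profs <- sample_profiles(vol, mesh, 2, 3, 0.25, truncate_chord = FALSE)
  usable <- vapply(profs, attr, logical(1), "usable")
  expect_true(any(!usable))
  expect_true(any(usable))
  expect_length(profs, nrow(mesh$vertices))
})

test_that("surface smoothing preserves constants and fills invalid vertices", {
  mesh <- small_mesh()
  set.seed(23)
  valid <- runif(nrow(mesh$vertices)) > 0.25
  m <- vertex_map("ct_th", ifelse(valid, 1.7, NA), valid, mesh)
  sm <- smooth_vertex_map(m, fwhm = 6)
  expect_true(all(sm$valid))
  expect_equal(sm$values, rep(1.7, length(sm$values)), tolerance = 1e-12)
})

test_that("surface smoothing reduces white-noise variance", {
  mesh <- small_mesh()
  set.seed(24)
  m <- vertex_map("ct_th", rnorm(nrow(mesh$vertices)), mesh = mesh)
  sm <- smooth_vertex_map(m, fwhm = 5)
  expect_lt(var(sm$values), 0.6 * var(m$values))
})

test_that("impulse response matches the Gaussian kernel on a flat grid", {
  mesh <- grid_mesh(15, 15, h = 1)
  nv <- nrow(mesh$vertices)
  center <- (7L) * 15L + 8L   # middle of the grid
  m <- vertex_map("ct_th", as.numeric(seq_len(nv) == center), mesh = mesh)
  fwhm <- 4
  sm <- smooth_vertex_map(m, fwhm = fwhm)
  sdk <- fwhm / (2 * sqrt(2 * log(2)))
  # brute-force oracle: axis-aligned vertices sit at exact geodesic
  # distances 0..d on the flat grid
  along <- center + 0:4       # step +1 in x per vertex
  d <- 0:4
  want <- exp(-d^2 / (2 * sdk^2))
  got <- sm$values[along]
  expect_equal(got / got[1], want, tolerance = 0.05)
})

test_that("isolated vertices with no valid neighbors stay invalid", {
  mesh <- grid_mesh(9, 9)
  nv <- nrow(mesh$vertices)
  valid <- rep(FALSE, nv)
  valid[1] <- TRUE            # lone valid corner
  m <- vertex_map("ct_th", ifelse(valid, 1, NA), valid, mesh)
  expect_message(sm <- smooth_vertex_map(m, fwhm = 1), "remain invalid")
  expect_false(all(sm$valid))
})

test_that("body restriction masks posterior vertices for interior metrics", {
  mesh <- small_mesh(posterior_cap = 0.3)
  nv <- nrow(mesh$vertices)
  m <- vertex_map("cn_bmd", rep(110, nv), mesh = mesh)
  r <- restrict_to_body(m)
  expect_equal(sum(r$valid), sum(mesh$labels == "body"))
  expect_true(all(is.na(r$values[mesh$labels == "posterior"])))
  expect_equal(mean(r$values[r$valid]), 110)
  # cortical metrics keep every vertex
  mc <- vertex_map("ct_th", rep(0.9, nv), mesh = mesh)
  expect_identical(restrict_to_body(mc), mc)
  # all-body labeling is the identity
  mesh2 <- small_mesh(posterior_cap = 0)
  m2 <- vertex_map("ec_th", rep(0.1, nrow(mesh2$vertices)), mesh = mesh2)
  expect_equal(restrict_to_body(m2)$values, m2$values)
  m3 <- m
  m3$mesh$labels <- NULL
  expect_error(restrict_to_body(m3), "labels")
})

test_that("percentage and absolute change maps honor floors and validity", {
  mesh <- small_mesh()
  nv <- nrow(mesh$vertices)
  base <- vertex_map("ct_th", rep(0.5, nv), mesh = mesh)
  fol <- vertex_map("ct_th", rep(0.6, nv), mesh = mesh)
  pc <- percent_change_map(base, fol)
  expect_equal(pc$values, rep(20, nv), tolerance = 1e-12)
  expect_equal(percent_change_map(base, base)$values, rep(0, nv))
  ab <- absolute_change_map(base, fol)
  expect_equal(ab$values, rep(0.1, nv), tolerance = 1e-12)
  # sub-floor baselines are flagged, the rest computed
  bv <- rep(0.1, nv)
  bv[1:10] <- 0.005           # below the 0.02 mm Ec.Th floor
  b2 <- vertex_map("ec_th", bv, mesh = mesh)
  f2 <- vertex_map("ec_th", bv * 1.5, mesh = mesh)
  pc2 <- percent_change_map(b2, f2)
  expect_false(any(pc2$valid[1:10]))
  expect_equal(pc2$values[11:nv], rep(50, nv - 10), tolerance = 1e-9)
  gm <- grid_mesh(5, 5)
  other <- vertex_map("ct_th", rep(1, nrow(gm$vertices)), mesh = gm)
  expect_error(percent_change_map(base, other), "mesh")
  expect_error(percent_change_map(base, vertex_map("cmsd", rep(1, nv),
                                                   mesh = mesh)), "metric")
})

test_that("fine and coarse renderings give consistent thickness maps", {
  # micro-CT-style validation analog: per-vertex thickness fitted from
  # near-unblurred fine profiles vs a 1 mm-slice blurred noisy phantom
  ct_field <- function(dirs) 1.15 + 0.8 * dirs[, 3] # 0.35..1.95 mm
  spec <- phantom_spec(semiaxes = c(16, 13, 10), ct_th = ct_field,
                       ec_th = 0.15, y_c = 790, y_t = 112, y_bg = 30,
                       sigma_inplane = 0.8, sigma_slice = 1.0,
                       noise_sd = 15, spacing = c(0.5, 0.5, 1.0),
                       n_theta = 10, n_phi = 14, supersample = 2, seed = 9)
  ph <- gen_shell_phantom(spec)
  vol <- calibrate_volume(ph$volume, c(0, 500, 1000),
                          c(0, 500, 1000) * spec$hu_slope + spec$hu_intercept)
  sig_v <- psf_sigma_along_normals(ph$mesh, 0.8, 1.0,
                                   spacing = spec$spacing, supersample = 2)
  free <- fit_surface(vol, ph$mesh, fit_config(), sigma_scan = sig_v,
                      depth_in = 6)
  anchor <- median(free$ct_bmd$values[free$ct_bmd$valid])
  coarse <- fit_surface(vol, ph$mesh, fit_config(y_c_fixed = anchor),
                        sigma_scan = sig_v, depth_in = 6)
  truth <- ph$truth$ct_th$values
  # fine rendering: per-vertex profiles at 0.05 mm, near-zero blur
  fine_ct <- vapply(seq_len(nrow(ph$mesh$vertices)), function(i) {
    p <- params_of(truth[i], 0.15, sigma = 0.08)
    fit_profile(gen_profile(p, 0.05, 2, 4, 0),
                fit_config(sigma = 0.08))$metrics$ct_th
  }, numeric(1))
  ok <- coarse$ct_th$valid & truth >= 0.3 & truth <= 2
  expect_gt(sum(ok), 50)
  expect_gt(cor(fine_ct[ok], coarse$ct_th$values[ok]), 0.9)
})

test_that("unusable and invalid fits abort the surface fit when dominant", {
  vol <- calibrated_volume(array(300, c(40, 40, 30)), c(1, 1, 1),
                           c(-20, -20, -15), unit = "BMD")   # featureless
  mesh <- small_mesh()
  expect_error(fit_surface(vol, mesh, fit_config(sigma = 0.8),
                           sigma_scan = 0.8, depth_in = 5),
               "invalid")
})
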