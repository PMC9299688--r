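test_that("profile generator samples the blurred model exactly at zero noise", {
  p <- params_of(0.9, 0.2, sigma = 1.0)
  pr <- gen_profile(p, 0.2, 4, 8, noise_sd = 0)
  expect_equal(pr$values, eval_blurred(p, pr$positions), tolerance = 1e-12)
  expect_equal(pr$spacing, 0.2)
})

test_that("profile generation is seed-reproducible and RNG-scoped", {
  p <- params_of(0.9, 0.2, sigma = 1.0)
  a <- gen_profile(p, 0.2, 4, 8, 25, seed = 99)
  b <- gen_profile(p, 0.2, 4, 8, 25, seed = 99)
  expect_identical(a$values, b$values)
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(gen_profile(p, 0.2, 4, 8, 25, seed = 7))
  expect_identical(rnorm(1), before)   # caller's RNG stream untouched
})

test_that("empirical profile noise matches the requested SD", {
  p <- params_of(0.9, 0.2, sigma = 1.0)
  pr <- gen_profile(p, spacing = 0.0012, depth_out = 4, depth_in = 8,
                    noise_sd = 25, seed = 5)   # ~10,000 samples
  resid <- pr$values - eval_blurred(p, pr$positions)
  expect_gt(length(resid), 9000)
  expect_lt(abs(sd(resid) - 25) / 25, 0.02)
})

test_that("shell phantom renders the layered density structure", {
  spec <- phantom_spec(semiaxes = c(14, 11, 9), ct_th = 2.2, ec_th = 0.4,
                       y_c = 1000, y_t = 150, y_bg = 30,
                       sigma_inplane = 0.4, sigma_slice = 0.5, noise_sd = 0,
                       spacing = c(0.5, 0.5, 0.5), n_theta = 10, n_phi = 14,
                       supersample = 2, seed = 3)
  ph <- gen_shell_phantom(spec)
  dens <- ph$volume$data * spec$hu_slope + spec$hu_intercept
  # histogram modes near y_bg, y_c, y_t for a thick shell
  expect_gt(mean(abs(dens - 30) < 40), 0.3)    # background dominates
  expect_gt(mean(abs(dens - 150) < 60), 0.05)  # cancellous interior
  expect_gt(mean(abs(dens - 1000) < 120), 0.005) # cortical shell
  # truth maps cover every vertex
  expect_equal(length(ph$truth$ct_th$values), nrow(ph$mesh$vertices))
  expect_true(all(ph$truth$cmsd$values ==
                    0.1 * ph$truth$ct_th$values * ph$truth$ct_bmd$values))
})

test_that("phantom generation is deterministic and validates its spec", {
  spec <- phantom_spec(semiaxes = c(10, 9, 8), noise_sd = 10,
                       spacing = c(0.8, 0.8, 1.0), n_theta = 8, n_phi = 10,
                       supersample = 1, seed = 11)
  a <- gen_shell_phantom(spec)
  b <- gen_shell_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  thin <- phantom_spec(semiaxes = c(10, 9, 8), ct_th = 0.3,
                       spacing = c(0.8, 0.8, 1.0), supersample = 1)
  expect_error(gen_shell_phantom(thin), "thinner")
  bad <- phantom_spec(semiaxes = c(10, 9, 8), ct_th = 0.5, ec_th = 1.6,
                      spacing = c(0.4, 0.4, 0.5), supersample = 2)
  expect_error(gen_shell_phantom(bad), "ct_th >= ec_th/2")
})

test_that("phantom profiles converge as the rasterization step refines", {
  # halve the fine rasterization step below the default (supersample 2
  # -> 4) and require the sampled profiles to be stable
  mk <- function(ss) phantom_spec(semiaxes = c(10, 8, 7), ct_th = 1.2,
                                  ec_th = 0.2, noise_sd = 0,
                                  sigma_inplane = 0.8, sigma_slice = 1.0,
                                  spacing = c(0.6, 0.6, 1.0),
                                  n_theta = 8, n_phi = 10,
                                  supersample = ss, seed = 2)
  p1 <- gen_shell_phantom(mk(2L))
  p2 <- gen_shell_phantom(mk(4L))
  v1 <- calibrate_volume(p1$volume, c(0, 500, 1000),
                         c(0, 500, 1000) * 0.8 - 5)
  v2 <- calibrate_volume(p2$volume, c(0, 500, 1000),
                         c(0, 500, 1000) * 0.8 - 5)
  pr1 <- sample_profiles(v1, p1$mesh, 3, 4, 0.25, truncate_chord = FALSE)
  pr2 <- sample_profiles(v2, p2$mesh, 3, 4, 0.25, truncate_chord = FALSE)
  diffs <- vapply(seq_along(pr1), function(i)
    max(abs(pr1[[i]]$values - pr2[[i]]$values), na.rm = TRUE), numeric(1))
  expect_lt(median(diffs), 0.005 * 790)
})

test_that("cohort truths are drawn from the configured group distributions", {
  # enlarged single-group draw so the sampling check is tight
  spec <- cohort_spec(n = c(romosozumab = 80), n_vertices = 2,
                      noise_sd = 0, seed = 21)
  coh <- gen_cohort(spec)
  tt <- coh$truth_table
  ct <- tt$true_change[tt$metric == "ct_th"]
  expect_equal(length(ct), 80)
  expect_lt(abs(mean(ct) - 10.3), 2 * 4.9 / sqrt(80) * 2)  # within ~2 SE
  cn_base <- tt$baseline[tt$metric == "cn_bmd"]
  expect_lt(abs(mean(cn_base) - 113.3), 3 * 24.7 / sqrt(80))
  # implied CMSD change is the compound of Ct.Th and Ct.BMD changes
  for (s in unique(tt$subject)[1:5]) {
    r <- tt[tt$subject == s, ]
    want <- 100 * ((1 + r$true_change[r$metric == "ct_th"] / 100) *
                     (1 + r$true_change[r$metric == "ct_bmd"] / 100) - 1)
    expect_equal(r$true_change[r$metric == "cmsd"], want, tolerance = 1e-9)
  }
})

test_that("zero-effect cohorts average to no change", {
  zero <- change_presets()
  zero$mean <- 0
  zero$sd <- 0.5
  spec <- cohort_spec(n = c(placebo = 40), changes = zero, n_vertices = 2,
                      noise_sd = 0, seed = 22)
  tt <- gen_cohort(spec)$truth_table
  expect_lt(abs(mean(tt$true_change[tt$metric == "ct_th"])),
            3 * 0.5 / sqrt(40))
})

test_that("cohorts are reproducible and share the PSF across timepoints", {
  spec <- cohort_spec(n = c(placebo = 2), n_vertices = 5, seed = 23)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$truth_table, b$truth_table)
  expect_identical(a$subjects[[1]]$baseline_profiles[[1]]$values,
                   b$subjects[[1]]$baseline_profiles[[1]]$values)
  for (s in a$subjects) expect_equal(s$sigma, spec$sigma)
  # baseline Ec.Th draws respect the floor
  expect_true(all(a$truth_table$baseline[a$truth_table$metric == "ec_th"]
                  >= spec$ec_th_floor))
})

test_that("inconsistent cohort specs are rejected after bounded redraws", {
  bad <- change_presets()
  bad$mean[bad$metric == "cn_bmd"] <- -150   # follow-up density would go negative
  bad$sd[bad$metric == "cn_bmd"] <- 1
  spec <- cohort_spec(n = c(placebo = 2), changes = bad, n_vertices = 2,
                      seed = 24)
  expect_error(gen_cohort(spec), "inconsistent")
})
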