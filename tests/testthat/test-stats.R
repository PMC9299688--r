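test_that("global percentage change uses the ratio of in-scope means", {
  mesh <- small_mesh(posterior_cap = 0.3)
  nv <- nrow(mesh$vertices)
  base <- vertex_map("ct_th", rep(0.8, nv), mesh = mesh)
  fol <- vertex_map("ct_th", rep(0.88, nv), mesh = mesh)
  expect_equal(as.numeric(subject_percent_change(base, fol)), 10,
               tolerance = 1e-9)
  expect_equal(as.numeric(subject_percent_change(base, base)), 0)
  # body-only metric excludes posterior vertices from the means
  bvals <- ifelse(mesh$labels == "body", 100, 1e6)
  b2 <- vertex_map("cn_bmd", bvals, mesh = mesh)
  f2 <- vertex_map("cn_bmd", bvals * 1.2, mesh = mesh)
  out <- subject_percent_change(b2, f2)
  expect_equal(as.numeric(out), 20, tolerance = 1e-9)
  expect_equal(attr(out, "n_used"), sum(mesh$labels == "body"))
  # low validity flags the subject
  valid <- rep(FALSE, nv)
  valid[1:10] <- TRUE
  b3 <- vertex_map("ct_th", ifelse(valid, 1, NA), valid, mesh)
  out3 <- subject_percent_change(b3, b3)
  expect_true(attr(out3, "flagged"))
})

test_that("cohort summary reproduces textbook t-test behavior", {
  changes <- data.frame(
    subject = 1:6,
    group = rep(c("placebo", "teriparatide"), each = 3),
    metric = "ct_th",
    pct_change = c(1, 2, 3, 1, 2, 3))
  s <- summarize_cohort(changes)
  tab <- s$table
  # identical groups: Welch t = 0, p = 1
  expect_equal(tab$p_vs_placebo[tab$group == "teriparatide"], 1)
  expect_equal(tab$mean, c(2, 2))
  expect_equal(tab$sd, c(1, 1))
  # against-zero test matches stats::t.test
  expect_equal(tab$p_vs_baseline[1], t.test(c(1, 2, 3))$p.value)
})

test_that("degenerate zero-variance groups take the equality fast path", {
  ch0 <- data.frame(subject = 1:4, group = "placebo", metric = "cmsd",
                    pct_change = rep(0, 4))
  expect_equal(summarize_cohort(ch0)$table$p_vs_baseline, 1)
  ch1 <- data.frame(subject = 1:4, group = "placebo", metric = "cmsd",
                    pct_change = rep(2.5, 4))
  expect_equal(summarize_cohort(ch1)$table$p_vs_baseline, 0)
})

test_that("baseline comparability uses a one-way ANOVA per metric", {
  set.seed(32)
  baseline <- data.frame(
    subject = 1:30, group = rep(c("placebo", "teriparatide", "romosozumab"),
                                each = 10),
    metric = "ct_th", value = rnorm(30, 0.9, 0.05))
  changes <- data.frame(subject = 1:30, group = baseline$group,
                        metric = "ct_th", pct_change = rnorm(30))
  s <- summarize_cohort(changes, baseline)
  want <- anova(aov(value ~ factor(group), data = baseline))[["Pr(>F)"]][1]
  expect_equal(s$baseline_anova$p_anova, want)
})

test_that("type-I error of the between-group test is nominal", {
  # identical distributions in both groups: rejection rate ~ alpha
  set.seed(33)
  n_mc <- 4000
  rej <- 0L
  for (r in seq_len(n_mc)) {
    x <- rnorm(10)
    y <- rnorm(12)
    if (t.test(x, y, var.equal = FALSE)$p.value <= 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_mc, 0.04)
  expect_lt(rej / n_mc, 0.06)
})

test_that("vertex-wise SPM saturates under a strong uniform effect", {
  mesh <- small_mesh(posterior_cap = 0.2)
  nv <- nrow(mesh$vertices)
  set.seed(34)
  X <- matrix(rnorm(12 * nv), 12, nv) + 10    # ~10 SD effect
  scope <- mesh$labels == "body"
  sp <- vertexwise_spm(X, mesh, scope = scope, n_perm = 600, seed = 5)
  expect_true(all(sp$mask[scope]))
  expect_false(any(sp$mask[!scope]))          # mask stays inside scope
})

test_that("SPM permutation inference is reproducible and order-invariant", {
  mesh <- small_mesh()
  nv <- nrow(mesh$vertices)
  set.seed(35)
  X <- matrix(rnorm(14 * nv), 14, nv)
  X[, 1:20] <- X[, 1:20] + 1.5
  a <- vertexwise_spm(X, mesh, n_perm = 800, seed = 9)
  b <- vertexwise_spm(X, mesh, n_perm = 800, seed = 9)
  expect_identical(a$p_corrected, b$p_corrected)
  perm <- sample(14)
  c2 <- vertexwise_spm(X[perm, ], mesh, n_perm = 800, seed = 9)
  expect_equal(abs(c2$tstat), abs(a$tstat), tolerance = 1e-12)
})

test_that("SPM enumerates sign flips exhaustively for small cohorts", {
  mesh <- grid_mesh(5, 5)
  set.seed(36)
  X <- matrix(rnorm(8 * 25), 8, 25)
  sp <- vertexwise_spm(X, mesh, n_perm = 500, seed = 1)
  expect_true(sp$exhaustive)
  expect_equal(sp$n_perm_used, 2^8)
})

test_that("two-sample SPM localizes a patch effect", {
  mesh <- small_mesh()
  nv <- nrow(mesh$vertices)
  patch <- mesh$vertices[, 3] > 7
  set.seed(37)
  X <- matrix(rnorm(20 * nv), 20, nv)
  grp <- rep(c("a", "b"), each = 10)
  X[grp == "b", patch] <- X[grp == "b", patch] + 3
  sp <- vertexwise_spm(X, mesh, groups = grp, n_perm = 600, seed = 2)
  hits <- sp$mask
  dice <- 2 * sum(hits & patch) / (sum(hits) + sum(patch))
  expect_gt(dice, 0.5)
  expect_lt(mean(hits[!patch]), 0.05)
})

test_that("stronger effects never lose significant vertices", {
  mesh <- grid_mesh(8, 8)
  nv <- nrow(mesh$vertices)
  set.seed(38)
  base <- matrix(rnorm(12 * nv), 12, nv)
  counts <- vapply(c(0.5, 1, 2, 4), function(eff) {
    sum(vertexwise_spm(base + eff, mesh, n_perm = 600, seed = 3)$mask)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("significance pattern extraction reads the summary table", {
  changes <- data.frame(
    subject = 1:30,
    group = rep(c("placebo", "teriparatide", "romosozumab"), each = 10),
    metric = "cmsd",
    pct_change = c(rnorm(10, 0, 1), rnorm(10, 4, 1), rnorm(10, 12, 1)))
  pat <- significance_pattern(summarize_cohort(changes))
  expect_true(pat$rom_vs_teri)
  expect_true(pat$rom_vs_placebo)
  expect_true(pat$teri_vs_placebo)
})

test_that("rendered maps encode the display convention and round-trip", {
  mesh <- small_mesh(posterior_cap = 0.2)
  nv <- nrow(mesh$vertices)
  set.seed(39)
  X <- matrix(rnorm(10 * nv), 10, nv) + 8
  scope <- mesh$labels == "body"
  sp <- vertexwise_spm(X, mesh, scope = scope, n_perm = 600, seed = 4)
  f <- file.path(tempdir(), "map.ply")
  render_map(sp, f)
  back <- read_mesh_ply(f)
  sc <- attr(back, "scalars")
  expect_equal(sc$value[scope], sp$mean_change[scope], tolerance = 1e-12)
  expect_equal(as.logical(sc$significant), sp$mask & scope)
  expect_equal(as.logical(sc$in_scope), scope)
  # all-significant map in scope: no light gray there
  expect_true(all(sc$significant[scope] == 1))
  # empty mask: everything light gray (no significant vertices)
  sp0 <- sp
  sp0$mask <- rep(FALSE, nv)
  f0 <- file.path(tempdir(), "map0.ply")
  render_map(sp0, f0)
  sc0 <- attr(read_mesh_ply(f0), "scalars")
  expect_true(all(sc0$significant == 0))
})
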