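#' Per-subject global percentage change of one metric
#'
#' Ratio-of-means convention: 100 x (mean follow-up - mean baseline) /
#' mean baseline over in-scope valid vertices (vertebral body only for
#' Cn.BMD and Ec.Th). The ratio of means is used for global summaries
#' because it is stable against near-zero per-vertex baselines; the
#' per-vertex display maps use vertex-wise changes instead.
#'
#' @param baseline,followup [vertex_map()]s of the same metric on the
#'   canonical mesh.
#' @param scope Optional logical vertex mask overriding the default
#'   metric scope.
#' @return Scalar percentage change, with attributes `n_used` (vertices
#'   contributing) and `flagged` (`TRUE` when fewer than 50% of
#'   in-scope vertices were valid in both maps).
#' @export
subject_percent_change <- function(baseline, followup, scope = NULL) {
  check_change_pair(baseline, followup)
  if (is.null(scope)) scope <- metric_scope(baseline$metric, baseline$mesh)
  ok <- scope & baseline$valid & followup$valid
  if (!any(ok)) stop("subject_percent_change: no usable in-scope vertices")
  mb <- mean(baseline$values[ok])
  mf <- mean(followup$values[ok])
  if (abs(mb) < 1e-12) stop("subject_percent_change: zero mean baseline")
  out <- 100 * (mf - mb) / mb
  attr(out, "n_used") <- sum(ok)
  attr(out, "flagged") <- sum(ok) < 0.5 * sum(scope)
  out
}

two_tailed_t <- function(x, y = NULL, mu = 0) {
  # Welch two-sample / one-sample two-tailed t test with a degenerate
  # zero-variance fast path: p = 1 on exact equality, 0 otherwise.
  if (is.null(y)) {
    if (stats::sd(x) < 1e-12)
      return(list(p = if (abs(mean(x) - mu) < 1e-12) 1 else 0, t = NA_real_,
                  degenerate = TRUE))
    ht <- stats::t.test(x, mu = mu)
  } else {
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12)
      return(list(p = if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0,
                  t = NA_real_, degenerate = TRUE))
    ht <- stats::t.test(x, y, var.equal = FALSE)
  }
  list(p = unname(ht$p.value), t = unname(ht$statistic), degenerate = FALSE)
}

#' Group-level summary of percentage changes
#'
#' Produces a Table-style cohort summary: per treatment group and
#' metric, the mean and SD of the per-subject global percentage
#' changes, with two-tailed t tests versus baseline (one-sample against
#' 0), versus placebo and versus teriparatide (Welch two-sample), and a
#' one-way ANOVA of baseline comparability when baseline values are
#' supplied.
#'
#' @param changes Data frame with columns `subject`, `group`, `metric`,
#'   `pct_change` (e.g. from [run_pipeline()]).
#' @param baseline Optional data frame with columns `subject`, `group`,
#'   `metric`, `value` of per-subject global baseline means, used for
#'   the baseline one-way ANOVA.
#' @param groups Group factor levels, reference groups first.
#' @return An object of class `cohort_summary`: data frame `table` with
#'   columns `metric`, `group`, `n`, `mean`, `sd`, `p_vs_baseline`,
#'   `p_vs_placebo`, `p_vs_teriparatide`, plus `baseline_anova` (per
#'   metric) when baselines are given.
#' @export
summarize_cohort <- function(changes, baseline = NULL,
                             groups = c("placebo", "teriparatide",
                                        "romosozumab")) {
  stopifnot(all(c("subject", "group", "metric", "pct_change") %in%
                  names(changes)))
  changes$group <- as.character(changes$group)
  if (!all(changes$group %in% groups))
    stop("summarize_cohort: unknown group label(s): ",
         paste(setdiff(unique(changes$group), groups), collapse = ", "))
  rows <- list()
  for (m in unique(changes$metric)) {
    dm <- changes[changes$metric == m, ]
    vals <- split(dm$pct_change, factor(dm$group, levels = groups))
    if (any(vapply(vals, length, integer(1)) < 2L & vapply(vals, length, integer(1)) > 0L))
      stop("summarize_cohort: at least 2 subjects per present group required")
    for (g in groups) {
      x <- vals[[g]]
      if (!length(x)) next
      p_base <- two_tailed_t(x)$p
      p_plc <- if (g != "placebo" && length(vals[["placebo"]]))
        two_tailed_t(x, vals[["placebo"]])$p else NA_real_
      p_ter <- if (g == "romosozumab" && length(vals[["teriparatide"]]))
        two_tailed_t(x, vals[["teriparatide"]])$p else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g, n = length(x),
        mean = mean(x), sd = stats::sd(x),
        p_vs_baseline = p_base, p_vs_placebo = p_plc,
        p_vs_teriparatide = p_ter, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  anova_tab <- NULL
  if (!is.null(baseline)) {
    stopifnot(all(c("group", "metric", "value") %in% names(baseline)))
    anova_tab <- do.call(rbind, lapply(unique(baseline$metric), function(m) {
      bm <- baseline[baseline$metric == m, ]
      p <- if (length(unique(bm$group)) >= 2L)
        stats::anova(stats::aov(value ~ factor(group), data = bm))[["Pr(>F)"]][1]
      else NA_real_
      data.frame(metric = m, p_anova = p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab, baseline_anova = anova_tab, groups = groups),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary: mean (SD) percentage changes from baseline\n")
  tab <- x$table
  tab$mean <- sprintf("%.1f", tab$mean)
  tab$sd <- sprintf("%.1f", tab$sd)
  for (p in c("p_vs_baseline", "p_vs_placebo", "p_vs_teriparatide"))
    tab[[p]] <- ifelse(is.na(tab[[p]]), "", sprintf("%.4f", tab[[p]]))
  print(tab, row.names = FALSE)
  if (!is.null(x$baseline_anova)) {
    cat("Baseline comparability (one-way ANOVA):\n")
    print(x$baseline_anova, row.names = FALSE)
  }
  invisible(x)
}

#' Vertex-wise statistical parametric map with permutation correction
#'
#' Computes a per-vertex test statistic across subjects (one-sample t
#' of within-group percentage changes against zero, or Welch t between
#' two groups) and controls the family-wise error rate over the
#' in-scope vertices with the max-statistic permutation distribution:
#' sign flipping for the one-sample test, group-label permutation for
#' the two-sample test. When the requested number of permutations
#' exceeds the exhaustive count, all permutations are enumerated.
#'
#' @param change_maps Subjects x vertices matrix of per-vertex
#'   percentage changes on the canonical mesh (`NA` allowed outside
#'   scope).
#' @param mesh The canonical [surface_mesh()].
#' @param groups `NULL` for the one-sample test, else a 2-level factor
#'   of length `nrow(change_maps)`.
#' @param scope Logical in-scope vertex mask (default: all vertices;
#'   pass the metric scope for body-only metrics).
#' @param n_perm Number of permutations (>= 500).
#' @param alpha Family-wise significance level.
#' @param seed Seed for the permutation draw.
#' @return An object of class `spm_result`: `mean_change`, `tstat`,
#'   `p_corrected`, `mask` (significant vertices), `scope`, `alpha`,
#'   `n_perm_used`, `exhaustive`.
#' @export
vertexwise_spm <- function(change_maps, mesh, groups = NULL, scope = NULL,
                           n_perm = 1000, alpha = 0.05, seed = 1) {
  stopifnot(is.matrix(change_maps))
  nv <- ncol(change_maps)
  if (nv != nrow(mesh$vertices))
    stop("vertexwise_spm: columns must match canonical mesh vertices")
  if (n_perm < 500) stop("vertexwise_spm: n_perm must be >= 500")
  if (is.null(scope)) scope <- rep(TRUE, nv)
  usable <- scope & colSums(is.na(change_maps)) == 0
  X <- change_maps[, usable, drop = FALSE]
  n <- nrow(X)

  if (is.null(groups)) {
    t_obs <- one_sample_t_rows(matrix(1, 1, n), X)[1, ]
    ex_count <- 2^n
    exhaustive <- ex_count <= n_perm
    signs <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                             n_perm, n))
    }
    t_null <- one_sample_t_rows(signs, X)
    mean_change_u <- colMeans(X)
  } else {
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
      stop("vertexwise_spm: exactly 2 groups required for the two-sample map")
    g1 <- groups == levels(groups)[1]
    t_obs <- welch_t_cols(X[g1, , drop = FALSE], X[!g1, , drop = FALSE])
    ex_count <- choose(n, sum(g1))
    exhaustive <- ex_count <= n_perm
    perms <- if (exhaustive) {
      utils::combn(n, sum(g1), simplify = FALSE)
    } else {
      with_seed(seed, replicate(n_perm, sample(n, sum(g1)), simplify = FALSE))
    }
    t_null <- t(vapply(perms, function(idx) {
      sel <- seq_len(n) %in% idx
      suppressWarnings(max(abs(welch_t_cols(X[sel, , drop = FALSE],
                                            X[!sel, , drop = FALSE])),
                           na.rm = TRUE))
    }, numeric(1)))
    t_null <- matrix(t_null, ncol = 1)
    mean_change_u <- colMeans(X[g1, , drop = FALSE]) -
      colMeans(X[!g1, , drop = FALSE])
  }
  max_null <- if (ncol(t_null) > 1) apply(abs(t_null), 1, max) else t_null[, 1]
  B <- length(max_null)
  p_u <- vapply(abs(t_obs), function(tv) (1 + sum(max_null >= tv - 1e-12)) /
                  (B + 1), numeric(1))

  expand <- function(v) { out <- rep(NA_real_, nv); out[usable] <- v; out }
  p_corrected <- expand(p_u)
  mask <- !is.na(p_corrected) & p_corrected <= alpha
  structure(list(mean_change = expand(mean_change_u),
                 tstat = expand(t_obs),
                 p_corrected = p_corrected,
                 mask = mask, scope = scope, alpha = alpha,
                 n_perm_used = B, exhaustive = exhaustive,
                 mesh = mesh),
            class = "spm_result")
}

# Row-wise one-sample t statistics for many sign patterns at once.
# signs: B x n matrix; X: n x V matrix. Uses the sign-flip invariance of
# sum(x^2) so only the flipped means need recomputation.
one_sample_t_rows <- function(signs, X) {
  n <- nrow(X)
  M <- (signs %*% X) / n                       # B x V flipped means
  ss <- matrix(colSums(X^2), nrow(M), ncol(M), byrow = TRUE)
  v <- (ss - n * M^2) / (n - 1)
  v[v < 0] <- 0
  M / sqrt(v / n)
}

welch_t_cols <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "spm_result: %d/%d in-scope vertices significant at alpha = %g (%s, %d permutations)\n",
    sum(x$mask), sum(x$scope), x$alpha,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_perm_used))
  invisible(x)
}

# Seed-scoped RNG: runs code under set.seed(seed) and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
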