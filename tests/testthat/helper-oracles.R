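# Independent numeric-convolution oracle for the blurred cortical model:
# adaptive quadrature of (piecewise model) x (Gaussian kernel), split at
# the model's breakpoints so each integrand piece is smooth. Shares no
# code path with eval_blurred's closed form.
conv_oracle <- function(p, xs) {
  brk <- c(-Inf, p$x0, p$x1, p$x2, Inf)
  vapply(xs, function(x) {
    tot <- 0
    for (i in 1:4) {
      lo <- max(brk[i], x - 9 * p$sigma)
      hi <- min(brk[i + 1], x + 9 * p$sigma)
      if (lo >= hi) next
      tot <- tot + stats::integrate(
        function(t) eval_unblurred(p, t) * stats::dnorm((x - t) / p$sigma) / p$sigma,
        lo, hi, rel.tol = 1e-12, abs.tol = 1e-12,
        subdivisions = 400L)$value
    }
    tot
  }, numeric(1))
}

# Random valid parameter set in a broad physiological range.
random_params <- function() {
  x0 <- stats::runif(1, -1, 1)
  ct <- stats::runif(1, 0.3, 3)
  ec <- stats::runif(1, 0.02, min(1.2, 1.5 * ct))
  cortical_params(x0, x0 + ct - ec / 2, x0 + ct + ec / 2,
                  y_bg = stats::runif(1, 0, 100),
                  y_c = stats::runif(1, 400, 1500),
                  y_t = stats::runif(1, 0, 300),
                  sigma = stats::runif(1, 0.2, 1.5))
}

params_of <- function(ct, ec, y_bg = 30, y_c = 790, y_t = 112, sigma = 1.0,
                      x0 = 0) {
  cortical_params(x0, x0 + ct - ec / 2, x0 + ct + ec / 2,
                  y_bg, y_c, y_t, sigma)
}

# Small phantom mesh shared by surface-level tests.
small_mesh <- function(posterior_cap = 0) {
  ellipsoid_mesh(c(16, 13, 10), n_theta = 10, n_phi = 14,
                 posterior_cap = posterior_cap)
}

# Flat regular-grid strip mesh (right-triangle split) in the z = 0
# plane; graph distance along a grid axis equals Euclidean distance.
grid_mesh <- function(nx = 15, ny = 15, h = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind((g$x - 1) * h, (g$y - 1) * h, 0)
  id <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  surface_mesh(v, do.call(rbind, tris),
               normals = matrix(rep(c(0, 0, 1), nrow(v)), ncol = 3,
                                byrow = TRUE))
}
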