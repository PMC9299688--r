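#' Render a surface map or SPM result to mesh-scalar and image files
#'
#' Writes the mesh with per-vertex scalar values, validity/significance
#' mask and display colors as ASCII PLY (bit-exact scalar round-trip),
#' plus an optional rasterized PNG snapshot (orthographic projection).
#' Display convention: light gray where changes are not statistically
#' significant, dark gray where the region is out of scope (posterior
#' elements for body-only metrics); numeric colors appear only where
#' the mask is true.
#'
#' @param x A [vertex_map()] or `spm_result`.
#' @param path Output `.ply` path; the snapshot (if any) replaces the
#'   extension with `.png`.
#' @param palette Color function mapping `n` to colors (default
#'   blue-white-red).
#' @param snapshot Write a PNG snapshot as well.
#' @return Named character vector of the files written, invisibly.
#' @export
render_map <- function(x, path, palette = NULL, snapshot = FALSE) {
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))
  if (inherits(x, "spm_result")) {
    mesh <- x$mesh
    values <- x$mean_change
    show <- x$mask
    scope <- x$scope
  } else if (inherits(x, "vertex_map")) {
    mesh <- x$mesh
    values <- x$values
    show <- x$valid
    scope <- metric_scope(x$metric, mesh)
  } else stop("render_map: x must be a vertex_map or spm_result")

  col <- rep("#C8C8C8", length(values))        # light gray: not significant
  col[!scope] <- "#5A5A5A"                     # dark gray: out of scope
  if (any(show & scope)) {
    v <- values[show & scope]
    ramp <- palette(256)
    lim <- max(abs(v), 1e-12)
    idx <- pmin(256L, pmax(1L, 1L + floor(255 * (v + lim) / (2 * lim))))
    col[show & scope] <- ramp[idx]
  }
  rgb <- grDevices::col2rgb(col)

  out_ply <- path
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    write_ply_colored(mesh, out_ply, values, show, scope, rgb)
    TRUE
  }, error = function(e)
    stop("render_map: failed writing ", out_ply, ": ", conditionMessage(e)))
  written <- c(ply = out_ply)
  if (snapshot) {
    out_png <- sub("\\.ply$", ".png", path)
    tryCatch({
      grDevices::png(out_png, width = 700, height = 700, type = "cairo")
      on.exit(grDevices::dev.off(), add = TRUE)
      ord <- order(mesh$vertices[, 2])  # painter's order along view axis
      plot(mesh$vertices[ord, 1], mesh$vertices[ord, 3],
           col = col[ord], pch = 16, cex = 1.4, asp = 1,
           xlab = "x (mm)", ylab = "z (mm)",
           main = if (inherits(x, "spm_result"))
             "mean % change (gray = not significant)" else x$metric)
    }, error = function(e)
      stop("render_map: failed writing ", out_png, ": ", conditionMessage(e)))
    written <- c(written, png = out_png)
  }
  invisible(written)
}

write_ply_colored <- function(mesh, path, values, show, scope, rgb) {
  nv <- nrow(mesh$vertices)
  header <- c("ply", "format ascii 1.0",
              "comment cbmap rendered map",
              sprintf("element vertex %d", nv),
              sprintf("property double %s", c("x", "y", "z")),
              "property double value",
              "property uchar significant",
              "property uchar in_scope",
              sprintf("property uchar %s", c("red", "green", "blue")),
              sprintf("element face %d", nrow(mesh$triangles)),
              "property list uchar int vertex_indices",
              "end_header")
  vals <- ifelse(is.na(values), 0, values)
  lines <- paste(
    apply(mesh$vertices, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")),
    sprintf("%.17g", vals),
    as.integer(show & scope), as.integer(scope),
    rgb[1, ], rgb[2, ], rgb[3, ])
  faces <- apply(mesh$triangles - 1L, 1, function(t)
    paste(3, paste(t, collapse = " ")))
  writeLines(c(header, lines, faces), path)
  invisible(path)
}
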