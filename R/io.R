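#' Read a CT volume from NIfTI or MetaImage
#'
#' Volumes are treated as axis-aligned in the world frame: spacing and
#' origin are honored, rotational components of a NIfTI affine are not
#' supported.
#'
#' @param path File path (`.nii`, `.nii.gz` or `.mha`).
#' @param unit `"HU"` for raw scans or `"BMD"` for calibrated ones; the
#'   unit flag is required because voxel data do not self-describe it.
#' @return A [calibrated_volume()].
#' @export
read_volume <- function(path, unit = c("HU", "BMD")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  if (grepl("\\.mha$", path, ignore.case = TRUE))
    return(read_mha(path, unit))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  off_diag <- aff[1:3, 1:3]
  diag(off_diag) <- 0
  if (any(abs(off_diag) > 1e-6))
    stop("read_volume: rotated/oblique NIfTI orientations are not supported")
  calibrated_volume(as.array(img),
                    spacing = abs(diag(aff[1:3, 1:3])),
                    origin = aff[1:3, 4], unit = unit)
}

#' Write a CT volume to NIfTI or MetaImage
#'
#' @param volume A [calibrated_volume()].
#' @param path Output path (`.nii`, `.nii.gz` or `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "calibrated_volume"))
  if (grepl("\\.mha$", path, ignore.case = TRUE))
    return(write_mha(volume, path))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal MetaImage (.mha, local uncompressed raw) support.
read_mha <- function(path, unit) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("read_mha: header ended before ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("read_mha: only ElementDataFile = LOCAL is supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, 3)
  size <- switch(hdr$ElementType, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("read_mha: unsupported ElementType ", hdr$ElementType))
  vals <- readBin(con, "double", n = prod(dims), size = size,
                  endian = "little")
  calibrated_volume(array(vals, dims), spacing = spacing, origin = origin,
                    unit = unit)
}

write_mha <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(volume$data), collapse = " ")),
           paste("ElementSpacing =", paste(volume$spacing, collapse = " ")),
           paste("Offset =", paste(volume$origin, collapse = " ")),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.vector(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Write a surface mesh (with optional per-vertex scalars) as ASCII PLY
#'
#' Vertex positions, normals, region labels and any number of named
#' per-vertex scalar fields are stored as PLY vertex properties with
#' full double precision, so scalar round-trips are bit-exact.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path (`.ply`).
#' @param scalars Optional named list of per-vertex numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, scalars = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices)
  if (!is.null(scalars)) {
    stopifnot(is.list(scalars), !is.null(names(scalars)))
    for (s in scalars) if (length(s) != nv)
      stop("write_mesh_ply: scalar length must match vertex count")
  }
  props <- c("x", "y", "z", "nx", "ny", "nz")
  header <- c("ply", "format ascii 1.0",
              "comment cbmap surface mesh",
              sprintf("element vertex %d", nv),
              sprintf("property double %s", props),
              "property uchar region",
              if (!is.null(scalars))
                sprintf("property double %s", names(scalars)),
              sprintf("element face %d", nrow(mesh$triangles)),
              "property list uchar int vertex_indices",
              "end_header")
  cols <- cbind(mesh$vertices, mesh$normals)
  num <- apply(cols, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  region <- as.integer(mesh$labels == "posterior")
  lines <- paste(num, region)
  if (!is.null(scalars)) {
    sc <- do.call(cbind, scalars)
    sc_str <- apply(sc, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    lines <- paste(lines, sc_str)
  }
  faces <- apply(mesh$triangles - 1L, 1, function(t)
    paste(3, paste(t, collapse = " ")))
  writeLines(c(header, lines, faces), path)
  invisible(path)
}

#' Read an ASCII PLY surface mesh written by [write_mesh_ply()]
#'
#' Also accepts generic ASCII PLY meshes with at least x/y/z vertex
#' properties and triangular faces; normals are recomputed when absent.
#'
#' @param path Input path.
#' @return A [surface_mesh()]; any extra per-vertex scalar properties
#'   are attached as the attribute `scalars` (named list).
#' @export
read_mesh_ply <- function(path) {
  if (!file.exists(path)) stop("read_mesh_ply: no such file: ", path)
  lines <- readLines(path)
  if (!identical(lines[1], "ply") || !any(grepl("^format ascii", lines[2])))
    stop("read_mesh_ply: not an ASCII PLY file: ", path)
  end_h <- match("end_header", lines)
  header <- lines[seq_len(end_h)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  v_start <- match(sprintf("element vertex %d", nv), header)
  f_start <- match(sprintf("element face %d", nf), header)
  vprops <- header[(v_start + 1):(f_start - 1)]
  vprops <- sub("^property \\S+ ", "", vprops[grepl("^property ", vprops)])
  vdat <- utils::read.table(text = lines[(end_h + 1):(end_h + nv)],
                            col.names = vprops)
  fdat <- utils::read.table(text = lines[(end_h + nv + 1):(end_h + nv + nf)])
  if (any(fdat[, 1] != 3)) stop("read_mesh_ply: non-triangular faces")
  triangles <- as.matrix(fdat[, 2:4]) + 1L
  normals <- if (all(c("nx", "ny", "nz") %in% vprops))
    as.matrix(vdat[, c("nx", "ny", "nz")]) else NULL
  labels <- if ("region" %in% vprops)
    ifelse(vdat$region == 1, "posterior", "body") else NULL
  mesh <- surface_mesh(as.matrix(vdat[, c("x", "y", "z")]), triangles,
                       normals = normals, labels = labels)
  extra <- setdiff(vprops, c("x", "y", "z", "nx", "ny", "nz", "region"))
  if (length(extra))
    attr(mesh, "scalars") <- as.list(vdat[, extra, drop = FALSE])
  mesh
}

#' Write a vertex map as CSV
#'
#' Interchange format for per-vertex metric values: columns
#' `vertex_id`, `value`, `valid`, `label`.
#'
#' @param map A [vertex_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "vertex_map"))
  df <- data.frame(vertex_id = seq_along(map$values),
                   value = sprintf("%.17g", map$values),
                   valid = as.integer(map$valid),
                   label = map$mesh$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vertex map from CSV
#'
#' @param path Input path.
#' @param mesh The [surface_mesh()] the map belongs to.
#' @param metric Metric name to record on the map.
#' @return A [vertex_map()].
#' @export
read_map_csv <- function(path, mesh, metric = "value") {
  if (!file.exists(path)) stop("read_map_csv: no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("vertex_id", "value", "valid")
  if (!all(need %in% names(df)))
    stop("read_map_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  nv <- nrow(mesh$vertices)
  missing_v <- setdiff(seq_len(nv), df$vertex_id)
  if (length(missing_v))
    stop("read_map_csv: no row for vertex ", missing_v[1],
         if (length(missing_v) > 1) sprintf(" (and %d more)", length(missing_v) - 1))
  df <- df[order(df$vertex_id), ]
  vertex_map(metric, as.numeric(df$value), as.logical(df$valid), mesh)
}

#' Persist the effective run configuration
#'
#' Every output directory should contain the effective configuration
#' and seed needed to reproduce it; this writes them as YAML.
#'
#' @param config A named list (e.g. [fit_config()], [cohort_spec()] or
#'   a run-level list combining them).
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), function(x)
    if (is.function(x)) "<function>" else x, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path Input path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  yaml::read_yaml(path)
}
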