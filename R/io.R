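# File formats: legacy-ASCII VTK and ASCII PLY meshes, CSV annotations,
# JSON ground truth, and the checksummed map bundle.

BUNDLE_FORMAT_VERSION <- "1.0"

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a mesh as legacy ASCII VTK polydata
#'
#' Per-vertex arrays (LAT, isochrone index, label code) go out as POINT_DATA
#' scalars for visualization.
#'
#' @param mesh an `ilam_mesh`.
#' @param path output file.
#' @param point_data named list of per-vertex numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ilamr surface mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(.fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      v[!is.finite(v)] <- -1
      writeLines(.fmt_num(v), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK polydata file written by [write_vtk()]
#'
#' @param path file path.
#' @return list with `vertices`, `triangles`, `point_data`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  vertices <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                     ncol = 3, byrow = TRUE)
  colnames(vertices) <- c("x", "y", "z")
  it <- grep("^POLYGONS", lines)[1]
  m <- as.integer(strsplit(lines[it], " ")[[1]][2])
  tri <- matrix(scan(text = lines[(it + 1):(it + m)], quiet = TRUE),
                ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  pd <- list()
  for (is in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is], " ")[[1]][2]
    vals <- scan(text = lines[(is + 2):(is + 1 + n)], quiet = TRUE)
    vals[vals == -1] <- NA_real_
    pd[[nm]] <- vals
  }
  list(vertices = vertices, triangles = tri, point_data = pd)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh an `ilam_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", m),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(.fmt_num(r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path file path.
#' @return list with `vertices` and `triangles` (1-based).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                  lines, value = TRUE)))
  m <- as.integer(sub("element face ", "", grep("^element face",
                                                lines, value = TRUE)))
  hdr <- grep("^end_header", lines)[1]
  vertices <- matrix(scan(text = lines[(hdr + 1):(hdr + n)], quiet = TRUE),
                     ncol = 3, byrow = TRUE)
  colnames(vertices) <- c("x", "y", "z")
  tri <- matrix(scan(text = lines[(hdr + n + 1):(hdr + n + m)], quiet = TRUE),
                ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  list(vertices = vertices, triangles = tri)
}

#' Write a map bundle
#'
#' A bundle directory holds the mesh (VTK + PLY), the site annotations (CSV),
#' optional ground truth (JSON) and a manifest with the format version, seed,
#' rhythm tag and an md5 checksum per file. Coordinates are 3D mm,
#' right-handed; vertex indices are 0-based in files; times are ms from the
#' map reference.
#'
#' @param bundle list with `mesh`, `annotations`, optional `ground_truth`
#'   (an `ilam_truth`), `seed`, `rhythm`, and optional `extra` manifest keys.
#' @param path bundle directory (created).
#' @return `path`, invisibly.
#' @export
write_map_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mesh <- bundle$mesh
  pd <- list(label_code = as.numeric(factor(mesh$label,
                                            levels = c("conducting",
                                                       STRUCTURE_LABELS))))
  if (!is.null(bundle$ground_truth)) pd$true_lat_ms <- bundle$ground_truth$lat
  write_vtk(mesh, file.path(path, "mesh.vtk"), point_data = pd)
  write_ply(mesh, file.path(path, "mesh.ply"))
  utils::write.csv(bundle$annotations, file.path(path, "annotations.csv"),
                   row.names = FALSE)
  files <- c("mesh.vtk", "mesh.ply", "annotations.csv")
  if (!is.null(bundle$ground_truth)) {
    jsonlite::write_json(list(lat = bundle$ground_truth$lat,
                              corridors = bundle$ground_truth$corridors),
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, "ground_truth.json")
  }
  manifest <- c(list(
    format_version = BUNDLE_FORMAT_VERSION,
    seed = bundle$seed %||% NA,
    rhythm = bundle$rhythm %||% "sinus",
    spacing_mm = mesh$spacing,
    kind = mesh$kind, nx = mesh$nx, ny = mesh$ny,
    label_levels = c("conducting", STRUCTURE_LABELS),
    checksums = as.list(tools::md5sum(file.path(path, files)))
  ), bundle$extra)
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a map bundle
#'
#' Verifies the format version and every checksum before loading; a mismatch
#' errors naming the offending file. Unknown manifest keys are preserved in
#' `$extra`.
#'
#' @param path bundle directory.
#' @return list with `mesh` (an `ilam_mesh` rebuilt from file),
#'   `annotations`, `ground_truth` (NULL when absent), `seed`, `rhythm`,
#'   `extra`.
#' @export
read_map_bundle <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(manifest$format_version)) stop_ilam("manifest has no version")
  if (manifest$format_version != BUNDLE_FORMAT_VERSION) {
    stop_ilam("unknown bundle format version '%s'", manifest$format_version)
  }
  for (f in names(manifest$checksums)) {
    got <- unname(tools::md5sum(file.path(path, f)))
    if (is.na(got) || got != manifest$checksums[[f]]) {
      stop_ilam("checksum mismatch for '%s'", f)
    }
  }
  vt <- read_vtk(file.path(path, "mesh.vtk"))
  label <- manifest$label_levels[vt$point_data$label_code]
  mesh <- structure(list(vertices = vt$vertices, triangles = vt$triangles,
                         label = label, spacing = manifest$spacing_mm,
                         kind = manifest$kind, nx = manifest$nx,
                         ny = manifest$ny, scenario = NULL, severed = NULL),
                    class = "ilam_mesh")
  mesh$edges <- .mesh_edge_list(mesh)
  mesh$edge_len <- .edge_lengths(mesh, mesh$edges)
  mesh$metric_edges <- .metric_edge_list(mesh)
  mesh$metric_len <- .edge_lengths(mesh, mesh$metric_edges)
  truth <- NULL
  if (file.exists(file.path(path, "ground_truth.json"))) {
    gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                              simplifyVector = TRUE)
    lat <- as.numeric(gt$lat)
    truth <- structure(list(lat = lat, corridors = gt$corridors,
                            severed = NULL), class = "ilam_truth")
  } else if (!is.null(vt$point_data$true_lat_ms)) {
    truth <- structure(list(lat = vt$point_data$true_lat_ms,
                            corridors = list(), severed = NULL),
                       class = "ilam_truth")
  }
  known <- c("format_version", "seed", "rhythm", "spacing_mm", "kind",
             "nx", "ny", "label_levels", "checksums")
  list(mesh = mesh,
       annotations = utils::read.csv(file.path(path, "annotations.csv")),
       ground_truth = truth,
       seed = manifest$seed, rhythm = manifest$rhythm,
       extra = manifest[setdiff(names(manifest), known)])
}
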