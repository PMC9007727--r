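# Format adapters: NIfTI statistical volumes, CSV surface/sensor tables,
# JSON metric bundles, and light run manifests with checksums.

#' Read a NIfTI statistical volume
#'
#' @param path .nii or .nii.gz file.
#' @return `stat_volume` (values + voxel-to-mm affine).
#' @export
read_stat_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  stat_volume(array(as.numeric(img), dim = dim(img)[1:3]), unclass(aff))
}

#' Write a stat volume (or cluster label volume) as NIfTI
#'
#' @param vol `stat_volume`.
#' @param path output path.
#' @export
write_stat_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export clusters as a NIfTI label volume
#'
#' @param clusters list from [threshold_statmap()].
#' @param vol the parent `stat_volume` (for grid and affine).
#' @param path output path.
#' @export
write_cluster_labels <- function(clusters, vol, path) {
  lab <- array(0L, dim = dim(vol$values))
  for (k in seq_along(clusters))
    lab[clusters[[k]]$voxel_indices] <- k
  write_stat_volume(stat_volume(lab, vol$affine), path)
}

#' Write / read a cortical mesh as CSV vertex and face tables
#'
#' @param mesh `cortical_mesh`.
#' @param stem file stem; writes `<stem>_vertices.csv` (x, y, z in mm and
#'   the unit normal) and `<stem>_faces.csv` (1-based indices).
#' @export
write_mesh_csv <- function(mesh, stem) {
  vdf <- data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                    z = mesh$vertices[, 3], nx = mesh$normals[, 1],
                    ny = mesh$normals[, 2], nz = mesh$normals[, 3])
  write.csv(vdf, paste0(stem, "_vertices.csv"), row.names = FALSE)
  write.csv(as.data.frame(mesh$faces), paste0(stem, "_faces.csv"),
            row.names = FALSE)
  invisible(stem)
}

#' @rdname write_mesh_csv
#' @export
read_mesh_csv <- function(stem) {
  v <- read.csv(paste0(stem, "_vertices.csv"))
  f <- as.matrix(read.csv(paste0(stem, "_faces.csv")))
  cortical_mesh(as.matrix(v[, c("x", "y", "z")]), f,
                normals = as.matrix(v[, c("nx", "ny", "nz")]))
}

#' Write / read a sensor array as CSV (mm positions)
#'
#' Columns: name, x, y, z (mm), ox, oy, oz.
#' @param sensors `sensor_array` (metres internally).
#' @param path CSV path.
#' @export
write_sensors_csv <- function(sensors, path) {
  df <- data.frame(name = sprintf("MEG%03d", seq_len(sensors$n_channels)),
                   x = sensors$positions[, 1] * MM_PER_M,
                   y = sensors$positions[, 2] * MM_PER_M,
                   z = sensors$positions[, 3] * MM_PER_M,
                   ox = sensors$orientations[, 1],
                   oy = sensors$orientations[, 2],
                   oz = sensors$orientations[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensors_csv
#' @export
read_sensors_csv <- function(path) {
  df <- read.csv(path)
  sensor_array(as.matrix(df[, c("x", "y", "z")]) / MM_PER_M,
               as.matrix(df[, c("ox", "oy", "oz")]))
}

#' Export a vertex indicator as CSV (vertex, weight)
#' @param q `vertex_indicator`.
#' @param path CSV path.
#' @export
write_indicator_csv <- function(q, path) {
  nz <- which(q$weights > 0)
  write.csv(data.frame(vertex = nz, weight = q$weights[nz]), path,
            row.names = FALSE)
  invisible(path)
}

#' Write a metrics bundle as JSON
#'
#' @param metrics named list (numbers, vectors, data.frames).
#' @param path output path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a run manifest with file checksums
#'
#' Records the configuration, package version, and an md5 checksum per
#' output file, so a rerun can be verified byte-for-byte.
#'
#' @param config list describing the run (must be JSON-serializable).
#' @param files character vector of produced files.
#' @param path manifest path (JSON).
#' @export
write_run_manifest <- function(config, files, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("pebmeg")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files)),
                       bytes = unname(file.size(files))))
  write_metrics_json(manifest, path)
  invisible(path)
}

#' Verify a run manifest's checksums
#'
#' @param path manifest JSON.
#' @return logical vector per file (TRUE = checksum matches), named by path.
#' @export
verify_run_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- m$files
  ok <- vapply(seq_along(fl$path), function(i) {
    file.exists(fl$path[i]) && unname(tools::md5sum(fl$path[i])) == fl$md5[i]
  }, TRUE)
  names(ok) <- fl$path
  ok
}
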