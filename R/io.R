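# Plain-text readers and writers.  GIFTI/NIfTI tooling is not assumed:
# surface maps, meshes and tables use documented flat text formats
# (tab-separated values with headers), configs use JSON.  Every writer has
# a matching reader and round-trips exactly at full double precision.

#' Write / read a surface map (one value per vertex)
#'
#' TSV with a single `value` column, row i = vertex i.
#' @param x numeric vector
#' @param path file path
#' @return `read_surface_map` returns a numeric vector
#' @export
write_surface_map <- function(x, path) {
  utils::write.table(data.frame(value = format(x, digits = 17)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_map
#' @export
read_surface_map <- function(path) {
  as.numeric(read.delim(path)$value)
}

#' Write / read a subject table
#' @param subjects data frame as produced by [generate_cohort()]
#' @param path file path
#' @export
write_subject_table <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a mesh as a directory of TSV files
#'
#' Writes `vertices.tsv`, `triangles.tsv`, `thickness.tsv`, `hemi.tsv`,
#' plus `parcel.tsv` and `patches.json` when present.  A documented flat
#' fallback for environments without surface-format tooling.
#'
#' @param mesh a `pet_mesh`
#' @param dir output directory (created if needed)
#' @export
write_mesh <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                         row.names = FALSE, quote = FALSE)
  w(as.data.frame(mesh$vertices), "vertices.tsv")
  w(as.data.frame(mesh$triangles), "triangles.tsv")
  w(data.frame(thickness = mesh$thickness, hemi = mesh$hemi), "thickness.tsv")
  if (!is.null(mesh$parcel))
    w(data.frame(parcel = mesh$parcel, cortex = mesh$cortex,
                 neocortex = mesh$neocortex), "parcel.tsv")
  if (!is.null(mesh$patches))
    jsonlite::write_json(mesh$patches, file.path(dir, "patches.json"))
  if (!is.null(mesh$unit)) w(as.data.frame(mesh$unit), "unit.tsv")
  invisible(dir)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(dir) {
  verts <- as.matrix(read.delim(file.path(dir, "vertices.tsv")))
  tris <- as.matrix(read.delim(file.path(dir, "triangles.tsv")))
  th <- read.delim(file.path(dir, "thickness.tsv"))
  m <- new_pet_mesh(unname(verts), unname(tris), th$thickness,
                    as.character(th$hemi))
  pf <- file.path(dir, "parcel.tsv")
  if (file.exists(pf)) {
    p <- read.delim(pf)
    m$parcel <- as.character(p$parcel)
    m$cortex <- p$cortex
    m$neocortex <- p$neocortex
  }
  pj <- file.path(dir, "patches.json")
  if (file.exists(pj))
    m$patches <- lapply(jsonlite::read_json(pj), function(v)
      as.integer(unlist(v)))
  uf <- file.path(dir, "unit.tsv")
  if (file.exists(uf)) m$unit <- unname(as.matrix(read.delim(uf)))
  m
}

#' Write / read a configuration object as JSON
#'
#' @param config a named list (e.g. [cohort_config()] or
#'   [pipeline_config()])
#' @param path file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
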