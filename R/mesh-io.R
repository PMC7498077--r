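# Mesh export: Wavefront OBJ (named groups, shared vertex numbering) and
# ASCII PLY, one organ per group or one file per mesh.

#' Write meshes to a Wavefront OBJ file
#'
#' A single \code{organ_mesh} or a named list of them; each mesh becomes an
#' \code{o}-group, with global 1-based vertex numbering, coordinates in mm.
#'
#' @param meshes An \code{organ_mesh} or named list of \code{organ_mesh}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_obj <- function(meshes, path) {
  if (inherits(meshes, "organ_mesh")) meshes <- list(mesh = meshes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tuberoot mesh export", con)
  offset <- 0L
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    writeLines(paste("o", nm), con)
    writeLines(sprintf("v %.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]), con)
    f <- m$faces + offset
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    offset <- offset + nrow(m$vertices)
  }
  invisible(path)
}

#' Read a Wavefront OBJ file written by [write_obj()]
#'
#' Minimal reader for round-tripping this package's own exports: handles
#' \code{o}, \code{v} and triangular \code{f} records.
#'
#' @param path OBJ file.
#' @return Named list of \code{organ_mesh}.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  verts <- list(); meshes <- list()
  current <- "mesh"; faces <- list()
  flush_mesh <- function() {
    if (length(faces)) {
      f <- do.call(rbind, faces)
      used <- sort(unique(as.integer(f)))
      v <- do.call(rbind, verts)[used, , drop = FALSE]
      remap <- integer(max(used)); remap[used] <- seq_along(used)
      meshes[[current]] <<- new_mesh(v, matrix(remap[f], ncol = 3))
    }
    faces <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "o ")) {
      flush_mesh()
      current <- sub("^o ", "", ln)
    } else if (startsWith(ln, "v ")) {
      verts[[length(verts) + 1L]] <- as.numeric(strsplit(ln, " +")[[1]][2:4])
    } else if (startsWith(ln, "f ")) {
      idx <- strsplit(ln, " +")[[1]][-1]
      faces[[length(faces) + 1L]] <- as.integer(sub("/.*", "", idx))
    }
  }
  flush_mesh()
  meshes
}

#' Write a mesh to an ASCII PLY file
#'
#' @param mesh An \code{organ_mesh} (lists are merged first).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_ply <- function(mesh, path) {
  if (!inherits(mesh, "organ_mesh")) mesh <- merge_meshes(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
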