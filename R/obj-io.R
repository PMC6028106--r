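#' Read meshes from a Wavefront OBJ file
#'
#' Supports `v` and `f` records and multiple objects delimited by `o` lines
#' (object names become mesh ids). Polygonal faces are fan-triangulated;
#' `f` index forms `v`, `v/vt`, `v//vn`, `v/vt/vn` and negative (relative)
#' indices are accepted. Coordinates are taken to be micrometres.
#'
#' @param path file path.
#' @return a list of [trimesh()] objects (length one for single-object files).
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  verts <- list()
  meshes <- list()
  cur_name <- NULL
  cur_faces <- list()
  flush <- function() {
    if (length(cur_faces) == 0L) return()
    f <- do.call(rbind, cur_faces)
    v <- do.call(rbind, verts)
    used <- sort(unique(as.vector(f)))
    remap <- integer(max(used)); remap[used] <- seq_along(used)
    meshes[[length(meshes) + 1L]] <<-
      trimesh(v[used, , drop = FALSE],
              matrix(remap[f], ncol = 3L), id = cur_name)
  }

  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    tag <- tok[1L]
    if (tag == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(tok[2:4])
    } else if (tag == "o" || tag == "g") {
      flush()
      cur_faces <- list()
      cur_name <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ") else NULL
    } else if (tag == "f") {
      idx <- vapply(tok[-1L], function(s) {
        as.integer(strsplit(s, "/", fixed = TRUE)[[1L]][1L])
      }, integer(1L), USE.NAMES = FALSE)
      nv <- length(verts)
      idx <- ifelse(idx < 0L, nv + 1L + idx, idx)
      if (length(idx) < 3L) stop("face with fewer than 3 vertices")
      for (k in seq_len(length(idx) - 2L)) {  # fan triangulation
        cur_faces[[length(cur_faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
      }
    }
    # vn/vt/usemtl etc. ignored
  }
  flush()
  if (length(meshes) == 0L) stop("no faces found in OBJ file")
  meshes
}

#' Write meshes to a Wavefront OBJ file
#'
#' @param meshes a [trimesh()] or list of them; ids become `o` names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(meshes, path) {
  if (inherits(meshes, "trimesh")) meshes <- list(meshes)
  con <- file(path, "w")
  on.exit(close(con))
  offset <- 0L
  for (k in seq_along(meshes)) {
    m <- meshes[[k]]
    name <- if (!is.null(m$id)) m$id else sprintf("object_%d", k)
    writeLines(paste("o", name), con)
    writeLines(sprintf("v %.9g %.9g %.9g",
                       m$vertices[, 1L], m$vertices[, 2L], m$vertices[, 3L]),
               con)
    writeLines(sprintf("f %d %d %d",
                       m$faces[, 1L] + offset, m$faces[, 2L] + offset,
                       m$faces[, 3L] + offset), con)
    offset <- offset + nrow(m$vertices)
  }
  invisible(path)
}
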