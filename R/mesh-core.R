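#' Triangle mesh in micrometre coordinates
#'
#' Constructs a triangulated surface from a vertex matrix and a face index
#' matrix. All reconstructed objects (neurites, boutons, spine heads, synaptic
#' contacts, mitochondria) are represented this way, with coordinates in
#' micrometres and counter-clockwise face orientation giving outward normals.
#'
#' Construction cleans the input: vertices closer than `tol` are merged and
#' zero-area faces are dropped. The number of merged vertices and dropped
#' faces is stored in the `"cleaned"` attribute.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z)
#'   in micrometres.
#' @param faces integer matrix, one row per triangle, three columns of
#'   1-based vertex indices.
#' @param id optional character identifier (carried through OBJ I/O).
#' @param tol merge tolerance for duplicate vertices, in micrometres.
#' @return an object of class `"trimesh"` with elements `vertices`, `faces`,
#'   `id`.
#' @examples
#' cube <- mesh_cube()
#' surface_area(cube)     # 6
#' enclosed_volume(cube)  # 1
#' @export
trimesh <- function(vertices, faces, id = NULL, tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have three columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L && ncol(faces) != 3L) {
    stop("faces must have three columns")
  }
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }

  n_merged <- 0L
  if (nrow(vertices) > 1L) {
    key <- apply(round(vertices / tol), 1L, paste, collapse = ",")
    first <- !duplicated(key)
    n_merged <- sum(!first)
    if (n_merged > 0L) {
      remap <- match(key, key[first])
      vertices <- vertices[first, , drop = FALSE]
      if (nrow(faces) > 0L) {
        faces <- matrix(remap[faces], ncol = 3L)
      }
    }
  }

  n_degenerate <- 0L
  if (nrow(faces) > 0L) {
    areas <- .triangle_areas(vertices, faces)
    repeated <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    keep <- !repeated & areas > .Machine$double.eps
    n_degenerate <- sum(!keep)
    faces <- faces[keep, , drop = FALSE]
  }

  structure(
    list(vertices = vertices, faces = faces, id = id),
    cleaned = c(merged_vertices = n_merged, dropped_faces = n_degenerate),
    class = "trimesh"
  )
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh%s: %d vertices, %d faces\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

.check_mesh <- function(mesh) {
  if (!inherits(mesh, "trimesh")) stop("not a trimesh")
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  invisible(mesh)
}

.triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Surface area of a triangle mesh
#'
#' Sum of the areas of all triangles, in square micrometres.
#'
#' @param mesh a [trimesh()].
#' @return non-negative numeric scalar.
#' @export
surface_area <- function(mesh) {
  .check_mesh(mesh)
  sum(.triangle_areas(mesh$vertices, mesh$faces))
}

#' Edges of a mesh that belong to exactly one face
#'
#' @param mesh a [trimesh()].
#' @return integer matrix of vertex index pairs (possibly zero rows).
#' @export
boundary_edges <- function(mesh) {
  .check_mesh(mesh)
  e <- .edge_table(mesh)
  e$edges[e$count == 1L, , drop = FALSE]
}

# Undirected edge census: unique edges, their multiplicity across faces.
.edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  uniq <- !duplicated(key)
  list(edges = e[uniq, , drop = FALSE],
       count = as.integer(tab[key[uniq]]),
       key = key, uniq_key = key[uniq])
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem (signed tetrahedra) volume, returned as an absolute
#' value in cubic micrometres. Requires a closed surface: an open mesh raises
#' an error naming the number of boundary edges.
#'
#' @param mesh a closed, consistently oriented [trimesh()].
#' @return non-negative numeric scalar.
#' @export
enclosed_volume <- function(mesh) {
  .check_mesh(mesh)
  nb <- nrow(boundary_edges(mesh))
  if (nb > 0L) {
    stop(sprintf("mesh is not closed: %d boundary edges", nb))
  }
  # anchor at the centroid so the signed sum is exactly translation-invariant
  origin <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2L, origin)
  a <- v[mesh$faces[, 1L], , drop = FALSE]
  b <- v[mesh$faces[, 2L], , drop = FALSE]
  c <- v[mesh$faces[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
    a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
    a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  abs(sum(det6)) / 6
}

#' Length of a neurite centerline
#'
#' Sum of the Euclidean lengths of consecutive segments of a polyline, in
#' micrometres.
#'
#' @param line numeric matrix with three columns, at least two rows;
#'   consecutive points must be distinct.
#' @return non-negative numeric scalar.
#' @export
polyline_length <- function(line) {
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline needs at least 2 points")
  d <- diff(line)
  seg <- sqrt(rowSums(d^2))
  if (any(seg == 0)) stop("consecutive polyline points must be distinct")
  sum(seg)
}

#' Minimum distance from points to a mesh surface
#'
#' Exact point-to-triangle distance (interior, edge, or vertex of every
#' triangle considered), minimised over all faces. Used for vesicle-to-
#' presynaptic-membrane distances.
#'
#' @param points numeric vector of length 3 or matrix with three columns
#'   (micrometres).
#' @param mesh a [trimesh()].
#' @return numeric vector of distances, one per query point (micrometres).
#' @export
nearest_surface_distance <- function(points, mesh) {
  .check_mesh(mesh)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  a <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  vapply(seq_len(nrow(points)), function(i) {
    sqrt(min(.point_tri_sqdist(points[i, ], a, b, c)))
  }, numeric(1L))
}

# Squared distance from one point to many triangles (Ericson's
# closest-point-on-triangle, vectorised over triangles).
.point_tri_sqdist <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  ap <- sweep(-a, 2L, p, "+")
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2L, p, "+")
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- sweep(-c, 2L, p, "+")
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)

  n <- nrow(a)
  qx <- numeric(n); qy <- numeric(n); qz <- numeric(n)
  done <- logical(n)

  set_q <- function(idx, pts) {
    qx[idx] <<- pts[, 1L]; qy[idx] <<- pts[, 2L]; qz[idx] <<- pts[, 3L]
    done[idx] <<- TRUE
  }

  r1 <- !done & d1 <= 0 & d2 <= 0                       # vertex A
  if (any(r1)) set_q(r1, a[r1, , drop = FALSE])
  r2 <- !done & d3 >= 0 & d4 <= d3                      # vertex B
  if (any(r2)) set_q(r2, b[r2, , drop = FALSE])
  vc <- d1 * d4 - d3 * d2
  r3 <- !done & vc <= 0 & d1 >= 0 & d3 <= 0             # edge AB
  if (any(r3)) {
    t <- d1[r3] / (d1[r3] - d3[r3])
    set_q(r3, a[r3, , drop = FALSE] + t * ab[r3, , drop = FALSE])
  }
  r4 <- !done & d6 >= 0 & d5 <= d6                      # vertex C
  if (any(r4)) set_q(r4, c[r4, , drop = FALSE])
  vb <- d5 * d2 - d1 * d6
  r5 <- !done & vb <= 0 & d2 >= 0 & d6 <= 0             # edge AC
  if (any(r5)) {
    t <- d2[r5] / (d2[r5] - d6[r5])
    set_q(r5, a[r5, , drop = FALSE] + t * ac[r5, , drop = FALSE])
  }
  va <- d3 * d6 - d5 * d4
  r6 <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(r6)) {
    t <- (d4[r6] - d3[r6]) / ((d4[r6] - d3[r6]) + (d5[r6] - d6[r6]))
    set_q(r6, b[r6, , drop = FALSE] +
            t * (c[r6, , drop = FALSE] - b[r6, , drop = FALSE]))
  }
  r7 <- !done                                            # face interior
  if (any(r7)) {
    denom <- va[r7] + vb[r7] + vc[r7]
    v <- vb[r7] / denom
    w <- vc[r7] / denom
    set_q(r7, a[r7, , drop = FALSE] + v * ab[r7, , drop = FALSE] +
            w * ac[r7, , drop = FALSE])
  }
  (qx - p[1L])^2 + (qy - p[2L])^2 + (qz - p[3L])^2
}

#' Axis-aligned box
#'
#' @param min_corner,max_corner numeric length-3 vectors (micrometres);
#'   `max_corner` must exceed `min_corner` on every axis.
#' @return object of class `"box3"`.
#' @export
box3 <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L) {
    stop("box corners must be length-3")
  }
  if (!all(max_corner > min_corner)) {
    stop("box max corner must exceed min corner on every axis")
  }
  structure(list(min = min_corner, max = max_corner), class = "box3")
}

#' @export
print.box3 <- function(x, ...) {
  cat(sprintf("box3: [%s] to [%s] um\n",
              paste(signif(x$min, 6), collapse = ", "),
              paste(signif(x$max, 6), collapse = ", ")))
  invisible(x)
}

#' Volume of a box in cubic micrometres
#' @param box a [box3()].
#' @export
box_volume <- function(box) prod(box$max - box$min)

#' Is a reconstructed object complete within an analysis box?
#'
#' An object is complete when it lies entirely inside the box: no vertex
#' outside and no triangle touching a box face, within tolerance `eps`.
#' Since the box is convex, a triangle whose three vertices are strictly
#' interior cannot reach a face, so the vertex test is exact.
#'
#' @param mesh a [trimesh()].
#' @param box a [box3()].
#' @param eps contact tolerance in micrometres.
#' @return `"complete"` or `"incomplete"`.
#' @export
completeness <- function(mesh, box, eps = 1e-6) {
  .check_mesh(mesh)
  v <- mesh$vertices
  inside <- all(sweep(v, 2L, box$min + eps, ">=")) &&
    all(sweep(v, 2L, box$max - eps, "<="))
  if (inside) "complete" else "incomplete"
}

#' Maximum cross-sectional caliper diameter along a sectioning axis
#'
#' Emulates measuring a synapse on the serial section where it appears
#' largest. A section is a slab of thickness `pitch` (default 6 nm, a
#' typical FIB milling step) perpendicular to `axis`: everything inside the
#' slab projects into the section image. The first slab is anchored at the
#' mesh's minimum coordinate along the axis. For each slab the mesh content
#' (vertices inside the slab plus edge crossings at the two slab faces) is
#' projected to the section plane; the returned value is the maximum
#' caliper width (largest pairwise distance) over all slabs.
#'
#' @param mesh a [trimesh()].
#' @param axis unit length-3 vector (sectioning/milling direction).
#' @param pitch section thickness/spacing in micrometres (0.006 = 6 nm).
#' @return maximum caliper diameter in micrometres.
#' @export
max_section_diameter <- function(mesh, axis = c(0, 0, 1), pitch = 0.006) {
  .check_mesh(mesh)
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8) stop("axis must be unit length")
  if (pitch <= 0) stop("pitch must be positive")

  R <- .rotation_to_z(axis)
  v <- mesh$vertices %*% t(R)
  f <- mesh$faces
  zmin <- min(v[, 3L]); zmax <- max(v[, 3L])
  n_slabs <- max(1L, ceiling((zmax - zmin) / pitch))
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  z1 <- v[e[, 1L], 3L]; z2 <- v[e[, 2L], 3L]
  zlo <- pmin(z1, z2); zhi <- pmax(z1, z2)

  plane_points <- function(z0) {
    hit <- zlo <= z0 & zhi >= z0
    if (!any(hit)) return(NULL)
    i1 <- e[hit, 1L]; i2 <- e[hit, 2L]
    za <- v[i1, 3L]; zb <- v[i2, 3L]
    flat <- abs(zb - za) < 1e-12
    t <- ifelse(flat, 0, (z0 - za) / (zb - za))
    px <- v[i1, 1L] + t * (v[i2, 1L] - v[i1, 1L])
    py <- v[i1, 2L] + t * (v[i2, 2L] - v[i1, 2L])
    if (any(flat)) {
      px <- c(px, v[i2[flat], 1L])
      py <- c(py, v[i2[flat], 2L])
    }
    cbind(px, py)
  }

  best <- 0
  for (k in seq_len(n_slabs)) {
    s_lo <- zmin + (k - 1L) * pitch
    s_hi <- s_lo + pitch
    inside <- v[, 3L] >= s_lo & v[, 3L] <= s_hi
    pts <- rbind(v[inside, 1:2, drop = FALSE],
                 plane_points(s_lo), plane_points(s_hi))
    if (is.null(pts) || nrow(pts) < 2L) next
    pts <- unique(pts)
    if (nrow(pts) < 2L) next
    if (nrow(pts) > 3L) {
      hull_ok <- tryCatch(
        {
          pts <- pts[grDevices::chull(pts[, 1L], pts[, 2L]), ,
                     drop = FALSE]
          TRUE
        }, error = function(e) FALSE)
    }
    if (nrow(pts) >= 2L) {
      dd <- max(stats::dist(pts))
      if (dd > best) best <- dd
    }
  }
  best
}

# Rotation matrix mapping `axis` onto +z.
.rotation_to_z <- function(axis) {
  z <- axis / sqrt(sum(axis^2))
  ref <- if (abs(z[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  rbind(x, y, z, deparse.level = 0)
}

#' Rigid-motion and scaling helpers for meshes
#'
#' @param mesh a [trimesh()].
#' @param offset length-3 translation (micrometres).
#' @return the transformed mesh.
#' @export
mesh_translate <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2L, as.numeric(offset), "+")
  mesh
}

#' @rdname mesh_translate
#' @param rotation 3x3 rotation matrix.
#' @export
mesh_rotate <- function(mesh, rotation) {
  mesh$vertices <- mesh$vertices %*% t(rotation)
  mesh
}

#' @rdname mesh_translate
#' @param factors scalar or length-3 scale factors.
#' @export
mesh_scale <- function(mesh, factors) {
  factors <- rep_len(as.numeric(factors), 3L)
  mesh$vertices <- sweep(mesh$vertices, 2L, factors, "*")
  mesh
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  cs <- cos(angle); sn <- sin(angle)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, cs, -sn), c(0, sn, cs)),
    y = rbind(c(cs, 0, sn), c(0, 1, 0), c(-sn, 0, cs)),
    z = rbind(c(cs, -sn, 0), c(sn, cs, 0), c(0, 0, 1)))
}
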