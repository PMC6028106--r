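#' Axis-aligned unit cube mesh
#'
#' 12 triangles, outward orientation, corner at the origin by default.
#'
#' @param min_corner,max_corner box corners (micrometres).
#' @param id optional id.
#' @return a [trimesh()].
#' @export
mesh_cube <- function(min_corner = c(0, 0, 0), max_corner = c(1, 1, 1),
                      id = NULL) {
  lo <- as.numeric(min_corner); hi <- as.numeric(max_corner)
  v <- rbind(
    c(lo[1], lo[2], lo[3]), c(hi[1], lo[2], lo[3]),
    c(hi[1], hi[2], lo[3]), c(lo[1], hi[2], lo[3]),
    c(lo[1], lo[2], hi[3]), c(hi[1], lo[2], hi[3]),
    c(hi[1], hi[2], hi[3]), c(lo[1], hi[2], hi[3]))
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # bottom (z = lo)
    c(5, 6, 7), c(5, 7, 8),   # top
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(2, 3, 7), c(2, 7, 6),   # x = hi
    c(3, 4, 8), c(3, 8, 7),   # y = hi
    c(4, 1, 5), c(4, 5, 8))   # x = lo
  trimesh(v, f, id = id)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected onto the sphere. Surface
#' area and enclosed volume approach \eqn{4\pi r^2} and \eqn{4\pi r^3/3}
#' from below as `subdiv` grows.
#'
#' @param radius sphere radius (micrometres).
#' @param subdiv number of 4-to-1 subdivisions (0 = icosahedron).
#' @param center length-3 center.
#' @param id optional id.
#' @return a closed [trimesh()].
#' @export
mesh_icosphere <- function(radius = 1, subdiv = 2, center = c(0, 0, 0),
                           id = NULL) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    res <- .subdivide_tri(v, f)
    v <- res$v / sqrt(rowSums(res$v^2))
    f <- res$f
  }
  v <- sweep(v * radius, 2L, as.numeric(center), "+")
  trimesh(v, f, id = id)
}

.subdivide_tri <- function(v, f) {
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  mid_cache <- new.env(parent = emptyenv())
  verts <- v
  midpoint <- function(i, j) {
    k <- edge_key(i, j)
    idx <- mid_cache[[k]]
    if (is.null(idx)) {
      verts <<- rbind(verts, (v[i, ] + v[j, ]) / 2)
      idx <- nrow(verts)
      mid_cache[[k]] <- idx
    }
    idx
  }
  newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
  for (t in seq_len(nrow(f))) {
    i <- f[t, 1L]; j <- f[t, 2L]; k <- f[t, 3L]
    a <- midpoint(i, j); b <- midpoint(j, k); c <- midpoint(k, i)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(
      c(i, a, c), c(a, j, b), c(c, b, k), c(a, b, c))
  }
  list(v = verts, f = newf)
}

#' Ellipsoid mesh
#'
#' Icosphere scaled by the three semi-axes.
#'
#' @param semi_axes length-3 semi-axis lengths (micrometres).
#' @param center length-3 center.
#' @param subdiv icosphere subdivisions.
#' @param id optional id.
#' @return a closed [trimesh()].
#' @export
mesh_ellipsoid <- function(semi_axes, center = c(0, 0, 0), subdiv = 2,
                           id = NULL) {
  m <- mesh_icosphere(1, subdiv = subdiv)
  m <- mesh_scale(m, semi_axes)
  m <- mesh_translate(m, center)
  m$id <- id
  m
}

#' Flat elliptical disc mesh (fan triangulation)
#'
#' A planar patch in the z = 0 plane, optionally rotated and translated.
#' Its polygon area is `pi * a * b * sinc` correction free: the triangulated
#' area equals the inscribed polygon area, slightly below the ellipse area,
#' and is what [surface_area()] reports.
#'
#' @param a,b semi-axes in micrometres.
#' @param n number of rim points.
#' @param center length-3 center after rotation.
#' @param rotation optional 3x3 rotation applied before translation.
#' @param id optional id.
#' @return an open [trimesh()] with one boundary loop.
#' @export
mesh_disc <- function(a = 0.15, b = a, n = 48, center = c(0, 0, 0),
                      rotation = NULL, id = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rim <- cbind(a * cos(th), b * sin(th), 0)
  v <- rbind(c(0, 0, 0), rim)
  f <- cbind(1L, 1L + seq_len(n), 1L + c(seq_len(n)[-1L], 1L))
  m <- trimesh(v, f, id = id)
  if (!is.null(rotation)) m <- mesh_rotate(m, rotation)
  mesh_translate(m, center)
}

#' Rectangular grid patch with optional square holes
#'
#' A flat n x n quad grid in the z = 0 plane, triangulated; `holes` interior
#' grid cells (given as cell index pairs) are removed, each producing one
#' boundary loop, which makes this the reference surface for perforation
#' counting tests and for generating perforated synaptic contacts.
#'
#' @param width,height patch extent (micrometres).
#' @param n grid cells per side.
#' @param holes list of length-2 integer vectors (cell column, cell row;
#'   1-based, must be interior and non-adjacent for distinct loops).
#' @param center length-3 center after rotation.
#' @param rotation optional 3x3 rotation.
#' @param id optional id.
#' @return an open [trimesh()].
#' @export
mesh_patch <- function(width = 0.3, height = 0.3, n = 8, holes = list(),
                       center = c(0, 0, 0), rotation = NULL, id = NULL) {
  xs <- seq(-width / 2, width / 2, length.out = n + 1L)
  ys <- seq(-height / 2, height / 2, length.out = n + 1L)
  v <- cbind(rep(xs, times = n + 1L), rep(ys, each = n + 1L), 0)
  vid <- function(i, j) (j - 1L) * (n + 1L) + i  # i = column, j = row
  fs <- list()
  hole_keys <- vapply(holes, function(h) paste(h[1L], h[2L]), character(1L))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (paste(i, j) %in% hole_keys) next
      a <- vid(i, j); b <- vid(i + 1L, j)
      c <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
      fs[[length(fs) + 1L]] <- rbind(c(a, b, c), c(a, c, d))
    }
  }
  m <- trimesh(v, do.call(rbind, fs), id = id)
  if (!is.null(rotation)) m <- mesh_rotate(m, rotation)
  mesh_translate(m, center)
}

#' Capped tube mesh around a polyline
#'
#' Coarse circular tube swept along a centerline, closed with fan caps;
#' used for neurite phantoms in volume-fraction tests.
#'
#' @param line polyline matrix (rows = points, micrometres).
#' @param radius tube radius (micrometres).
#' @param n_side points around the circumference.
#' @param id optional id.
#' @return a closed [trimesh()].
#' @export
mesh_tube <- function(line, radius = 0.2, n_side = 10, id = NULL) {
  line <- as.matrix(line)
  np <- nrow(line)
  if (np < 2L) stop("tube centerline needs at least 2 points")
  th <- seq(0, 2 * pi, length.out = n_side + 1L)[-(n_side + 1L)]
  ring0 <- cbind(cos(th), sin(th))
  verts <- matrix(0, nrow = np * n_side, ncol = 3L)
  prev_u <- NULL
  for (k in seq_len(np)) {
    tangent <- if (k == 1L) line[2L, ] - line[1L, ]
               else if (k == np) line[np, ] - line[np - 1L, ]
               else line[k + 1L, ] - line[k - 1L, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    if (is.null(prev_u)) {
      ref <- if (abs(tangent[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * tangent) * tangent
    } else {
      u <- prev_u - sum(prev_u * tangent) * tangent
    }
    u <- u / sqrt(sum(u^2))
    w <- c(tangent[2L] * u[3L] - tangent[3L] * u[2L],
           tangent[3L] * u[1L] - tangent[1L] * u[3L],
           tangent[1L] * u[2L] - tangent[2L] * u[1L])
    prev_u <- u
    ring <- sweep(radius * (ring0[, 1L, drop = FALSE] %*% rbind(u) +
                              ring0[, 2L, drop = FALSE] %*% rbind(w)),
                  2L, line[k, ], "+")
    verts[(k - 1L) * n_side + seq_len(n_side), ] <- ring
  }
  fs <- list()
  for (k in seq_len(np - 1L)) {
    o1 <- (k - 1L) * n_side; o2 <- k * n_side
    for (s in seq_len(n_side)) {
      s2 <- if (s == n_side) 1L else s + 1L
      fs[[length(fs) + 1L]] <- rbind(
        c(o1 + s, o1 + s2, o2 + s2), c(o1 + s, o2 + s2, o2 + s))
    }
  }
  # end caps
  vcap1 <- line[1L, ]; vcap2 <- line[np, ]
  verts <- rbind(verts, vcap1, vcap2)
  c1 <- nrow(verts) - 1L; c2 <- nrow(verts)
  for (s in seq_len(n_side)) {
    s2 <- if (s == n_side) 1L else s + 1L
    fs[[length(fs) + 1L]] <- rbind(c(c1, s2, s))
    o <- (np - 1L) * n_side
    fs[[length(fs) + 1L]] <- rbind(c(c2, o + s, o + s2))
  }
  trimesh(verts, do.call(rbind, fs), id = id)
}
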