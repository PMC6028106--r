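# Independent oracles used across the suite. These deliberately use
# different formulations than the package internals.

# Total surface area by per-triangle Heron's formula, plain loop.
oracle_area_heron <- function(mesh) {
  total <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    p <- mesh$vertices[mesh$faces[i, ], ]
    a <- sqrt(sum((p[1, ] - p[2, ])^2))
    b <- sqrt(sum((p[2, ] - p[3, ])^2))
    c <- sqrt(sum((p[3, ] - p[1, ])^2))
    s <- (a + b + c) / 2
    total <- total + sqrt(max(s * (s - a) * (s - b) * (s - c), 0))
  }
  total
}

# Point-to-mesh distance by plane projection + point-to-segment fallback,
# minimised over all faces (a different decomposition than the package's
# closest-point region walk).
oracle_point_mesh_dist <- function(p, mesh) {
  seg_dist2 <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sum((a + t * ab - p)^2)
  }
  best <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
    n <- pracma::cross(b - a, c - a)
    nn <- sum(n^2)
    d2 <- NA
    if (nn > 0) {
      q <- p - sum((p - a) * n) / nn * n  # projection onto the plane
      # barycentric coordinates of the projection
      v0 <- b - a; v1 <- c - a; v2 <- q - a
      d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
      d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
      den <- d00 * d11 - d01^2
      v <- (d11 * d20 - d01 * d21) / den
      w <- (d00 * d21 - d01 * d20) / den
      if (v >= 0 && w >= 0 && v + w <= 1) d2 <- sum((q - p)^2)
    }
    if (is.na(d2)) {
      d2 <- min(seg_dist2(p, a, b), seg_dist2(p, b, c), seg_dist2(p, c, a))
    }
    best <- min(best, d2)
  }
  sqrt(best)
}

# Fraction-of-grid containment volume for a CONVEX closed mesh: a point is
# inside iff it is behind every face plane (outward normals).
oracle_convex_volume <- function(mesh, n_grid = 60) {
  v <- mesh$vertices
  f <- mesh$faces
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  xs <- seq(lo[1], hi[1], length.out = n_grid)
  ys <- seq(lo[2], hi[2], length.out = n_grid)
  zs <- seq(lo[3], hi[3], length.out = n_grid)
  pts <- as.matrix(expand.grid(xs, ys, zs))
  a <- v[f[, 1], , drop = FALSE]
  normals <- t(vapply(seq_len(nrow(f)), function(i) {
    pracma::cross(v[f[i, 2], ] - v[f[i, 1], ], v[f[i, 3], ] - v[f[i, 1], ])
  }, numeric(3)))
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(f))) {
    inside <- inside &
      (pts %*% normals[i, ] <= sum(a[i, ] * normals[i, ]) + 1e-12)
    if (!any(inside)) break
  }
  cell <- prod((hi - lo) / (n_grid - 1))
  sum(inside) * cell
}

# Euler-characteristic hole count: holes = 1 - (V - E + F) for a connected
# surface with boundary (0 for a closed component contributes via chi = 2).
oracle_euler_holes <- function(mesh) {
  f <- mesh$faces
  v_used <- length(unique(as.vector(f)))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e_n <- nrow(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  chi <- v_used - e_n + nrow(f)
  1 - chi
}

# Exhaustive completeness predicate: every vertex strictly interior AND no
# edge segment crossing a box face plane (checked segment-by-segment).
oracle_complete <- function(mesh, box, eps = 1e-6) {
  v <- mesh$vertices
  vin <- all(sweep(v, 2, box$min + eps, ">=")) &&
    all(sweep(v, 2, box$max - eps, "<="))
  if (!vin) return("incomplete")
  f <- mesh$faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  for (i in seq_len(nrow(e))) {
    p <- v[e[i, 1], ]; q <- v[e[i, 2], ]
    for (ax in 1:3) {
      for (lim in c(box$min[ax] + eps, box$max[ax] - eps)) {
        if ((p[ax] - lim) * (q[ax] - lim) < 0) return("incomplete")
      }
    }
  }
  "complete"
}

# Dense 1-nm sweep caliper for a tilted elliptical disc of semi-axes a >= b
# tilted by `tilt` about the x axis: analytic chord caliper per plane.
oracle_tilted_disc_caliper <- function(a, b, tilt, pitch_nm = 1) {
  if (tilt == 0) return(2 * a)
  h <- pitch_nm * 1e-3
  zmax <- b * sin(tilt)
  zs <- seq(-zmax, zmax, by = h)
  # section at z cuts the disc along the line y' = z / sin(tilt) in disc
  # coordinates; chord of the ellipse at that y'
  yp <- zs / sin(tilt)
  chord_x <- 2 * a * sqrt(pmax(1 - (yp / b)^2, 0))
  # the chord lies in the section plane; caliper includes the projected
  # in-plane extent only (chord along x is unforeshortened)
  max(chord_x)
}

# Closed-form pooled-variance t statistic and two-sided p.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Two-sample KS statistic from first principles.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}
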