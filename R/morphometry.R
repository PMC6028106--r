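#' Synapse diameter from the maximum-section proxy
#'
#' The size proxy used at annotation time: the diameter of the ball placed
#' at the contact center equals the maximum width of the contact on the
#' serial section where it appears largest. Computed from the reconstructed
#' contact mesh as [max_section_diameter()] along the milling axis,
#' converted to nanometres.
#'
#' @param contact a [trimesh()] of the synaptic contact (micrometres).
#' @param axis sectioning axis (unit vector).
#' @param pitch section spacing in micrometres.
#' @return diameter in nanometres.
#' @export
estimate_diameter <- function(contact, axis = c(0, 0, 1), pitch = 0.006) {
  d_um <- max_section_diameter(contact, axis = axis, pitch = pitch)
  if (d_um <= 0) stop("degenerate contact: zero caliper diameter")
  1e3 * d_um
}

#' Quadratic calibration of the diameter proxy against contact area
#'
#' Ordinary least squares fit of contact surface area (um^2) on annotated
#' maximum diameter (um): `area = a0 + a1 d + a2 d^2`, with the coefficient
#' of determination against the mean-only model.
#'
#' @param pairs data frame with columns `diameter_um` and `area_um2`
#'   (at least 3 rows, diameters not all equal).
#' @return object of class `"calibration_fit"`: `coefficients` (a0, a1, a2),
#'   `r_squared`, `n`.
#' @export
fit_calibration <- function(pairs) {
  d <- as.numeric(pairs$diameter_um)
  a <- as.numeric(pairs$area_um2)
  if (length(d) < 3L) stop("calibration needs at least 3 pairs")
  X <- cbind(1, d, d^2)
  if (qr(X)$rank < 3L) stop("rank-deficient calibration design matrix")
  fit <- stats::lm.fit(X, a)
  coef <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((a - mean(a))^2)
  structure(list(coefficients = c(a0 = coef[1L], a1 = coef[2L],
                                  a2 = coef[3L]),
                 r_squared = 1 - ss_res / ss_tot, n = length(d)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("area = %.4g %+.4g d %+.4g d^2  (R^2 = %.3f, n = %d)\n",
              co[1L], co[2L], co[3L], x$r_squared, x$n))
  invisible(x)
}

#' Predict contact area from an annotated diameter
#'
#' Evaluates the calibration polynomial; negative predictions (possible for
#' very small diameters outside the calibrated range) are clamped to zero
#' with a warning.
#'
#' @param fit a [fit_calibration()] result, or a numeric vector
#'   (a0, a1, a2).
#' @param diameter_um diameters in micrometres.
#' @return predicted areas in square micrometres.
#' @export
apply_calibration <- function(fit, diameter_um) {
  co <- if (inherits(fit, "calibration_fit")) fit$coefficients
        else as.numeric(fit)
  y <- co[1L] + co[2L] * diameter_um + co[3L] * diameter_um^2
  if (any(y < 0)) {
    warning(sprintf("%d predicted areas below zero clamped to 0", sum(y < 0)))
    y <- pmax(y, 0)
  }
  unname(y)
}

#' Log-normal fit to a binned synapse size distribution
#'
#' Least-squares fit of the log-normal peak function
#' \eqn{f(x) = A \exp(-\ln(x/c)^2 / (2 w^2))} to the bin-center frequencies
#' (percent of total per bin) of the diameter histogram. Note that when the
#' underlying diameters are log-normally distributed with log-median m and
#' log-sd s, the histogram on a linear axis peaks at \eqn{c = m e^{-s^2}}
#' (the 1/x Jacobian of the log-normal density); the distribution median is
#' therefore recovered as \eqn{c\,e^{w^2}} and reported in the `median`
#' field.
#'
#' @param diameters_nm synapse diameters in nanometres.
#' @param bin_width histogram bin width in nanometres (default 25).
#' @param max_restarts random restarts before giving up.
#' @param histogram optionally a precomputed histogram as a data frame with
#'   columns `x` (bin centers, nm) and `y` (percent per bin); when given,
#'   `diameters_nm` is ignored.
#' @return object of class `"lognormal_fit"`: `center`, `amplitude`,
#'   `width`, `r_squared`, `median`, plus the fitted `histogram`.
#' @export
fit_lognormal_histogram <- function(diameters_nm, bin_width = 25,
                                    max_restarts = 8, histogram = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (is.null(histogram)) {
    d <- as.numeric(diameters_nm)
    d <- d[is.finite(d)]
    if (length(d) == 0L || all(d <= 0)) stop("no positive diameters to bin")
    brks <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
    counts <- graphics::hist(d, breaks = brks, plot = FALSE,
                             right = FALSE)$counts
    if (sum(counts) == 0L) stop("all histogram bins are empty")
    if (sum(counts > 0) < 5L) stop("need at least 5 non-empty bins")
    centers <- brks[-length(brks)] + bin_width / 2
    pct <- 100 * counts / sum(counts)
    keep <- centers >= min(d) - bin_width & centers <= max(d) + bin_width
    df <- data.frame(x = centers[keep], y = pct[keep])
    s <- stats::sd(log(d))
    start0 <- list(A = max(df$y), c = exp(mean(log(d)) - s^2), w = s)
  } else {
    df <- data.frame(x = as.numeric(histogram$x),
                     y = as.numeric(histogram$y))
    if (all(df$y == 0)) stop("all histogram bins are empty")
    if (sum(df$y > 0) < 5L) stop("need at least 5 non-empty bins")
    n <- length(df$x)
    start0 <- list(A = max(df$y), c = df$x[which.max(df$y)], w = 0.4)
  }
  fit <- NULL
  set_try <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-log(x / c)^2 / (2 * w^2)), data = df, start = st,
        lower = c(A = 1e-9, c = 1e-9, w = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- set_try(start0)
  tries <- 0L
  while (is.null(fit) && tries < max_restarts) {
    tries <- tries + 1L
    jit <- lapply(start0, function(v) v * stats::runif(1, 0.5, 2))
    fit <- set_try(jit)
  }
  if (is.null(fit)) {
    stop(sprintf(paste0(
      "log-normal histogram fit did not converge after %d restarts ",
      "(bins = %d, start A = %.3g, c = %.3g, w = %.3g)"),
      max_restarts, nrow(df), start0$A, start0$c, start0$w))
  }
  co <- stats::coef(fit)
  resid <- df$y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((df$y - mean(df$y))^2)
  structure(list(center = unname(co["c"]), amplitude = unname(co["A"]),
                 width = unname(co["w"]), r_squared = r2,
                 median = unname(co["c"] * exp(co["w"]^2)),
                 histogram = df, bin_width = bin_width),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "log-normal peak fit: center = %.1f nm, amplitude = %.2f%%, width = %.3f (R^2 = %.3f)\nimplied distribution median = %.1f nm\n",
    x$center, x$amplitude, x$width, x$r_squared, x$median))
  invisible(x)
}

#' Count perforations of a synaptic contact surface
#'
#' A contact is perforated when its reconstructed surface has a clear hole:
#' a boundary loop beyond the outer rim. For each connected component, the
#' number of holes is (boundary loops - 1); complex or horse-shoe outlines
#' without a through-hole count zero. Non-manifold edges (shared by more
#' than two faces) raise an error listing them.
#'
#' @param contact a [trimesh()] (open surface with boundary).
#' @return non-negative integer, total holes over all components.
#' @export
count_perforations <- function(contact) {
  .check_mesh(contact)
  et <- .edge_table(contact)
  bad <- et$count > 2L
  if (any(bad)) {
    e <- et$edges[bad, , drop = FALSE]
    stop("non-manifold edges: ",
         paste(sprintf("(%d,%d)", e[, 1L], e[, 2L]), collapse = " "))
  }
  comp <- .face_components(contact)
  total <- 0L
  for (cc in unique(comp)) {
    sub_faces <- contact$faces[comp == cc, , drop = FALSE]
    sub <- structure(list(vertices = contact$vertices, faces = sub_faces),
                     class = "trimesh")
    loops <- .boundary_loops(sub)
    if (loops >= 1L) total <- total + loops - 1L
  }
  total
}

# Connected components of faces via shared edges (union-find).
.face_components <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  parent <- seq_len(nf)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  face_of <- rep(seq_len(nf), 3L)
  groups <- split(face_of, key)
  for (g in groups) {
    if (length(g) > 1L) {
      r <- find(g[1L])
      for (j in g[-1L]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  vapply(seq_len(nf), find, integer(1L))
}

# Number of boundary loops, by walking boundary edges. Errors on boundary
# vertices with more than two incident boundary edges.
.boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(0L)
  adj <- split(c(seq_len(nrow(be)), seq_len(nrow(be))),
               c(be[, 1L], be[, 2L]))
  deg <- lengths(adj)
  if (any(deg > 2L)) {
    stop("non-manifold boundary: vertex with >2 boundary edges")
  }
  visited <- logical(nrow(be))
  loops <- 0L
  for (start in seq_len(nrow(be))) {
    if (visited[start]) next
    loops <- loops + 1L
    cur <- start
    v <- be[start, 2L]
    visited[start] <- TRUE
    repeat {
      nxt <- setdiff(adj[[as.character(v)]], cur)
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]
      if (visited[nxt]) break
      visited[nxt] <- TRUE
      v <- if (be[nxt, 1L] == v) be[nxt, 2L] else be[nxt, 1L]
      cur <- nxt
    }
  }
  loops
}
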