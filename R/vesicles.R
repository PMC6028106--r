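#' Vesicle cloud of a single-synapse bouton
#'
#' Vesicle centers were annotated by placing a sphere that approximately
#' fills each vesicle; the center of that sphere is what distance
#' measurements use (the radius exists for generation/rendering only, and is
#' never subtracted from distances).
#'
#' @param bouton_id identifier.
#' @param centers matrix of vesicle centers (micrometres).
#' @param radii_nm vesicle radii in nanometres (> 0).
#' @param membrane a [trimesh()] of the presynaptic membrane.
#' @param bouton_volume_um3 bouton volume (um^3).
#' @param contact_area_um2 synaptic contact surface area (um^2).
#' @return list of class `"vesicle_set"`.
#' @export
vesicle_set <- function(bouton_id, centers, radii_nm, membrane,
                        bouton_volume_um3, contact_area_um2) {
  centers <- as.matrix(centers)
  if (nrow(centers) > 0L && !all(is.finite(centers))) {
    stop("vesicle centers must be finite")
  }
  radii_nm <- rep_len(as.numeric(radii_nm), nrow(centers))
  if (nrow(centers) > 0L && any(radii_nm <= 0)) {
    stop("vesicle radii must be positive")
  }
  structure(list(bouton_id = as.character(bouton_id), centers = centers,
                 radii_nm = radii_nm, membrane = membrane,
                 bouton_volume_um3 = bouton_volume_um3,
                 contact_area_um2 = contact_area_um2),
            class = "vesicle_set")
}

#' Vesicle-to-membrane distances
#'
#' Euclidean distance from each vesicle center to the nearest point on the
#' presynaptic membrane mesh, in nanometres.
#'
#' @param vs a [vesicle_set()].
#' @return numeric vector of distances (nm), one per vesicle.
#' @export
membrane_distances <- function(vs) {
  if (nrow(vs$centers) == 0L) return(numeric(0))
  1e3 * nearest_surface_distance(vs$centers, vs$membrane)
}

#' Distance profile in 30-nm bins
#'
#' Half-open bins `[k*w, (k+1)*w)`; the counts sum to the number of
#' vesicles. The normalized profile divides counts by the synaptic contact
#' surface area.
#'
#' @param distances_nm distances from [membrane_distances()] (must be
#'   non-negative).
#' @param bin_width bin width in nanometres (default 30).
#' @param contact_area_um2 contact area for normalization (optional).
#' @return data frame with `bin_lo`, `bin_hi`, `count`, and `normalized`
#'   (count per um^2 of contact) when an area is given.
#' @export
bin_profile <- function(distances_nm, bin_width = 30,
                        contact_area_um2 = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  d <- as.numeric(distances_nm)
  if (any(d < 0)) stop("negative vesicle distance")
  n_bins <- if (length(d)) max(d) %/% bin_width + 1 else 0
  idx <- if (length(d)) d %/% bin_width + 1L else integer(0)
  counts <- tabulate(idx, nbins = n_bins)
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
                    bin_hi = seq_len(n_bins) * bin_width,
                    count = counts)
  if (!is.null(contact_area_um2)) {
    if (contact_area_um2 <= 0) stop("contact area must be positive")
    out$normalized <- counts / contact_area_um2
  }
  out
}

#' Vesicle number density of a bouton
#'
#' @param vs a [vesicle_set()].
#' @return vesicles per cubic micrometre.
#' @export
vesicle_density <- function(vs) {
  if (is.null(vs$bouton_volume_um3) || vs$bouton_volume_um3 <= 0) {
    stop("bouton volume must be positive")
  }
  nrow(vs$centers) / vs$bouton_volume_um3
}

#' Pooled normalized distance profile over several boutons
#'
#' Sums per-bouton counts bin-wise and normalizes by the summed contact
#' area, the form used for group comparisons of the profiles.
#'
#' @param vesicle_sets list of [vesicle_set()].
#' @param bin_width bin width (nm).
#' @return data frame as in [bin_profile()].
#' @export
pooled_profile <- function(vesicle_sets, bin_width = 30) {
  all_d <- unlist(lapply(vesicle_sets, membrane_distances))
  total_area <- sum(vapply(vesicle_sets, `[[`, numeric(1L),
                           "contact_area_um2"))
  bin_profile(all_d, bin_width = bin_width, contact_area_um2 = total_area)
}
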