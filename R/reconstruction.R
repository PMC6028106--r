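#' One reconstructed neurite fragment
#'
#' @param id identifier.
#' @param kind `"axon"` or `"dendrite"`.
#' @param centerline polyline matrix (micrometres).
#' @param mesh optional [trimesh()] of the neurite surface.
#' @param subclass axons only: `"excitatory"`, `"inhibitory"`, `"unknown"`
#'   or `"non_connecting"` (carried from annotation; nothing is classified
#'   here).
#' @param links character vector of linked object ids (boutons, spines,
#'   synapses, mitochondria).
#' @return list of class `"neurite_record"`.
#' @export
neurite_record <- function(id, kind = c("axon", "dendrite"), centerline,
                           mesh = NULL, subclass = NULL,
                           links = character()) {
  kind <- match.arg(kind)
  if (kind == "dendrite" && !is.null(subclass)) {
    stop("subclass applies to axons only")
  }
  if (kind == "axon" && is.null(subclass)) subclass <- "unknown"
  if (!is.null(subclass) &&
      !subclass %in% c("excitatory", "inhibitory", "unknown",
                       "non_connecting")) {
    stop("invalid axon subclass")
  }
  structure(list(id = as.character(id), kind = kind,
                 centerline = as.matrix(centerline), mesh = mesh,
                 subclass = subclass, links = as.character(links)),
            class = "neurite_record")
}

#' Densely reconstructed analysis sub-volume
#'
#' Container for everything reconstructed in one 5 x 5 x 5 um cube
#' (125 um^3): neurites with centerlines, boutons, spine heads, synaptic
#' contacts, mitochondria, glial meshes and vesicle sets.
#'
#' @param box a [box3()] (default the canonical 5-um cube at the origin).
#' @param neurites list of [neurite_record()].
#' @param boutons,spines,contacts,mitochondria,glia lists of object records;
#'   each element a list with at least `id` and `mesh`, contacts also
#'   `syn_class`, mitochondria also `host` and `donut`.
#' @param vesicle_sets list of [vesicle_set()].
#' @param animal,group labels.
#' @return list of class `"subvolume"`.
#' @export
subvolume <- function(box = box3(c(0, 0, 0), c(5, 5, 5)),
                      neurites = list(), boutons = list(), spines = list(),
                      contacts = list(), mitochondria = list(),
                      glia = list(), vesicle_sets = list(),
                      animal = NA, group = NA) {
  structure(list(box = box, neurites = neurites, boutons = boutons,
                 spines = spines, contacts = contacts,
                 mitochondria = mitochondria, glia = glia,
                 vesicle_sets = vesicle_sets, animal = animal,
                 group = group),
            class = "subvolume")
}

#' Length of a polyline clipped to a box
#'
#' Segments are cut at box faces by linear interpolation; partial segments
#' contribute their inside portion. Splitting a polyline at a face conserves
#' total clipped length exactly.
#'
#' @param line polyline matrix.
#' @param box a [box3()].
#' @return clipped length in micrometres.
#' @export
clip_polyline_length <- function(line, box) {
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline needs at least 2 points")
  p <- line[-nrow(line), , drop = FALSE]
  q <- line[-1L, , drop = FALSE]
  d <- q - p
  seg_len <- sqrt(rowSums(d^2))
  t0 <- rep(0, nrow(p)); t1 <- rep(1, nrow(p))
  for (ax in 1:3) {
    # parametric (Liang-Barsky) clipping against the two slabs
    for (bound in c("lo", "hi")) {
      lim <- if (bound == "lo") box$min[ax] else box$max[ax]
      sgn <- if (bound == "lo") 1 else -1
      num <- sgn * (p[, ax] - lim)
      den <- sgn * d[, ax]
      par <- abs(den) < 1e-300
      # den > 0: entering; den < 0: leaving  (after sign flip both slabs
      # reduce to: inside iff num + t*den >= 0)
      ent <- !par & den > 0
      t0[ent] <- pmax(t0[ent], -num[ent] / den[ent])
      lea <- !par & den < 0
      t1[lea] <- pmin(t1[lea], -num[lea] / den[lea])
      out <- par & num < 0
      t1[out] <- -1  # fully outside this slab
    }
  }
  inside <- pmax(t1 - t0, 0)
  sum(seg_len * inside)
}

.sub_neurites <- function(sub, kind) {
  Filter(function(r) r$kind == kind, sub$neurites)
}

.total_clipped_length <- function(sub, kind) {
  recs <- .sub_neurites(sub, kind)
  if (length(recs) == 0L) return(0)
  sum(vapply(recs, function(r) clip_polyline_length(r$centerline, sub$box),
             numeric(1L)))
}

#' Neurite length density in a sub-volume
#'
#' Micrometres of axon (or dendrite) centerline, clipped to the analysis
#' box, per cubic micrometre of neuropil.
#'
#' @param sub a [subvolume()].
#' @param kind `"axon"` or `"dendrite"`.
#' @return density in um / um^3.
#' @export
length_density <- function(sub, kind = c("axon", "dendrite")) {
  kind <- match.arg(kind)
  .total_clipped_length(sub, kind) / box_volume(sub$box)
}

#' Synapses per unit neurite length
#'
#' Number of synaptic contacts in the sub-volume divided by the total
#' clipped length of neurites of the given kind. The paper's alternative
#' formulation "um of axon per synapse" is the reciprocal.
#'
#' @param sub a [subvolume()].
#' @param kind `"axon"` or `"dendrite"`.
#' @param syn_class restrict the contact count to one class
#'   (default `"asymmetric"`); `NULL` counts all contacts.
#' @return synapses per micrometre.
#' @export
synapses_per_length <- function(sub, kind = c("axon", "dendrite"),
                                syn_class = "asymmetric") {
  kind <- match.arg(kind)
  len <- .total_clipped_length(sub, kind)
  if (len <= 0) stop("zero total neurite length of kind ", kind)
  n <- if (is.null(syn_class)) length(sub$contacts) else
    sum(vapply(sub$contacts,
               function(ct) identical(ct$syn_class, syn_class), logical(1L)))
  n / len
}

#' Asymmetric synaptic surface density
#'
#' Sum of asymmetric contact surface areas over: total axon length, total
#' dendrite length, and the sub-volume.
#'
#' @param sub a [subvolume()].
#' @return named numeric: `per_um_axon` (um^2/um), `per_um_dendrite`,
#'   `per_um3` (um^2/um^3), and `total_area_um2`.
#' @export
synaptic_surface_density <- function(sub) {
  areas <- vapply(sub$contacts, function(ct) {
    if (identical(ct$syn_class, "asymmetric")) surface_area(ct$mesh) else 0
  }, numeric(1L))
  total <- if (length(areas)) sum(areas) else 0
  la <- .total_clipped_length(sub, "axon")
  ld <- .total_clipped_length(sub, "dendrite")
  c(per_um_axon = if (la > 0) total / la else NA_real_,
    per_um_dendrite = if (ld > 0) total / ld else NA_real_,
    per_um3 = total / box_volume(sub$box),
    total_area_um2 = total)
}

#' Size summary over complete objects
#'
#' Surface-area and volume statistics for one object class, restricted to
#' objects whose meshes lie entirely inside the analysis box
#' ([completeness()]); incomplete objects still appear in the counts.
#' SD is the sample standard deviation (n - 1).
#'
#' @param sub a [subvolume()].
#' @param object_kind `"boutons"`, `"spines"`, `"contacts"` or
#'   `"mitochondria"`.
#' @param closed whether the meshes are closed (volume computed); contact
#'   patches are open, so volume is skipped for them.
#' @return a list: counts (`n_total`, `n_complete`, `n_incomplete`) and,
#'   over complete objects, `area` and `volume` components each with
#'   `total`, `mean`, `sd`.
#' @export
size_summary <- function(sub,
                         object_kind = c("boutons", "spines", "contacts",
                                         "mitochondria"),
                         closed = !identical(object_kind, "contacts")) {
  object_kind <- match.arg(object_kind)
  objs <- sub[[object_kind]]
  n <- length(objs)
  if (n == 0L) {
    return(list(n_total = 0L, n_complete = 0L, n_incomplete = 0L,
                area = c(total = 0, mean = NA_real_, sd = NA_real_),
                volume = c(total = 0, mean = NA_real_, sd = NA_real_)))
  }
  comp <- vapply(objs, function(o) completeness(o$mesh, sub$box), character(1L))
  complete <- objs[comp == "complete"]
  stat <- function(vals) {
    if (length(vals) == 0L) {
      c(total = 0, mean = NA_real_, sd = NA_real_)
    } else {
      c(total = sum(vals), mean = mean(vals),
        sd = if (length(vals) > 1L) stats::sd(vals) else 0)
    }
  }
  areas <- vapply(complete, function(o) surface_area(o$mesh), numeric(1L))
  vols <- if (closed) {
    vapply(complete, function(o) enclosed_volume(o$mesh), numeric(1L))
  } else numeric(0)
  list(n_total = n, n_complete = length(complete),
       n_incomplete = n - length(complete),
       area = stat(areas),
       volume = if (closed) stat(vols)
                else c(total = NA_real_, mean = NA_real_, sd = NA_real_))
}

#' Compartment volume fractions of a sub-volume
#'
#' Percent occupancy of connecting units (boutons and spine heads combined),
#' axons, dendrites, glia, and mitochondria: summed enclosed volumes clipped
#' to the box over the box volume. Compartments need not sum to 100
#' (extracellular space and unassigned structures remain). Neurite
#' compartments use neurite meshes where present. With
#' `check_overlap = TRUE` pairwise compartment overlap is estimated on a
#' voxel grid and a warning is raised above 1% of the box volume.
#'
#' @param sub a [subvolume()].
#' @param voxel_nm voxel size used for boundary-crossing meshes (and the
#'   overlap check).
#' @param check_overlap estimate pairwise overlap (slower).
#' @return named numeric vector of percentages.
#' @export
volume_fractions <- function(sub, voxel_nm = 40, check_overlap = FALSE) {
  vol_of <- function(meshes) {
    if (length(meshes) == 0L) return(0)
    sum(vapply(meshes, function(m) clipped_volume(m, sub$box, voxel_nm),
               numeric(1L)))
  }
  grab <- function(objs) Filter(Negate(is.null), lapply(objs, `[[`, "mesh"))
  comp_meshes <- list(
    connecting = c(grab(sub$boutons), grab(sub$spines)),
    axons = grab(.sub_neurites(sub, "axon")),
    dendrites = grab(.sub_neurites(sub, "dendrite")),
    glia = grab(sub$glia),
    mitochondria = grab(sub$mitochondria))
  vols <- vapply(comp_meshes, vol_of, numeric(1L))
  bv <- box_volume(sub$box)
  if (check_overlap) {
    nonempty <- names(comp_meshes)[lengths(comp_meshes) > 0]
    # mitochondria live inside neurites by construction; skip that pairing
    pairs <- utils::combn(setdiff(nonempty, "mitochondria"), 2,
                          simplify = FALSE)
    for (pr in pairs) {
      l1 <- voxelize(comp_meshes[[pr[1L]]], voxel_nm, box = sub$box)
      l2 <- voxelize(comp_meshes[[pr[2L]]], voxel_nm, box = sub$box)
      ov <- sum(l1 > 0 & l2 > 0) * attr(l1, "voxel_um")^3
      if (ov > 0.01 * bv) {
        warning(sprintf("compartments %s and %s overlap by ~%.2f um^3",
                        pr[1L], pr[2L], ov))
      }
    }
  }
  100 * vols / bv
}

#' Mitochondria census of a sub-volume
#'
#' Counts by host compartment, a volume-binned density histogram
#' (mitochondria per cubic micrometre of neuropil, per volume bin), and the
#' donut (toroidal) fraction. The donut flag is annotation input, never
#' computed.
#'
#' @param sub a [subvolume()].
#' @param bin_width volume histogram bin width in um^3.
#' @return list with `counts` (by host), `n_total`, `donut_count`,
#'   `donut_percent`, `volumes`, and `histogram` (bin, count, density).
#' @export
mito_census <- function(sub, bin_width = 0.05) {
  mt <- sub$mitochondria
  hosts <- vapply(mt, function(m) {
    h <- m$host
    if (is.null(h)) "undefined" else as.character(h)
  }, character(1L))
  donut <- vapply(mt, function(m) isTRUE(m$donut), logical(1L))
  vols <- vapply(mt, function(m) {
    if (!is.null(m$volume)) m$volume else enclosed_volume(m$mesh)
  }, numeric(1L))
  counts <- c(axon = sum(hosts == "axon"),
              dendrite = sum(hosts == "dendrite"),
              undefined = sum(!hosts %in% c("axon", "dendrite")))
  histo <- NULL
  if (length(vols)) {
    brks <- seq(0, (max(vols) %/% bin_width + 1) * bin_width, by = bin_width)
    h <- graphics::hist(vols, breaks = brks, plot = FALSE, right = FALSE)
    histo <- data.frame(bin_lo = brks[-length(brks)],
                        bin_hi = brks[-1L], count = h$counts,
                        density = h$counts / box_volume(sub$box))
  }
  list(counts = counts, n_total = length(mt),
       donut_count = sum(donut),
       donut_percent = if (length(mt)) 100 * sum(donut) / length(mt) else 0,
       volumes = vols, histogram = histo)
}

#' Donut-mitochondrion percentage from raw counts
#'
#' @param donut_count,total_count integers.
#' @return percentage.
#' @export
donut_percent <- function(donut_count, total_count) {
  if (total_count <= 0) stop("total_count must be positive")
  100 * donut_count / total_count
}
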