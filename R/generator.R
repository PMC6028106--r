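#' Configuration of the synthetic neuropil generator
#'
#' Defaults are the adult layer-1 study conditions: per-category synapse
#' densities equal to the published adult group means, log-normal diameters
#' (median 290 nm, log-sd 0.33), axon length density 8.15 and dendrite
#' 1.37 um/um^3, ~250 vesicles per bouton at 2000/um^3, perforation
#' probability 3.8%, ~190 mitochondria per 125-um^3 sub-volume with donut
#' probability 0.18%. `group = "aged"` switches every target to the aged
#' group values.
#'
#' @param group `"adult"` or `"aged"` preset.
#' @param ... named overrides of any field.
#' @return list of class `"neuropil_config"`.
#' @export
neuropil_config <- function(group = c("adult", "aged"), ...) {
  group <- match.arg(group)
  cfg <- list(
    group = group,
    stack_edge_um = 10,           # full annotated stack (cube edge)
    guard_um = 1,                 # brick inset from every stack edge
    sub_edge_um = 5,              # dense-reconstruction cube edge
    # marker densities per um^3 (published adult group means)
    density = c(asym_spine_single = 0.920, asym_spine_msb = 0.135,
                asym_shaft_single = 0.150, asym_shaft_msb = 0.023,
                sym_spine = 0.071, sym_shaft = 0.080, unknown = 0.013),
    msb_both_fraction = 0.2,      # MSB boutons mixing spine+shaft targets
    diameter_median_nm = 290,
    diameter_log_sd = 0.33,
    axon_length_density = 8.15,   # um / um^3
    dendrite_length_density = 1.37,
    axon_subclass_prob = c(excitatory = 0.377, inhibitory = 0.105,
                           unknown = 0.105, non_connecting = 0.413),
    contact_density = 1.50,       # reconstructed contacts per um^3 (sub-vol)
    perforation_prob = 0.038,
    spine_volume_meanlog = log(0.055),  # um^3; mean ~0.075
    spine_volume_sdlog = 0.6,
    bouton_volume_meanlog = log(0.13),  # um^3; mean ~0.17
    bouton_volume_sdlog = 0.55,
    area_coupling_alpha = 2.0,    # synapse area = alpha * spine volume + eps
    area_coupling_noise = 0.05,   # um^2
    vesicle_density = 2000,       # per um^3 of bouton
    vesicle_radius_nm = 20,
    n_vesicle_boutons = 5,
    mito_count = 190,             # per sub-volume
    mito_volume_meanlog = log(0.045),
    mito_volume_sdlog = 0.7,
    mito_host_prob = c(axon = 0.72, dendrite = 0.225, undefined = 0.055),
    donut_prob = 0.0018)
  if (group == "aged") {
    cfg$density <- c(asym_spine_single = 0.831, asym_spine_msb = 0.127,
                     asym_shaft_single = 0.108, asym_shaft_msb = 0.004,
                     sym_spine = 0.018, sym_shaft = 0.065,
                     unknown = 0.013)
    cfg$diameter_median_nm <- 305
    cfg$diameter_log_sd <- 0.47
    cfg$axon_length_density <- 10.07
    cfg$dendrite_length_density <- 1.51
    cfg$perforation_prob <- 0.081
    cfg$donut_prob <- 0.0131
  }
  dots <- list(...)
  unknown_fields <- setdiff(names(dots), names(cfg))
  if (length(unknown_fields)) {
    stop("unknown config fields: ", paste(unknown_fields, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (any(cfg$density < 0)) stop("densities must be non-negative")
  class(cfg) <- "neuropil_config"
  cfg
}

#' Simulate an annotated image stack of synapse markers
#'
#' Poisson-places markers of each census category uniformly in the stack
#' cube, draws log-normal diameters, and wires multi-synaptic-bouton ids:
#' markers of the MSB categories are grouped two per bouton, with a
#' configured fraction of mixed spine+shaft boutons. Deterministic for a
#' fixed seed.
#'
#' @param config a [neuropil_config()].
#' @param seed integer random seed (mandatory for reproducibility).
#' @return list: `markers` ([synapse_markers()]), `brick` (the 1-um-inset
#'   [counting_brick()]), and `ground_truth` (programmed densities, realised
#'   per-category counts, MSB bouton census by target combination).
#' @export
simulate_stack <- function(config = neuropil_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  edge <- config$stack_edge_um
  vol <- edge^3
  lam <- config$density

  place <- function(n) matrix(stats::runif(3 * n, 0, edge), ncol = 3L)
  rows <- list()
  bouton_counter <- 0L
  new_ids <- function(n) {
    out <- sprintf("b%06d", bouton_counter + seq_len(n))
    bouton_counter <<- bouton_counter + n
    out
  }
  add <- function(n, syn_class, target, bouton_id, pos = NULL) {
    if (n == 0L) return()
    p <- if (is.null(pos)) place(n) else pos
    rows[[length(rows) + 1L]] <<- data.frame(
      x = p[, 1L], y = p[, 2L], z = p[, 3L],
      syn_class = syn_class, target = target, bouton_id = bouton_id,
      stringsAsFactors = FALSE)
  }
  # synapses of one bouton sit within ~0.3 um of its center, so partners
  # almost always share the brick-inclusion outcome (as in real tissue)
  bouton_positions <- function(ids) {
    centers <- matrix(stats::runif(3 * length(unique(ids)), 0, edge),
                      ncol = 3L, dimnames = list(unique(ids), NULL))
    ctr <- centers[ids, , drop = FALSE]
    off <- matrix(stats::runif(3 * length(ids), -0.15, 0.15), ncol = 3L)
    pmin(pmax(ctr + off, 0), edge)
  }

  counts <- stats::setNames(
    stats::rpois(length(lam), lam * vol), names(lam))

  add(counts["asym_spine_single"], "asymmetric", "spine",
      new_ids(counts["asym_spine_single"]))
  add(counts["asym_shaft_single"], "asymmetric", "shaft",
      new_ids(counts["asym_shaft_single"]))
  add(counts["sym_spine"], "symmetric", "spine", NA)
  add(counts["sym_shaft"], "symmetric", "shaft", NA)
  add(counts["unknown"], "unknown", "unknown", NA)

  # MSB wiring: mixed boutons take one spine- and one shaft-target marker
  n_sp <- counts["asym_spine_msb"]; n_sh <- counts["asym_shaft_msb"]
  n_both <- floor(config$msb_both_fraction * min(n_sp, n_sh))
  msb_census_truth <- c(spines_only = 0L, shafts_only = 0L,
                        both = as.integer(n_both))
  if (n_both > 0L) {
    ids <- new_ids(n_both)
    pos <- bouton_positions(rep(ids, 2L))
    add(n_both, "asymmetric", "spine", ids,
        pos = pos[seq_len(n_both), , drop = FALSE])
    add(n_both, "asymmetric", "shaft", ids,
        pos = pos[n_both + seq_len(n_both), , drop = FALSE])
  }
  pair_up <- function(n_left, target, combo) {
    if (n_left <= 0L) return()
    n_b <- n_left %/% 2L
    if (n_b == 0L) {  # a lone marker cannot form an MSB; give it a partner
      n_b <- 1L; n_left <- 2L
      counts[paste0("asym_", target, "_msb")] <<-
        counts[paste0("asym_", target, "_msb")] + 1L
    }
    ids <- rep(new_ids(n_b), length.out = n_left)  # odd one joins a bouton
    add(n_left, "asymmetric", target, ids, pos = bouton_positions(ids))
    msb_census_truth[combo] <<- msb_census_truth[combo] + n_b
  }
  pair_up(n_sp - n_both, "spine", "spines_only")
  pair_up(n_sh - n_both, "shaft", "shafts_only")

  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               syn_class = character(0), target = character(0),
               bouton_id = character(0), stringsAsFactors = FALSE)
  n <- nrow(df)
  diam <- if (n) stats::rlnorm(n, log(config$diameter_median_nm),
                               config$diameter_log_sd) else numeric(0)
  markers <- synapse_markers(df$x, df$y, df$z, diam,
                             syn_class = df$syn_class, target = df$target,
                             bouton_id = df$bouton_id, animal = "sim")
  g <- config$guard_um
  brick <- counting_brick(box3(rep(g, 3L), rep(edge - g, 3L)))
  list(markers = markers, brick = brick,
       ground_truth = list(
         density = lam, counts = counts, stack_volume = vol,
         msb_boutons = msb_census_truth,
         diameter_median_nm = config$diameter_median_nm,
         diameter_log_sd = config$diameter_log_sd))
}

# Random smooth polyline: fixed step with angular jitter, started in a
# dilated box so fragments cross the faces like real neurites.
.random_polyline <- function(box, step = 0.5, n_steps, dilate = 0.5) {
  lo <- box$min - dilate; hi <- box$max + dilate
  p <- stats::runif(3, lo, hi)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(0, nrow = n_steps + 1L, ncol = 3L)
  pts[1L, ] <- p
  for (k in seq_len(n_steps)) {
    dir <- dir + stats::rnorm(3, sd = 0.25)
    dir <- dir / sqrt(sum(dir^2))
    p <- p + step * dir
    pts[k + 1L, ] <- p
  }
  pts
}

#' Simulate a densely reconstructed 5-um sub-volume
#'
#' Axon and dendrite centerlines are random smooth polylines accumulated
#' until the programmed length density (clipped to the cube) is reached;
#' synaptic contacts are disc meshes (perforated contacts become punctured
#' grid patches), boutons ellipsoids, spine heads spheres, mitochondria
#' ellipsoids carrying host and donut flags. Spine-head volume and contact
#' area are coupled by the programmed linear relation
#' `area = alpha * volume + noise`, and the alpha used is recorded in the
#' ground truth. A subset of boutons gets a vesicle cloud of non-overlapping
#' spheres (dart throwing) with the contact disc as the presynaptic
#' membrane.
#'
#' @param config a [neuropil_config()].
#' @param seed integer random seed.
#' @param with_vesicles generate vesicle clouds (slowest part).
#' @return list: `sub` (a [subvolume()]) and `ground_truth`.
#' @export
simulate_subvolume <- function(config = neuropil_config(), seed,
                               with_vesicles = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  e <- config$sub_edge_um
  box <- box3(c(0, 0, 0), c(e, e, e))
  vol <- box_volume(box)

  grow_neurites <- function(kind, target_density) {
    target <- target_density * vol
    recs <- list()
    total <- 0
    i <- 0L
    while (total < target && target > 0) {
      i <- i + 1L
      line <- .random_polyline(box, step = 0.5,
                               n_steps = sample(8:16, 1L))
      cl <- clip_polyline_length(line, box)
      if (cl <= 0) next
      sub_cls <- if (kind == "axon") {
        sample(names(config$axon_subclass_prob), 1L,
               prob = config$axon_subclass_prob)
      } else NULL
      recs[[length(recs) + 1L]] <- neurite_record(
        sprintf("%s%04d", substr(kind, 1L, 1L), i), kind, line,
        subclass = sub_cls)
      total <- total + cl
    }
    list(recs = recs, total_clipped = total)
  }
  ax <- grow_neurites("axon", config$axon_length_density)
  de <- grow_neurites("dendrite", config$dendrite_length_density)

  # synaptic contacts with coupled bouton/spine sizes
  n_contact <- stats::rpois(1L, config$contact_density * vol)
  dens <- config$density
  asym_frac <- if (sum(dens) > 0) {
    sum(dens[startsWith(names(dens), "asym")]) / sum(dens)
  } else 0
  spine_frac_asym <- if (sum(dens[c(1, 2, 3, 4)]) > 0) {
    sum(dens[c("asym_spine_single", "asym_spine_msb")]) /
      sum(dens[startsWith(names(dens), "asym")])
  } else 0

  contacts <- list(); boutons <- list(); spines <- list()
  n_perforated <- 0L
  truth_pairs <- data.frame(spine_volume = numeric(0), area = numeric(0))
  for (i in seq_len(n_contact)) {
    is_asym <- stats::runif(1) < asym_frac
    on_spine <- is_asym && stats::runif(1) < spine_frac_asym
    v_sp <- stats::rlnorm(1, config$spine_volume_meanlog,
                          config$spine_volume_sdlog)
    area <- max(0.01, config$area_coupling_alpha * v_sp +
                  stats::rnorm(1, 0, config$area_coupling_noise))
    center <- stats::runif(3, 0.3, e - 0.3)
    rot <- rotation_about("x", stats::runif(1, 0, pi / 4)) %*%
      rotation_about("z", stats::runif(1, 0, 2 * pi))
    perforated <- is_asym && stats::runif(1) < config$perforation_prob
    if (perforated) {
      n_perforated <- n_perforated + 1L
      w <- sqrt(area / (1 - 1 / 36))
      cmesh <- mesh_patch(w, w, n = 6, holes = list(c(3L, 4L)),
                          center = center, rotation = rot,
                          id = sprintf("contact%04d", i))
    } else {
      r_eff <- sqrt(area / pi)
      cmesh <- mesh_disc(r_eff, r_eff, n = 24, center = center,
                         rotation = rot, id = sprintf("contact%04d", i))
    }
    contacts[[i]] <- list(
      id = sprintf("contact%04d", i), mesh = cmesh,
      syn_class = if (is_asym) "asymmetric" else "symmetric",
      target = if (on_spine) "spine" else "shaft",
      bouton_id = sprintf("sb%04d", i), perforated = perforated,
      area_um2 = surface_area(cmesh))
    if (is_asym) {
      v_b <- stats::rlnorm(1, config$bouton_volume_meanlog,
                           config$bouton_volume_sdlog)
      r0 <- (3 * v_b / (4 * pi))^(1 / 3)
      ar <- stats::runif(2, 0.7, 1.3)
      semi <- r0 * c(ar[1L], ar[2L], 1 / (ar[1L] * ar[2L]))
      bc <- center + stats::runif(3, -0.2, 0.2)
      boutons[[length(boutons) + 1L]] <- list(
        id = sprintf("sb%04d", i),
        mesh = mesh_ellipsoid(semi, center = bc, subdiv = 2,
                              id = sprintf("sb%04d", i)),
        contact_id = sprintf("contact%04d", i))
    }
    if (on_spine) {
      r_sp <- (3 * v_sp / (4 * pi))^(1 / 3)
      sc <- center + stats::runif(3, -0.2, 0.2)
      spines[[length(spines) + 1L]] <- list(
        id = sprintf("sp%04d", i),
        mesh = mesh_icosphere(r_sp, subdiv = 2, center = sc,
                              id = sprintf("sp%04d", i)),
        contact_id = sprintf("contact%04d", i))
      truth_pairs <- rbind(truth_pairs,
                           data.frame(spine_volume = v_sp, area = area))
    }
  }

  # mitochondria
  n_mito <- stats::rpois(1L, config$mito_count)
  mito <- vector("list", n_mito)
  for (i in seq_len(n_mito)) {
    v_m <- stats::rlnorm(1, config$mito_volume_meanlog,
                         config$mito_volume_sdlog)
    r0 <- (3 * v_m / (4 * pi))^(1 / 3)
    stretch <- stats::runif(1, 1.2, 2.5)  # mitochondria are elongated
    semi <- r0 * c(stretch, 1 / sqrt(stretch), 1 / sqrt(stretch))
    m <- mesh_ellipsoid(semi, center = stats::runif(3, 0, e), subdiv = 1,
                        id = sprintf("mito%04d", i))
    mito[[i]] <- list(
      id = sprintf("mito%04d", i), mesh = m,
      volume = enclosed_volume(m),
      host = sample(names(config$mito_host_prob), 1L,
                    prob = config$mito_host_prob),
      donut = stats::runif(1) < config$donut_prob)
  }

  # vesicle clouds on the first few asymmetric-on-spine boutons
  vsets <- list()
  if (with_vesicles && length(boutons) > 0L) {
    take <- utils::head(seq_along(boutons), config$n_vesicle_boutons)
    for (bi in take) {
      b <- boutons[[bi]]
      ct <- Filter(function(ctc) identical(ctc$id, b$contact_id),
                   contacts)[[1L]]
      bvol <- enclosed_volume(b$mesh)
      n_ves <- round(config$vesicle_density * bvol)
      vsets[[length(vsets) + 1L]] <- .fill_vesicles(
        b, ct, n_ves, config$vesicle_radius_nm)
    }
  }

  sub <- subvolume(box = box, neurites = c(ax$recs, de$recs),
                   boutons = boutons, spines = spines, contacts = contacts,
                   mitochondria = mito, vesicle_sets = vsets,
                   animal = "sim", group = config$group)
  truth <- list(
    axon_length = ax$total_clipped, dendrite_length = de$total_clipped,
    axon_length_density = ax$total_clipped / vol,
    dendrite_length_density = de$total_clipped / vol,
    n_contacts = n_contact, n_perforated = n_perforated,
    perforated_fraction = if (n_contact) n_perforated /
      sum(vapply(contacts, function(ctc) ctc$syn_class == "asymmetric",
                 logical(1L))) else NA_real_,
    contact_areas = vapply(contacts, `[[`, numeric(1L), "area_um2"),
    alpha = config$area_coupling_alpha,
    coupling_pairs = truth_pairs,
    mito = data.frame(
      host = vapply(mito, `[[`, character(1L), "host"),
      volume = vapply(mito, `[[`, numeric(1L), "volume"),
      donut = vapply(mito, function(m) isTRUE(m$donut), logical(1L))),
    vesicle_counts = vapply(vsets, function(v) nrow(v$centers), numeric(1L)))
  list(sub = sub, ground_truth = truth)
}

# Dart-throwing vesicle cloud inside an ellipsoidal bouton; hard
# non-overlap between vesicle spheres.
.fill_vesicles <- function(bouton, contact, n_ves, radius_nm,
                           max_tries = 40L) {
  m <- bouton$mesh
  ctr <- colMeans(m$vertices)
  # recover semi-axes from the axis-aligned extent (generator ellipsoids
  # are axis-aligned)
  semi <- (apply(m$vertices, 2L, max) - apply(m$vertices, 2L, min)) / 2
  r <- radius_nm * 1e-3
  pts <- matrix(0, nrow = 0L, ncol = 3L)
  consec_fail <- 0L
  while (nrow(pts) < n_ves && consec_fail < max_tries * 50L) {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) > 1) {
      consec_fail <- consec_fail + 1L
      next
    }
    cand <- ctr + u * (semi - r) * 0.95
    if (nrow(pts) > 0L) {
      d2 <- colSums((t(pts) - cand)^2)
      if (min(d2) < (2 * r)^2) {
        consec_fail <- consec_fail + 1L
        next
      }
    }
    pts <- rbind(pts, cand)
    consec_fail <- 0L
  }
  if (nrow(pts) < n_ves) {
    stop(sprintf("vesicle packing infeasible: placed %d of %d",
                 nrow(pts), n_ves))
  }
  vesicle_set(bouton$id, pts, radius_nm, contact$mesh,
              bouton_volume_um3 = enclosed_volume(m),
              contact_area_um2 = contact$area_um2)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: one annotated stack plus one densely reconstructed
#' sub-volume under the same configuration, with their ground truths.
#'
#' @param config a [neuropil_config()].
#' @param seed integer seed.
#' @param with_vesicles passed to [simulate_subvolume()].
#' @return list: `stack`, `sub`, `ground_truth` (merged).
#' @export
generate_neuropil <- function(config = neuropil_config(), seed,
                              with_vesicles = TRUE) {
  st <- simulate_stack(config, seed = seed)
  sv <- simulate_subvolume(config, seed = seed + 1L,
                           with_vesicles = with_vesicles)
  list(stack = st, sub = sv$sub,
       ground_truth = c(st$ground_truth, sv$ground_truth))
}

#' Generate a diameter/area calibration set
#'
#' Tilted elliptical contact meshes with known (triangulated) surface area;
#' the diameter is measured from the mesh with [estimate_diameter()], the
#' area carries additive Gaussian noise. Emulates the 57-synapse validation
#' set used to calibrate the diameter proxy.
#'
#' @param n number of contacts.
#' @param noise_sd additive area noise (um^2).
#' @param seed integer seed.
#' @param max_tilt maximum tilt from the section plane (radians); 0 keeps
#'   every contact in-plane.
#' @param ratio_range range of minor/major ellipse axis ratios; `c(1, 1)`
#'   makes all contacts circular.
#' @return data frame with `diameter_um` (measured), `area_um2` (true +
#'   noise) and `true_area_um2`; meshes in the `"meshes"` attribute.
#' @export
generate_calibration_set <- function(n = 57, noise_sd = 0.02, seed = 1,
                                     max_tilt = 35 * pi / 180,
                                     ratio_range = c(0.6, 1)) {
  set.seed(seed)
  meshes <- vector("list", n)
  d_meas <- numeric(n); a_true <- numeric(n)
  for (i in seq_len(n)) {
    d <- stats::runif(1, 0.2, 0.7)
    ratio <- stats::runif(1, ratio_range[1L], ratio_range[2L])
    rot <- rotation_about("x", stats::runif(1, 0, max_tilt)) %*%
      rotation_about("z", stats::runif(1, 0, 2 * pi))
    m <- mesh_disc(d / 2, d / 2 * ratio, n = 48, rotation = rot,
                   id = sprintf("cal%03d", i))
    meshes[[i]] <- m
    a_true[i] <- surface_area(m)
    d_meas[i] <- estimate_diameter(m) * 1e-3
  }
  out <- data.frame(diameter_um = d_meas,
                    area_um2 = a_true + stats::rnorm(n, 0, noise_sd),
                    true_area_um2 = a_true)
  attr(out, "meshes") <- meshes
  out
}

#' Simple non-overlapping compartment phantom
#'
#' Disjoint closed meshes with known volumes for the five occupancy
#' compartments, used to validate [volume_fractions()] against programmed
#' fractions and the voxel oracle.
#'
#' @param seed integer seed.
#' @return list: `sub` (a [subvolume()]) and `fractions` (programmed
#'   percent occupancy per compartment, from exact mesh volumes).
#' @export
generate_phantom <- function(seed = 1) {
  set.seed(seed)
  box <- box3(c(0, 0, 0), c(5, 5, 5))
  # jittered grid of cell centers keeps objects disjoint
  centers <- as.matrix(expand.grid(x = seq(0.7, 4.3, by = 1.2),
                                   y = seq(0.7, 4.3, by = 1.2),
                                   z = seq(0.7, 4.3, by = 1.2)))
  centers <- centers + matrix(stats::runif(length(centers), -0.1, 0.1),
                              ncol = 3L)
  centers <- centers[sample(nrow(centers)), ]
  k <- 0L
  next_center <- function() {
    k <<- k + 1L
    centers[k, ]
  }
  sphere_at <- function(r, id) {
    mesh_icosphere(r, subdiv = 2, center = next_center(), id = id)
  }
  axons <- lapply(1:8, function(i) {
    list(sphere = sphere_at(0.42, sprintf("ax%d", i)))
  })
  dendrites <- lapply(1:6, function(i) {
    list(sphere = sphere_at(0.45, sprintf("de%d", i)))
  })
  glia <- lapply(1:5, function(i) list(mesh = sphere_at(0.4,
                                                        sprintf("gl%d", i))))
  connecting <- lapply(1:6, function(i) list(mesh = sphere_at(0.3,
                                                              sprintf("cu%d", i))))
  mito <- lapply(1:8, function(i) {
    m <- sphere_at(0.2, sprintf("mt%d", i))
    list(id = sprintf("mt%d", i), mesh = m, volume = enclosed_volume(m),
         host = "axon", donut = FALSE)
  })
  ax_recs <- lapply(seq_along(axons), function(i) {
    m <- axons[[i]]$sphere
    neurite_record(sprintf("ax%d", i), "axon",
                   rbind(colMeans(m$vertices) - c(0.1, 0, 0),
                         colMeans(m$vertices) + c(0.1, 0, 0)),
                   mesh = m)
  })
  de_recs <- lapply(seq_along(dendrites), function(i) {
    m <- dendrites[[i]]$sphere
    neurite_record(sprintf("de%d", i), "dendrite",
                   rbind(colMeans(m$vertices) - c(0.1, 0, 0),
                         colMeans(m$vertices) + c(0.1, 0, 0)),
                   mesh = m)
  })
  sub <- subvolume(box = box, neurites = c(ax_recs, de_recs),
                   boutons = connecting[1:3], spines = connecting[4:6],
                   mitochondria = mito, glia = glia, animal = "phantom")
  vol_sum <- function(objs) {
    sum(vapply(objs, function(o) enclosed_volume(o$mesh), numeric(1L)))
  }
  fractions <- 100 / box_volume(box) * c(
    connecting = vol_sum(connecting),
    axons = sum(vapply(ax_recs, function(r) enclosed_volume(r$mesh),
                       numeric(1L))),
    dendrites = sum(vapply(de_recs, function(r) enclosed_volume(r$mesh),
                           numeric(1L))),
    glia = vol_sum(glia),
    mitochondria = vol_sum(mito))
  list(sub = sub, fractions = fractions)
}
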