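#' Synapse marker table
#'
#' Point annotations of synapses: one ball per synapse at the contact center,
#' with diameter equal to the maximum width of the contact. Built from raw
#' vectors or an annotation data frame (CSV); coordinates in micrometres,
#' diameters in nanometres.
#'
#' @param x,y,z marker centers (micrometres).
#' @param diameter_nm maximum-width diameters (nanometres, > 0).
#' @param syn_class `"asymmetric"`, `"symmetric"` or `"unknown"`.
#' @param target postsynaptic target: `"spine"`, `"shaft"` or `"unknown"`.
#' @param bouton_id presynaptic bouton identifier (`NA` when not annotated).
#' @param animal optional animal identifier.
#' @return a `data.frame` with class `"synapse_markers"`.
#' @export
synapse_markers <- function(x, y, z, diameter_nm,
                            syn_class = "unknown", target = "unknown",
                            bouton_id = NA, animal = NA) {
  n <- length(x)
  syn_class <- rep_len(as.character(syn_class), n)
  target <- rep_len(as.character(target), n)
  if (!all(syn_class %in% c("asymmetric", "symmetric", "unknown"))) {
    stop("syn_class must be asymmetric, symmetric or unknown")
  }
  if (!all(target %in% c("spine", "shaft", "unknown"))) {
    stop("target must be spine, shaft or unknown")
  }
  diameter_nm <- rep_len(as.numeric(diameter_nm), n)
  if (n > 0 && any(diameter_nm <= 0)) stop("diameters must be positive")
  out <- data.frame(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    diameter_nm = diameter_nm, syn_class = syn_class, target = target,
    bouton_id = rep_len(as.character(bouton_id), n),
    animal = rep_len(as.character(animal), n),
    stringsAsFactors = FALSE)
  class(out) <- c("synapse_markers", "data.frame")
  out
}

#' Read synapse markers from an annotation CSV
#'
#' Expects columns x, y, z, diameter, syn_class, target, bouton_id (and
#' optionally animal). `units` says which length unit the coordinate columns
#' carry; nm coordinates are converted to micrometres at ingest. Diameters
#' are always interpreted in nm.
#'
#' @param path CSV path.
#' @param units `"um"` or `"nm"` for the coordinate columns.
#' @return a [synapse_markers()] table.
#' @export
read_markers_csv <- function(path, units = c("um", "nm")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "diameter")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("annotation CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("annotation CSV is empty: ", path)
  s <- if (units == "nm") 1e-3 else 1
  synapse_markers(
    df$x * s, df$y * s, df$z * s, df$diameter,
    syn_class = if ("syn_class" %in% names(df)) df$syn_class else "unknown",
    target = if ("target" %in% names(df)) df$target else "unknown",
    bouton_id = if ("bouton_id" %in% names(df)) df$bouton_id else NA,
    animal = if ("animal" %in% names(df)) df$animal else NA)
}

#' Unbiased counting brick
#'
#' An axis-aligned box with inclusion planes on three mutually orthogonal
#' faces and exclusion planes on the three opposite faces. A marker whose
#' center lies on an inclusion face is counted; one on (or beyond) an
#' exclusion face is not. Default inclusion faces are -x (left), +y (top)
#' and +z (upper); the assignment is configurable since the imaging axes are
#' arbitrary. The estimate is unbiased for any assignment.
#'
#' @param box a [box3()].
#' @param inclusion three strings among `"-x"`, `"+x"`, `"-y"`, `"+y"`,
#'   `"-z"`, `"+z"`, exactly one per axis.
#' @return object of class `"counting_brick"`.
#' @export
counting_brick <- function(box, inclusion = c("-x", "+y", "+z")) {
  inclusion <- as.character(inclusion)
  ax <- substr(inclusion, 2L, 2L)
  if (length(inclusion) != 3L || !setequal(ax, c("x", "y", "z"))) {
    stop("inclusion must name one face per axis")
  }
  sign <- ifelse(substr(inclusion, 1L, 1L) == "-", -1L, 1L)
  names(sign) <- ax
  structure(list(box = box, inclusion_sign = sign[c("x", "y", "z")]),
            class = "counting_brick")
}

#' Apply the inclusion/exclusion-plane rule
#'
#' Keeps the markers whose centers fall inside the brick, counting centers
#' on inclusion faces and discarding centers on exclusion faces. The test
#' uses the center point only; the marker ball's extent is ignored.
#'
#' @param markers a [synapse_markers()] table.
#' @param brick a [counting_brick()].
#' @return the included subset of `markers`.
#' @export
brick_filter <- function(markers, brick) {
  if (!inherits(brick, "counting_brick")) stop("not a counting_brick")
  lo <- brick$box$min; hi <- brick$box$max
  keep <- rep(TRUE, nrow(markers))
  coords <- list(markers$x, markers$y, markers$z)
  for (a in 1:3) {
    if (brick$inclusion_sign[a] < 0) {
      # min face inclusive, max face exclusive
      keep <- keep & coords[[a]] >= lo[a] & coords[[a]] < hi[a]
    } else {
      keep <- keep & coords[[a]] > lo[a] & coords[[a]] <= hi[a]
    }
  }
  markers[keep, , drop = FALSE]
}

.census_categories <- c(
  "asym_spine_single", "asym_spine_msb",
  "asym_shaft_single", "asym_shaft_msb",
  "sym_spine", "sym_shaft", "unknown")

#' Per-category synapse density census
#'
#' Counts the markers passing [brick_filter()] in the seven published
#' categories (asymmetric on spines / on dendritic shafts, each split by
#' single vs multi-synaptic bouton; symmetric on spines; symmetric on
#' shafts; unclassified) and divides by the brick volume. A bouton is
#' multi-synaptic when two or more included asymmetric markers share its id.
#' Markers with a known class but unknown target are inconsistent with the
#' published categories and are routed to `"unknown"` with a warning.
#'
#' @param markers a [synapse_markers()] table (one animal).
#' @param brick a [counting_brick()].
#' @return a one-row `data.frame` of class `"density_table"` with counts
#'   (`n_*`), densities per category, `total` density, `volume_um3` and
#'   `n_included`.
#' @export
density_census <- function(markers, brick) {
  inc <- brick_filter(markers, brick)
  vol <- box_volume(brick$box)

  cat <- rep("unknown", nrow(inc))
  asym <- inc$syn_class == "asymmetric"
  sym <- inc$syn_class == "symmetric"
  # MSB status among included asymmetric markers
  msb_ids <- character(0)
  if (any(asym)) {
    ids <- inc$bouton_id[asym]
    ids <- ids[!is.na(ids)]
    tab <- table(ids)
    msb_ids <- names(tab)[tab >= 2L]
  }
  is_msb <- asym & !is.na(inc$bouton_id) & inc$bouton_id %in% msb_ids

  inconsistent <- (asym | sym) & inc$target == "unknown"
  if (any(inconsistent)) {
    warning(sprintf(
      "%d markers with known class but unknown target routed to 'unknown'",
      sum(inconsistent)))
  }
  ok <- !inconsistent
  cat[ok & asym & inc$target == "spine" & !is_msb] <- "asym_spine_single"
  cat[ok & asym & inc$target == "spine" & is_msb] <- "asym_spine_msb"
  cat[ok & asym & inc$target == "shaft" & !is_msb] <- "asym_shaft_single"
  cat[ok & asym & inc$target == "shaft" & is_msb] <- "asym_shaft_msb"
  cat[ok & sym & inc$target == "spine"] <- "sym_spine"
  cat[ok & sym & inc$target == "shaft"] <- "sym_shaft"

  counts <- vapply(.census_categories, function(k) sum(cat == k), numeric(1))
  dens <- counts / vol
  out <- data.frame(
    animal = if (nrow(inc) > 0) inc$animal[1L] else NA_character_,
    volume_um3 = vol, n_included = nrow(inc), t(counts), t(dens),
    total = sum(dens), stringsAsFactors = FALSE)
  names(out) <- c("animal", "volume_um3", "n_included",
                  paste0("n_", .census_categories), .census_categories,
                  "total")
  class(out) <- c("density_table", "data.frame")
  out
}

#' Build a density table directly from per-category densities
#'
#' Used when densities (not raw annotations) are the available input, e.g.
#' the published per-animal table.
#'
#' @param densities data frame with columns named as the seven census
#'   categories plus optionally `animal`, `group`, `volume_um3`,
#'   `n_included`.
#' @return a `"density_table"` data frame with recomputed `total`.
#' @export
density_table <- function(densities) {
  missing_cols <- setdiff(.census_categories, names(densities))
  if (length(missing_cols)) {
    stop("missing density columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(densities)
  out$total <- rowSums(out[, .census_categories])
  class(out) <- c("density_table", "data.frame")
  out
}

#' Multi-synaptic bouton census
#'
#' A bouton is multi-synaptic (MSB) when two or more asymmetric markers
#' passing the brick filter share its id; symmetric-only bouton groups are
#' ignored (boutons of symmetric synapses cannot be delineated reliably).
#' MSBs are classified by the set of their postsynaptic targets and reported
#' as densities.
#'
#' @param markers a [synapse_markers()] table.
#' @param brick a [counting_brick()].
#' @return `data.frame` with one row per combination (`spines_only`,
#'   `shafts_only`, `both`): counts and densities per cubic micrometre.
#' @export
msb_census <- function(markers, brick) {
  inc <- brick_filter(markers, brick)
  vol <- box_volume(brick$box)
  asym <- inc[inc$syn_class == "asymmetric" & !is.na(inc$bouton_id), ,
              drop = FALSE]
  combo <- c(spines_only = 0, shafts_only = 0, both = 0)
  if (nrow(asym) > 0) {
    for (id in unique(asym$bouton_id)) {
      tg <- asym$target[asym$bouton_id == id]
      if (length(tg) < 2L) next
      has_sp <- any(tg == "spine"); has_sh <- any(tg == "shaft")
      if (has_sp && has_sh) combo["both"] <- combo["both"] + 1
      else if (has_sp) combo["spines_only"] <- combo["spines_only"] + 1
      else if (has_sh) combo["shafts_only"] <- combo["shafts_only"] + 1
    }
  }
  data.frame(combination = names(combo), count = as.numeric(combo),
             density = as.numeric(combo) / vol, stringsAsFactors = FALSE)
}

#' Inhibitory-to-excitatory density ratio
#'
#' (symmetric on spines + symmetric on shafts) / (sum of the four asymmetric
#' categories), computed per animal (per row of the density table). Group
#' means are taken over the per-animal ratios with [group_summary()].
#'
#' @param table a `"density_table"` data frame (one row per animal).
#' @return numeric vector of per-animal ratios (named by animal when known).
#' @export
ei_ratio <- function(table) {
  asym <- table$asym_spine_single + table$asym_spine_msb +
    table$asym_shaft_single + table$asym_shaft_msb
  if (any(asym <= 0)) stop("asymmetric density must be positive")
  r <- (table$sym_spine + table$sym_shaft) / asym
  if (!is.null(table$animal)) names(r) <- table$animal
  r
}

#' Fraction of markers that could be classified
#'
#' @param markers a [synapse_markers()] table.
#' @return percent of markers with a known synapse class.
#' @export
classified_fraction <- function(markers) {
  if (nrow(markers) == 0L) return(NA_real_)
  100 * mean(markers$syn_class != "unknown")
}
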