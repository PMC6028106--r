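.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "neuropilr")
  if (p == "") {
    # during in-source development (pkgload) extdata sits under inst/
    p <- system.file("inst", "extdata", file, package = "neuropilr")
  }
  if (p == "") stop("fixture not found: ", file)
  p
}

.adult_animals <- c("1", "3", "6")
.aged_animals <- c("2", "4", "5")

#' Published per-animal synapse density table
#'
#' The per-animal, per-category synapse densities and imaged volumes of the
#' six animals (three 4-month adults, three 24-month aged). Shipped as
#' printed, decimal commas and all; commas are normalized to points at
#' ingest.
#'
#' @return a `"density_table"` data frame with `animal`, `group`,
#'   `volume_um3`, `n_included`, the seven category densities and the
#'   recomputed `total`.
#' @export
load_table1 <- function() {
  df <- utils::read.csv2(.fixture_path("table1_synapse_density.csv"),
                         stringsAsFactors = FALSE)
  out <- data.frame(
    animal = as.character(df$animal),
    group = ifelse(df$age == "4 months", "adult", "aged"),
    volume_um3 = df$total_vol,
    n_included = df$n_synapses,
    asym_spine_single = df$asym_spine_single,
    asym_spine_msb = df$asym_spine_msb,
    asym_shaft_single = df$asym_shaft_single,
    asym_shaft_msb = df$asym_shaft_msb,
    sym_spine = df$sym_spine,
    sym_shaft = df$sym_shaft,
    unknown = df$unknown,
    printed_total = df$total_density,
    stringsAsFactors = FALSE)
  density_table(out)
}

#' Published per-sub-volume reconstruction measurements
#'
#' Lengths, counts, surface areas and volumes of every reconstructed object
#' class in the six 5 x 5 x 5 um sub-volumes (animal columns 1, 3, 6 adult;
#' 2, 4, 5 aged). Decimal commas normalized at ingest.
#'
#' @return long data frame: `section`, `subgroup`, `measure`, `animal`,
#'   `group`, `value`.
#' @export
load_table2 <- function() {
  df <- utils::read.csv2(.fixture_path("table2_reconstructions.csv"),
                         stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c("a1", "a3", "a6", "a2", "a4", "a5"),
                                function(col) {
    an <- sub("^a", "", col)
    data.frame(section = df$section, subgroup = df$subgroup,
               measure = df$measure, animal = an,
               group = if (an %in% .adult_animals) "adult" else "aged",
               value = as.numeric(df[[col]]), stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Published group-level summary values
#'
#' Group means (or counts) printed in the text and figure captions, used as
#' the reference column of [reproduce_paper()].
#'
#' @return data frame: `quantity`, `adult`, `aged`, `unit`.
#' @export
load_printed_values <- function() {
  utils::read.csv(.fixture_path("printed_group_values.csv"),
                  stringsAsFactors = FALSE)
}

.printed_value <- function(pv, quantity, group) {
  pv[pv$quantity == quantity, group]
}

#' Census report over per-animal densities
#'
#' Group summaries (mean +/- sem) and adult-vs-aged pooled t-tests for the
#' total density and every census category, from a density table (either
#' computed from annotations with [density_census()] or loaded from the
#' published fixture).
#'
#' @param table a `"density_table"` data frame with `group` column.
#' @return list: `per_animal` (the input), `groups` (data frame of mean,
#'   sem, n per group and category), `tests` (t, df, p per category).
#' @export
census_report <- function(table) {
  if (is.null(table$group)) stop("density table needs a 'group' column")
  cats <- c(.census_categories, "total")
  groups <- do.call(rbind, lapply(unique(table$group), function(g) {
    sub <- table[table$group == g, ]
    do.call(rbind, lapply(cats, function(cc) {
      gs <- group_summary(sub[[cc]], label = g)
      data.frame(group = g, category = cc, mean = gs$mean, sem = gs$sem,
                 n = gs$n, stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (all(c("adult", "aged") %in% table$group)) {
    tests <- do.call(rbind, lapply(cats, function(cc) {
      ht <- unpaired_t(table[[cc]][table$group == "adult"],
                       table[[cc]][table$group == "aged"])
      data.frame(category = cc, t = ht$t, df = ht$df, p = ht$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_animal = table, groups = groups, tests = tests)
}

.t2_values <- function(t2, section, subgroup, measure, group) {
  v <- t2[t2$section == section & t2$subgroup == subgroup &
            t2$measure == measure & t2$group == group, ]
  v <- v[match(if (group == "adult") .adult_animals else .aged_animals,
               v$animal), ]
  v$value
}

#' Recompute the published group-level quantities from the fixtures
#'
#' Reruns the arithmetic behind the group-level numbers from the per-animal
#' fixture tables (densities, E/I ratio, percent changes, length densities,
#' synapses per length, donut fractions, thickness changes) and compares
#' each with the printed value. Quantities whose printed values are known
#' not to follow from the printed per-animal data are flagged rather than
#' forced to match.
#'
#' @return data frame: `quantity`, `group`, `recomputed`, `printed`,
#'   `rel_dev_pct`, `flag`.
#' @export
reproduce_paper <- function() {
  t1 <- load_table1()
  t2 <- load_table2()
  pv <- load_printed_values()
  sub_vol <- 125  # the 5 x 5 x 5 um cube

  rows <- list()
  push <- function(quantity, group, recomputed, printed, flag = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, group = group, recomputed = recomputed,
      printed = printed,
      rel_dev_pct = 100 * abs(recomputed - printed) / abs(printed),
      flag = flag, stringsAsFactors = FALSE)
  }

  adult <- t1[t1$group == "adult", ]
  aged <- t1[t1$group == "aged", ]

  # total density recomputed the way the published column defines it:
  # synapse count over imaged volume, per animal, then group mean
  push("total_synapse_density", "adult",
       mean(adult$n_included / adult$volume_um3),
       .printed_value(pv, "total_synapse_density", "adult"))
  push("total_synapse_density", "aged",
       mean(aged$n_included / aged$volume_um3),
       .printed_value(pv, "total_synapse_density", "aged"))
  asum <- function(d) d$asym_spine_single + d$asym_spine_msb +
    d$asym_shaft_single + d$asym_shaft_msb
  ssum <- function(d) d$sym_spine + d$sym_shaft
  push("asym_density", "adult", mean(asum(adult)),
       .printed_value(pv, "asym_density", "adult"))
  push("asym_density", "aged", mean(asum(aged)),
       .printed_value(pv, "asym_density", "aged"))
  push("sym_density", "adult", mean(ssum(adult)),
       .printed_value(pv, "sym_density", "adult"))
  push("sym_density", "aged", mean(ssum(aged)),
       .printed_value(pv, "sym_density", "aged"))
  push("sym_density_decrease_pct", "both",
       percent_change(mean(ssum(adult)), mean(ssum(aged))), 45)

  # E/I ratio and its decrease
  ei_ad <- mean(ei_ratio(adult))
  ei_ag <- mean(ei_ratio(aged))
  push("ei_ratio", "adult", ei_ad, .printed_value(pv, "ei_ratio", "adult"))
  push("ei_ratio", "aged", ei_ag, .printed_value(pv, "ei_ratio", "aged"))
  push("ei_ratio_decrease_pct", "both", percent_change(ei_ad, ei_ag), 36.6,
       flag = "printed 36.6 arises from the rounded ratios 0.123/0.078")

  # length densities from sub-volume totals over 125 um^3
  for (g in c("adult", "aged")) {
    ax <- .t2_values(t2, "Axons", "Total", "total_length", g) / sub_vol
    de <- .t2_values(t2, "Dendrites", "Total", "total_length", g) / sub_vol
    push("axon_length_density", g, mean(ax),
         .printed_value(pv, "axon_length_density", g),
         flag = if (g == "aged")
           "printed 10.27 not reproduced by the printed totals / 125" else "")
    push("dendrite_length_density", g, mean(de),
         .printed_value(pv, "dendrite_length_density", g))
  }

  # synapses per unit axon length (flagged: not derivable as printed)
  for (g in c("adult", "aged")) {
    syn <- .t2_values(t2, "Synapses", "Total", "count", g)
    axl <- .t2_values(t2, "Axons", "Total", "total_length", g)
    push("synapses_per_um_axon", g, mean(syn / axl),
         .printed_value(pv, "synapses_per_um_axon", g),
         flag = "printed value not derivable from the per-animal table")
  }

  # thickness percent changes
  push("cortical_thickness_decrease_pct", "both",
       percent_change(.printed_value(pv, "cortical_thickness", "adult"),
                      .printed_value(pv, "cortical_thickness", "aged")),
       15.6)
  push("layer1_thickness_decrease_pct", "both",
       percent_change(.printed_value(pv, "layer1_thickness", "adult"),
                      .printed_value(pv, "layer1_thickness", "aged")),
       19.4)

  # donut mitochondria
  push("donut_mito_pct", "adult",
       donut_percent(.printed_value(pv, "donut_mitochondria", "adult"),
                     .printed_value(pv, "mitochondria_total", "adult")),
       0.18)
  push("donut_mito_pct", "aged",
       donut_percent(.printed_value(pv, "donut_mitochondria", "aged"),
                     .printed_value(pv, "mitochondria_total", "aged")),
       1.31)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
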