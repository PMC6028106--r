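box5 <- box3(c(0, 0, 0), c(5, 5, 5))

test_that("polyline clipping is exact and conserves length under splits", {
  # a segment crossing the whole box keeps exactly the inside part
  line <- rbind(c(-1, 2.5, 2.5), c(6, 2.5, 2.5))
  expect_equal(clip_polyline_length(line, box5), 5, tolerance = 1e-12)
  # fully inside and fully outside cases
  inside <- rbind(c(1, 1, 1), c(4, 3, 2))
  expect_equal(clip_polyline_length(inside, box5),
               polyline_length(inside), tolerance = 1e-12)
  expect_equal(clip_polyline_length(rbind(c(6, 6, 6), c(7, 7, 7)), box5), 0)

  # splitting at an arbitrary interior point conserves clipped length
  set.seed(12)
  for (i in 1:25) {
    p <- runif(3, -2, 7); q <- runif(3, -2, 7)
    t <- runif(1)
    mid <- p + t * (q - p)
    whole <- clip_polyline_length(rbind(p, q), box5)
    parts <- clip_polyline_length(rbind(p, mid), box5) +
      clip_polyline_length(rbind(mid, q), box5)
    expect_equal(whole, parts, tolerance = 1e-9)
  }
})

test_that("length density and synapses per length follow definitions", {
  expect_equal(length_density(subvolume(box5), "axon"), 0)

  ax <- neurite_record("a1", "axon", rbind(c(-1, 2.5, 2.5), c(6, 2.5, 2.5)))
  sub <- subvolume(box5, neurites = list(ax))
  expect_equal(length_density(sub, "axon"), 5 / 125)

  # 10 synapses on 100 um of axon -> 0.1 per um, reciprocal 10 um/synapse
  zig <- do.call(rbind, lapply(0:20, function(k) {
    c(0.25 + 4.5 * (k %% 2), 0.25 + 0.2 * k, 2.5)
  }))
  len <- clip_polyline_length(zig, box5)
  sub2 <- subvolume(box5,
                    neurites = list(neurite_record("a1", "axon", zig)),
                    contacts = replicate(10, list(
                      id = "c", syn_class = "asymmetric",
                      mesh = mesh_disc(0.1, 0.1)), simplify = FALSE))
  rate <- synapses_per_length(sub2, "axon")
  expect_equal(rate, 10 / len, tolerance = 1e-12)
  expect_equal(1 / rate, len / 10, tolerance = 1e-12)
  expect_error(synapses_per_length(subvolume(box5), "dendrite"), "zero")
})

test_that("synaptic surface density sums asymmetric contact areas", {
  contact <- list(id = "c1", syn_class = "asymmetric",
                  mesh = mesh_disc(0.3, 0.3, n = 48,
                                   center = c(2.5, 2.5, 2.5)))
  area <- surface_area(contact$mesh)
  ax <- neurite_record("a1", "axon", rbind(c(0, 2.5, 2.5), c(5, 2.5, 2.5)))
  sub <- subvolume(box5, neurites = list(ax), contacts = list(contact))
  got <- synaptic_surface_density(sub)
  expect_equal(unname(got["per_um_axon"]), area / 5, tolerance = 1e-12)
  expect_equal(unname(got["per_um3"]), area / 125, tolerance = 1e-12)
  expect_true(is.na(got["per_um_dendrite"]))

  # symmetric contacts do not contribute
  sub$contacts[[1]]$syn_class <- "symmetric"
  expect_equal(unname(synaptic_surface_density(sub)["per_um3"]), 0)
})

test_that("size summaries use complete objects only, totals are exact sums", {
  sp <- function(ctr) list(id = "s", mesh = mesh_icosphere(0.4, 2, ctr))
  sub <- subvolume(box5, boutons = list(sp(c(1.5, 1.5, 1.5)),
                                        sp(c(3, 3, 3)),
                                        sp(c(2, 3.5, 1.5))))
  ss <- size_summary(sub, "boutons")
  expect_equal(ss$n_complete, 3)
  expect_equal(unname(ss$volume["sd"]), 0, tolerance = 1e-12)
  v1 <- enclosed_volume(sub$boutons[[1]]$mesh)
  expect_equal(unname(ss$volume["total"]), 3 * v1, tolerance = 1e-9)
  expect_equal(unname(ss$volume["mean"]), v1, tolerance = 1e-9)

  # an object straddling the box face is excluded from moments, kept in counts
  sub2 <- subvolume(box5, boutons = list(sp(c(2.5, 2.5, 2.5)),
                                         sp(c(0, 2.5, 2.5))))
  ss2 <- size_summary(sub2, "boutons")
  expect_equal(ss2$n_total, 2)
  expect_equal(ss2$n_complete, 1)
  expect_equal(unname(ss2$volume["total"]), v1, tolerance = 1e-9)

  # no objects: zero counts, flagged moments
  ss0 <- size_summary(subvolume(box5), "spines")
  expect_equal(ss0$n_total, 0)
  expect_true(is.na(ss0$volume["mean"]))
})

test_that("volume fractions: cube phantom, empty box, generator phantom", {
  glia_cube <- mesh_cube(c(1, 1, 1), c(3.5, 3.5, 3.5))  # 15.625 um^3
  sub <- subvolume(box5, glia = list(list(id = "g", mesh = glia_cube)))
  vf <- volume_fractions(sub)
  expect_equal(unname(vf["glia"]), 12.5, tolerance = 1e-9)
  expect_equal(unname(vf["axons"]), 0)

  expect_equal(unname(volume_fractions(subvolume(box5))),
               rep(0, 5))

  ph <- generate_phantom(seed = 2)
  got <- volume_fractions(ph$sub)
  expect_equal(got, ph$fractions, tolerance = 1e-9)
  # voxel-containment oracle agrees within 1% absolute occupancy
  lab <- voxelize(lapply(ph$sub$glia, `[[`, "mesh"), voxel_nm = 50,
                  box = ph$sub$box)
  vox_pct <- 100 * sum(lab > 0) * attr(lab, "voxel_um")^3 /
    box_volume(ph$sub$box)
  expect_lt(abs(vox_pct - ph$fractions[["glia"]]), 1)
})

test_that("mitochondria census: donut arithmetic and generator truth", {
  expect_equal(round(donut_percent(8, 611), 2), 1.31)
  expect_equal(round(donut_percent(1, 570), 2), 0.18)
  expect_equal(donut_percent(0, 100), 0)
  expect_error(donut_percent(1, 0), "positive")

  cfg <- neuropil_config(contact_density = 0.2, mito_count = 60,
                         donut_prob = 0.2)
  sv <- simulate_subvolume(cfg, seed = 77, with_vesicles = FALSE)
  mc <- mito_census(sv$sub)
  truth <- sv$ground_truth$mito
  expect_equal(mc$n_total, nrow(truth))
  expect_equal(unname(mc$counts["axon"]), sum(truth$host == "axon"))
  expect_equal(mc$donut_count, sum(truth$donut))
  expect_equal(mc$donut_percent, 100 * mean(truth$donut), tolerance = 1e-12)
  expect_equal(sum(mc$histogram$count), mc$n_total)
  expect_equal(sum(mc$histogram$density) * 125, mc$n_total,
               tolerance = 1e-9)
})
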