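make_markers <- function(pos, ...) {
  synapse_markers(pos[, 1], pos[, 2], pos[, 3], diameter_nm = 300, ...)
}

test_that("brick filter honors inclusion and exclusion faces exactly", {
  brick <- counting_brick(box3(c(0, 0, 0), c(2, 2, 2)))
  pos <- rbind(
    c(1, 1, 1),    # strictly interior
    c(0, 1, 1),    # on the -x inclusion face
    c(2, 1, 1),    # on the +x exclusion face
    c(1, 2, 1),    # on the +y inclusion face
    c(1, 0, 1),    # on the -y exclusion face
    c(1, 1, 2),    # on the +z inclusion face
    c(1, 1, 0),    # on the -z exclusion face
    c(3, 1, 1))    # beyond an exclusion face
  mk <- make_markers(pos)
  inc <- brick_filter(mk, brick)
  expect_equal(nrow(inc), 4)
  expect_true(all(inc$x < 2 & inc$y > 0 & inc$z > 0))

  # idempotent and order-independent
  expect_equal(nrow(brick_filter(inc, brick)), nrow(inc))
  perm <- mk[sample(nrow(mk)), ]
  expect_equal(sort(brick_filter(perm, brick)$x), sort(inc$x))
})

test_that("uniform random markers recover the programmed density (3 sigma)", {
  set.seed(101)
  n <- 10000
  super <- 10  # markers annotated across the whole 10-um stack
  mk <- make_markers(matrix(runif(3 * n, 0, super), ncol = 3))
  brick <- counting_brick(box3(c(1, 1, 1), c(9, 9, 9)))
  vol <- box_volume(brick$box)
  lambda <- n / super^3
  inc <- nrow(brick_filter(mk, brick))
  p <- vol / super^3
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(inc / vol - lambda), 3 * se / vol)
})

test_that("density census reproduces count-over-volume and category sums", {
  # 1190 included markers in a brick of 849.7224 um^3 give density 1.400
  edge <- 849.7224^(1 / 3)
  brick <- counting_brick(box3(c(0, 0, 0), rep(edge, 3)))
  set.seed(5)
  mk <- make_markers(matrix(runif(3 * 1190, 0.01, edge - 0.01), ncol = 3),
                     syn_class = "asymmetric", target = "spine")
  cen <- density_census(mk, brick)
  expect_equal(cen$n_included, 1190)
  expect_equal(round(cen$total, 3), 1.400)

  # zero markers: an all-zero table
  empty <- make_markers(matrix(numeric(0), 0, 3))
  cen0 <- density_census(empty, brick)
  expect_equal(cen0$total, 0)
  expect_equal(cen0$n_included, 0)

  # total equals the category sum exactly
  st <- simulate_stack(neuropil_config(), seed = 11)
  cen2 <- density_census(st$markers, st$brick)
  cats <- c("asym_spine_single", "asym_spine_msb", "asym_shaft_single",
            "asym_shaft_msb", "sym_spine", "sym_shaft", "unknown")
  expect_equal(cen2$total, sum(unlist(cen2[, cats])), tolerance = 1e-12)
})

test_that("generator densities are recovered within 3 Poisson SE", {
  cfg <- neuropil_config()
  st <- simulate_stack(cfg, seed = 11)
  cen <- density_census(st$markers, st$brick)
  vol <- box_volume(st$brick$box)
  for (cat in c("asym_spine_single", "sym_spine", "sym_shaft", "unknown")) {
    lam <- cfg$density[[cat]]
    se <- sqrt(lam / vol)   # Poisson SE of a density estimate
    expect_lt(abs(cen[[cat]] - lam), 3 * se + 1e-12)
  }
  expect_lt(abs(cen$total - sum(cfg$density)),
            3 * sqrt(sum(cfg$density) / vol))
})

test_that("inconsistent class/target markers are warned and routed unknown", {
  brick <- counting_brick(box3(c(0, 0, 0), c(2, 2, 2)))
  mk <- make_markers(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                     syn_class = c("asymmetric", "symmetric"),
                     target = c("unknown", "unknown"))
  expect_warning(cen <- density_census(mk, brick), "unknown")
  expect_equal(cen$n_unknown, 2)
})

test_that("MSB census follows the asymmetric-only rule and ground truth", {
  brick <- counting_brick(box3(c(0, 0, 0), c(2, 2, 2)))
  # two asymmetric markers on one bouton, both on spines -> one MSB
  mk <- make_markers(rbind(c(1, 1, 1), c(1.2, 1, 1)),
                     syn_class = "asymmetric", target = "spine",
                     bouton_id = "b1")
  ms <- msb_census(mk, brick)
  expect_equal(ms$count[ms$combination == "spines_only"], 1)

  # an asymmetric + a symmetric synapse sharing a bouton is NOT an MSB
  mk2 <- make_markers(rbind(c(1, 1, 1), c(1.2, 1, 1)),
                      syn_class = c("asymmetric", "symmetric"),
                      target = c("spine", "shaft"), bouton_id = "b1")
  expect_equal(sum(msb_census(mk2, brick)$count), 0)

  # generator ground truth is reproduced exactly on the full stack
  st <- simulate_stack(neuropil_config(), seed = 11)
  full <- counting_brick(box3(c(0, 0, 0), c(10, 10, 10)))
  got <- msb_census(st$markers, full)
  expect_equal(stats::setNames(got$count, got$combination),
               st$ground_truth$msb_boutons[got$combination],
               tolerance = 1e-12, ignore_attr = FALSE)
})

test_that("E/I ratio reproduces the published group values", {
  t1 <- load_table1()
  adult <- t1[t1$group == "adult", ]
  aged <- t1[t1$group == "aged", ]
  expect_equal(round(mean(ei_ratio(adult)), 3), 0.123)
  expect_equal(round(mean(ei_ratio(aged)), 3), 0.078)

  # all-symmetric-zero table gives 0; zero asymmetric density errors
  zero_sym <- adult
  zero_sym$sym_spine <- 0; zero_sym$sym_shaft <- 0
  expect_equal(unname(ei_ratio(zero_sym)), rep(0, 3))
  zero_asym <- adult
  zero_asym[, c("asym_spine_single", "asym_spine_msb",
                "asym_shaft_single", "asym_shaft_msb")] <- 0
  expect_error(ei_ratio(zero_asym), "positive")
})

test_that("markers can be read from an annotation CSV with nm conversion", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(1000, 2000), y = c(500, 500), z = c(0, 100),
                       diameter = c(300, 400), syn_class = "asymmetric",
                       target = "spine", bouton_id = c("b1", "b2")),
            tmp, row.names = FALSE)
  mk <- read_markers_csv(tmp, units = "nm")
  expect_equal(mk$x, c(1, 2))           # nm -> um at ingest
  expect_equal(mk$diameter_nm, c(300, 400))

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_markers_csv(bad), "lacks columns")
  empty <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       diameter = numeric(0)), empty, row.names = FALSE)
  expect_error(read_markers_csv(empty), "empty")
})
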