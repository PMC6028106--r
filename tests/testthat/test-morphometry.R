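test_that("diameter proxy measures discs and ellipses correctly", {
  # in-plane circular contact of diameter 380 nm
  disc <- mesh_disc(0.19, 0.19, n = 48)
  expect_equal(estimate_diameter(disc), 380, tolerance = 1e-9)

  # elongated elliptical contact 500 x 200 nm in-plane: the major axis
  ell <- mesh_disc(0.25, 0.10, n = 48)
  expect_equal(estimate_diameter(ell), 500, tolerance = 1e-9)

  # disc rotated out of plane: dense-sweep oracle
  tilt <- 30 * pi / 180
  rot <- mesh_disc(0.19, 0.19, n = 96, rotation = rotation_about("x", tilt))
  want_nm <- 1e3 * oracle_tilted_disc_caliper(0.19, 0.19, tilt)
  expect_equal(estimate_diameter(rot, pitch = 0.001), want_nm,
               tolerance = 0.01)
})

test_that("quadratic calibration: exact circles, noisy recovery, errors", {
  d <- seq(0.2, 0.7, length.out = 20)
  exact <- data.frame(diameter_um = d, area_um2 = pi / 4 * d^2)
  fit <- fit_calibration(exact)
  expect_equal(unname(fit$coefficients), c(0, 0, pi / 4), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # known quadratic plus noise: coefficients within 3 standard errors
  set.seed(57)
  x <- runif(57, 0.2, 0.7)
  y <- 0.03 - 0.1 * x + 0.9 * x^2 + rnorm(57, 0, 0.02)
  fit2 <- fit_calibration(data.frame(diameter_um = x, area_um2 = y))
  se <- summary(lm(y ~ x + I(x^2)))$coefficients[, 2]
  expect_true(all(abs(fit2$coefficients - c(0.03, -0.1, 0.9)) < 3 * se))

  expect_error(fit_calibration(data.frame(diameter_um = c(0.2, 0.4),
                                          area_um2 = c(0.03, 0.12))),
               "at least 3")
  expect_error(fit_calibration(data.frame(diameter_um = rep(0.3, 5),
                                          area_um2 = runif(5))),
               "rank-deficient")
})

test_that("calibration evaluation clamps at zero and matches the polynomial", {
  expect_equal(apply_calibration(c(0, 0, pi / 4), 1), pi / 4)
  # published polynomial at d = 0.4 um
  expect_equal(apply_calibration(c(0.032, -0.09, 0.95), 0.4), 0.148,
               tolerance = 1e-12)
  expect_equal(apply_calibration(c(0.032, -0.09, 0.95), 0), 0.032)
  expect_warning(out <- apply_calibration(c(-0.01, 0, 1), 0), "clamped")
  expect_equal(out, 0)
})

test_that("log-normal histogram fit is self-consistent on exact data", {
  cc <- 300; A <- 5; w <- 0.4
  x <- seq(12.5, 1200, by = 25)
  h <- data.frame(x = x, y = A * exp(-log(x / cc)^2 / (2 * w^2)))
  fit <- fit_lognormal_histogram(histogram = h)
  expect_equal(fit$center, cc, tolerance = 1e-6)
  expect_equal(fit$amplitude, A, tolerance = 1e-6)
  expect_equal(fit$width, w, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_lognormal_histogram(histogram = data.frame(
    x = x, y = 0)), "empty")
  expect_error(fit_lognormal_histogram(numeric(0)), "no positive")
})

test_that("log-normal fit on samples recovers peak center and median", {
  # Linear 25-nm binning of log-normal draws peaks at m*exp(-s^2), not at
  # the log-median m (the 1/x Jacobian); the median field undoes the shift.
  set.seed(287)
  m <- 287.5; s <- 0.33
  d <- rlnorm(1e5, log(m), s)
  fit <- fit_lognormal_histogram(d, bin_width = 25)
  expect_equal(fit$center, m * exp(-s^2), tolerance = 0.02)
  expect_equal(fit$median, m, tolerance = 0.02)
  expect_equal(fit$width, s, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.98)
})

test_that("perforation counting matches the Euler-characteristic oracle", {
  expect_equal(count_perforations(mesh_disc(0.2, 0.2, n = 24)), 0)
  expect_equal(count_perforations(mesh_patch(n = 8,
                                             holes = list(c(4, 4)))), 1)

  # k well-separated punctures on a grid patch, vs independent chi count
  set.seed(9)
  slots <- expand.grid(i = c(3, 5, 7, 9), j = c(3, 5, 7, 9))
  for (k in 1:4) {
    pick <- slots[sample(nrow(slots), k), ]
    holes <- lapply(seq_len(k), function(r) c(pick$i[r], pick$j[r]))
    m <- mesh_patch(n = 11, holes = holes)
    expect_equal(count_perforations(m), k)
    expect_equal(count_perforations(m), oracle_euler_holes(m))
  }

  # horse-shoe: a deep boundary notch is NOT a perforation
  notch <- mesh_patch(n = 8, holes = list(c(1, 4), c(2, 4), c(3, 4),
                                          c(4, 4), c(5, 4)))
  expect_equal(count_perforations(notch), 0)
  expect_equal(oracle_euler_holes(notch), 0)

  # non-manifold edge (three faces sharing an edge) is rejected
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(count_perforations(trimesh(v, f)), "non-manifold")
})

test_that("programmed perforation fraction is recovered from contacts", {
  cfg <- neuropil_config(perforation_prob = 0.15, contact_density = 1.5,
                         n_vesicle_boutons = 0, mito_count = 5)
  sv <- simulate_subvolume(cfg, seed = 33, with_vesicles = FALSE)
  asym <- Filter(function(ct) ct$syn_class == "asymmetric", sv$sub$contacts)
  n_holes <- vapply(asym, function(ct) count_perforations(ct$mesh),
                    numeric(1))
  frac <- mean(n_holes >= 1)
  expect_equal(frac, sv$ground_truth$perforated_fraction, tolerance = 1e-12)
  se <- sqrt(0.15 * 0.85 / length(asym))
  expect_lt(abs(frac - 0.15), 3 * se)
})
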