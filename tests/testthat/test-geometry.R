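test_that("surface area matches closed forms and the Heron oracle", {
  expect_equal(surface_area(mesh_cube()), 6)
  tri <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)

  ico <- mesh_icosphere(1, subdiv = 3)
  expect_equal(surface_area(ico), oracle_area_heron(ico), tolerance = 1e-9)

  # refinement approaches 4*pi*r^2 from below
  areas <- vapply(0:3, function(k) surface_area(mesh_icosphere(1, k)),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < 4 * pi))
  expect_lt(abs(areas[4] - 4 * pi) / (4 * pi), 0.01)

  expect_error(surface_area(trimesh(matrix(0, 1, 3),
                                    matrix(integer(0), 0, 3))),
               "no faces")
})

test_that("enclosed volume: cube, translation invariance, sphere convergence", {
  expect_equal(enclosed_volume(mesh_cube()), 1)
  expect_equal(enclosed_volume(mesh_translate(mesh_cube(), c(100, 100, 100))),
               1, tolerance = 1e-12)

  vols <- vapply(0:3, function(k) enclosed_volume(mesh_icosphere(0.5, k)),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < pi / 6))
  expect_lt(abs(vols[4] - pi / 6) / (pi / 6), 0.01)

  # independent convex-containment grid oracle
  ico <- mesh_icosphere(0.5, 2)
  expect_equal(enclosed_volume(ico), oracle_convex_volume(ico, 70),
               tolerance = 0.01)

  # open mesh errors with the boundary-edge count
  disc <- mesh_disc(0.5, 0.5, n = 12)
  expect_error(enclosed_volume(disc), "12 boundary edges")
})

test_that("area and volume are invariant under rigid motion", {
  set.seed(7)
  m <- mesh_icosphere(0.7, 2)
  ang <- runif(3, 0, 2 * pi)
  R <- rotation_about("x", ang[1]) %*% rotation_about("y", ang[2]) %*%
    rotation_about("z", ang[3])
  m2 <- mesh_translate(mesh_rotate(m, R), c(3.2, -1.5, 8))
  expect_equal(surface_area(m2), surface_area(m), tolerance = 1e-9)
  expect_equal(enclosed_volume(m2), enclosed_volume(m), tolerance = 1e-9)
})

test_that("polyline length: closed forms, brute-force oracle, errors", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(polyline_length(square), 4)

  set.seed(42)
  walk <- matrix(cumsum(rnorm(300)), ncol = 3)
  brute <- sum(vapply(seq_len(nrow(walk) - 1), function(i) {
    sqrt(sum((walk[i + 1, ] - walk[i, ])^2))
  }, numeric(1)))
  expect_equal(polyline_length(walk), brute, tolerance = 1e-12)

  expect_error(polyline_length(matrix(0, 1, 3)), "at least 2")
  expect_error(polyline_length(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
})

test_that("nearest surface distance agrees with the projection oracle", {
  ico <- mesh_icosphere(1, 2)
  # a mesh vertex has distance zero
  expect_equal(nearest_surface_distance(ico$vertices[5, ], ico), 0)
  # the center of the sphere sees the polyhedron inradius, just under r
  d_ctr <- nearest_surface_distance(c(0, 0, 0), ico)
  expect_lt(d_ctr, 1)
  expect_gt(d_ctr, 0.98)

  set.seed(11)
  pts <- matrix(runif(3 * 300, -2, 2), ncol = 3)
  got <- nearest_surface_distance(pts, ico)
  want <- vapply(seq_len(nrow(pts)), function(i) {
    oracle_point_mesh_dist(pts[i, ], ico)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("section caliper: flat disc, cube diagonal, tilted disc sweep", {
  d <- mesh_disc(0.19, 0.19, n = 48)            # in-plane, diameter 0.38
  expect_equal(max_section_diameter(d), 0.38, tolerance = 1e-12)

  expect_equal(max_section_diameter(mesh_cube()), sqrt(2), tolerance = 1e-12)

  tilt <- pi / 4
  td <- mesh_disc(0.2, 0.2, n = 96, rotation = rotation_about("x", tilt))
  want <- oracle_tilted_disc_caliper(0.2, 0.2, tilt)
  got <- max_section_diameter(td, pitch = 0.001)
  expect_equal(got, want, tolerance = 0.01)

  expect_error(max_section_diameter(mesh_cube(), axis = c(0, 0, 2)),
               "unit length")
})

test_that("completeness matches the exhaustive oracle on random spheres", {
  box <- box3(c(0, 0, 0), c(5, 5, 5))
  expect_equal(completeness(mesh_icosphere(0.5, 1, center = c(2.5, 2.5, 2.5)),
                            box), "complete")
  # sphere centered on a box face straddles it
  expect_equal(completeness(mesh_icosphere(0.5, 1, center = c(0, 2.5, 2.5)),
                            box), "incomplete")

  set.seed(3)
  for (i in 1:60) {
    m <- mesh_icosphere(runif(1, 0.2, 1.5), 1, center = runif(3, -1, 6))
    expect_identical(completeness(m, box), oracle_complete(m, box))
  }
})

test_that("OBJ round-trip preserves geometry, ids, and fan-triangulates", {
  tmp <- tempfile(fileext = ".obj")
  meshes <- list(mesh_icosphere(0.3, 1, center = c(1, 2, 3), id = "bouton_7"),
                 mesh_disc(0.2, 0.1, n = 16, id = "contact_7"))
  write_obj(meshes, tmp)
  back <- read_obj(tmp)
  expect_length(back, 2)
  expect_identical(vapply(back, `[[`, character(1), "id"),
                   c("bouton_7", "contact_7"))
  expect_equal(surface_area(back[[1]]), surface_area(meshes[[1]]),
               tolerance = 1e-6)
  expect_equal(enclosed_volume(back[[1]]), enclosed_volume(meshes[[1]]),
               tolerance = 1e-6)
  expect_equal(nrow(back[[2]]$faces), nrow(meshes[[2]]$faces))

  # quad faces (and v//vn forms) are fan-triangulated on read
  quad <- tempfile(fileext = ".obj")
  writeLines(c("o square", "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1//1 2//1 3//1 4//1"), quad)
  sq <- read_obj(quad)[[1]]
  expect_equal(nrow(sq$faces), 2)
  expect_equal(surface_area(sq), 1)
})

test_that("mesh construction cleans duplicates and degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0) + 1e-9)
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 1, 2))
  m <- trimesh(v, f)
  cl <- attr(m, "cleaned")
  expect_equal(unname(cl["merged_vertices"]), 1)
  # the duplicate-vertex face collapses onto the first and the repeated-index
  # face is dropped
  expect_equal(nrow(m$vertices), 3)
  expect_error(trimesh(rbind(c(0, 0, Inf)), matrix(integer(0), 0, 3)),
               "finite")
  expect_error(trimesh(rbind(c(0, 0, 0)), rbind(c(1, 2, 3))), "out of range")
})
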