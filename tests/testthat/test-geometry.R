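# Structure sets, phantom and prostate generators, margins, BEV.

test_that("polygon area and even-odd ring area match closed forms", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(polygon_area(sq), 4)
  expect_equal(polygon_area(sq[4:1, ]), -4)
  ann <- list(circle_poly(0, 0, 10, n = 720), circle_poly(0, 0, 5, n = 720))
  expect_equal(rings_area(ann), pi * 75, tolerance = 1e-3)
})

test_that("structure set validation names the violated invariant", {
  good <- tibble::tibble(structure = "PTV", z = 0,
                         poly = list(circle_poly(0, 0, 10)))
  expect_silent(structure_set(good, 2.5, 1))
  expect_error(structure_set(dplyr::mutate(good, poly = list(rbind(c(0, 0), c(1, 0)))),
                             2.5, 1), "fewer than 3")
  bow <- rbind(c(0, 0), c(3, 3), c(3, 0), c(0, 2))
  expect_error(structure_set(tibble::tibble(structure = "PTV", z = 0,
                                            poly = list(bow)), 2.5, 1),
               "self-intersecting")
  off_grid <- dplyr::bind_rows(good, dplyr::mutate(good, z = 1.3))
  expect_error(structure_set(off_grid, 2.5, 1), "common grid")
})

test_that("structure set JSON round-trip is byte-identical", {
  ph <- generate_quasimodo(phantom_spec(n_slices = 2), 0.05)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_structure_set(ph$ct1, f1)
  ss2 <- read_structure_set(f1)
  write_structure_set(ss2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(structure_volumes(ss2), structure_volumes(ph$ct1))
})

test_that("paired phantom geometries: identity, delta-rho and gap constancy", {
  spec <- phantom_spec(n_slices = 2)
  same <- generate_quasimodo(spec, 0)
  expect_identical(same$ct1, same$ct2)

  ph <- generate_quasimodo(spec, 0.05)
  g1 <- measure_normalized_geometry(ph$ct1, 0, 0, target = "PTV")
  g2 <- measure_normalized_geometry(ph$ct2, 0, 0, target = "PTV")
  expect_equal(g1$rho_oar - g2$rho_oar, 0.05, tolerance = 1e-3)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-3)

  # target extends inwards: CT2 ring area exceeds CT1 on every slice
  a1 <- structure_areas(ph$ct1); a2 <- structure_areas(ph$ct2)
  p1 <- a1$area_mm2[a1$structure == "PTV"]
  p2 <- a2$area_mm2[a2$structure == "PTV"]
  expect_true(all(p2 > p1))

  expect_error(generate_quasimodo(spec, 0.9), "delta_rho")
  expect_error(phantom_spec(r_oar = 60, gap = 10, r_ptv = 60), "smaller")
})

test_that("synthetic prostate cases are reproducible and hit the shrink regimes", {
  a <- generate_prostate_case(7, prostate_deformation(), n_slices = 16)
  expect_identical(a$ct1, a$ct2)   # zero deformation is the identity
  b <- prostate_large_pair()
  b2 <- generate_prostate_case(7, large_deformation(), n_slices = 16)
  expect_identical(b$ct1, b2$ct1)  # same seed, bit-identical
  expect_identical(b$ct2, b2$ct2)
  shrink <- b$volumes$ratio[b$volumes$structure == "Boost"]
  expect_equal(shrink, 0.75, tolerance = 0.02)
  # margins respected: Boost never overlaps the rectum
  for (z in unique(b$ct2$z)) {
    br <- adapt2step:::slice_rings(b$ct2, "Boost", z)
    rr <- adapt2step:::slice_rings(b$ct2, "OAR", z)
    if (length(br) == 0 || length(rr) == 0) next
    pts <- do.call(rbind, lapply(rr, adapt2step:::densify_ring, step = 1))
    expect_false(any(points_in_rings(br, pts)))
  }
})

test_that("margin expansion dilates, respects forbidden structures, is monotone", {
  rows <- tibble::tibble(structure = c("CTV", "OAR"), z = 0,
                         poly = list(circle_poly(0, 0, 20, n = 120),
                                     circle_poly(0, -32, 8, n = 90)))
  ss <- structure_set(rows, 2.5, 1)

  ss0 <- expand_margin(ss, "CTV", 0, new_name = "same")
  expect_equal(adapt2step:::slice_rings(ss0, "same", 0),
               adapt2step:::slice_rings(ss0, "CTV", 0))

  ss1 <- expand_margin(ss, "CTV", 10, new_name = "PTV")
  a <- structure_areas(ss1)
  r_eff <- sqrt(a$area_mm2[a$structure == "PTV"] / pi)
  expect_equal(r_eff, 30, tolerance = 1 / 30)  # within in-plane resolution

  # anisotropic: posterior reach limited to 7 mm
  ss2 <- expand_margin(ss, "CTV", 10, posterior_mm = 7, new_name = "PTV")
  p <- do.call(rbind, adapt2step:::slice_rings(ss2, "PTV", 0))
  expect_lt(min(p[, 2]), -25.5)
  expect_gt(min(p[, 2]), -28.5)   # ~ -27, not -30
  expect_equal(max(p[, 2]), 30, tolerance = 1.5)

  # forbidden: expanded structure never enters the OAR
  ss3 <- expand_margin(ss, "CTV", 5, forbidden = "OAR", new_name = "Boost")
  rings_b <- adapt2step:::slice_rings(ss3, "Boost", 0)
  oar_pts <- adapt2step:::densify_ring(circle_poly(0, -32, 7.5, n = 90), 0.5)
  expect_false(any(points_in_rings(rings_b, oar_pts)))

  # monotone: larger margins never shrink the per-slice area
  areas <- vapply(c(2, 5, 8, 10), function(m) {
    sse <- expand_margin(ss, "CTV", m, new_name = "X")
    a <- structure_areas(sse); a$area_mm2[a$structure == "X"]
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("BEV projection follows the angle convention and splits disjoint structures", {
  rows <- tibble::tibble(
    structure = c("A", "B", "B"), z = 0,
    poly = list(circle_poly(15, 0, 5, n = 90),
                circle_poly(-30, 0, 5, n = 90), circle_poly(30, 0, 5, n = 90)))
  ss <- structure_set(rows, 2.5, 1)
  bev0 <- project_to_bev(ss, 0)
  a0 <- bev0[bev0$structure == "A", ]
  expect_equal((a0$x_lo + a0$x_hi) / 2, 15, tolerance = 1e-2)
  # at 90 deg the offset circle centred on +x projects to centre 0
  bev90 <- project_to_bev(ss, 90)
  a90 <- bev90[bev90$structure == "A", ]
  expect_equal((a90$x_lo + a90$x_hi) / 2, 0, tolerance = 1e-2)
  # at 180 deg it flips sign
  b180 <- project_to_bev(ss, 180)
  a180 <- b180[b180$structure == "A", ]
  expect_equal((a180$x_lo + a180$x_hi) / 2, -15, tolerance = 1e-2)
  # disjoint structures give two sorted, disjoint intervals
  b <- bev0[bev0$structure == "B", ]
  expect_equal(nrow(b), 2)
  expect_lt(b$x_hi[1], b$x_lo[2])
  # a centred circle projects to [-r, r] at any angle
  ph <- concentric_set(n_slices = 2)
  for (ang in c(0, 37, 122)) {
    bv <- project_to_bev(ph, ang)
    o <- bv[bv$structure == "OAR", ]
    expect_equal(o$x_lo, rep(-18, nrow(o)), tolerance = 0.02)
    expect_equal(o$x_hi, rep(18, nrow(o)), tolerance = 0.02)
  }
})

test_that("normalized geometry: concentric values, rotational symmetry, scale invariance", {
  ss <- concentric_set(r_ptv = 100, rho_oar = 0.3, gamma = 0.1, n = 720)
  for (ang in c(0, 45, 200)) {
    g <- measure_normalized_geometry(ss, ang, 0)
    expect_equal(g$rho_oar, 0.3, tolerance = 1e-3)
    expect_equal(g$gamma, 0.1, tolerance = 1e-3)
    expect_equal(g$r_ptv, 100, tolerance = 0.1)
  }
  # invariant under uniform scaling of all lengths
  half <- concentric_set(r_ptv = 50, rho_oar = 0.3, gamma = 0.1, n = 720)
  gh <- measure_normalized_geometry(half, 0, 0)
  expect_equal(gh$rho_oar, 0.3, tolerance = 1e-3)
  expect_equal(gh$gamma, 0.1, tolerance = 1e-3)
  # no OAR in view: rho 0, flagged
  rows <- tibble::tibble(structure = "PTV", z = 0,
                         poly = list(circle_poly(0, 0, 50)))
  ss2 <- structure_set(rows, 2.5, 1)
  g2 <- measure_normalized_geometry(ss2, 0, 0, oar = "OAR")
  expect_equal(g2$rho_oar, 0)
  expect_true(g2$flagged)
})
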