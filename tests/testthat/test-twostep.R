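# Two-step segment generation and the beta* optimum / lookup table.

test_that("S0 apertures conform to the target silhouette", {
  ss <- concentric_set(n_slices = 4)  # 10 mm of target -> pairs -1, 0, 1
  bev <- project_to_bev(ss, 0)
  s0 <- generate_s0(bev, "PTV")
  lv <- s0$leaves[[1]]
  expect_setequal(lv[, "pair"], sort(unique(bev$pair[bev$structure == "PTV"])))
  expect_equal(unname(lv[, "lo"]), rep(-60, nrow(lv)), tolerance = 0.05)
  expect_equal(unname(lv[, "hi"]), rep(60, nrow(lv)), tolerance = 0.05)
  # chord oracle on an off-axis sphere-like target: per-pair half-width
  zs <- c(-3.75, -1.25, 1.25, 3.75)
  rows <- purrr::map_dfr(zs, function(z) tibble::tibble(
    structure = "PTV", z = z,
    poly = list(circle_poly(0, 0, sqrt(20^2 - z^2), n = 240))))
  sph <- structure_set(rows, 2.5, 1, validate = FALSE)
  s0s <- generate_s0(project_to_bev(sph, 0), "PTV")
  lvs <- s0s$leaves[[1]]
  for (k in seq_len(nrow(lvs))) {
    zr <- adapt2step:::pair_z_range(lvs[k, "pair"], 0, 4)
    covered <- zs[zs >= zr[1] & zs < zr[2]]
    expect_equal(unname(lvs[k, "hi"]),
                 max(sqrt(20^2 - covered^2)), tolerance = 0.05)
  }
  expect_error(generate_s0(bev, "nope"), "empty target")
})

test_that("S1 subtracts the OAR shadow into one-sided segments", {
  ss <- concentric_set(n_slices = 2)
  bev <- project_to_bev(ss, 0)
  s1 <- generate_s1(bev, "PTV", "OAR")
  expect_equal(nrow(s1), 2)
  expect_setequal(s1$side, c("left", "right"))
  left <- s1$leaves[[which(s1$side == "left")]]
  right <- s1$leaves[[which(s1$side == "right")]]
  expect_equal(unname(left[, "lo"]), rep(-60, nrow(left)), tolerance = 0.05)
  expect_equal(unname(left[, "hi"]), rep(-18, nrow(left)), tolerance = 0.05)
  expect_equal(unname(right[, "lo"]), rep(18, nrow(right)), tolerance = 0.05)
  expect_equal(unname(right[, "hi"]), rep(60, nrow(right)), tolerance = 0.05)

  # no OAR in view: S1 equals S0 as a single segment
  rows <- tibble::tibble(structure = "PTV", z = 0,
                         poly = list(circle_poly(0, 0, 30)))
  solo <- structure_set(rows, 2.5, 1)
  bev2 <- project_to_bev(solo, 0)
  s1b <- generate_s1(bev2, "PTV", "OAR")
  expect_equal(nrow(s1b), 1)
  expect_equal(s1b$side, "both")
  expect_equal(s1b$leaves[[1]], generate_s0(bev2, "PTV")$leaves[[1]])

  # horseshoe phantom: interior shadow at every angle -> two one-sided
  # segments, verified by interval arithmetic against the projections
  ph <- generate_quasimodo(phantom_spec(n_slices = 2), 0.05)
  for (ang in c(0, 70, 240)) {
    bv <- project_to_bev(ph$ct1, ang)
    s <- generate_s1(bv, "PTV", "OAR")
    expect_equal(nrow(s), 2)
    t_iv <- adapt2step:::bev_hull(bv, "PTV", 0)
    o_iv <- adapt2step:::bev_hull(bv, "OAR", 0)
    l <- s$leaves[[which(s$side == "left")]]
    expect_equal(unname(l[l[, "pair"] == 0, c("lo", "hi")]),
                 c(t_iv[1], o_iv[1]))
  }
})

test_that("S2 strips have width beta* R_PTV, shrink with the OAR, vanish without one", {
  tab <- beta_table()
  ss <- concentric_set(rho_oar = 0.3, gamma = 0.1)
  bev <- project_to_bev(ss, 0)
  geo <- pairwise_geometry(ss, 0)
  geo$target <- "PTV"
  s2 <- generate_s2(bev, geo, tab, "PTV", "OAR")
  expect_equal(nrow(s2), 2)
  bstar <- beta_star_eval(tab, 0.1, geo$rho_oar[geo$pair == 0],
                          mode = "generation")
  lv <- s2$leaves[[which(s2$side == "left")]]
  expect_equal(unname(lv[, "hi"] - lv[, "lo"]),
               as.numeric(bstar) * geo$r_ptv[geo$pair == 0],
               tolerance = 0.02)

  ss_small <- concentric_set(rho_oar = 0.2, gamma = 0.1)
  geo_s <- pairwise_geometry(ss_small, 0); geo_s$target <- "PTV"
  s2_s <- generate_s2(project_to_bev(ss_small, 0), geo_s, tab, "PTV", "OAR")
  lv_s <- s2_s$leaves[[which(s2_s$side == "left")]]
  expect_lt(max(lv_s[, "hi"] - lv_s[, "lo"]), min(lv[, "hi"] - lv[, "lo"]))

  # rho_oar = 0 on every pair -> no strips
  geo0 <- dplyr::mutate(geo, rho_oar = 0)
  expect_null(generate_s2(bev, geo0, tab, "PTV", "OAR"))
})

test_that("joint (omega, beta) optimum matches a brute-force grid search", {
  # the worked geometry at the spec'd 1e-3 grid, plus coarser scans over a
  # spread of geometries
  b <- brute_force_f2(0.3, 0.1, 1e-3, 1e-2)
  o <- optimize_beta_omega(0.3, 0.1)
  expect_lte(o$f2_min, b[1] + 1e-9)          # continuous search beats the grid
  expect_lt((b[1] - o$f2_min) / o$f2_min, 0.01)
  expect_equal(o$omega_opt * o$beta_opt, b[2] * b[3], tolerance = 0.02)

  geoms <- list(c(0.15, 0.05), c(0.2, 0.2), c(0.4, 0.1), c(0.5, 0), c(0.6, 0.15))
  for (g in geoms) {
    b <- brute_force_f2(g[1], g[2], 2e-3, 2e-2)
    o <- optimize_beta_omega(g[1], g[2])
    expect_lte(o$f2_min, b[1] + 1e-9)
    expect_lt((b[1] - o$f2_min) / o$f2_min, 0.05)
    # the optimum genuinely compensates: f2 strictly below the no-strip value
    expect_lt(o$f2_min, o$f2_s1)
  }
})

test_that("fixed-omega optimum restores homogeneity and vanishes with the block", {
  o <- optimize_beta_omega(0.01, 0.05, fixed_omega = 1)
  expect_lt(o$f2_min, 1e-4)      # nothing to compensate
  expect_lt(o$beta_opt, 0.02)
  for (g in list(c(0.2, 0.1), c(0.4, 0.2))) {
    o <- optimize_beta_omega(g[1], g[2], fixed_omega = 1)
    expect_lt(o$f2_min, o$f2_s1) # homogeneity restored vs S1 alone
  }
})

test_that("beta* table: monotone in rho_oar, weakly gamma-dependent, consistent fit", {
  tab <- beta_table()
  for (g in unique(tab$grid$gamma)) {
    sub <- tab$grid[tab$grid$gamma == g, ]
    sub <- sub[order(sub$rho_oar), ]
    expect_true(all(diff(sub$beta_star_gen) > 0))
    expect_true(all(diff(sub$beta_star_adapt) > 0))
  }
  # weak gamma dependence: spread across gamma bounded (regression value)
  wide <- tidyr::pivot_wider(tab$grid[, c("gamma", "rho_oar", "beta_star_adapt")],
                             names_from = "gamma", values_from = "beta_star_adapt")
  m <- as.matrix(wide[, -1])
  rel_spread <- apply(m, 1, function(r) diff(range(r, na.rm = TRUE)) /
                        mean(r, na.rm = TRUE))
  expect_lt(max(rel_spread), 0.25)
  # polynomial reproduces the tabulated values within the reported residual
  worst <- max(tab$fits$max_rel_residual)
  for (g in unique(tab$grid$gamma)) {
    sub <- tab$grid[tab$grid$gamma == g, ]
    pred <- beta_star_eval(tab, g, sub$rho_oar, mode = "adapt")
    expect_lt(max(abs(pred - sub$beta_star_adapt) / sub$beta_star_adapt),
              worst + 1e-8)
  }
  # out-of-domain geometry is clamped with a warning
  expect_warning(v <- beta_star_eval(tab, 0.1, 0.9), "clamped")
  expect_equal(as.numeric(v),
               as.numeric(beta_star_eval(tab, 0.1, tab$rho_range[2])))
  # round trip through JSON
  f <- withr::local_tempfile(fileext = ".json")
  write_beta_star_table(tab, f)
  tab2 <- read_beta_star_table(f)
  expect_equal(beta_star_eval(tab2, 0.12, 0.33), beta_star_eval(tab, 0.12, 0.33))
})

test_that("two-step plan on concentric geometry restores target homogeneity", {
  # S1 + omega_opt S2 has smaller target spread than S1 alone (closed form)
  for (g in list(c(0.2, 0.1), c(0.35, 0.05), c(0.5, 0.2))) {
    o <- optimize_beta_omega(g[1], g[2])
    nodes <- adapt2step:::annulus_nodes(g[1], g[2])
    d_s1 <- radial_dose_closed_form(nodes$rho, g[1], component = "S1")
    d_12 <- radial_dose_closed_form(nodes$rho, g[1], o$beta_opt, "total",
                                    omega = o$omega_opt)
    cv <- function(d) stats::sd(d) / mean(d)
    expect_lt(cv(d_12), cv(d_s1))
  }
})
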