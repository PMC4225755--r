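# Exposure-fraction dose engine, closed-form radial dose, DVH metrics.

test_that("elementary dose fields: empty plan, open field, orthogonal apertures", {
  toy <- toy_two_segment()
  empty <- rt_plan(tibble::as_tibble(toy$plan)[0, ], beams = 0,
                   prescription = c(PTV = 60))
  d0 <- compute_dose(empty, toy$ss, resolution = 2, calibration = 1)
  expect_true(all(d0$dose == 0))

  # one fully open segment at one angle: dose = mu inside the silhouette
  segs <- tibble::tibble(angle_deg = 0, step_type = "S0", target = "PTV",
                         side = "both", mu = 1,
                         leaves = list(cbind(pair = 0, lo = -100, hi = 100)))
  open_plan <- rt_plan(segs, beams = 0, prescription = c(PTV = 60))
  d1 <- compute_dose(open_plan, toy$ss, resolution = 2, calibration = 1)
  expect_true(all(d1$dose %in% c(0, 1)))
  expect_true(all(d1$dose == 1))   # field covers the whole body slab

  # orthogonal rectangles: brute-force voxel indicator oracle
  segs2 <- dplyr::bind_rows(
    tibble::tibble(angle_deg = 0, step_type = "S0", target = "PTV",
                   side = "both", mu = 1,
                   leaves = list(cbind(pair = 0, lo = -10, hi = 10))),
    tibble::tibble(angle_deg = 90, step_type = "S0", target = "PTV",
                   side = "both", mu = 1,
                   leaves = list(cbind(pair = 0, lo = -5, hi = 15))))
  plan2 <- rt_plan(segs2, beams = c(0, 90), prescription = c(PTV = 60))
  d2 <- compute_dose(plan2, toy$ss, resolution = 2, calibration = 1)
  g <- expand.grid(x = d2$x, y = d2$y)
  oracle <- (abs(g$x) < 10) + (g$y > -5 & g$y < 15)
  expect_equal(as.vector(d2$dose[, , 1]), oracle)

  # unknown angle is rejected by name
  bad <- rt_plan(dplyr::mutate(tibble::as_tibble(segs2), angle_deg = c(0, 45)),
                 beams = c(0, 90), prescription = c(PTV = 60))
  expect_error(compute_dose(bad, toy$ss), "45")
})

test_that("dose is linear in segments and scales with MU", {
  toy <- toy_two_segment()
  plan <- toy$plan
  pa <- rt_plan(tibble::as_tibble(plan)[1, ], 0, c(PTV = 60))
  pb <- rt_plan(tibble::as_tibble(plan)[2, ], 0, c(PTV = 60))
  dab <- compute_dose(plan, toy$ss, 2, calibration = 1)
  da <- compute_dose(pa, toy$ss, 2, calibration = 1)
  db <- compute_dose(pb, toy$ss, 2, calibration = 1)
  expect_equal(dab$dose, da$dose + db$dose)

  scaled <- rt_plan(dplyr::mutate(tibble::as_tibble(plan), mu = mu * 3),
                    0, c(PTV = 60))
  ds <- compute_dose(scaled, toy$ss, 2, calibration = 1)
  expect_equal(ds$dose, 3 * dab$dose)
})

test_that("closed-form radial dose: limits and special points", {
  rho <- seq(0.05, 1, by = 0.05)
  expect_equal(radial_dose_closed_form(rho, 0), rep(1, length(rho)))
  expect_equal(radial_dose_closed_form(0.3, 0.3), 0)   # block edge: arcsin(1)
  expect_equal(radial_dose_closed_form(0, 0.3), 0)     # fully shadowed centre
  s2_strip <- radial_dose_closed_form(0.35, 0.3, beta = 0.1, component = "S2")
  s2_out <- radial_dose_closed_form(c(0.6, 0.9), 0.3, beta = 0.1, component = "S2")
  expect_true(all(s2_strip > s2_out))     # strip dose peaks inside the strip
  expect_equal(radial_dose_closed_form(0.3, 0.3, beta = 0.1, component = "S2"),
               0)                          # on the block edge itself
  expect_equal(radial_dose_closed_form(0.8, 0.3, 0.1, "total", omega = 2),
               radial_dose_closed_form(0.8, 0.3, component = "S1") +
                 2 * radial_dose_closed_form(0.8, 0.3, 0.1, "S2"))
})

test_that("discrete engine converges to the closed form with beam count", {
  ss <- concentric_set()
  rms_of <- function(n_ang) {
    d <- compute_dose(ring_plan(n_ang, beta = 0.2), ss, resolution = 1,
                      calibration = 1)
    g <- expand.grid(x = d$x, y = d$y)
    r <- sqrt(g$x^2 + g$y^2) / 60
    sel <- r >= 0.4 & r <= 1
    pred <- radial_dose_closed_form(r[sel], 0.3, 0.2, "total")
    err <- as.vector(d$dose[, , 1])[sel] - pred
    sqrt(mean(err^2)) / mean(pred)
  }
  r36 <- rms_of(36); r120 <- rms_of(120)
  expect_lt(r120, r36 / 2)      # refinement towards the continuum
  expect_lt(r120, 0.03)
})

test_that("DVH metrics: uniform and two-level dose, ordering, isodose threshold", {
  toy <- toy_two_segment()
  # uniform field
  du <- compute_dose(rt_plan(tibble::tibble(
    angle_deg = 0, step_type = "S0", target = "PTV", side = "both", mu = 1,
    leaves = list(cbind(pair = 0, lo = -100, hi = 100))), 0, c(PTV = 60)),
    toy$ss, 2, calibration = 80)
  dvh <- compute_dvh(du, toy$ss, "PTV")
  m <- dvh_metrics(dvh, "PTV", d_pct = c(99, 50, 1), v_pct = 95,
                   reference_dose = 76.2)
  expect_equal(m$value[m$metric == "D_99%"], 80)
  expect_equal(m$value[m$metric == "D_1%"], 80)
  expect_equal(m$value[m$metric == "D_mean"], 80)
  v <- structure_volumes(toy$ss)
  expect_equal(m$value[m$metric == "V_95%"],
               v$volume_cm3[v$structure == "PTV"], tolerance = 0.05)
  # threshold arithmetic: the 95% isodose of 76.2 Gy is 72.39 Gy, so a
  # uniform 72 Gy field contributes nothing
  du2 <- compute_dose(rt_plan(tibble::tibble(
    angle_deg = 0, step_type = "S0", target = "PTV", side = "both", mu = 1,
    leaves = list(cbind(pair = 0, lo = -100, hi = 100))), 0, c(PTV = 60)),
    toy$ss, 2, calibration = 72)
  m2 <- dvh_metrics(compute_dvh(du2, toy$ss, "PTV"), "PTV", v_pct = 95,
                    reference_dose = 76.2)
  expect_equal(m2$value[m2$metric == "V_95%"], 0)

  # two-level dose: half the target at 80, half at 60 (left/right fields)
  segs <- dplyr::bind_rows(
    tibble::tibble(angle_deg = 0, step_type = "S0", target = "PTV",
                   side = "both", mu = 60, leaves = list(cbind(pair = 0, lo = -100, hi = 100))),
    tibble::tibble(angle_deg = 0, step_type = "S0", target = "PTV",
                   side = "left", mu = 20, leaves = list(cbind(pair = 0, lo = -100, hi = 0.5))))
  d2 <- compute_dose(rt_plan(segs, 0, c(PTV = 60)), toy$ss, 2, calibration = 1)
  dvh2 <- compute_dvh(d2, toy$ss, "PTV")
  # enumeration oracle on the voxel doses
  vox <- attr(dvh2, "voxel_doses")$PTV
  expect_setequal(unique(vox), c(60, 80))
  m3 <- dvh_metrics(dvh2, "PTV", d_pct = c(99, 50, 1))
  expect_equal(m3$value[m3$metric == "D_99%"], 60)
  expect_equal(m3$value[m3$metric == "D_1%"], 80)
  expect_equal(m3$value[m3$metric == "D_50%"],
               unname(stats::quantile(vox, 0.5, type = 7)))
  # monotone curve and metric ordering on any grid
  cur <- dvh2[dvh2$structure == "PTV", ]
  expect_true(all(diff(cur$volume_fraction) <= 0))
  mm <- dvh_metrics(dvh2, "PTV", d_pct = c(99, 95, 1))
  vals <- stats::setNames(mm$value, mm$metric)
  expect_true(vals[["D_99%"]] <= vals[["D_95%"]])
  expect_true(vals[["D_95%"]] <= vals[["D_mean"]])
  expect_true(vals[["D_mean"]] <= vals[["D_1%"]])
  expect_error(dvh_metrics(dvh2, "PTV", d_pct = 101), "100")
})

test_that("plan JSON round-trip is byte-identical and preserves the segment table", {
  toy <- toy_two_segment()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_plan(toy$plan, f1)
  p2 <- read_plan(f1)
  write_plan(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(total_mu(p2), total_mu(toy$plan))
  expect_equal(p2$leaves, toy$plan$leaves)
})
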