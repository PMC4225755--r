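# Shared fixtures. Heavy objects (the beta* table, the full phantom
# planning + adaptation run) are memoized so the suite pays for them once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

beta_table <- function() fixture("beta_table", function() build_beta_star_table())

# concentric-circle structure set: ring target (annulus via even-odd rings)
# around a central OAR cylinder, the geometry of the closed-form model
concentric_set <- function(r_ptv = 60, rho_oar = 0.3, gamma = 0.1,
                           n_slices = 1, slice_thickness = 2.5, n = 240) {
  r_oar <- rho_oar * r_ptv
  r_in <- r_oar + gamma * r_ptv
  zs <- (seq_len(n_slices) - (n_slices + 1) / 2) * slice_thickness
  rows <- purrr::map_dfr(zs, function(z) tibble::tibble(
    structure = c("PTV", "PTV", "OAR"), z = z,
    poly = list(circle_poly(0, 0, r_ptv, n = n),
                circle_poly(0, 0, r_in, n = n),
                circle_poly(0, 0, r_oar, n = n))))
  structure_set(rows, slice_thickness, 1, validate = FALSE)
}

# hand-built rotational plan on the concentric set: S1 one-sided apertures,
# optionally with S2 strips of normalized width beta at weight omega
ring_plan <- function(n_ang, r_ptv = 60, rho_oar = 0.3, beta = NULL,
                      omega = 1, pairs = 0) {
  r_oar <- rho_oar * r_ptv
  angs <- seq(0, 360 - 360 / n_ang, by = 360 / n_ang)
  segs <- purrr::map_dfr(angs, function(a) dplyr::bind_rows(
    tibble::tibble(angle_deg = a, step_type = "S1", target = "PTV",
                   side = "left", mu = 1 / n_ang,
                   leaves = list(cbind(pair = pairs, lo = -r_ptv, hi = -r_oar))),
    tibble::tibble(angle_deg = a, step_type = "S1", target = "PTV",
                   side = "right", mu = 1 / n_ang,
                   leaves = list(cbind(pair = pairs, lo = r_oar, hi = r_ptv))),
    if (!is.null(beta)) dplyr::bind_rows(
      tibble::tibble(angle_deg = a, step_type = "S2", target = "PTV",
                     side = "left", mu = omega / n_ang,
                     leaves = list(cbind(pair = pairs,
                                         lo = -(r_oar + beta * r_ptv), hi = -r_oar))),
      tibble::tibble(angle_deg = a, step_type = "S2", target = "PTV",
                     side = "right", mu = omega / n_ang,
                     leaves = list(cbind(pair = pairs, lo = r_oar,
                                         hi = r_oar + beta * r_ptv))))))
  rt_plan(segs, beams = angs, prescription = c(PTV = 1))
}

# full planning + adaptation run on the horseshoe phantom pair (36 beams)
phantom_fixture <- function() fixture("phantom_pipeline", function() {
  ph <- generate_quasimodo(phantom_spec(), 0.05)
  cfg <- run_config(prescriptions = c(PTV = 74),
                    beams = seq(0, 350, by = 10),
                    optimizer = list(iterations = 10, step_mm = 2,
                                     leaf_sweeps = 1))
  native <- plan_native(ph$ct1, beta_table(), cfg)
  res <- adapt_plan(native, ph$ct2)
  list(ph = ph, cfg = cfg, native = native, res = res)
})

# small phantom config for cheap unit runs (12 beams)
small_phantom_cfg <- function() {
  run_config(prescriptions = c(PTV = 74), beams = seq(0, 330, by = 30),
             optimizer = list(iterations = 5, step_mm = 2, leaf_sweeps = 1))
}

# deterministic two-segment toy: one slice, two abutting rectangular fields
toy_two_segment <- function() {
  rows <- tibble::tibble(
    structure = c("body", "PTV"), z = 0,
    poly = list(ellipse_poly(0, 0, 60, 40, n = 60),
                rbind(c(-30, -20), c(30, -20), c(30, 20), c(-30, 20))))
  ss <- structure_set(rows, 2.5, 1, validate = FALSE)
  segs <- dplyr::bind_rows(
    tibble::tibble(angle_deg = 0, step_type = "S0", target = "PTV",
                   side = "left", mu = 1,
                   leaves = list(cbind(pair = 0, lo = -30, hi = 0))),
    tibble::tibble(angle_deg = 0, step_type = "S0", target = "PTV",
                   side = "right", mu = 1,
                   leaves = list(cbind(pair = 0, lo = 0, hi = 30))))
  plan <- rt_plan(segs, beams = 0, prescription = c(PTV = 60))
  list(ss = ss, plan = plan)
}

# brute-force grid search oracle for the (omega, beta) optimum; independent
# of the optimizer's quadratic-moment shortcut
brute_force_f2 <- function(rho, gam, d_beta, d_omega) {
  nodes <- adapt2step:::annulus_nodes(rho, gam)
  s1 <- radial_dose_closed_form(nodes$rho, rho, component = "S1")
  oms <- seq(0.2, 3, by = d_omega)
  best <- c(Inf, NA, NA)
  for (b in seq(0.005, min(0.3, 1 - rho), by = d_beta)) {
    s2 <- radial_dose_closed_form(nodes$rho, rho, b, component = "S2")
    dev <- outer(s1 - 1, rep(1, length(oms))) + outer(s2, oms)
    f2 <- colSums(nodes$w * dev^2)
    i <- which.min(f2)
    if (f2[i] < best[1]) best <- c(f2[i], oms[i], b)
  }
  best  # c(f2_min, omega, beta)
}

prostate_pair <- function() fixture("prostate_pair", function()
  generate_prostate_case(11, small_deformation(), n_slices = 16))

prostate_large_pair <- function() fixture("prostate_large", function()
  generate_prostate_case(7, large_deformation(), n_slices = 16))

prostate_adapt_fixture <- function() fixture("prostate_adapt", function() {
  pc <- prostate_pair()
  cfg <- run_config(beams = seq(0, 315, by = 45),
                    optimizer = list(iterations = 3, step_mm = 2,
                                     leaf_sweeps = 1),
                    dose_resolution = 4)
  native <- suppressWarnings(plan_native(pc$ct1, beta_table(), cfg))
  res <- suppressWarnings(adapt_plan(native, pc$ct2))
  list(pc = pc, cfg = cfg, native = native, res = res)
})

phantom_fixed_point <- function() fixture("phantom_fixed_point", function() {
  fx <- phantom_fixture()
  adapt_plan(fx$native, fx$ph$ct1)
})
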