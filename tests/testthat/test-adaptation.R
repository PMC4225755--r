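# Isocenter relocation, MU transfer, width adaptation, fine-tune imitation
# and the assembled three-step protocol.

test_that("isocenter relocation: zero for identical sets, equivariant to translation", {
  ph <- generate_quasimodo(phantom_spec(n_slices = 4), 0.05)
  expect_equal(relocate_isocenter(ph$ct1, ph$ct1, targets = "PTV"), c(0, 0, 0))
  # for the paired phantom geometries the necessary shift is zero too
  expect_equal(relocate_isocenter(ph$ct1, ph$ct2, targets = "PTV"), c(0, 0, 0))

  t <- c(4, -6, 2.5)
  moved <- translate_structure_set(ph$ct1, t)
  got <- relocate_isocenter(ph$ct1, moved, targets = "PTV")
  expect_equal(got, t, tolerance = 1e-9)

  # exhaustive-search oracle on a deformed pair: the returned shift is at
  # least as good as every probed alternative
  pc <- prostate_pair()
  s <- relocate_isocenter(pc$ct1, pc$ct2)
  grid <- list(x = seq(-45, 45, by = 2), y = seq(-55, 35, by = 2),
               z = sort(unique(pc$ct1$z)))
  ov_of <- function(shift) {
    m1 <- structure_mask(translate_structure_set(pc$ct1, shift), "PTV", grid) |
      structure_mask(translate_structure_set(pc$ct1, shift), "Boost", grid)
    m2 <- structure_mask(pc$ct2, "PTV", grid) |
      structure_mask(pc$ct2, "Boost", grid)
    sum(m1 & m2)
  }
  best <- ov_of(s)
  for (probe in list(c(0, 0, 0), s + c(2, 0, 0), s + c(0, -2, 0),
                     s + c(0, 0, 2.5), s + c(-2, 2, 0)))
    expect_gte(best, ov_of(probe))
})

test_that("pair mapping between target extents preserves fractional position", {
  expect_equal(adapt2step:::map_pair(3, c(0, 10), c(0, 10)), 3L)   # identity
  # extent scaled x1.5: fraction 0.4 maps to fraction 0.4
  expect_equal(adapt2step:::map_pair(4, c(0, 10), c(0, 15)), 6L)
  expect_equal(adapt2step:::map_pair(-2, c(-4, 4), c(-6, 6)), -3L)
  expect_equal(adapt2step:::map_pair(5, c(5, 5), c(2, 9)), 2L)     # degenerate
})

test_that("MU transfer regenerates matching segments and copies MUs by key", {
  fx <- phantom_fixture()
  regen <- regenerate_with_mu_transfer(fx$native, fx$ph$ct2, shift = c(0, 0, 0))
  expect_equal(total_mu(regen), total_mu(fx$native$plan))
  k1 <- adapt2step:::segment_keys(fx$native$plan)
  k2 <- adapt2step:::segment_keys(regen)
  expect_setequal(k1, k2)
  expect_equal(regen$mu, fx$native$plan$mu[match(k2, k1)])  # ledger audit
  # identical geometry regenerates the pre-fine-tune apertures exactly
  same <- regenerate_with_mu_transfer(fx$native, fx$ph$ct1, shift = c(0, 0, 0))
  expect_equal(same$leaves, fx$native$pre$leaves)
  # a mutilated plan (missing key) fails loudly
  broken <- fx$native
  broken$plan <- rt_plan(tibble::as_tibble(fx$native$plan)[-1, ],
                         attr(fx$native$plan, "beams"),
                         attr(fx$native$plan, "prescription"))
  expect_error(regenerate_with_mu_transfer(broken, fx$ph$ct2, c(0, 0, 0)),
               "do not match")
})

test_that("S2 width adaptation follows the beta* ratio and leaves MUs alone", {
  fx <- phantom_fixture()
  tab <- beta_table()
  geo1 <- adaptation_geometry(fx$ph$ct1, fx$cfg)
  geo2 <- adaptation_geometry(fx$ph$ct2, fx$cfg)
  plan <- fx$native$pre

  # identical geometry: widths unchanged
  same <- adapt_s2_widths(plan, geo1, geo1, tab)
  expect_equal(same$leaves, plan$leaves)
  expect_equal(same$mu, plan$mu)

  adapted <- adapt_s2_widths(plan, geo1, geo2, tab)
  expect_equal(adapted$mu, plan$mu)
  i_s2 <- which(plan$step_type == "S2")
  ratio_want <- beta_star_eval(tab, geo2$gamma[geo2$pair == 0],
                               geo2$rho_oar[geo2$pair == 0], mode = "adapt") /
    beta_star_eval(tab, geo1$gamma[geo1$pair == 0],
                   geo1$rho_oar[geo1$pair == 0], mode = "adapt")
  # smaller OAR radius at equal gap: every width strictly narrower
  expect_lt(ratio_want, 1)
  for (i in i_s2) {
    w_old <- plan$leaves[[i]][, "hi"] - plan$leaves[[i]][, "lo"]
    w_new <- adapted$leaves[[i]][, "hi"] - adapted$leaves[[i]][, "lo"]
    expect_true(all(w_new < w_old))
    expect_equal(unname(w_new / w_old), rep(as.numeric(ratio_want), length(w_old)),
                 tolerance = 0.02)  # within the polynomial fit residual
  }
})

test_that("fine-tune imitation replays shifts and maps extents; zero record is identity", {
  fx <- phantom_fixture()
  plan <- fx$native$pre
  rec <- fx$native$record
  e <- attr(rec, "target_extents")
  zero_rec <- rec
  zero_rec$d_lo <- 0; zero_rec$d_hi <- 0
  zero_rec <- adapt2step:::new_shift_record(zero_rec, e)
  expect_equal(imitate_finetuning(plan, zero_rec, e)$leaves, plan$leaves)
  # identical extents: imitation equals plain replay
  expect_equal(imitate_finetuning(plan, rec, e)$leaves,
               apply_shift_record(plan, rec)$leaves)
})

test_that("adaptation of an unchanged geometry is a fixed point and conserves MU", {
  fx <- phantom_fixture()
  res_same <- phantom_fixed_point()
  expect_equal(res_same$shift, c(0, 0, 0))
  expect_equal(total_mu(res_same$adapted), total_mu(fx$native$plan))
  expect_equal(res_same$adapted$leaves, fx$native$plan$leaves, tolerance = 1e-9)
  d_a <- compute_dose(res_same$adapted, fx$ph$ct1, 2,
                      calibration = fx$native$calibration)
  d_n <- compute_dose(fx$native$plan, fx$ph$ct1, 2,
                      calibration = fx$native$calibration)
  expect_lt(max(abs(d_a$dose - d_n$dose)), 1e-6)
})

test_that("MU is conserved exactly through every step on phantom and prostate cases", {
  fx <- phantom_fixture()
  expect_true(all(fx$res$mu_ledger$total_mu == total_mu(fx$native$plan)))

  pfx <- prostate_adapt_fixture()
  native <- pfx$native; res <- pfx$res
  expect_true(all(res$mu_ledger$total_mu == total_mu(native$plan)))
  # the small regime stays inside the small-change guard (~1% MU difference)
  expect_lt(abs(res$mu_equiv - total_mu(native$plan)) / total_mu(native$plan),
            0.10)
  # relocation recovered the imposed posterior push
  expect_equal(res$shift[2], -2, tolerance = 1)
  expect_equal(res$shift[c(1, 3)], c(0, 0), tolerance = 1)
})
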