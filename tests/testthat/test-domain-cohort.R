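test_that("synthetic brain domain carries the two-tissue shear-modulus map", {
  dom <- tiny_domain(wobble = 0.05)
  G <- dom$shear_modulus[dom$brain_mask]
  expect_setequal(unique(G), c(466, 800))
  expect_true(any(dom$tissue == "white") && any(dom$tissue == "gray"))
  # one-voxel margin at every face
  n <- dom$grid$shape
  expect_false(any(dom$brain_mask[c(1, n[1]), , ]) ||
                 any(dom$brain_mask[, c(1, n[2]), ]) ||
                 any(dom$brain_mask[, , c(1, n[3])]))

  # degenerate config: no white matter -> constant gray shear modulus
  g <- dom$grid
  allgray <- build_tissue_domain(g, domain_config(
    brain_semiaxes = c(0.8, 0.8, 0.8), white_fraction = 0), seed = 1)
  expect_equal(unique(allgray$shear_modulus[allgray$brain_mask]), 466)

  # determinism: same seed gives identical domains, labels included
  d1 <- tiny_domain(seed = 7, wobble = 0.08)
  d2 <- tiny_domain(seed = 7, wobble = 0.08)
  expect_identical(d1$tissue, d2$tissue)
  expect_identical(d1$brain_mask, d2$brain_mask)

  # a grid too small to hold the geometry errors out
  expect_error(build_tissue_domain(grid3d(c(3, 3, 3), c(0.25, 0.25, 0.25)),
                                   domain_config()), "domain construction")
})

test_that("synthetic initial conditions are compact, bounded and analytically sized", {
  dom <- tiny_domain(shape = c(21, 21, 21), spacing = 0.1,
                     semiaxes = c(0.9, 0.9, 0.9))
  cfg <- lesion_config(radius = 0.5)
  ic <- synthesize_initial_conditions(dom, cfg, seed = 1)
  expect_true(all(ic$N_t$values >= 0 & ic$N_t$values <= 0.9716))
  expect_true(all(ic$N_t$values[!dom$brain_mask] == 0))
  expect_true(all(ic$N_v$values[!dom$brain_mask] == 0))
  # the profile peaks at theta_max at the lesion center (a voxel sits there
  # on this odd-shaped grid)
  expect_equal(max(ic$N_t$values), 0.9716, tolerance = 1e-12)
  # vasculature positive within and around the lesion
  expect_true(all(ic$N_v$values[dom$brain_mask] > 0))

  # discretized lesion mass matches the closed-form profile integral
  expect_lt(abs(field_mass(ic$N_t) -
                  lesion_mass_closed_form(0.5, 0.9716)) /
              lesion_mass_closed_form(0.5, 0.9716), 0.05)

  # zero-radius lesion vanishes
  ic0 <- synthesize_initial_conditions(dom, lesion_config(radius = 0),
                                       seed = 1)
  expect_true(all(ic0$N_t$values == 0))

  # radius beyond the brain extent is a configuration error
  expect_error(synthesize_initial_conditions(dom, lesion_config(radius = 2)),
               "configuration error")

  # isotropic config on a cubic grid: invariant under axis permutation
  perm <- aperm(ic$N_t$values, c(2, 3, 1))
  expect_equal(perm, ic$N_t$values, tolerance = 1e-12)
})

test_that("the virtual cohort spans the four quadrants at three magnitudes", {
  central <- model_parameters()
  cohort <- build_virtual_cohort(central)
  expect_length(cohort, 13)
  offs <- t(vapply(cohort, function(s) s$offsets, numeric(2)))
  expect_equal(sum(offs[, 1] == 0 & offs[, 2] == 0), 1)
  expect_setequal(unique(abs(offs[, 1])), c(0, 25, 50, 75))

  expect_equal(cohort$central$parameters$D_t0, 0.0263)
  expect_equal(cohort$central$parameters$D_v0, 0.0100)
  expect_equal(cohort$central$parameters$k_t, 0.45)
  expect_equal(cohort$central$parameters$k_v, 0.25)

  # quadrant 1, 25 percent: joint +25% proliferation and diffusion
  expect_equal(cohort$`11`$parameters$k_t, 0.5625)
  expect_equal(cohort$`11`$parameters$k_v, 0.3125)
  expect_equal(cohort$`11`$parameters$D_t0, 0.0263 * 1.25)
  # quadrant 2 lowers diffusion while raising proliferation
  expect_equal(cohort$`23`$parameters$k_t, 0.45 * 1.75)
  expect_equal(cohort$`23`$parameters$D_t0, 0.0263 * 0.25)
  # fixed constants are untouched
  expect_true(all(vapply(cohort, function(s) s$parameters$k_dv, 1) == 0.125))

  # pure function: applying it twice yields identical specs
  expect_identical(cohort, build_virtual_cohort(central))
})

test_that("model parameter validation rejects unphysical values", {
  expect_error(model_parameters(k_t = -1), ">= 0")
  expect_error(model_parameters(theta_min = 1, theta_max = 0.5), "theta_min")
  expect_error(model_parameters(N_v_thresh = 0), "N_v_thresh")
})
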