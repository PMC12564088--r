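test_that("carrying capacity is piecewise linear and continuous at the threshold", {
  expect_equal(carrying_capacity(0), 0.1)
  expect_equal(carrying_capacity(0.022), 0.9716)
  expect_equal(carrying_capacity(0.011), 0.1 + 0.5 * (0.9716 - 0.1))
  expect_equal(carrying_capacity(0.011), 0.5358)
  expect_equal(carrying_capacity(0.5), 0.9716)
  eps <- 1e-10
  expect_equal(carrying_capacity(0.022 - eps), carrying_capacity(0.022 + eps),
               tolerance = 1e-6)
  # vectorized over fields
  g <- grid3d(c(2, 2, 2), c(1, 1, 1))
  f <- scalar_field(array(0.011, g$shape), g, "vasculature_fraction")
  th <- carrying_capacity(f)
  expect_s3_class(th, "scalar_field")
  expect_equal(unique(as.vector(th$values)), 0.5358)
})

test_that("periphery distance is exact on rods, balls and degenerate masks", {
  # 5-voxel rod inside a 7-voxel 1-D grid: depths (0,1,2,1,0) * spacing
  g <- grid3d(c(7, 1, 1), c(0.2, 0.2, 0.2))
  nt <- array(0, g$shape); nt[2:6] <- 0.5
  d <- distance_to_periphery(scalar_field(nt, g, "tumor_fraction"), 0.05)
  expect_equal(as.vector(d$values), c(1, 1, 0.5, 0, 0.5, 1, 1))

  # single-voxel tumor is its own periphery
  nt1 <- array(0, g$shape); nt1[4] <- 0.5
  d1 <- distance_to_periphery(scalar_field(nt1, g, "tumor_fraction"), 0.05)
  expect_true(all(d1$values == 1))

  # solid ball: 0 at the center, 1 on the surface, 1 outside
  gb <- grid3d(c(11, 11, 11), c(1, 1, 1))
  cc <- expand.grid(x = 1:11, y = 1:11, z = 1:11)
  ball <- array((cc$x - 6)^2 + (cc$y - 6)^2 + (cc$z - 6)^2 <= 16, gb$shape)
  db <- distance_to_periphery(scalar_field(array(0.5 * ball, gb$shape), gb,
                                           "tumor_fraction"), 0.05)
  expect_equal(db$values[6, 6, 6], 0)
  expect_equal(db$values[6, 6, 2], 1)
  expect_equal(db$values[1, 1, 1], 1)
  expect_true(all(db$values >= 0 & db$values <= 1))

  # empty tumor mask: d = 1 everywhere
  d0 <- distance_to_periphery(scalar_field(array(0, gb$shape), gb,
                                           "tumor_fraction"), 0.05)
  expect_true(all(d0$values == 1))

  # anisotropic spacing: depth measured in mm, not voxels
  ga <- grid3d(c(9, 1, 1), c(0.5, 0.5, 2))
  nta <- array(0, ga$shape); nta[2:8] <- 0.5
  da <- distance_to_periphery(scalar_field(nta, ga, "tumor_fraction"), 0.05)
  expect_equal(as.vector(da$values),
               c(1, 1, 1 - 1/3, 1 - 2/3, 0, 1 - 2/3, 1 - 1/3, 1, 1))
})

test_that("a zero-rate step leaves the state unchanged and guards its inputs", {
  dom <- tiny_domain()
  ic <- synthesize_initial_conditions(dom, lesion_config(radius = 0.4),
                                      seed = 1)
  p0 <- model_parameters(D_t0 = 0, D_v0 = 0, k_t = 0, k_v = 0, k_dv = 0,
                         lambda_f = 0)
  Dz <- field_on(dom, 0, role = "generic")
  out <- growth_step(ic$N_t, ic$N_v, Dz, Dz, p0, dom, dt = 0.01)
  expect_equal(out$N_t$values, ic$N_t$values, tolerance = 1e-15)
  expect_equal(out$N_v$values, ic$N_v$values, tolerance = 1e-15)

  # negative inputs rejected
  bad <- field_on(dom, -0.1, role = "generic")
  expect_error(growth_step(bad, ic$N_v, Dz, Dz, p0, dom, dt = 0.01),
               "negative")

  # stability audit names the offending coefficient
  Dbig <- field_on(dom, 50, role = "generic")
  expect_error(growth_step(ic$N_t, ic$N_v, Dbig, Dz, p0, dom, dt = 0.01),
               "D_t")
})

test_that("zero-diffusion dynamics follow the logistic closed form", {
  dom <- slab_domain(c(3, 3, 3))
  p <- model_parameters(D_t0 = 0, D_v0 = 0, k_t = 0.45, k_v = 0, k_dv = 0,
                        lambda_f = 0)
  th <- p$theta_max
  n0 <- 0.1 * th
  ic <- list(N_t = field_on(dom, n0),
             N_v = field_on(dom, 0.03, "vasculature_fraction"))
  # mask threshold above theta_max: empty tumor mask, d = 1 everywhere
  tc <- simulate_growth(ic, p, dom, days = 6, dt = 0.01,
                        mask_threshold_frac = 2)
  num <- tc$N_t[[6]]$values[1]
  closed <- th / (1 + (th / n0 - 1) * exp(-0.45 * 5))
  expect_lt(abs(num - closed) / closed, 2e-3)

  # independent 0-D forward-Euler oracle reproduces the solver bit-for-bit
  y <- n0
  for (i in 1:500) y <- y + 0.01 * 0.45 * y * (1 - y / th)
  expect_equal(num, y, tolerance = 1e-12)

  # first-order convergence: halving dt roughly halves the error
  tc2 <- simulate_growth(ic, p, dom, days = 6, dt = 0.005,
                         mask_threshold_frac = 2)
  err1 <- abs(num - closed)
  err2 <- abs(tc2$N_t[[6]]$values[1] - closed)
  expect_lt(err2 / err1, 0.6)
})

test_that("vessel regression decays exponentially at rate k_dv where d = 0", {
  # rod core: the deepest voxel has d = 0 exactly
  dom <- slab_domain(c(7, 1, 1))
  p <- model_parameters(D_t0 = 0, D_v0 = 0, k_t = 0, k_v = 0, k_dv = 0.125,
                        lambda_f = 0)
  nt <- array(0, c(7, 1, 1)); nt[2:6] <- 0.5
  nv <- array(0, c(7, 1, 1)); nv[2:6] <- 0.05
  ic <- list(N_t = scalar_field(nt, dom$grid, "tumor_fraction"),
             N_v = scalar_field(nv, dom$grid, "vasculature_fraction"))
  tc <- simulate_growth(ic, p, dom, days = 10, dt = 0.01)
  num <- tc$N_v[[10]]$values[4, 1, 1]
  expect_lt(abs(num - 0.05 * exp(-0.125 * 9)) / (0.05 * exp(-0.125 * 9)),
            1e-3)
  # at the periphery (d = 1) vasculature is untouched
  expect_equal(tc$N_v[[10]]$values[2, 1, 1], 0.05, tolerance = 1e-12)
})

test_that("pure diffusion conserves total mass under zero-flux boundaries", {
  st <- base_study()
  p <- model_parameters(k_t = 0, k_v = 0, k_dv = 0, lambda_f = 0)
  # small fields so clipping never engages; cross-diffusion stays active
  ic <- list(N_t = field_on(st$domain, st$ic$N_t$values * 0.05),
             N_v = st$ic$N_v)
  tc <- simulate_growth(ic, p, st$domain, days = 10, dt = 0.01)
  for (sp in c("N_t", "N_v")) {
    m1 <- field_mass(tc[[sp]][[1]])
    m10 <- field_mass(tc[[sp]][[10]])
    expect_lt(abs(m10 - m1) / m1, 1e-6)
  }
  # and diffusion actually moved mass around
  expect_gt(rel_l2(tc$N_t[[10]]$values, tc$N_t[[1]]$values), 0.01)
})

test_that("the simulator is deterministic, day-indexed, and a semigroup", {
  st <- base_study()
  p <- model_parameters()
  tc1 <- simulate_growth(st$ic, p, st$domain, days = 1)
  expect_equal(tc1$days, 1L)
  expect_equal(tc1$N_t[[1]]$values, st$ic$N_t$values)

  # zero-parameter run: every snapshot equals the initial condition
  p0 <- model_parameters(D_t0 = 0, D_v0 = 0, k_t = 0, k_v = 0, k_dv = 0,
                         lambda_f = 0)
  tcz <- simulate_growth(st$ic, p0, st$domain, days = 5)
  for (i in 1:5)
    expect_equal(tcz$N_t[[i]]$values, st$ic$N_t$values, tolerance = 1e-15)

  # bit-for-bit reproducibility
  a <- simulate_growth(st$ic, p, st$domain, days = 6)
  b <- simulate_growth(st$ic, p, st$domain, days = 6)
  expect_identical(a$N_t[[6]]$values, b$N_t[[6]]$values)

  # restarting from the day-5 snapshot reproduces the day-10 field
  full <- simulate_growth(st$ic, p, st$domain, days = 10)
  part <- simulate_growth(list(N_t = full$N_t[[5]], N_v = full$N_v[[5]]),
                          p, st$domain, days = 6)
  expect_equal(part$N_t[[6]]$values, full$N_t[[10]]$values,
               tolerance = 1e-12)
  expect_equal(part$N_v[[6]]$values, full$N_v[[10]]$values,
               tolerance = 1e-12)
})

test_that("species stay inside [0, theta_tot] and develop a necrotic core", {
  st <- base_study()
  p <- model_parameters()
  tc <- simulate_growth(st$ic, p, st$domain, days = 10)
  for (i in c(5, 10)) {
    nt <- tc$N_t[[i]]$values
    nv <- tc$N_v[[i]]$values
    th <- carrying_capacity(nv, p$theta_min, p$theta_max, p$N_v_thresh)
    expect_true(all(nt >= 0 & nt <= th + 1e-12))
    expect_true(all(nv >= 0 & nv <= th + 1e-12))
  }
  # vessel regression empties the core at the resolution that resolves it:
  # on the finest grid the day-10 center vasculature falls below its
  # initial value while the rim gains vessels
  domf <- build_tissue_domain(resolution_grid(st$scale, 0.008), seed = 1L)
  icf <- synthesize_initial_conditions(domf, seed = 1L)
  tcf <- simulate_growth(icf, p, domf, days = 10)
  ctr <- which(icf$N_t$values == max(icf$N_t$values), arr.ind = TRUE)[1, ]
  expect_lt(tcf$N_v[[10]]$values[ctr[1], ctr[2], ctr[3]],
            icf$N_v$values[ctr[1], ctr[2], ctr[3]])
  expect_gt(max(tcf$N_v[[10]]$values), max(icf$N_v$values))
})

test_that("time courses persist to NIfTI plus manifest and read back", {
  st <- base_study()
  p <- model_parameters()
  tc <- simulate_growth(st$ic, p, st$domain, days = 3)
  dir <- tempfile("tc")
  on.exit(unlink(dir, recursive = TRUE))
  write_timecourse(tc, dir)
  back <- read_timecourse(dir)
  expect_equal(back$days, tc$days)
  expect_equal(back$N_t[[3]]$values, tc$N_t[[3]]$values, tolerance = 1e-7)
  expect_equal(back$parameters$k_t, p$k_t)
  expect_equal(back$grid$spacing, tc$grid$spacing)
})
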