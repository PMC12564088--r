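test_that("the condition grid enumerates exactly the 6 x 3 x 3 factorial", {
  cond <- experiment_conditions()
  expect_equal(nrow(cond), 54)
  expect_equal(length(unique(cond$condition_id)), 54)
  expect_setequal(unique(cond$snr), c(5, 10, 20, 40, 80, 160))
  expect_setequal(unique(cond$voxel_volume), c(0.008, 0.063, 0.50))
  expect_setequal(unique(cond$tr), c("2", "3", "5"))
  expect_equal(cond$tr_days[cond$tr == "2"][[1]], c(1, 5))
  expect_equal(cond$tr_days[cond$tr == "3"][[1]], c(1, 3, 5))
  expect_equal(cond$tr_days[cond$tr == "5"][[1]], 1:5)
})

test_that("multiplicative noise preserves zeros, is seeded, and has sd 1/SNR", {
  g <- grid3d(c(100, 100, 100), c(0.1, 0.1, 0.1))
  zero <- scalar_field(array(0, g$shape), g, "tumor_fraction")
  expect_equal(add_noise(zero, 5, seed = 1)$values, zero$values)

  ones <- scalar_field(array(1, g$shape), g, "generic")
  n1 <- add_noise(ones, 40, seed = 7, clip = c(0, Inf))
  n2 <- add_noise(ones, 40, seed = 7, clip = c(0, Inf))
  expect_identical(n1$values, n2$values)
  n3 <- add_noise(ones, 40, seed = 8, clip = c(0, Inf))
  expect_false(identical(n1$values, n3$values))

  # Monte-Carlo check of the noise scale on 1e6 unit voxels
  ratio <- as.vector(n1$values)
  expect_lt(abs(sd(ratio) - 1 / 40), 5e-4)
  expect_lt(abs(mean(ratio) - 1), 3 * (1 / 40) / sqrt(length(ratio)))

  # clipping keeps fractions physical at the worst SNR
  frac <- scalar_field(array(0.9, c(10, 10, 10)),
                       grid3d(c(10, 10, 10), c(1, 1, 1)), "tumor_fraction")
  noisy <- add_noise(frac, 5, seed = 3)
  expect_true(all(noisy$values >= 0 & noisy$values <= 0.9716))

  expect_error(add_noise(ones, 0, seed = 1), "positive")
})

test_that("timepoint selection subsets a course and flags missing days", {
  st <- base_study()
  tc <- simulate_growth(st$ic, model_parameters(), st$domain, days = 10)
  two <- select_timepoints(tc, c(1, 5))
  expect_equal(two$days, c(1, 5))
  expect_length(two$N_t, 2)
  expect_equal(two$N_t[[2]]$values, tc$N_t[[5]]$values)
  all5 <- select_timepoints(tc, 1:5)
  expect_length(all5$N_t, 5)
  # selecting every day of a course is the identity
  full <- select_timepoints(tc, tc$days)
  expect_equal(full$N_t[[10]]$values, tc$N_t[[10]]$values)
  expect_error(select_timepoints(tc, c(1, 11)), "not present")
})

test_that("degradation applies per-day noise then timepoint subsetting", {
  st <- base_study()
  tc <- simulate_growth(st$ic, model_parameters(), st$domain, days = 10)
  cond <- experiment_conditions()
  c40 <- cond[cond$snr == 40 & cond$voxel_volume == 0.063 & cond$tr == "3", ]
  deg <- degrade_timecourse(tc, c40, replicate_seed = 11)
  expect_equal(deg$days, c(1, 3, 5))
  # noise differs between days and species but respects the seed
  deg2 <- degrade_timecourse(tc, c40, replicate_seed = 11)
  expect_identical(deg$N_t[[1]]$values, deg2$N_t[[1]]$values)
  deg3 <- degrade_timecourse(tc, c40, replicate_seed = 12)
  expect_false(identical(deg$N_t[[1]]$values, deg3$N_t[[1]]$values))
  expect_false(identical(deg$N_t[[1]]$values, deg$N_t[[2]]$values))

  # an infinite-SNR condition with all days is the identity protocol
  cInf <- list(snr = Inf, tr_days = list(1:10))
  degInf <- degrade_timecourse(tc, cInf, replicate_seed = 1)
  expect_equal(degInf$N_t[[7]]$values, tc$N_t[[7]]$values)

  # noisy fields stay within the clipped physical range
  expect_true(all(deg$N_t[[2]]$values >= 0 & deg$N_t[[2]]$values <= 0.9716))
})

test_that("noisy fields are unbiased on interior tumor voxels", {
  st <- base_study()
  nt <- st$ic$N_t
  # nonzero voxels well below the clip ceiling, so clipping cannot bias
  core <- nt$values > 0.005 & nt$values < 0.5
  for (snr in c(5, 40)) {
    ratios <- replicate(40, {
      noisy <- add_noise(nt, snr, seed = sample.int(1e6, 1))
      mean(noisy$values[core] / nt$values[core])
    })
    # mean ratio within 3 sigma of 1 (clipping bias negligible below ~0.5)
    expect_lt(abs(mean(ratios) - 1),
              3 * (1 / snr) / sqrt(40 * sum(core)) + 0.01 / snr)
  }
})
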