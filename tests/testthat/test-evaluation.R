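test_that("Dice handles identical, disjoint, partial and empty masks", {
  g <- grid3d(c(4, 1, 1), c(1, 1, 1))
  mk <- function(v) scalar_field(array(v, g$shape), g, "generic")
  a <- mk(c(1, 1, 1, 0)); b <- mk(c(0, 1, 1, 1))
  expect_equal(dice_coefficient(a, a, 0.5), 1)
  expect_equal(dice_coefficient(mk(c(1, 1, 0, 0)), mk(c(0, 0, 1, 1)), 0.5), 0)
  # |A|=3, |B|=3, |A n B|=2 -> 2*2/6
  expect_equal(dice_coefficient(a, b, 0.5), 2 / 3, tolerance = 1e-12)
  # both masks empty: trivial perfect agreement
  expect_equal(dice_coefficient(mk(0), mk(0), 0.5), 1)
  g2 <- grid3d(c(4, 1, 1), c(2, 1, 1))
  expect_error(dice_coefficient(a, scalar_field(array(1, g2$shape), g2), 0.5),
               "different grids")
})

test_that("Lin's CCC agrees with direct evaluation of the closed form", {
  g <- grid3d(c(4, 1, 1), c(1, 1, 1))
  mk <- function(v) scalar_field(array(v, g$shape), g, "generic")
  p <- c(1, 2, 3, 4); t <- c(1.1, 2.1, 2.9, 4.2)

  # brute-force population-moment oracle, written out in sums
  mp <- sum(p) / 4; mt <- sum(t) / 4
  vp <- sum((p - mp)^2) / 4; vt <- sum((t - mt)^2) / 4
  cv <- sum((p - mp) * (t - mt)) / 4
  oracle <- 2 * cv / (vp + vt + (mp - mt)^2)
  expect_equal(lins_ccc(mk(p), mk(t), detection_threshold = 0), oracle,
               tolerance = 1e-12)

  # perfect agreement and perfect anti-agreement
  expect_equal(lins_ccc(mk(p), mk(p), 0), 1)
  q <- c(-2, -1, 1, 2)
  expect_equal(lins_ccc(mk(q), mk(-q), -10), -1)

  # degenerate sets raise, never silently return
  expect_error(lins_ccc(mk(c(1, 0, 0, 0)), mk(c(1, 0, 0, 0)), 0.5),
               "fewer than two")
  expect_error(lins_ccc(mk(c(1, 1, 1, 1)), mk(c(1, 1, 1, 1)), 0.5),
               "constant")
})

test_that("percent error is exact, symmetric in scale, and guards zero truth", {
  expect_equal(percent_error(0.45, 0.45), 0)
  expect_equal(percent_error(0.45, 0.486), 8, tolerance = 1e-12)
  expect_equal(percent_error(1, 1.1), percent_error(10, 11))
  expect_equal(percent_error(0.0263, 0.01), percent_error(0.0263, 0.0426),
               tolerance = 1e-9)
  expect_error(percent_error(0, 1), "undefined")
})

test_that("summaries report medians with interpolated quartiles", {
  tbl <- data.frame(tumor_id = "central", condition_id = "c1", snr = 40,
                    voxel_volume = 0.063, tr = "5", replicate = 1:5,
                    pe_kt = c(1, 2, 3, 4, 5), dice_day6 = 0.95,
                    status = "ok", stringsAsFactors = FALSE)
  s <- summarize_metrics(tbl, metrics = c("pe_kt", "dice_day6"))
  kt <- s[s$metric == "pe_kt", ]
  expect_equal(kt$median, 3)
  expect_equal(kt$q25, 2)
  expect_equal(kt$q75, 4)
  d6 <- s[s$metric == "dice_day6", ]
  expect_equal(d6$median, 0.95)
  expect_equal(d6$q75 - d6$q25, 0)

  # single replicate: median is the value, IQR zero
  s1 <- summarize_metrics(tbl[1, ], metrics = "pe_kt")
  expect_equal(s1$median, 1)
  expect_equal(s1$q75 - s1$q25, 0)
})

test_that("a noise-free single-replicate grid reproduces itself end to end", {
  cohort <- build_virtual_cohort()
  clean <- data.frame(snr = Inf, voxel_volume = 0.063, tr = "5",
                      stringsAsFactors = FALSE)
  clean$tr_days <- list(1:5)
  clean$condition_id <- "clean_sr0.063_tr5"
  tbl <- run_experiment_grid(cohort["central"], clean, replicates = 1,
                             seed = 1)
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$status, "ok")
  # parameters recovered to optimizer tolerance, predictions self-identical
  expect_lt(tbl$pe_kt, 1); expect_lt(tbl$pe_kv, 1); expect_lt(tbl$pe_Dt, 1)
  expect_gt(tbl$dice_day6, 1 - 1e-6)
  expect_gt(tbl$dice_day10, 1 - 1e-6)
  expect_gt(tbl$ccc_tumor_day10, 0.999)
  expect_gt(tbl$ccc_vasc_day10, 0.999)
})

test_that("per-row seeds derive deterministically from the master seed", {
  cohort <- build_virtual_cohort()
  cond <- experiment_conditions()
  one <- cond[cond$snr == 40 & cond$voxel_volume == 0.5 & cond$tr == "2", ]
  t1 <- run_experiment_grid(cohort["central"], one, replicates = 2, seed = 9)
  t2 <- run_experiment_grid(cohort["central"], one, replicates = 2, seed = 9)
  expect_equal(t1$k_t_hat, t2$k_t_hat)
  expect_equal(t1$seed, t2$seed)
  # replicates within a run see different noise
  expect_false(identical(t1$k_t_hat[1], t1$k_t_hat[2]))
})
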