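# deliberately small problem sizes: the drivers' bookkeeping is under test
# here, not the biology (which the acceptance suite probes at larger scale)
mini_cfg <- sim_config(grid = c(40, 40), t_end = 8, output_times = 8,
                       aggregate_radius = 3, seed = 11)

test_that("a degenerate sweep grid with one replicate equals a plain run", {
  sw <- run_sweep("kt", 1, mini_cfg, replicates = 1, eval_time = 8)
  expect_equal(nrow(sw), 1)
  ref <- run_simulation(sim_config(grid = c(40, 40), t_end = 8,
                                   output_times = 8, aggregate_radius = 3,
                                   seed = sw$seed[1]))
  expect_equal(sw$arel_ec, ref$series$arel_ec[nrow(ref$series)])
})

test_that("sweep tables are reproducible and replicates differ", {
  sw1 <- run_sweep("k_nicd_degradation", c(0.5, 1), mini_cfg,
                   replicates = 2, eval_time = 8)
  sw2 <- run_sweep("k_nicd_degradation", c(0.5, 1), mini_cfg,
                   replicates = 2, eval_time = 8)
  expect_equal(sw1, sw2)
  expect_equal(nrow(sw1), 4)
  expect_equal(unique(sw1$scaling), c(0.5, 1))
  # scaled values are multiplicative on the calibrated parameter
  expect_equal(unique(sw1$value),
               c(0.5, 1) * mini_cfg$model$params[["k_nicd_degradation"]])
  s <- summarize_sweep(sw1)
  expect_equal(nrow(s), 2)
})

test_that("scenario pairs share seeds and the KO exceeds WT in vessel area", {
  res <- run_scenarios(mini_cfg, replicates = 2)
  expect_equal(nrow(res$results), 4)
  wt <- res$results[res$results$scenario == "wild_type", ]
  ko <- res$results[res$results$scenario == "vegfr1_ko", ]
  expect_equal(wt$seed, ko$seed)  # paired
  expect_equal(res$summary$n, c(2, 2))
})

test_that("heterogeneity rows carry group, ratio and tip metrics", {
  het <- run_heterogeneity(mini_cfg, groups = c("tc", "nicd_deg"),
                           sd_grid = c(0.1, 0.4), replicates = 1)
  expect_equal(nrow(het), 4)
  expect_setequal(unique(het$group), c("tc", "nicd_deg"))
  expect_true(all(het$first_tip_time > 0))
  expect_true(all(het$arel_ec >= 0 & het$arel_ec <= 100))
})

test_that("the sprouting criterion is the majority-of-replicates rule", {
  expect_true(sprouted(c(50, 100, 1000)))
  expect_false(sprouted(c(1000, 1000, 60)))
  expect_true(sprouted(c(10, 20)))
})
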