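test_that("tip criterion truth table uses strict inequalities on all three conditions", {
  b <- behavior_params(A_star = 2, D_star = 100)
  expect_true(is_tip(10, 5, filopodia = 3, dll4_mRNA = 101, behavior = b))
  # equality on any criterion is non-tip
  expect_false(is_tip(5, 5, filopodia = 3, dll4_mRNA = 101, behavior = b))
  expect_false(is_tip(10, 5, filopodia = 2, dll4_mRNA = 101, behavior = b))
  expect_false(is_tip(10, 5, filopodia = 3, dll4_mRNA = 100, behavior = b))
  # each criterion individually necessary
  expect_false(is_tip(4, 5, filopodia = 3, dll4_mRNA = 101, behavior = b))
  expect_false(is_tip(10, 5, filopodia = 0, dll4_mRNA = 101, behavior = b))
  expect_false(is_tip(10, 5, filopodia = 3, dll4_mRNA = 1, behavior = b))
  # named state vector interface
  st <- c(vegfr2_mRNA = 10, vegfr1_mRNA = 5, filopodia = 3, dll4_mRNA = 101)
  expect_true(is_tip(st, behavior = b))
})

test_that("filopodia extend above the setpoint, retract below, and clip", {
  b <- behavior_params(filo_ext = 2, filo_ret = 1, v2a_set = 100,
                       filo_max = 3)
  expect_equal(update_filopodia(1, 200, b, dt = 0.5), 2)
  expect_equal(update_filopodia(1, 0, b, dt = 0.5), 0.5)
  expect_equal(update_filopodia(0.2, 0, b, dt = 0.5), 0)   # floor
  expect_equal(update_filopodia(2.9, 1e6, b, dt = 1), 3)   # ceiling
  # alternating activity reproduces the two-branch rule step by step
  f <- 1; acts <- c(200, 0, 200, 200, 0)
  expected <- f
  for (a in acts) {
    f <- update_filopodia(f, a, b, dt = 0.25)
    expected <- min(max(expected + ifelse(a > 100, 2, -1) * 0.25, 0), 3)
    expect_equal(f, expected)
  }
})

test_that("gradient direction follows a monotone field and is NA when uniform", {
  g <- matrix(rep(1:20, each = 20), 20, 20)  # increases with column: eastward
  expect_equal(gradient_direction(g, 10, 10, radius = 2), 3L)  # E
  expect_equal(gradient_direction(t(g), 10, 10, radius = 2), 5L)  # S
  expect_true(is.na(gradient_direction(matrix(4, 20, 20), 10, 10, radius = 3)))
})

test_that("ties between equal maxima are broken uniformly", {
  g <- matrix(0, 21, 21)
  g[11, 21] <- 100  # east peak
  g[11, 1] <- 100   # west peak (symmetric)
  set.seed(11)
  draws <- replicate(4000, gradient_direction(g, 11, 11, radius = 10))
  expect_setequal(unique(draws), c(3L, 7L))
  expect_equal(mean(draws == 3L), 0.5, tolerance = 0.05)
})

test_that("movement deviation hits the 1-2p / p / p frequencies", {
  set.seed(13)
  draws <- replicate(10000, deviate_direction(3L, p_dev = 0.2))
  expect_equal(mean(draws == 3L), 0.6, tolerance = 0.03)
  expect_equal(mean(draws == 4L), 0.2, tolerance = 0.03)
  expect_equal(mean(draws == 2L), 0.2, tolerance = 0.03)
  # p_dev = 0 is deterministic
  expect_true(all(replicate(50, deviate_direction(5L, 0)) == 5L))
  # deviation wraps around the compass
  set.seed(14)
  d <- replicate(2000, deviate_direction(8L, 0.5))
  expect_setequal(unique(d), c(1L, 7L))
})

test_that("neighbor Dll4 follows the per-contact sharing rule", {
  dll4 <- matrix(0, 5, 5)
  occ <- matrix(FALSE, 5, 5)
  # isolated agent
  occ[3, 3] <- TRUE
  expect_equal(neighbor_dll4(dll4, occ, 3, 3), 0)
  # one neighbor with dll4 = 8 whose only contact is the focal cell
  occ[3, 4] <- TRUE
  dll4[3, 4] <- 8
  expect_equal(neighbor_dll4(dll4, occ, 3, 3), 8)
  # 3-cell row: the middle cell receives each end's ligand undivided (ends
  # have one contact), each end receives half of the middle cell's ligand
  occ <- matrix(FALSE, 5, 5); dll4 <- matrix(0, 5, 5)
  occ[3, 2:4] <- TRUE
  dll4[3, 2] <- 10; dll4[3, 3] <- 6; dll4[3, 4] <- 20
  expect_equal(neighbor_dll4(dll4, occ, 3, 3), 30)        # 10/1 + 20/1
  expect_equal(neighbor_dll4(dll4, occ, 3, 2), 6 / 2)     # middle shared
  expect_equal(neighbor_dll4(dll4, occ, 3, 4), 6 / 2)
})

test_that("behavior parameter validation rejects out-of-range settings", {
  expect_error(behavior_params(A_star = 0), "> 0")
  expect_error(behavior_params(p_dev = 0.7), "p_dev")
  expect_silent(behavior_params(p_dev = 0))
})
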