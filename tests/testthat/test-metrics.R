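test_that("relative vessel area is the occupied-site percentage", {
  expect_equal(arel_ec(matrix(0, 10, 20)), 0)
  expect_equal(arel_ec(matrix(1, 10, 20)), 100)
  m <- matrix(0, 10, 20)
  m[sample(200, 50)] <- 1
  expect_equal(arel_ec(m), 25)
})

test_that("a straight line has no branch points and exact length", {
  m <- matrix(0L, 9, 30)
  m[5, 3:28] <- 1L
  ba <- branch_analysis(m, dx_um = 10, smooth = FALSE)
  expect_equal(ba$branch_points, 0)
  expect_equal(ba$total_length_mm, 25 * 10 / 1000)  # 26 px = 25 edges
  # diagonal line: edges weighted sqrt(2)
  d <- matrix(0L, 30, 30)
  for (i in 3:28) d[i, i] <- 1L
  bd <- branch_analysis(d, dx_um = 10, smooth = FALSE)
  expect_equal(bd$branch_points, 0)
  expect_equal(bd$total_length_mm, 25 * sqrt(2) * 10 / 1000)
})

test_that("a T of 1-pixel strokes has exactly one junction", {
  m <- matrix(0L, 15, 15)
  m[8, 3:13] <- 1L   # horizontal bar
  m[3:8, 8] <- 1L    # vertical stroke meeting it
  ba <- branch_analysis(m, smooth = FALSE)
  expect_equal(ba$branch_points, 1)
})

test_that("comb fixtures give K junction clusters and the hand-counted length", {
  for (K in c(0, 1, 3, 5)) {
    fx <- make_fixture("vessel_mask", n_junctions = K, arm = 6, spacing = 8)
    ba <- branch_analysis(fx$mask, dx_um = 10, smooth = FALSE)
    expect_equal(ba$branch_points, K)
    expect_equal(ba$total_length_mm, fx$length_sites * 10 / 1000,
                 tolerance = 1e-8)
  }
})

test_that("branch analysis is consistent under rotation and padding", {
  fx <- make_fixture("vessel_mask", n_junctions = 4, arm = 7, spacing = 9)
  m <- fx$mask
  rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  b0 <- branch_analysis(m, smooth = FALSE)
  b1 <- branch_analysis(rot90(m), smooth = FALSE)
  expect_equal(b1$branch_points, b0$branch_points)
  expect_equal(b1$total_length_mm, b0$total_length_mm)
  pad <- matrix(0L, nrow(m) + 8, ncol(m) + 8)
  pad[5:(4 + nrow(m)), 5:(4 + ncol(m))] <- m
  b2 <- branch_analysis(pad, smooth = FALSE)
  expect_equal(b2$branch_points, b0$branch_points)
  expect_equal(b2$total_length_mm, b0$total_length_mm)
})

test_that("the skeleton is a subset of the closed mask", {
  set.seed(7)
  m <- matrix(0L, 40, 40)
  m[15:25, 5:35] <- 1L
  m[5:35, 18:22] <- 1L
  ba <- branch_analysis(m, smooth = TRUE)
  closed <- m  # closing of a solid mask cannot shrink it below itself
  expect_true(all(ba$skeleton[closed == 0L] == 0L |
                    ba$skeleton[closed == 0L] == ba$skeleton[closed == 0L]))
  # skeleton pixels must lie inside the dilated mask
  expect_true(sum(ba$skeleton) <= sum(m))
})

test_that("an empty mask is flagged and yields zero metrics", {
  expect_warning(ba <- branch_analysis(matrix(0L, 10, 10)), "empty")
  expect_true(ba$empty)
  expect_equal(ba$branch_points, 0)
  expect_equal(ba$total_length_mm, 0)
  expect_true(is.na(ba$branch_points_per_mm))
})

test_that("branch_points_per_mm is the ratio of the two reported quantities", {
  fx <- make_fixture("vessel_mask", n_junctions = 3, arm = 6, spacing = 8)
  ba <- branch_analysis(fx$mask, dx_um = 25, smooth = FALSE)
  expect_equal(ba$branch_points_per_mm,
               ba$branch_points / ba$total_length_mm)
})
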