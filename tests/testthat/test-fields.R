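test_that("diffusion leaves a uniform field at the boundary value unchanged", {
  f <- field(matrix(5, 20, 20), D = 10, boundary = 5)
  g <- diffuse(f, dt = 0.5)
  expect_equal(g$grid, f$grid)
})

test_that("one lambda = 0.25 step spreads a point mass onto the 4-neighbors", {
  f <- field(matrix(0, 11, 11), D = 2.5, boundary = 0)   # lambda = 2.5 * 0.1
  f$grid[6, 6] <- 100
  g <- diffuse(f, dt = 0.1)
  expect_equal(g$grid[6, 6], 0)
  expect_equal(g$grid[5, 6], 25)
  expect_equal(g$grid[7, 6], 25)
  expect_equal(g$grid[6, 5], 25)
  expect_equal(g$grid[6, 7], 25)
  expect_equal(sum(g$grid), 100)
})

test_that("interior mass is nonincreasing under a zero boundary", {
  set.seed(1)
  f <- field(matrix(runif(400, 0, 10), 20, 20), D = 8, boundary = 0)
  f <- diffuse(f, dt = 0.05)  # first step pins the boundary ring to 0
  tot <- sum(f$grid)
  for (i in 1:30) {
    f <- diffuse(f, dt = 0.05)
    expect_lte(sum(f$grid), tot + 1e-9)
    expect_true(all(f$grid >= 0))
    tot <- sum(f$grid)
  }
})

test_that("diffusion of a centered point source is 4-fold symmetric", {
  f <- field(matrix(0, 21, 21), D = 5, boundary = 0)
  f$grid[11, 11] <- 1000
  for (i in 1:20) f <- diffuse(f, dt = 0.1)
  g <- f$grid
  expect_equal(g, g[21:1, ])           # vertical mirror
  expect_equal(g, g[, 21:1])           # horizontal mirror
  expect_equal(g, t(g))                # transpose symmetry
})

test_that("excessive diffusion stability demands fail loudly", {
  f <- field(matrix(1, 10, 10), D = 1000, boundary = 1)
  expect_error(diffuse(f, dt = 1, max_substeps = 10), "unstable")
})

test_that("degradation follows the Euler decay law and the exponential limit", {
  f <- field(matrix(100, 5, 5), k_deg = 0.01)
  expect_equal(degrade(f, dt = 1)$grid, matrix(99, 5, 5))
  expect_equal(degrade(field(matrix(7, 3, 3), k_deg = 0), dt = 5)$grid,
               matrix(7, 3, 3))
  # long-run decay approaches exp(-k t) as dt shrinks (first-order Euler error)
  k <- 0.1; t_end <- 10
  for (dt in c(0.1, 0.01)) {
    g <- field(matrix(100, 2, 2), k_deg = k)
    for (i in seq_len(t_end / dt)) g <- degrade(g, dt)
    err <- abs(g$grid[1, 1] - 100 * exp(-k * t_end))
    expect_lt(err, 100 * k^2 * dt * t_end)  # O(dt) global error bound
  }
})

test_that("medium replenishment relaxes the field to the reference", {
  med <- list(vegf_reference = 100, k_in = 0.1)
  f <- field(matrix(100, 4, 4))
  expect_equal(replenish_vegf(f, med, dt = 1)$grid, matrix(100, 4, 4))
  f2 <- field(matrix(60, 4, 4))
  expect_equal(replenish_vegf(f2, med, dt = 1)$grid[1, 1], 64)
  # signed law: efflux above the reference
  f3 <- field(matrix(140, 4, 4))
  expect_equal(replenish_vegf(f3, med, dt = 1)$grid[1, 1], 136)
  # fixed point: converges to the reference everywhere
  f4 <- field(matrix(runif(16, 0, 300), 4, 4))
  for (i in 1:2000) f4 <- replenish_vegf(f4, med, dt = 0.1)
  expect_equal(f4$grid, matrix(100, 4, 4), tolerance = 1e-6)
})

test_that("sVEGFR1-VEGF binding is conservative and clipped", {
  set.seed(2)
  vegf <- field(matrix(runif(100, 0, 50), 10, 10), name = "vegf")
  sv <- field(matrix(runif(100, 0, 20), 10, 10), name = "sv")
  svb <- field(matrix(runif(100, 0, 5), 10, 10), name = "svb")
  tot_v <- vegf$grid + svb$grid
  tot_s <- sv$grid + svb$grid
  out <- list(vegf = vegf, svegfr1 = sv, svegfr1b = svb)
  for (i in 1:50) {
    out <- svegfr1_vegf_kinetics(out$vegf, out$svegfr1, out$svegfr1b,
                                 k_on = 0.02, k_off = 0.5, dt = 0.1)
    expect_true(all(out$vegf$grid >= 0) && all(out$svegfr1$grid >= 0) &&
                  all(out$svegfr1b$grid >= 0))
  }
  expect_equal(out$vegf$grid + out$svegfr1b$grid, tot_v)
  expect_equal(out$svegfr1$grid + out$svegfr1b$grid, tot_s)
  # zero rates leave everything unchanged
  same <- svegfr1_vegf_kinetics(vegf, sv, svb, 0, 0, dt = 1)
  expect_equal(same$vegf$grid, vegf$grid)
  expect_equal(same$svegfr1$grid, sv$grid)
  expect_equal(same$svegfr1b$grid, svb$grid)
  # vegf = 0: complexes only dissociate
  dis <- svegfr1_vegf_kinetics(field(matrix(0, 2, 2)),
                               field(matrix(1, 2, 2)),
                               field(matrix(10, 2, 2)), 0.1, 0.2, dt = 1)
  expect_equal(dis$svegfr1b$grid, matrix(8, 2, 2))
  expect_equal(dis$vegf$grid, matrix(2, 2, 2))
})

test_that("field constructor validates its inputs", {
  expect_error(field(matrix(-1, 2, 2)), "finite and >= 0")
  expect_error(field(matrix(1, 2, 2), D = -1), ">= 0")
  f <- field(c(3, 4), name = "empty")
  expect_equal(dim(f$grid), c(3, 4))
})
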