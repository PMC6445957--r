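m_pkg <- ec_model()

test_that("mass-action and zero-reactant rates follow the rate laws", {
  r <- reaction_rates(m_pkg, state = c(notch1 = 10), dll4_nb = 5,
                      params = c(kt = 0.1))
  expect_equal(r[["trans_bind"]], 5)
  # zero reactant nullifies cis binding
  r0 <- reaction_rates(m_pkg, state = c(dll4 = 0))
  expect_equal(r0[["cis_bind"]], 0)
  r0b <- reaction_rates(m_pkg, state = c(notch1 = 0, dll4 = 100))
  expect_equal(r0b[["cis_bind"]], 0)
  # transcription rates agree with the R-level Hill laws
  x <- angiosprout:::model_initial_state(m_pkg)
  p <- m_pkg$params
  rr <- reaction_rates(m_pkg, state = x)
  expect_equal(rr[["tc_vegfr1"]],
               hill_transcription(x[["nicd"]], p[["vmax_tc_vegfr1"]],
                                  p[["a_vegfr1_nicd"]], p[["m0_vegfr1_nicd"]]))
  expect_equal(rr[["tc_vegfr2"]],
               hill_repression(x[["nicd"]], p[["vmax_tc_vegfr2"]],
                               p[["a_vegfr2_nicd"]], p[["m0_vegfr2_nicd"]]))
  expect_equal(rr[["tc_notch1"]],
               p[["vmax_tc_notch1"]] *
                 hill_transcription(x[["nicd"]], 1, p[["a_notch1_nicd"]],
                                    p[["m0_notch1_nicd"]]) *
                 hill_transcription(x[["notch1"]], 1, p[["a_notch1_auto"]],
                                    p[["m0_notch1_auto"]]))
  expect_error(reaction_rates(m_pkg, dll4_nb = -1), ">= 0")
})

test_that("a single Euler step integrates pure degradation exactly", {
  # an isolated species decaying at k = 0.01/h from 100 gives 99 after 1 h
  x <- euler_step(m_pkg, state = c(cis_complex = 100, nicd = 0,
                                   notch1 = 0, dll4 = 0),
                  dt = 1, params = c(k_deg_cis = 0.01, kc = 0, kt = 0),
                  max_halvings = 0)
  expect_equal(x[["cis_complex"]], 99)
  # dt = 0 is the identity
  x0 <- angiosprout:::model_initial_state(m_pkg)
  expect_equal(euler_step(m_pkg, dt = 0), x0)
})

test_that("states remain non-negative along trajectories", {
  set.seed(5)
  for (i in 1:5) {
    x0 <- angiosprout:::model_initial_state(m_pkg)
    jitter <- stats::rlnorm(length(x0), 0, 0.5)
    x <- angiosprout:::prep_state(m_pkg, x0 * jitter)
    sim <- simulate_cell(m_pkg, state = x, t_end = 30, dt = 0.1,
                         dll4_nb = runif(1, 0, 3000),
                         vegf_local = runif(1, 0, 1e5))
    expect_true(all(sim$state >= 0))
    expect_true(all(is.finite(sim$state)))
  }
})

test_that("the isolated-cell steady state matches an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  sim <- simulate_cell(m_pkg, t_end = 500, dt = 0.1, dll4_nb = 0,
                       vegf_local = 0, record_every = 100)
  eul <- sim$state[nrow(sim$state), ode_species]
  orc <- final_states(oracle_run(m_pkg, n = 1, vegf_bath = 0, t_end = 500), 1)[1, ]
  rel <- abs(eul - orc) / pmax(abs(orc), 1e-8)
  expect_lt(max(rel[orc > 1]), 1e-3)   # < 0.1% per variable
  # and under a VEGF bath
  simv <- simulate_cell(m_pkg, t_end = 500, dt = 0.1, vegf_local = 9e4,
                        record_every = 100)
  eulv <- simv$state[nrow(simv$state), ode_species]
  orcv <- final_states(oracle_run(m_pkg, n = 1, vegf_bath = 9e4,
                                  t_end = 500), 1)[1, ]
  relv <- abs(eulv - orcv) / pmax(abs(orcv), 1e-8)
  expect_lt(max(relv[orcv > 1]), 1e-3)
})

test_that("forward Euler converges to the reference at order about one", {
  skip_if_not_installed("deSolve")
  # short transient far from equilibrium, at a VEGF level where no reaction
  # flux is clipped (clipping makes the scheme piecewise and masks the order)
  ref <- oracle_run(m_pkg, n = 1, vegf_bath = 2000, t_end = 4, dt_out = 4)
  xr <- final_states(ref, 1)[1, ]
  dts <- c(0.4, 0.2, 0.1, 0.05)
  errs <- vapply(dts, function(dt) {
    sim <- simulate_cell(m_pkg, t_end = 4, dt = dt, vegf_local = 2000,
                         record_every = max(1, round(4 / dt)),
                         max_halvings = 0)
    xe <- sim$state[nrow(sim$state), ode_species]
    sqrt(mean(((xe - xr) / pmax(abs(xr), 1))^2))
  }, 1)
  expect_true(all(diff(errs) < 0))  # error shrinks with dt
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.7 & orders < 1.3))
})

test_that("two coupled cells diverge to opposite fates from a 1% perturbation", {
  fx <- make_fixture("two_cell", perturb = 0, seed = 1)
  fx$states[1, "notch1"] <- fx$states[1, "notch1"] * 1.01
  res <- simulate_cells(fx, t_end = 400, dt = 0.1, vegf_bath = 9e4)
  f <- res$final
  r2 <- f[, "vegfr2_mRNA"]; r1 <- f[, "vegfr1_mRNA"]
  expect_equal(sum(r2 > r1), 1)       # exactly one tip-like cell
  expect_equal(sum(r1 > r2), 1)
  hi <- which.max(r2); lo <- which.min(r2)
  expect_gt(r2[hi] / max(r2[lo], 1e-9), 3)  # strong contrast
  expect_gt(f[lo, "nicd"], f[hi, "nicd"])   # inhibited cell holds the NICD
  skip_if_not_installed("deSolve")
  orc <- final_states(oracle_run(m_pkg, n = 2, neighbors = list(2L, 1L),
                                 vegf_bath = 9e4, t_end = 400,
                                 states = fx$states[, ode_species]), 2)
  expect_equal(sum(orc[, "vegfr2_mRNA"] > orc[, "vegfr1_mRNA"]), 1)
})

test_that("a 1-D ring patterns into alternating high/low vegfr2 fates", {
  for (n in c(4, 6)) {
    fx <- make_fixture("ring_n", n = n, perturb = 0.02, seed = n)
    res <- simulate_cells(fx, t_end = 400, dt = 0.1, vegf_bath = 9e4)
    r2 <- res$final[, "vegfr2_mRNA"]
    thr <- sqrt(max(r2) * min(r2))  # geometric midpoint separates the fates
    states <- r2 > thr
    expect_gt(max(r2) / min(r2), 3)
    # alternation: no two adjacent cells share the high fate
    high <- which(states)
    for (i in high) {
      nb <- c(if (i == 1) n else i - 1, if (i == n) 1 else i + 1)
      expect_true(all(!states[nb]))
    }
  }
})

test_that("removing trans binding (kt = 0) abolishes NICD production", {
  m_ko <- ec_model(params = c(kt = 0))
  fx <- make_fixture("two_cell", perturb = 0.01, seed = 2, model = m_ko)
  res <- simulate_cells(fx, t_end = 300, dt = 0.1, vegf_bath = 9e4)
  expect_lt(max(res$final[, "nicd"]), 1e-6)
  expect_lt(max(res$final[, "trans_complex"]), 1e-6)
  # both cells escape inhibition: no stalk fate remains
  expect_true(all(res$final[, "vegfr2_mRNA"] > res$final[, "vegfr1_mRNA"]))
})

test_that("state and parameter contracts are enforced", {
  expect_error(euler_step(m_pkg, state = c(nicd = -5)), ">= 0")
  expect_error(euler_step(m_pkg, state = rep(1, 5)), "21 variables")
  expect_error(reaction_rates(m_pkg, params = c(bogus = 1)), "unknown")
})
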