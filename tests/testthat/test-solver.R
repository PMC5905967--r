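# Numerical solver: fixed points, conservation, linearity, stability.

test_that("with all rates zero the steady erythrocyte count is S0 * T_RBC", {
  p <- patient_parameters(T_RBC = 100, S0 = 1e9,
                          constants = transport_constants())
  ss <- steady_state(p, E_const = 10)
  expect_equal(total_rbc(ss), 1e9 * 100, tolerance = 1e-12)
  p0 <- patient_parameters(S0 = 0, constants = transport_constants())
  expect_equal(total_rbc(steady_state(p0, 10)), 0)
  expect_true(all(unlist(lapply(steady_state(p0, 10)$classes,
                                `[[`, "density")) == 0))
})

test_that("the discrete solver holds the analytic steady profile to machine precision", {
  p <- ref_params()
  prof <- ref_profile()
  p$S0 <- calibrate_stem_influx(p, prof, 14.5)
  ss <- steady_state(p, p$E_endo)
  sim <- simulate_erythropoiesis(p, prof, t_end = 150, init_state = ss)
  expect_lt(max(abs(sim$rbc / sim$rbc[1] - 1)), 1e-10)
  for (k in 1:5) {
    rel <- sim$state$classes[[k]]$density / ss$classes[[k]]$density - 1
    expect_lt(max(abs(rel)), 1e-10)
  }
})

test_that("steady-state persistence also holds below the neocytolysis threshold", {
  # endogenous EPO under E_neo: the piecewise profile must still be a
  # fixed point of the solver
  p <- patient_parameters(T_RBC = 90, E_endo = 3)
  prof <- ref_profile()
  p$S0 <- calibrate_stem_influx(p, prof, 9)
  ss <- steady_state(p, 3)
  sim <- simulate_erythropoiesis(p, prof, t_end = 60, init_state = ss)
  expect_lt(max(abs(sim$rbc / sim$rbc[1] - 1)), 1e-10)
})

test_that("pure transport conserves cells until the pulse reaches the boundary", {
  p <- patient_parameters(T_RBC = 120, S0 = 0,
                          constants = transport_constants())
  st <- pulse_state(p, center = 60, width = 5)
  prof <- ref_profile()
  # keep the (numerically diffused) pulse well clear of the boundary
  sim <- simulate_erythropoiesis(p, prof, t_end = 25, init_state = st,
                                 dmu = 0.25, dmu_ery = 0.5)
  expect_lt(max(abs(sim$rbc / sim$rbc[1] - 1)), 1e-8)
  # after the pulse exits at the lifespan boundary the count drops to ~0
  sim2 <- simulate_erythropoiesis(p, prof, t_end = 100, init_state = st,
                                  dmu = 0.25, dmu_ery = 0.5)
  expect_lt(sim2$rbc[length(sim2$rbc)], 1e-2 * sim2$rbc[1])
})

test_that("the simulation is exactly linear in the stem-cell influx", {
  prof <- ref_profile()
  doses <- data.frame(time = c(0, 7, 14), dose = c(3000, 3000, 1500))
  p1 <- ref_params(S0 = 2e9)
  p2 <- ref_params(S0 = 4e9)
  s1 <- simulate_erythropoiesis(p1, prof, doses = doses, t_end = 60)
  s2 <- simulate_erythropoiesis(p2, prof, doses = doses, t_end = 60)
  expect_equal(s2$rbc, 2 * s1$rbc, tolerance = 1e-12)
})

test_that("a transfusion raises the count by exactly units * 473 * 5e9 cells", {
  p <- ref_params()
  prof <- ref_profile()
  p$S0 <- calibrate_stem_influx(p, prof, 10)
  ev <- blood_event("transfusion", time = 20, units = 2)
  sim <- simulate_erythropoiesis(p, prof, events = list(ev), t_end = 40)
  jump <- diff(sim$rbc)
  expect_equal(max(jump), 2 * 473 * 5e9, tolerance = 1e-9)
})

test_that("violating the CFL bound raises an error", {
  p <- ref_params(S0 = 1e9)
  st <- steady_state(p, 10)
  expect_error(advance(st, dt = 1, E_total = 10, p = p), "CFL")
  expect_silent(advance(st, dt = 0.05, E_total = 10, p = p))
})

test_that("one advance step with near-zero velocity decays cells at e^(-alpha dt)", {
  cst <- transport_constants()
  cst$alpha_ret <- 0.3
  cst$v_min <- 1e-6          # reticulocyte velocity ~ 0 at E = 0
  p <- patient_parameters(s_v = 0, S0 = 0, constants = cst)
  st <- pulse_state(p)
  st$classes[[4]]$density <- rep(1e9, length(st$classes[[4]]$grid))
  st2 <- advance(st, dt = 0.1, E_total = 0, p = p)
  interior <- 2:(length(st2$classes[[4]]$density) - 1)
  expect_equal(st2$classes[[4]]$density[interior],
               rep(1e9 * exp(-0.3 * 0.1), length(interior)),
               tolerance = 1e-6)
})

test_that("boundary influx chains the classes by the maturity flux", {
  p <- ref_params(S0 = 5e8)
  st <- steady_state(p, 10)
  expect_equal(boundary_influx(1, st, 10, p), 5e8)
  for (k in 2:5) {
    up <- st$classes[[k - 1]]
    v <- maturation_velocity(up$name, 10, p)
    expect_equal(boundary_influx(k, st, 10, p),
                 v * up$density[length(up$density)])
  }
  st$classes[[4]]$density[] <- 0
  expect_equal(boundary_influx(5, st, 10, p), 0)
})

test_that("a large ESA dose raises the count after a marrow transit delay", {
  p <- ref_params()
  prof <- ref_profile()
  p$S0 <- calibrate_stem_influx(p, prof, 10)
  dose <- data.frame(time = 1, dose = 20000)
  sim <- simulate_erythropoiesis(p, prof, doses = dose, t_end = 80)
  base <- sim$rbc[1]
  # nothing happens before the dose; afterwards the count rises (the
  # reticulocyte flush is fast, the progenitor wave follows over weeks)
  rel <- sim$rbc / base - 1
  expect_lt(abs(rel[which.min(abs(sim$times - 0.9))]), 1e-9)
  expect_gt(max(rel), 0.02)
  expect_gt(sim$times[which.max(rel)], 5)
})
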