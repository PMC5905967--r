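# Rate functions, EPO kinetics and blood-event bookkeeping.

test_that("CFU-E apoptosis decreases exponentially in EPO between its bounds", {
  p <- ref_params()
  cst <- p$constants
  expect_equal(apoptosis_rate("CFU_E", 1e9, p = p), cst$alpha_min,
               tolerance = 1e-12)
  expect_equal(apoptosis_rate("CFU_E", 0, p = p), cst$alpha_max)
  # at E = 1/s_alpha the exponential term is exactly 1/e
  expect_equal(apoptosis_rate("CFU_E", 1 / p$s_alpha, p = p),
               cst$alpha_min + (cst$alpha_max - cst$alpha_min) / exp(1))
  E <- seq(0, 200, by = 0.5)
  a <- apoptosis_rate("CFU_E", E, p = p)
  expect_true(all(diff(a) <= 0))
  expect_true(all(is.finite(a)) && all(a >= 0))
})

test_that("non-CFU-E classes have constant apoptosis rates", {
  p <- ref_params()
  expect_equal(apoptosis_rate("BFU_E", c(0, 50), p = p), rep(0.02, 2))
  expect_equal(apoptosis_rate("erythroblast", 7, p = p), 0.02)
  expect_equal(apoptosis_rate("marrow_reticulocyte", 7, p = p), 0)
  expect_error(apoptosis_rate("megakaryocyte", 7, p = p), "unknown")
})

test_that("proliferation rates are constant in EPO and zero for erythrocytes", {
  p <- ref_params()
  expect_equal(proliferation_rate("erythrocyte", 123, p), 0)
  expect_equal(proliferation_rate("CFU_E", 10, p),
               proliferation_rate("CFU_E", 100, p))
  expect_equal(proliferation_rate("erythroblast", 5, p), 0.7)
  expect_error(proliferation_rate("stem_cell", 5, p), "unknown")
})

test_that("reticulocyte velocity rises linearly with EPO up to its cap", {
  p <- ref_params()
  cst <- p$constants
  expect_equal(maturation_velocity("marrow_reticulocyte", 0, p), cst$v_min)
  expect_equal(maturation_velocity("marrow_reticulocyte", 1e6, p), cst$v_max)
  expect_equal(maturation_velocity("marrow_reticulocyte", 10, p),
               cst$v_min + p$s_v * 10)
  expect_equal(maturation_velocity("BFU_E", c(0, 99), p), c(1, 1))
  E <- seq(0, 100, by = 1)
  v <- maturation_velocity("marrow_reticulocyte", E, p)
  expect_true(all(diff(v) >= 0) && all(v > 0))
})

test_that("neocytolysis hits only young cells below the EPO threshold", {
  p <- ref_params()
  cst <- p$constants
  expect_equal(neocytolysis_rate(cst$E_neo, 5, p), 0)
  expect_equal(neocytolysis_rate(0, cst$mu_neo, p), cst$alpha_neo)
  expect_equal(neocytolysis_rate(0, cst$mu_neo + 1, p), 0)
  expect_equal(neocytolysis_rate(cst$E_neo / 2, 3, p), cst$alpha_neo / 2)
  expect_equal(neocytolysis_rate(2 * cst$E_neo, 3, p), 0)
})

test_that("EPO concentration follows the closed-form bolus elimination", {
  prof <- patient_profile("male", 180, 4 / erythroid_defaults()$Vd_per_kg)
  expect_equal(prof$V_d, 4)
  p <- patient_parameters(E_endo = 7, t_half = 8)
  no_doses <- data.frame(time = numeric(0), dose = numeric(0))
  expect_equal(epo_concentration(c(0, 5, 80), no_doses, p, prof),
               rep(7, 3))
  # one half-life after a dose, half the initial concentration remains
  d <- data.frame(time = 2, dose = 4000)
  expect_equal(epo_concentration(2 + 8 / 24, d, p, prof), 7 + 1000 / 2)
  # 1 day = 3 half-lives at t_half = 8 h
  d2 <- data.frame(time = 0, dose = 8000)
  expect_equal(epo_concentration(1, d2, p, prof), 7 + 2000 * 2^-3)
  bad <- p; bad$t_half <- -1
  expect_error(epo_concentration(1, d2, bad, prof), "positive")
})

test_that("EPO closed form agrees with a numerical ODE integration", {
  # independent oracle: integrate dE/dt = -(ln2 * 24 / t_half) E with bolus
  # jumps using deSolve and compare on a fine grid
  prof <- ref_profile()
  p <- patient_parameters(E_endo = 9, t_half = 6.3)
  doses <- data.frame(time = c(0.5, 2.5, 4.75), dose = c(3000, 1500, 5000))
  lambda <- log(2) * 24 / p$t_half
  # evaluation grid avoids the exact dose instants, where the two
  # conventions (pre/post event) differ by construction
  ode_out <- suppressWarnings(deSolve::ode(
    y = c(E = 0), times = seq(0.001, 7, by = 0.01),
    func = function(t, y, parms) list(-lambda * y),
    events = list(data = data.frame(var = "E", time = doses$time,
                                    value = doses$dose / prof$V_d,
                                    method = "add"))))
  keep <- !(ode_out[, "time"] %in% doses$time)
  closed <- epo_concentration(ode_out[keep, "time"], doses, p, prof) -
    p$E_endo
  expect_equal(closed, unname(ode_out[keep, "E"]), tolerance = 1e-6)
})

test_that("one transfused unit adds 23.65e11 cells, exactly and only to erythrocytes", {
  p <- ref_params(S0 = 1e9)
  st <- steady_state(p, p$E_endo)
  ev <- blood_event("transfusion", time = 0, units = 1)
  st2 <- apply_blood_event(st, ev, TBV = 5)
  expect_equal(total_rbc(st2) - total_rbc(st), 23.65e11, tolerance = 1e-12)
  expect_equal(st2$total_counts[1:4], st$total_counts[1:4])
  for (k in 1:4)
    expect_identical(st2$classes[[k]]$density, st$classes[[k]]$density)
  # arbitrary volumes scale linearly
  ev2 <- blood_event("transfusion", time = 0, units = 1,
                     unit_volume_ml = 100)
  expect_equal(total_rbc(apply_blood_event(st, ev2, 5)) - total_rbc(st),
               5e11, tolerance = 1e-12)
})

test_that("bleeds scale the erythrocyte class by the lost volume fraction", {
  p <- ref_params(S0 = 1e9)
  st <- steady_state(p, p$E_endo)
  expect_equal(apply_blood_event(st, blood_event("bleed", 0, volume_ml = 0),
                                 5)$classes[[5]]$density,
               st$classes[[5]]$density)
  st2 <- apply_blood_event(st, blood_event("bleed", 0, volume_ml = 500), 5)
  expect_equal(total_rbc(st2), total_rbc(st) * (1 - 500 / 5000))
  expect_equal(st2$total_counts[1:4], st$total_counts[1:4])
  expect_error(apply_blood_event(st, blood_event("bleed", 0,
                                                 volume_ml = 6000), 5),
               "exceeds")
})
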