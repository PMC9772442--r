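# structural model: closed forms, ODE oracle, steady state, derived scalars

p_def <- default_structural_params()
reg50 <- pk_regimen(dose_event(0, 50))

test_that("initial condition: dose sits in the depot, central compartments empty", {
  a0 <- amounts_ode(p_def, reg50, 0)
  expect_equal(a0$depot, 50)
  expect_equal(a0$ven, 0)
  expect_equal(a0$odv, 0)
  expect_equal(conc_parent(p_def, reg50, 0), 0)
  expect_equal(conc_metabolite(p_def, reg50, 0), 0)
})

test_that("amounts match a Richardson-extrapolated RK4 reference at 2 h", {
  ref <- rk4_richardson(p_def, 0, 50, 2)
  cf_ven <- conc_parent(p_def, reg50, 2) * p_def$v_f / 1000
  cf_odv <- conc_metabolite(p_def, reg50, 2) * p_def$vm_f / 1000
  expect_equal(cf_ven, ref[2], tolerance = 1e-8)
  expect_equal(cf_odv, ref[3], tolerance = 1e-8)
  ode <- amounts_ode(p_def, reg50, 2)
  expect_equal(ode$depot, ref[1], tolerance = 1e-8)
  expect_equal(ode$ven, ref[2], tolerance = 1e-8)
  expect_equal(ode$odv, ref[3], tolerance = 1e-8)
})

test_that("complete pre-systemic conversion reduces the metabolite to a Bateman profile", {
  p <- structural_params(cl_f = 80.9, v_f = 628, clm_f = 22.1, vm_f = 238,
                         ka = 0.63, fp = 1)
  t <- c(0.5, 2, 8, 24)
  expect_equal(conc_parent(p, reg50, t), rep(0, 4))
  km <- derived_rates(p)[["km"]]
  expect_equal(conc_metabolite(p, reg50, t),
               1000 * bateman_amount(50, 0.63, km, t) / p$vm_f,
               tolerance = 1e-10)
})

test_that("closed form agrees with the ODE oracle over random parameter draws", {
  set.seed(42)
  for (i in 1:100) {
    mult <- exp(runif(6, log(0.25), log(4)))
    p <- structural_params(80.9 * mult[1], 628 * mult[2], 22.1 * mult[3],
                           238 * mult[4], 0.63 * mult[5],
                           min(0.048 * mult[6], 1))
    times <- sort(runif(20, 0.1, 48))
    ode <- amounts_ode(p, reg50, times, rtol = 1e-12, atol = 1e-12)
    cv <- conc_parent(p, reg50, times)
    co <- conc_metabolite(p, reg50, times)
    # denominator floored at 1e-6 x Cmax: below that the comparison is
    # limited by the integrator tolerance, not the closed form
    expect_lt(max(abs(cv - 1000 * ode$ven / p$v_f) /
                    pmax(abs(cv), 1e-6 * max(cv))), 1e-6)
    expect_lt(max(abs(co - 1000 * ode$odv / p$vm_f) /
                    pmax(abs(co), 1e-6 * max(co))), 1e-6)
  }
})

test_that("mass balance holds along the integrated trajectories", {
  reg <- pk_regimen(dose_event(0, 50), dose_event(12, 100, 6, 2))
  times <- seq(0.25, 60, by = 2.5)  # offset from dose times
  a <- amounts_ode(p_def, reg, times)
  administered <- 50 + 100 * pmin(pmax(floor((times - 12) / 6) + 1, 0), 3)
  expect_equal(a$depot + a$ven + a$odv + a$eliminated, administered,
               tolerance = 1e-9)
})

test_that("the system is linear: doubling the dose doubles every concentration", {
  reg2 <- pk_regimen(dose_event(0, 100))
  t <- c(1, 3, 7, 19, 30)
  expect_equal(conc_parent(p_def, reg2, t), 2 * conc_parent(p_def, reg50, t))
  expect_equal(conc_metabolite(p_def, reg2, t),
               2 * conc_metabolite(p_def, reg50, t))
})

test_that("superposing two regimens adds their predictions exactly", {
  regA <- pk_regimen(dose_event(0, 50))
  regB <- pk_regimen(dose_event(8, 75))
  regAB <- pk_regimen(dose_event(0, 50), dose_event(8, 75))
  t <- c(2, 9, 15, 40)
  for (an in c("VEN", "ODV"))
    expect_equal(predict_conc(p_def, regAB, t, an),
                 predict_conc(p_def, regA, t, an) +
                   predict_conc(p_def, regB, t, an))
})

test_that("times before the first dose predict zero, not an error", {
  reg <- pk_regimen(dose_event(10, 50))
  expect_equal(conc_parent(p_def, reg, c(0, 5, 9.9)), rep(0, 3))
  expect_equal(conc_metabolite(p_def, reg, c(0, 5)), rep(0, 2))
})

test_that("nearly equal absorption and elimination rates stay continuous (confluent limit)", {
  kp <- p_def$cl_f / p_def$v_f
  p_eq <- structural_params(p_def$cl_f, p_def$v_f, p_def$clm_f, p_def$vm_f,
                            ka = kp, fp = 0.048)
  p_near <- structural_params(p_def$cl_f, p_def$v_f, p_def$clm_f, p_def$vm_f,
                              ka = kp * (1 + 1e-9), fp = 0.048)
  t <- c(0.5, 2, 6, 12)
  expect_equal(conc_parent(p_eq, reg50, t), conc_parent(p_near, reg50, t),
               tolerance = 1e-7)
  # L'Hopital form: A1 = (1-fp) D ka t exp(-ka t)
  expect_equal(conc_parent(p_eq, reg50, t),
               1000 * (1 - 0.048) * 50 * kp * t * exp(-kp * t) / p_def$v_f,
               tolerance = 1e-9)
  ode <- amounts_ode(p_eq, reg50, t)
  expect_equal(conc_metabolite(p_eq, reg50, t), 1000 * ode$odv / p_def$vm_f,
               tolerance = 1e-7)
})

test_that("fast parent turnover makes the metabolite a pass-through Bateman profile", {
  # fp = 0, kp = 100 ka: parent acts as an instantaneous conduit, so ODV
  # looks like a drug absorbed at ka and eliminated at km (1% tolerance)
  ka <- 0.63
  v <- 628
  cl <- 100 * ka * v
  p <- structural_params(cl, v, 22.1, 238, ka, fp = 0)
  km <- derived_rates(p)[["km"]]
  t <- c(2, 6, 12, 24)
  lim <- 1000 * bateman_amount(50, ka, km, t) / 238
  expect_equal(conc_metabolite(p, reg50, t), lim, tolerance = 1e-2)
})

test_that("steady state reduces to the single dose when tau spans many half-lives", {
  # 50 half-lives of the slowest rate
  tau <- 50 * log(2) / min(derived_rates(p_def), p_def$ka)
  for (an in c("VEN", "ODV"))
    expect_equal(steady_state_conc(p_def, 50, tau, 6, an),
                 predict_conc(p_def, reg50, 6, an), tolerance = 1e-9)
})

test_that("steady-state trough equals brute-force superposition of 60 doses", {
  reg60 <- pk_regimen(dose_event(0, 150, interdose_interval = 24,
                                 n_additional_doses = 59))
  t_obs <- 59 * 24 + 24
  expect_equal(steady_state_conc(p_def, 150, 24, 24, "VEN"),
               conc_parent(p_def, reg60, t_obs), tolerance = 1e-6)
  expect_equal(steady_state_conc(p_def, 150, 24, 24, "ODV"),
               conc_metabolite(p_def, reg60, t_obs), tolerance = 1e-6)
})

test_that("accumulation at steady state is at least one", {
  for (an in c("VEN", "ODV")) {
    single <- predict_conc(p_def, reg50, 24, an)
    ss <- steady_state_conc(p_def, 50, 24, 24, an)
    expect_gte(ss / single, 1)
  }
})

test_that("steady-state VEN trough decreases strictly with clearance", {
  cls <- seq(20, 160, by = 20)
  troughs <- vapply(cls, function(cl) {
    p <- structural_params(cl, 628, 22.1, 238, 0.63, 0.048)
    steady_state_conc(p, 150, 24, 24, "VEN")
  }, 0)
  expect_true(all(diff(troughs) < 0))
})

test_that("a vanishing accumulation factor raises a numerical error", {
  expect_error(steady_state_conc(p_def, 50, 1e-14, 1e-14, "VEN"),
               "numerical error")
})

test_that("invalid structural parameters are rejected", {
  expect_error(structural_params(-1, 628, 22.1, 238, 0.63, 0.048),
               "strictly positive")
  expect_error(structural_params(80.9, 628, 22.1, 238, 0.63, 1.2), "fp")
  expect_error(structural_params(NaN, 628, 22.1, 238, 0.63, 0.5), "finite")
})

test_that("half-life and absorption time match the reported healthy-subject values", {
  expect_equal(round(elimination_half_life(p_def, "VEN"), 1), 5.4)
  expect_equal(elimination_half_life(p_def, "ODV"), log(2) * 238 / 22.1)
  expect_equal(round(mean_absorption_time(p_def), 1), 1.6)
  expect_equal(mean_absorption_time(structural_params(80.9, 628, 22.1, 238,
                                                      1, 0.048)), 1)
  # reciprocal scaling
  p_half <- structural_params(80.9, 628, 22.1, 238, 0.315, 0.048)
  expect_equal(mean_absorption_time(p_half), 2 * mean_absorption_time(p_def))
  # scale invariance of the half-life
  p_sc <- structural_params(2 * 80.9, 2 * 628, 2 * 22.1, 2 * 238, 0.63, 0.048)
  expect_equal(elimination_half_life(p_sc, "VEN"),
               elimination_half_life(p_def, "VEN"))
})

test_that("metabolite terminal slope reproduces the ODV half-life", {
  t_half <- elimination_half_life(p_def, "ODV")
  tt <- c(150, 170)  # deep terminal phase (faster phases decayed away)
  a <- amounts_ode(p_def, reg50, tt, rtol = 1e-12, atol = 1e-12)
  slope <- (log(a$odv[1]) - log(a$odv[2])) / (tt[2] - tt[1])
  expect_equal(log(2) / slope, t_half, tolerance = 5e-3)
})
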