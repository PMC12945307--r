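test_that("the basal state is an exact fixed point of the model", {
  p <- truth_params()
  d <- twin_derivative(basal_state(p), t = 0, p, basal_forcing(p))
  expect_equal(unname(d), rep(0, 6), tolerance = 1e-12)

  # and the simulated trajectory stays there
  tr <- twin_simulate(p, basal_forcing(p, n = 200L))
  expect_lt(max(abs(tr$G - p$Gb)), 1e-6 * p$Gb)
  expect_lt(max(abs(tr$I - p$Ib)), 1e-6 * max(p$Ib, 1))
})

test_that("the initial-condition identity Ib = (p4/n) u1b holds at construction", {
  p <- patient_params(n = 0.1, p4 = 0.075, u1b = 10,
                      xref = c(n = 0.1, VolG = 117, p1 = 0.035, p2 = 0.05,
                               p3 = 2.8e-5, p4 = 0.075, a1 = 0.00158,
                               a2 = 0.056, a3 = 0.00195, a4 = 0.0485,
                               a5 = 0.00125, a6 = 0.075))
  expect_equal(p$Ib, 0.075 / 0.1 * 10)
})

test_that("meal forcing enters only the glucose balance, linearly", {
  p <- truth_params()
  f0 <- basal_forcing(p, n = 10L)
  f1 <- forcing_set(f0$u1, uniform_series(rep(0.2, 10), 0, 5, "g/min"),
                    f0$u3)
  f2 <- forcing_set(f0$u1, uniform_series(rep(0.4, 10), 0, 5, "g/min"),
                    f0$u3)
  s <- basal_state(p)
  d0 <- twin_derivative(s, 10, p, f0)
  d1 <- twin_derivative(s, 10, p, f1)
  d2 <- twin_derivative(s, 10, p, f2)
  expect_equal(d1[-3], d0[-3])
  expect_equal(d2[["G"]] - d0[["G"]], 2 * (d1[["G"]] - d0[["G"]]))
  expect_equal(d1[["G"]] - d0[["G"]],
               0.2 * 1000 / param_value(p, "VolG"), tolerance = 1e-12)
})

test_that("a single meal raises glucose after the meal and relaxes back toward basal", {
  p <- truth_params()
  n <- 1440 / 5
  grid <- time_grid(0, 1440, dt = 5)
  u2 <- meals_to_u2(event_records("meal", 240, 60), grid)
  f <- forcing_set(uniform_series(rep(p$u1b, n), 0, 5), u2,
                   uniform_series(numeric(n), 0, 5))
  tr <- twin_simulate(p, f)
  expect_gt(max(tr$G), p$Gb + 20)
  expect_gt(tr$t_min[which.max(tr$G)], 240)
  expect_lt(abs(tail(tr$G, 1) - p$Gb), 12)
})

test_that("after an exercise bout the exercise states decay as pure exponentials", {
  p <- truth_params()
  n <- 600 / 5
  u3v <- numeric(n); u3v[13:24] <- 30   # bout on [60, 120)
  f <- forcing_set(uniform_series(rep(p$u1b, n), 0, 5),
                   uniform_series(numeric(n), 0, 5),
                   uniform_series(u3v, 0, 5))
  tr <- twin_simulate(p, f, rtol = 1e-10, atol = 1e-10)
  expect_gt(max(tr$Gup), 0)
  expect_gt(max(tr$Gprod), 0)
  # decay from t1 = 180 (u3 is zero from 120 + interpolation ramp)
  i0 <- which(tr$t_min == 180)
  idx <- tr$t_min >= 180
  dt_rel <- tr$t_min[idx] - 180
  a2 <- param_value(p, "a2"); a4 <- param_value(p, "a4")
  a6 <- param_value(p, "a6")
  expect_equal(tr$Gprod[idx], tr$Gprod[i0] * exp(-a2 * dt_rel),
               tolerance = 1e-6)
  expect_equal(tr$Gup[idx], tr$Gup[i0] * exp(-a4 * dt_rel),
               tolerance = 1e-6)
  expect_equal(tr$Ie[idx], tr$Ie[i0] * exp(-a6 * dt_rel),
               tolerance = 1e-6)
})

test_that("solver tolerance refinement converges (step-halving analogue)", {
  p <- truth_params()
  sc <- make_scenario(5, duration_days = 1)
  tr1 <- twin_simulate(p, sc$forcing, rtol = 1e-6, atol = 1e-6)
  tr2 <- twin_simulate(p, sc$forcing, rtol = 1e-9, atol = 1e-9)
  tr3 <- twin_simulate(p, sc$forcing, rtol = 1e-8, atol = 1e-8)
  expect_lt(max(abs(tr1$G - tr2$G)), 0.01)
  expect_lt(max(abs(tr3$G - tr2$G)), max(abs(tr1$G - tr2$G)))
})

test_that("increasing the bolus dose never raises the glucose minimum", {
  p <- truth_params()
  grid <- time_grid(0, 1440, dt = 5)
  n <- length(grid$values)
  u2 <- meals_to_u2(event_records("meal", 240, 60), grid)
  gmin <- vapply(c(0, 2000, 4000, 8000), function(dose) {
    bol <- if (dose > 0) event_records("bolus", 240, dose, mode = "normal")
           else NULL
    basal <- event_records("basal", 0, p$u1b, t_end = 1440)
    u1 <- total_insulin_rate(basal, NULL, bol, grid)
    f <- forcing_set(u1, u2, uniform_series(numeric(n), 0, 5))
    min(twin_simulate(p, f)$G)
  }, numeric(1))
  expect_true(all(diff(gmin) <= 1e-8))
})

test_that("time-varying parameters are honoured by the simulator", {
  xref <- reference_params()
  n_series <- uniform_series(rep(c(xref[["n"]], 1.5 * xref[["n"]]),
                                 each = 50), 0, 5)
  p <- patient_params(n = n_series)
  f <- basal_forcing(p, n = 100L)
  tr <- twin_simulate(p, f)
  # when n doubles mid-record the basal balance breaks and I falls
  expect_lt(min(tr$I), p$Ib * 0.9)
  expect_equal(tr$I[1], p$Ib)
})

test_that("ground-truth parameter tables round-trip exactly", {
  p <- truth_params()
  path <- tempfile(fileext = ".csv")
  write_ground_truth(p, path)
  q <- read_ground_truth(path)
  for (nm in c("n", "VolG", "p1", "p2", "p3", "p4",
               "a1", "a2", "a3", "a4", "a5", "a6")) {
    expect_identical(q$kinetic[[nm]], p$kinetic[[nm]])
  }
  expect_identical(q$W, p$W)
  expect_identical(q$Gb, p$Gb)

  # time-varying and clamped-at-bound parameters survive the round trip
  xref <- reference_params()
  pv <- patient_params(
    p1 = uniform_series(seq(0.8, 1.2, length.out = 10) * xref[["p1"]], 0, 60),
    a6 = 0.2 * xref[["a6"]])
  path2 <- tempfile(fileext = ".csv")
  write_ground_truth(pv, path2)
  qv <- read_ground_truth(path2)
  expect_identical(qv$kinetic$p1$values, pv$kinetic$p1$values)
  expect_identical(qv$kinetic$a6, 0.2 * xref[["a6"]])
})

test_that("parameters outside the admissible box are rejected", {
  xref <- reference_params()
  expect_error(patient_params(n = 2 * xref[["n"]]), "box")
  expect_error(patient_params(n = -0.1), "positive")
})

test_that("scenario generation is deterministic and respects meal bounds", {
  a <- make_scenario(42, duration_days = 7)
  b <- make_scenario(42, duration_days = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$forcing$u1$values, b$forcing$u1$values)
  meals <- a$events[a$events$kind == "meal", ]
  per_day <- table(floor(meals$t_start / 1440))
  expect_true(all(per_day >= 2 & per_day <= 4))
  expect_true(all(meals$value >= 15 & meals$value <= 150))
  # different seeds differ
  expect_false(identical(make_scenario(43, duration_days = 7)$events,
                         a$events))
})

test_that("underdosed scenarios produce hyperglycemic excursions on the twin", {
  p <- patient_params(Gb = 155)
  sc <- make_scenario(21, duration_days = 2,
                      cfg = scenario_config(dose_fraction = 0.5))
  sim <- simulate_patient(sc, p)
  expect_gt(sum(sim$table$G > 180), 0)
})
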