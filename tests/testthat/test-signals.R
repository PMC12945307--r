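test_that("normal and square boluses rasterize to the documented rates and conserve dose", {
  g <- time_grid(0, 120, dt = 1)

  r <- bolus_to_rate(event_records("bolus", 0, 500, mode = "normal")[1, ], g)
  expect_equal(r$values[1:10], rep(50, 10))
  expect_equal(r$values[11:120], rep(0, 110))
  expect_equal(sum(r$values) * 1, 500, tolerance = 1e-9)

  r <- bolus_to_rate(
    event_records("bolus", 0, 600, t_end = 60, mode = "square")[1, ], g)
  expect_equal(r$values[1:60], rep(10, 60))
  expect_equal(sum(r$values), 600, tolerance = 1e-9)

  # zero dose, any mode
  r0 <- bolus_to_rate(event_records("bolus", 5, 0, mode = "normal")[1, ], g)
  expect_true(all(r0$values == 0))

  # conservation holds on misaligned grids too (cell averaging)
  g7 <- time_grid(0, 119, dt = 7)
  r7 <- bolus_to_rate(event_records("bolus", 3, 500, mode = "normal")[1, ], g7)
  expect_equal(sum(r7$values) * 7, 500, tolerance = 1e-9)
})

test_that("dual-mode boluses split the dose 50/50 and conserve it; strict mode reproduces the literal profile", {
  g <- time_grid(0, 200, dt = 1)
  for (mode in c("normal_dual", "square_dual")) {
    rec <- event_records("bolus", 10, 800, t_end = 90, mode = mode)[1, ]
    r <- bolus_to_rate(rec, g)
    expect_equal(sum(r$values), 800, tolerance = 1e-9)
    # each half-interval delivers half the dose
    mid <- (10 + 90) / 2
    tt <- series_times(g)
    first <- sum(r$values[tt < mid])
    expect_equal(first, 400, tolerance = 1e-9)
  }
  # strict literal profile: normal half released at 0.5 x / 10 over the whole
  # half-interval, which over-delivers when the half-interval exceeds 10 min
  rec <- event_records("bolus", 0, 800, t_end = 80, mode = "normal_dual")[1, ]
  rs <- bolus_to_rate(rec, g, strict = TRUE)
  expect_equal(rs$values[1], 0.5 * 800 / 10)
  expect_gt(sum(rs$values), 800)
  # when the half-interval is exactly 10 min the two readings coincide
  rec10 <- event_records("bolus", 0, 800, t_end = 20, mode = "normal_dual")[1, ]
  expect_equal(bolus_to_rate(rec10, g)$values,
               bolus_to_rate(rec10, g, strict = TRUE)$values)
})

test_that("invalid bolus records are rejected", {
  g <- time_grid(0, 60, dt = 5)
  expect_error(event_records("bolus", 0, -5, mode = "normal"),
               "non-negative")
  expect_error(event_records("bolus", 0, 100), "mode")
  rec <- event_records("bolus", 30, 100, t_end = 40, mode = "square")[1, ]
  rec$t_end <- 20  # corrupt after validation
  expect_error(bolus_to_rate(rec, g), "t_end")
})

test_that("total insulin rate adds components and temp-basal overrides the bolus term", {
  g <- time_grid(0, 60, dt = 1)
  basal <- event_records("basal", 0, 10, t_end = 60)
  expect_equal(total_insulin_rate(basal, grid = g)$values, rep(10, 60))

  boluses <- event_records("bolus", 0, 500, mode = "normal")
  u1 <- total_insulin_rate(basal, boluses = boluses, grid = g)
  expect_equal(u1$values[1:10], rep(60, 10))
  expect_equal(u1$values[11:60], rep(10, 50))

  # a bolus inside a temp-basal window is suppressed; basal persists
  tb <- event_records("temp_basal", 0, 5, t_end = 30)
  u1 <- total_insulin_rate(basal, tb, boluses, g)
  expect_equal(u1$values[1:30], rep(15, 30))
  expect_equal(u1$values[31:60], rep(10, 30))

  expect_error(
    total_insulin_rate(basal,
                       event_records("temp_basal", c(0, 20), 5,
                                     t_end = c(30, 50)), boluses, g),
    "overlapping temp-basal")
  expect_error(
    total_insulin_rate(event_records("basal", c(0, 20), 10,
                                     t_end = c(30, 60)), grid = g),
    "overlapping basal")
})

test_that("meal signal follows the exponential-decay kernel and conserves carbohydrate mass", {
  g <- time_grid(0, 3000, dt = 1)
  m <- event_records("meal", 10, 50)
  u2 <- meals_to_u2(m, g)
  tt <- series_times(g)
  expect_equal(u2$values[tt < 10], rep(0, sum(tt < 10)))
  expect_equal(u2$values[tt == 10], 0.0083 * 50)
  # decay rate recovered by log-linear fit
  on <- tt >= 10 & tt <= 210
  fit <- lm(log(u2$values[on]) ~ tt[on])
  expect_equal(unname(coef(fit)[2]), -0.0083, tolerance = 1e-9)
  # carb conservation within 1% over a horizon >= 10 / 0.0083 min
  integral <- sum((u2$values[-1] + u2$values[-length(u2$values)]) / 2)
  expect_equal(integral, 50, tolerance = 0.01)
  # superposition of several meals
  m3 <- event_records("meal", c(0, 300, 800), c(30, 60, 45))
  u23 <- meals_to_u2(m3, g)
  integral3 <- sum((u23$values[-1] + u23$values[-length(u23$values)]) / 2)
  expect_equal(integral3, 135, tolerance = 0.015)
  expect_error(meals_to_u2(data.frame(kind = "meal", t_start = 0,
                                      t_end = NA, value = -1,
                                      mode = NA), g), "negative")
})

test_that("heart-rate conversion matches the linear PVO2max relation with basal clamping", {
  hr <- uniform_series(c(90, 60, 100, 130), 0, 5, "bpm")
  out <- heart_rate_to_u3(hr)
  expect_equal(out$pvo2max$values, 0.888 * c(90, 60, 100, 130) - 71.91)
  expect_equal(out$u3$values[1], 0.01, tolerance = 1e-12)
  expect_equal(out$u3$values[2], 0)   # clamp branch
  expect_equal(out$u3$values[3], 8.89, tolerance = 1e-12)
  # monotone non-decreasing in HR
  hr_grid <- uniform_series(seq(40, 200, by = 0.5), 0, 1, "bpm")
  u3 <- heart_rate_to_u3(hr_grid)$u3$values
  expect_true(all(diff(u3) >= 0))
  expect_true(all(u3 >= 0))
})

test_that("alignment trims to the common span, interpolates gaps, and flags long CGM gaps", {
  a <- uniform_series(1:10, t0 = 0, dt = 10)
  b <- uniform_series(rep(5, 10), t0 = 30, dt = 10)
  out <- impute_and_align(list(x = a, y = b), target_dt = 10,
                          flag_gaps = character(0))
  expect_equal(out$x$t0, 30)
  expect_equal(series_times(out$x), series_times(out$y))
  expect_equal(max(series_times(out$x)), 90)
  # identical grids pass through unchanged
  out2 <- impute_and_align(list(x = a), target_dt = 10,
                           flag_gaps = character(0))
  expect_equal(out2$x$values, a$values)

  # linear interpolation across a 2-point gap
  hr <- data.frame(t = c(0, 10, 40, 50), value = c(80, 80, 110, 110))
  out3 <- impute_and_align(list(hr = hr), target_dt = 10,
                           flag_gaps = character(0))
  expect_equal(out3$hr$values, c(80, 80, 90, 100, 110, 110))

  # long CGM gaps are flagged, not trusted
  cgm <- data.frame(t = c(seq(0, 60, 5), seq(180, 240, 5)),
                    value = 120)
  out4 <- impute_and_align(list(cgm = cgm), target_dt = 5,
                           flag_gaps = "cgm", gap_threshold = 60)
  gap <- attr(out4$cgm, "gap")
  tt <- series_times(out4$cgm)
  expect_true(all(gap[tt > 60 & tt < 180]))
  expect_false(any(gap[tt < 60]))
})

test_that("rasterized forcing signals are non-negative", {
  g <- time_grid(0, 1440, dt = 5)
  sc <- make_scenario(3, duration_days = 1)
  expect_true(all(sc$forcing$u1$values >= 0))
  expect_true(all(sc$forcing$u2$values >= 0))
  expect_true(all(sc$forcing$u3$values >= 0))
})
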