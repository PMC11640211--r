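# Energy balance, required rate, stage ladder, pad hysteresis, and the
# exception precedence of the heat-balance controller.

test_that("ventilation heat requirement is the linear energy balance", {
  cfg <- tiny_cfg()
  expect_equal(ventilation_heat_requirement(24, 24, 0, 0, 0, cfg), 0)
  # 1.2 * 1006 * 5176.5 * 2 / 150
  expect_equal(ventilation_heat_requirement(26, 24, 0, 0, 0, cfg),
               1.2 * 1006 * 5176.5 * 2 / 150, tolerance = 1e-9)
  base <- ventilation_heat_requirement(26, 24, 1000, 500, -200, cfg)
  expect_equal(ventilation_heat_requirement(26, 24, 1000 + 123, 500, -200, cfg) - base,
               123, tolerance = 1e-9)
})

test_that("required rate inverts the sensible balance and flags degeneracy", {
  cfg <- tiny_cfg()
  expect_equal(required_ventilation_rate(0, 28, 24, 0, cfg)$vrr, 0)
  rv <- required_ventilation_rate(83328, 28, 24, 0, cfg)
  expect_equal(rv$vrr, 83328 / (1.2 * 1006 * 4), tolerance = 1e-9)
  expect_false(rv$degenerate)
  # halving the effective difference doubles the rate
  expect_equal(required_ventilation_rate(83328, 26, 24, 0, cfg)$vrr,
               2 * rv$vrr, tolerance = 1e-9)
  # pads widen the difference in inlet-corrected mode, shrink it as printed
  with_pad <- required_ventilation_rate(83328, 28, 24, 2, cfg)$vrr
  expect_lt(with_pad, rv$vrr)
  as_printed <- required_ventilation_rate(83328, 28, 24, 2, cfg,
                                          denominator_mode = "as_printed")$vrr
  expect_gt(as_printed, rv$vrr)
  expect_true(required_ventilation_rate(1000, 24.05, 24, 0, cfg)$degenerate)
  # negative requirement clamps at zero
  expect_equal(required_ventilation_rate(-5000, 28, 24, 0, cfg)$vrr, 0)
})

test_that("stage ladder covers the requirement and is non-decreasing", {
  cfg <- tiny_cfg()
  # 148,000 m3/h with 37,000 m3/h fans -> 4 fans -> stage 1
  s <- stage_from_vrr(148000 / 3600, 30, cfg)
  expect_identical(s$stage, 1L)
  expect_identical(s$n_fans, 4L)
  # 5 fans needed -> stage 2 (6 fans)
  s5 <- stage_from_vrr(5 * 37000 / 3600, 30, cfg)
  expect_identical(s5$stage, 2L)
  expect_identical(s5$n_fans, 6L)
  # zero requirement -> minimum ventilation
  s0 <- stage_from_vrr(0, 30, cfg)
  expect_identical(s0$stage, 0L)
  expect_equal(s0$q_m3s * 3600, min_vent_at(cfg$min_vent, 30), tolerance = 1e-6)
  expect_true(s0$stage0_duty > 0 && s0$stage0_duty <= 1)
  # above the top stage: capped at 14 fans
  top <- stage_from_vrr(1e4, 30, cfg)
  expect_identical(top$stage, 5L)
  expect_identical(top$n_fans, 14L)
  # monotone in the requirement, capacity always covers it (above minimum)
  vrrs <- seq(0, 160, length.out = 200)
  st <- vapply(vrrs, function(v) stage_from_vrr(v, 30, cfg)$stage, integer(1))
  expect_true(all(diff(st) >= 0))
  qs <- vapply(vrrs, function(v) stage_from_vrr(v, 30, cfg)$q_m3s, numeric(1))
  above_min <- vrrs > min_vent_at(cfg$min_vent, 30) / 3600 &
    vrrs <= 14 * cfg$fan_capacity / 3600
  expect_true(all(qs[above_min] >= vrrs[above_min] - 1e-9))
})

test_that("pad hysteresis follows the on/off thresholds and holds in the band", {
  cfg <- tiny_cfg()  # Tda = 1.5
  Td <- 25
  expect_true(pad_hysteresis(29, 30, Td, cfg, FALSE))    # > 28.5, To >= 29.5
  expect_true(pad_hysteresis(28.2, 30, Td, cfg, TRUE))   # inside (28, 28.5]
  expect_false(pad_hysteresis(28.2, 30, Td, cfg, FALSE)) # band holds prev
  expect_false(pad_hysteresis(27.9, 30, Td, cfg, TRUE))  # <= 28 switches off
  expect_false(pad_hysteresis(29, 29, Td, cfg, FALSE))   # To below trigger
  expect_true(pad_hysteresis(29, 29, Td, cfg, TRUE))     # ... but holds on
})

test_that("pad hysteresis does not chatter on a sinusoidal sweep", {
  cfg <- tiny_cfg()
  Td <- 25; To <- 31
  h <- seq(0, 48, by = 1 / 60)                 # two days at 1-min steps
  Ti <- Td + 2 * cfg$Tda + 0.25 + 1.5 * sin(2 * pi * h / 24)  # sweeps the band
  state <- FALSE
  states <- logical(length(h))
  for (i in seq_along(h)) {
    state <- pad_hysteresis(Ti[i], To, Td, cfg, state)
    states[i] <- state
  }
  transitions <- sum(abs(diff(states)))
  # one on and one off per diurnal cycle, no extra cycling
  expect_lte(transitions, 4)
  expect_gte(transitions, 2)
})

test_that("exactly the first satisfied exception fires, matching a brute-force interpreter", {
  cfg <- tiny_cfg()
  flock <- flock_state(30, 28120)
  grid <- expand.grid(
    Ti = seq(20, 34, by = 0.6),
    To = seq(15, 40, by = 1.2),
    Td = seq(22, 28, by = 1.4)
  )
  # independent Qv: plain arithmetic, no controller code
  m30 <- (-35.783 + 19.098 * 30 + 0.6008 * 900) / 1000
  k <- 4184 / 86400
  Sc_a <- 1 - 0.21 * sin(2 * pi * (12 + 6 - 0.38) / 24)
  Sc_l <- 1 - 0.46 * sin(2 * pi * (12 + 6 - 0.67) / 24)
  ua <- 0.247 * default_wall_area() + 2.75 * 1218
  ok <- TRUE
  for (i in seq_len(nrow(grid))) {
    Ti <- grid$Ti[i]; To <- grid$To[i]; Td <- grid$Td[i]
    dec <- decide_vrr(Ti, To, 60, flock, Td, 12, cfg, prev_pad_state = FALSE)
    Qa <- 28120 * m30^0.75 * (307.87 - 15.63 * Ti + 0.3105 * Ti^2) * k * Sc_a
    Ql <- 28120 * 0.4 * max(0, 583.5 - 17.1 * Ti + 25.25 * m30) * k * Sc_l
    Qv <- 1.2 * 1006 * 5176.5 * (Ti - Td) / 150 + Qa + Ql - ua * (Ti - To)
    pad_would <- (To >= Td + 3 * 1.5) && (Ti > Td + 2 * 1.5 + 0.5)
    want <- oracle_exception(Qv, Ti, To, Td, 1.5, pad_would)
    ok <- ok && identical(dec$exception_fired, want) &&
      abs(dec$qv - Qv) < 1e-6 * max(1, abs(Qv))
  }
  expect_true(ok)
})

test_that("exception branches produce the documented stages", {
  cfg <- tiny_cfg()
  flock <- flock_state(30, 28120)
  # Exception 1: below the band -> minimum ventilation
  d1 <- decide_vrr(25, 20, 60, flock, 24, 12, cfg)
  expect_identical(d1$exception_fired, "1")
  expect_identical(d1$stage, 0L)
  expect_false(d1$pad_on)
  # Exception 3: warm outside, no pads -> capped by one air exchange per dt
  d3 <- decide_vrr(26, 26, 60, flock, 24, 12, cfg)
  expect_identical(d3$exception_fired, "3")
  expect_lte(d3$vrr, air_exchange_rate(cfg) + 1e-9)
  # VRR2 = 5176.5/150 = 34.51 m3/s = 124,236 m3/h -> 4 fans -> stage 1
  expect_equal(air_exchange_rate(cfg), 34.51, tolerance = 1e-9)
  if (d3$vrr == air_exchange_rate(cfg)) expect_identical(d3$stage, 1L)
  # Exception 2: hot outside and inside -> pads on, rate staged with Tc > 0
  d2 <- decide_vrr(29.5, 33, 50, flock, 25, 14, cfg)
  expect_identical(d2$exception_fired, "2")
  expect_true(d2$pad_on)
  expect_gt(d2$Tc, 0)
  # no-exception path: mild outside, hot inside
  dn <- decide_vrr(27, 20, 60, flock, 24, 12, cfg)
  expect_identical(dn$exception_fired, "none")
  expect_gt(dn$vrr, 0)
})

test_that("required rate is non-decreasing in indoor temperature at fixed loads", {
  cfg <- tiny_cfg()
  To <- 20; Td <- 24
  vrrs <- vapply(seq(25.5, 32, by = 0.25), function(Ti) {
    Qv <- ventilation_heat_requirement(Ti, Td, 5e4, 1e4, 0, cfg)
    required_ventilation_rate(Qv, Ti, To, 0, cfg)$vrr
  }, numeric(1))
  expect_true(all(diff(vrrs) > -1e-9))
})
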