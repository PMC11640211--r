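# Discrepancy computation, quadrant classification, and energy accounting.

test_that("discrepancies vanish when the log ventilates at the recomputed requirement", {
  cfg <- tiny_cfg()
  log <- make_log(n = 5, Ti = 27, To = 20, Td = 24, age = 30)
  d0 <- compute_discrepancies(log, cfg, bird_count = 28120)
  # forward-construct: put the recomputed requirement into actual_vent
  log$actual_vent_m3h <- log$actual_vent_m3h + d0$vr_disc_m3h
  d <- compute_discrepancies(log, cfg, bird_count = 28120)
  expect_equal(d$vr_disc_m3h, rep(0, 5), tolerance = 1e-9)
  expect_equal(d$t_disc_C, rep(24 - 27, 5))
  # on-setpoint record
  log2 <- make_log(n = 1, Ti = 24, Td = 24)
  expect_equal(compute_discrepancies(log2, cfg, 28120)$t_disc_C, 0)
  expect_error(compute_discrepancies(make_log()[, -2], cfg, 28120),
               "missing channels")
})

test_that("audited requirement matches a hand-computed heat balance", {
  cfg <- tiny_cfg()
  # midnight record so the activity modulation is hand-computable
  log <- make_log(n = 1, dt = 600, Ti = 27, To = 20, RHo = 60, Td = 24,
                  age = 30, pad_on = 0)
  d <- compute_discrepancies(log, cfg, bird_count = 100)
  m30 <- (-35.783 + 19.098 * 30 + 0.6008 * 900) / 1000
  k <- 4184 / 86400
  Sc_a <- 1 - 0.21 * sin(2 * pi * (0 + 6 - 0.38) / 24)
  Sc_l <- 1 - 0.46 * sin(2 * pi * (0 + 6 - 0.67) / 24)
  Qa <- 100 * m30^0.75 * (307.87 - 15.63 * 27 + 0.3105 * 27^2) * k * Sc_a
  Ql <- 100 * 0.4 * (583.5 - 17.1 * 27 + 25.25 * m30) * k * Sc_l
  Qd <- -(0.247 * default_wall_area() + 2.75 * 1218) * (27 - 20)
  Qv <- 1.2 * 1006 * 5176.5 * (27 - 24) / 150 + Qa + Ql + Qd
  vrr_m3h <- Qv / (1.2 * 1006 * 7) * 3600
  expect_equal(d$vr_disc_m3h, vrr_m3h - 148000, tolerance = 1e-6)
})

test_that("quadrant summary reproduces constructed category counts", {
  # 100 records: 74 proper, 15 under-vent/hot, 3 over-vent/cold,
  # 8 over-vent/hot (anomalous)
  discs <- data.frame(
    timestamp_s = seq_len(100),
    vr_disc_m3h = c(rep(0, 74), rep(5000, 15), rep(-5000, 3), rep(-5000, 8)),
    t_disc_C = c(rep(0, 74), rep(-3, 15), rep(3, 3), rep(-3, 8)),
    pad_on = rep(FALSE, 100)
  )
  q <- quadrant_summary(discs, band = 1.5)
  expect_equal(q$proper_pct, 74)
  expect_equal(q$high_undervent_pct, 15)
  expect_equal(q$low_overvent_pct, 3)
  expect_equal(q$anomalous_pct, 8)
  expect_equal(q$rare_pct, 0)
  expect_equal(q$potential_proper_pct, 92)
  expect_equal(q$record_count, 100)
})

test_that("quadrant percentages always sum to 100 and pad exclusion works", {
  set.seed(42)
  discs <- data.frame(
    timestamp_s = 1:500,
    vr_disc_m3h = stats::rnorm(500, 0, 2e4),
    t_disc_C = stats::rnorm(500, 0, 2),
    pad_on = stats::runif(500) < 0.3
  )
  q <- quadrant_summary(discs)
  total <- q$proper_pct + q$high_undervent_pct + q$low_overvent_pct +
    q$anomalous_pct + q$rare_pct
  expect_equal(total, 100, tolerance = 1e-9)
  expect_equal(q$record_count, sum(!discs$pad_on))
  q_all <- quadrant_summary(discs, exclude_pad_on = FALSE)
  expect_equal(q_all$record_count, 500)
  expect_error(quadrant_summary(discs[discs$pad_on, ]), "no records")
  # all-proper degenerate case
  all_ok <- data.frame(timestamp_s = 1:4, vr_disc_m3h = 0,
                       t_disc_C = c(-1, 0, 1, 1.5), pad_on = FALSE)
  expect_equal(quadrant_summary(all_ok)$proper_pct, 100)
})

test_that("fan-hour accounting follows the definition and is additive", {
  # 14 fans for one hour at 1-min sampling
  log <- make_log(n = 60, dt = 60, n_fans = 14)
  expect_equal(fan_hours(log), 14, tolerance = 1e-9)
  expect_equal(fan_hours(make_log(n = 10, n_fans = 0)), 0)
  # alternating 4 and 6 fans over equal time -> mean 5 per unit time
  alt <- make_log(n = 120, dt = 60)
  alt$n_fans <- rep(c(4, 6), 60)
  expect_equal(fan_hours(alt), 5 * 2, tolerance = 1e-9)
  # additive over concatenation
  a <- make_log(n = 30, dt = 60, n_fans = 8)
  b <- make_log(n = 30, dt = 60, n_fans = 10)
  b$timestamp_s <- b$timestamp_s + max(a$timestamp_s) + 60
  expect_equal(fan_hours(rbind(a, b)), fan_hours(a) + fan_hours(b),
               tolerance = 1e-9)
  bad <- make_log(n = 5)
  bad$timestamp_s[3] <- bad$timestamp_s[3] + 1
  expect_error(fan_hours(bad), "uniform")
})

test_that("fan energy and usage comparison reproduce the reference arithmetic", {
  expect_equal(fan_energy_kwh(3182)$kwh_reported, 2660)
  expect_equal(fan_energy_kwh(1645)$kwh_reported, 1375)
  expect_equal(fan_energy_kwh(0)$kwh, 0)
  cmp <- usage_comparison(
    control = list(fan_hours = 3182, pad_hours = 11.75),
    experimental = list(fan_hours = 1645, pad_hours = 88.80)
  )
  expect_equal(cmp$fan_usage_pct, 51.69, tolerance = 0.01)
  expect_equal(cmp$pad_fold_change, 7.56, tolerance = 0.005)
  expect_equal(cmp$energy_saved_kwh_reported, 1285)
  self <- usage_comparison(list(fan_hours = 10, pad_hours = 2),
                           list(fan_hours = 10, pad_hours = 2))
  expect_equal(self$fan_usage_pct, 100)
  expect_equal(self$pad_fold_change, 1)
  expect_error(usage_comparison(list(fan_hours = 0, pad_hours = 1),
                                list(fan_hours = 1, pad_hours = 1)), "zero")
})
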