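# Conventional set-temperature stage controller: fan stage from indoor
# temperature thresholds per bird age, pads on a threshold with an
# intermittent duty.

#' Stage-threshold table for the conventional controller
#'
#' Per-age start temperatures for fan stages 1-5 and the pad threshold. The
#' default is a synthetic table, NOT farm data: the base temperature
#' declines linearly from 32 degC at stocking to 24 degC at day 28, stage k
#' starts at base + k degC, and the pads start at base + 5 degC. Supply a
#' farm's own table to replicate a specific installation.
#'
#' @param age_days Breakpoint ages, days.
#' @param base_C Base (set) temperature at each breakpoint, degC.
#' @param stage_offsets_C Offsets above base for stages 1-5, degC, strictly
#'   increasing.
#' @param pad_offset_C Offset above base for the pad threshold, degC.
#' @param pad_duty Fraction of each cycle the pads run once triggered (the
#'   conventional system runs them intermittently; default 60 s per 300 s).
#' @return A `bv_stage_table` list.
#' @export
stage_threshold_table <- function(age_days = c(0, 28, 60),
                                  base_C = c(32, 24, 24),
                                  stage_offsets_C = 1:5,
                                  pad_offset_C = 5,
                                  pad_duty = 60 / 300) {
  stopifnot(length(age_days) == length(base_C), !is.unsorted(age_days))
  if (length(stage_offsets_C) != 5 ||
      is.unsorted(stage_offsets_C, strictly = TRUE)) {
    stop("stage_threshold_table: stage_offsets_C must be 5 strictly increasing values")
  }
  stopifnot(pad_duty >= 0, pad_duty <= 1)
  structure(list(age_days = age_days, base_C = base_C,
                 stage_offsets_C = stage_offsets_C,
                 pad_offset_C = pad_offset_C, pad_duty = pad_duty),
            class = "bv_stage_table")
}

#' Threshold row at a given age
#' @param table A [stage_threshold_table()].
#' @param age_days Age, days; must lie within the table's age range.
#' @return List: `starts_C` (stage 1-5 start temperatures), `pad_C`.
#' @export
thresholds_at <- function(table, age_days) {
  rng <- range(table$age_days)
  if (age_days < rng[1] || age_days > rng[2]) {
    stop("thresholds_at: age ", age_days, " outside table range [",
         rng[1], ", ", rng[2], "]")
  }
  base <- stats::approx(table$age_days, table$base_C, xout = age_days)$y
  list(starts_C = base + table$stage_offsets_C, pad_C = base + table$pad_offset_C)
}

#' One control decision of the conventional controller
#'
#' The fan stage is the highest stage whose start temperature has been
#' reached (comparison with `>=`; stage 0 when the indoor temperature is
#' below all starts). Pads run at the configured intermittent duty whenever
#' the indoor temperature is at or above the pad threshold. No hysteresis
#' is applied by default.
#'
#' @param Ti Indoor temperature, degC.
#' @param age_days Bird age, days (must lie within the table's range).
#' @param table A [stage_threshold_table()].
#' @param cfg A [house_config()].
#' @param prev_pad_state Unused by the default (stateless) rule; kept for
#'   interface parity with [decide_vrr()].
#' @return A `bv_decision` list (same shape as [decide_vrr()]; `vrr` and
#'   `qv` are `NA` --- this controller does not compute them;
#'   `exception_fired` is `"none"`).
#' @export
decide_baseline <- function(Ti, age_days, table, cfg, prev_pad_state = FALSE) {
  th <- thresholds_at(table, age_days)
  stage <- sum(Ti >= th$starts_C)
  cap_m3s <- cfg$fan_capacity / 3600
  if (stage == 0) {
    minv_m3s <- min_vent_at(cfg$min_vent, age_days) / 3600
    duty <- min(1, minv_m3s / (cfg$stage_fans[1] * cap_m3s))
    n_fans <- cfg$stage_fans[1]
    q <- n_fans * cap_m3s * duty
  } else {
    duty <- 1
    n_fans <- cfg$stage_fans[stage + 1]
    q <- n_fans * cap_m3s
  }
  pad_on <- Ti >= th$pad_C
  structure(list(
    stage = as.integer(stage), n_fans = as.integer(n_fans),
    stage0_duty = duty, pad_on = pad_on,
    pad_duty = if (pad_on) table$pad_duty else 0,
    vrr = NA_real_, q_m3s = q, qv = NA_real_,
    Tc = 0, exception_fired = "none"
  ), class = "bv_decision")
}
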