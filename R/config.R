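# House configuration, set-temperature schedule, minimum-ventilation schedule.

#' Age-dependent set-temperature schedule
#'
#' Piecewise-linear schedule of target indoor temperature (Td) against bird
#' age; chicks need warmth, grown birds less. The default declines from
#' 32 degC at stocking to 24 degC at day 28 and stays there.
#'
#' @param age_days Breakpoint ages, days.
#' @param Td_C Set temperatures at the breakpoints, degC (non-increasing).
#' @return A `bv_setpoints` data.frame.
#' @export
setpoint_schedule <- function(age_days = c(0, 28, 60),
                              Td_C = c(32, 24, 24)) {
  stopifnot(length(age_days) == length(Td_C), !is.unsorted(age_days))
  if (is.unsorted(rev(Td_C))) {
    stop("setpoint_schedule: Td_C must be non-increasing with age")
  }
  structure(data.frame(age_days = age_days, Td_C = Td_C),
            class = c("bv_setpoints", "data.frame"))
}

#' Set temperature at a given age
#' @param schedule A [setpoint_schedule()].
#' @param age_days Age, days.
#' @return Td in degC (linear interpolation, clamped at the ends).
#' @export
setpoint_at <- function(schedule, age_days) {
  stats::approx(schedule$age_days, schedule$Td_C, xout = age_days,
                rule = 2)$y
}

#' Age-dependent minimum-ventilation schedule
#'
#' Baseline airflow delivered at stage 0 for air quality regardless of
#' temperature. Defaults interpolate linearly from 1233 m3/h at stocking to
#' 22,611 m3/h at day 35 (harvest), constant thereafter.
#'
#' @param age_days Breakpoint ages, days.
#' @param vent_m3h Minimum ventilation at the breakpoints, m3/h
#'   (non-decreasing).
#' @return A `bv_minvent` data.frame.
#' @export
min_vent_schedule <- function(age_days = c(0, 35),
                              vent_m3h = c(1233, 22611)) {
  stopifnot(length(age_days) == length(vent_m3h), !is.unsorted(age_days))
  if (is.unsorted(vent_m3h)) {
    stop("min_vent_schedule: vent_m3h must be non-decreasing with age")
  }
  structure(data.frame(age_days = age_days, vent_m3h = vent_m3h),
            class = c("bv_minvent", "data.frame"))
}

#' Minimum ventilation at a given age
#' @param schedule A [min_vent_schedule()].
#' @param age_days Age, days.
#' @return Minimum ventilation, m3/h.
#' @export
min_vent_at <- function(schedule, age_days) {
  stats::approx(schedule$age_days, schedule$vent_m3h, xout = age_days,
                rule = 2)$y
}

#' House and ventilation-plant configuration
#'
#' All physical and operational constants of the building and its
#' ventilation plant. Defaults describe the reference tunnel-ventilated
#' house: 87 x 14 m floor, 3.5 m eaves, 5 m ridge (air volume 5176.5 m3),
#' 14 tunnel fans of 37,000 m3/h each in six stages (stage 0 is an
#' intermittent two-fan minimum-ventilation stage; stages 1-5 run 4, 6, 8,
#' 10 and 14 fans continuously), evaporative pads of 65% saturation
#' efficiency.
#'
#' @param Vb House air volume, m3.
#' @param rho Air density, kg m-3.
#' @param cp Specific heat of air, J kg-1 degC-1.
#' @param delta_t Energy-balance control horizon, s (the time over which the
#'   indoor-to-set temperature gap is to be closed).
#' @param Tda Allowable temperature band around the set temperature, degC.
#' @param pad_efficiency Evaporative pad saturation efficiency in \[0, 1\].
#' @param fan_capacity Airflow per tunnel fan, m3/h.
#' @param stage_fans Fans per stage, stages 0-5; the first entry is the
#'   intermittent pair.
#' @param min_vent Minimum-ventilation schedule ([min_vent_schedule()]).
#' @param envelope Envelope spec ([envelope_spec()]).
#' @param control_interval Controller update period, s.
#' @param fan_power_w Electrical power per tunnel fan, W.
#' @param pad_power_w Electrical power of the pad circulation pump, W.
#' @param denominator_mode How the ventilation-rate denominator treats the
#'   pad drop: `"inlet_corrected"` uses `Ti - (To - Tc)` (pads widen the
#'   difference, the default); `"as_printed"` uses `Ti - To - Tc`.
#' @param degenerate_tol Absolute indoor/inlet temperature difference, degC,
#'   below which the ventilation-rate denominator is treated as degenerate
#'   and the air-exchange fallback `Vb / delta_t` applies.
#' @param mass_floor_kg Optional hatch-weight floor passed to
#'   [broiler_mass()] (needed for episodes that start before day 2).
#' @return A `bv_house` list.
#' @export
house_config <- function(Vb = 5176.5,
                         rho = 1.2,
                         cp = 1006,
                         delta_t = 150,
                         Tda = 1.5,
                         pad_efficiency = 0.65,
                         fan_capacity = 37000,
                         stage_fans = c(2L, 4L, 6L, 8L, 10L, 14L),
                         min_vent = min_vent_schedule(),
                         envelope = envelope_spec(),
                         control_interval = 10,
                         fan_power_w = 836,
                         pad_power_w = 1100,
                         denominator_mode = c("inlet_corrected", "as_printed"),
                         degenerate_tol = 0.2,
                         mass_floor_kg = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  for (nm in c("Vb", "rho", "cp", "delta_t", "Tda", "fan_capacity",
               "control_interval", "fan_power_w", "pad_power_w",
               "degenerate_tol")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("house_config: ", nm, " must be a positive number")
    }
  }
  if (pad_efficiency < 0 || pad_efficiency > 1) {
    stop("house_config: pad_efficiency must be in [0, 1]")
  }
  if (is.unsorted(stage_fans, strictly = TRUE)) {
    stop("house_config: stage_fans must be strictly increasing")
  }
  if (!inherits(envelope, "bv_envelope")) stop("house_config: envelope must be an envelope_spec()")
  if (!inherits(min_vent, "bv_minvent")) stop("house_config: min_vent must be a min_vent_schedule()")
  structure(list(
    Vb = Vb, rho = rho, cp = cp, delta_t = delta_t, Tda = Tda,
    pad_efficiency = pad_efficiency, fan_capacity = fan_capacity,
    stage_fans = as.integer(stage_fans), min_vent = min_vent,
    envelope = envelope, control_interval = control_interval,
    fan_power_w = fan_power_w, pad_power_w = pad_power_w,
    denominator_mode = denominator_mode, degenerate_tol = degenerate_tol,
    mass_floor_kg = mass_floor_kg
  ), class = "bv_house")
}
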