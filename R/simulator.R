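# Lumped-parameter (single-zone, complete-mixing) thermal model of the house
# and a seeded synthetic diurnal weather generator, for closed-loop runs of
# either controller.

#' Synthetic weather scenario
#'
#' Sinusoidal diurnal outdoor temperature between `night_min_T` and
#' `day_max_T`, peaking at `peak_hour`; relative humidity in anti-phase
#' between `RH_day` and `RH_night`; optional seeded Gaussian noise on
#' temperature. Presets: `"hot_spell"` (37/26 degC, the summer heat-wave
#' regime in which daytime temperatures run 33-37 degC), `"mild"` (26/16),
#' `"winter"` (5/-5).
#'
#' @param preset One of `"hot_spell"`, `"mild"`, `"winter"`, or `NULL` to
#'   use the explicit parameters.
#' @param day_max_T,night_min_T Daily extremes, degC.
#' @param peak_hour Hour of the temperature maximum.
#' @param RH_day,RH_night Relative humidity at the temperature peak and
#'   trough, percent.
#' @param day_count Number of simulated days.
#' @param seed Integer seed for the noise stream.
#' @param noise_sd Gaussian noise s.d. on temperature, degC.
#' @return A `bv_scenario` list.
#' @export
weather_scenario <- function(preset = NULL,
                             day_max_T = 26, night_min_T = 16,
                             peak_hour = 15, RH_day = 55, RH_night = 90,
                             day_count = 5, seed = 1, noise_sd = 0) {
  if (!is.null(preset)) {
    p <- switch(preset,
      hot_spell = list(day_max_T = 37, night_min_T = 26, RH_day = 52, RH_night = 90),
      mild      = list(day_max_T = 26, night_min_T = 16, RH_day = 55, RH_night = 90),
      winter    = list(day_max_T = 5,  night_min_T = -5, RH_day = 60, RH_night = 85),
      stop("weather_scenario: unknown preset '", preset, "'")
    )
    day_max_T <- p$day_max_T; night_min_T <- p$night_min_T
    RH_day <- p$RH_day; RH_night <- p$RH_night
  }
  stopifnot(day_max_T >= night_min_T, RH_day > 0, RH_day <= 100,
            RH_night > 0, RH_night <= 100, day_count >= 1, noise_sd >= 0)
  structure(list(day_max_T = day_max_T, night_min_T = night_min_T,
                 peak_hour = peak_hour, RH_day = RH_day,
                 RH_night = RH_night, day_count = as.integer(day_count),
                 seed = as.integer(seed), noise_sd = noise_sd),
            class = "bv_scenario")
}

#' Generate an outdoor weather series
#'
#' @param scenario A [weather_scenario()].
#' @param dt_s Sampling interval, s.
#' @return data.frame with `time_s`, `hour` (hour of day), `To_C`,
#'   `RHo_pct`. Deterministic for a fixed scenario seed.
#' @export
weather_generate <- function(scenario, dt_s = 10) {
  n <- ceiling(scenario$day_count * 86400 / dt_s)
  time_s <- (seq_len(n) - 1) * dt_s
  hour <- (time_s / 3600) %% 24
  mid <- (scenario$day_max_T + scenario$night_min_T) / 2
  amp <- (scenario$day_max_T - scenario$night_min_T) / 2
  phase <- cos(2 * pi * (hour - scenario$peak_hour) / 24)
  To <- mid + amp * phase
  if (scenario$noise_sd > 0) {
    # seed locally; leave the caller's RNG stream untouched
    rs <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(scenario$seed)
    To <- To + stats::rnorm(n, 0, scenario$noise_sd)
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  }
  RH_mid <- (scenario$RH_day + scenario$RH_night) / 2
  RH_amp <- (scenario$RH_night - scenario$RH_day) / 2
  RHo <- RH_mid - RH_amp * phase
  RHo <- pmin(99, pmax(5, RHo))
  data.frame(time_s = time_s, hour = hour, To_C = To, RHo_pct = RHo)
}

#' One explicit-Euler step of the single-zone thermal model
#'
#' `dTi/dt = [Qa + Ql + Qd + rho*cp*q*((To - Tc) - Ti)] / (rho*cp*Vb)` with
#' `q` the delivered ventilation (m3/s) and `To - Tc` the pad-cooled inlet
#' temperature. The model assumes complete mixing of the indoor air.
#'
#' @param Ti Indoor temperature at the start of the step, degC.
#' @param q_m3s Delivered ventilation, m3/s.
#' @param To Outdoor temperature, degC.
#' @param Tc Effective pad temperature drop of the inlet air, degC.
#' @param loads_W Total internal + envelope heat `Qa + Ql + Qd`, W.
#' @param cfg A [house_config()].
#' @param dt Step length, s (> 0).
#' @return Indoor temperature after `dt`, degC.
#' @export
sim_step <- function(Ti, q_m3s, To, Tc, loads_W, cfg, dt) {
  stopifnot(dt > 0)
  rc <- cfg$rho * cfg$cp
  Ti_new <- Ti + dt * (loads_W + rc * q_m3s * ((To - Tc) - Ti)) / (rc * cfg$Vb)
  if (!is.finite(Ti_new)) stop("sim_step: non-finite indoor temperature (instability)")
  Ti_new
}

#' Closed-form solution of the single-zone model under constant forcing
#'
#' With constant loads `L`, airflow `q` and inlet temperature `Ta`, the
#' model is linear with steady state `Ta + L/(rho*cp*q)` and time constant
#' `Vb/q`; used as the integration oracle and for the restoration analysis.
#'
#' @param Ti0 Initial indoor temperature, degC.
#' @param q_m3s Airflow, m3/s (> 0).
#' @param Ta Inlet air temperature (outdoor minus pad drop), degC.
#' @param loads_W Constant heat loads, W.
#' @param cfg A [house_config()].
#' @param t_s Elapsed time, s.
#' @return Indoor temperature at `t_s`, degC.
#' @export
zone_closed_form <- function(Ti0, q_m3s, Ta, loads_W, cfg, t_s) {
  stopifnot(q_m3s > 0)
  Tss <- Ta + loads_W / (cfg$rho * cfg$cp * q_m3s)
  Tss + (Ti0 - Tss) * exp(-q_m3s * t_s / cfg$Vb)
}

#' Run a closed-loop episode
#'
#' Couples a controller to the thermal model at the control interval:
#' weather sample -> control decision -> Euler step -> log record. The VRR
#' controller carries pad hysteresis state between ticks; the conventional
#' controller is stateless. Fan and pad runtimes and electrical energy are
#' accumulated exactly (stage-0 and pad duties weighted).
#'
#' @param controller `"vrr"` or `"baseline"`.
#' @param scenario A [weather_scenario()].
#' @param cfg A [house_config()].
#' @param setpoints A [setpoint_schedule()].
#' @param start_age_days Bird age on the first simulated day.
#' @param bird_count Number of birds.
#' @param Ti0 Initial indoor temperature, degC (defaults to the day-one set
#'   temperature).
#' @param baseline_table A [stage_threshold_table()] (conventional
#'   controller only).
#' @param substeps Integer >= 1; Euler sub-steps per control interval.
#' @return A `bv_log` data.frame (one row per control interval) with
#'   columns `timestamp_s, Ti_C, To_C, RHo_pct, Td_C, age_days, stage,
#'   n_fans, pad_on, actual_vent_m3h` and attribute `summary`: list of
#'   `fan_hours`, `pad_hours`, `fan_energy_kwh`, `pad_energy_kwh`,
#'   `mean_Ti`, `mean_daytime_Ti` (hours 11-19), `step_s`.
#' @export
run_episode <- function(controller = c("vrr", "baseline"), scenario, cfg,
                        setpoints = setpoint_schedule(),
                        start_age_days = 20, bird_count = 28120,
                        Ti0 = NULL, baseline_table = stage_threshold_table(),
                        substeps = 1L) {
  controller <- match.arg(controller)
  dt <- cfg$control_interval
  wx <- weather_generate(scenario, dt_s = dt)
  n <- nrow(wx)
  if (is.null(Ti0)) Ti0 <- setpoint_at(setpoints, start_age_days)

  Ti <- Ti0
  pad_prev <- FALSE
  fan_sec <- 0; pad_sec <- 0
  out_Ti <- numeric(n); out_Td <- numeric(n); out_age <- integer(n)
  out_stage <- integer(n); out_nfans <- integer(n); out_pad <- numeric(n)
  out_vent <- numeric(n)

  # per-day quantities, hoisted out of the control loop
  ages <- start_age_days + (wx$time_s %/% 86400)
  uage <- sort(unique(ages))
  Td_by_age <- setpoint_at(setpoints, uage)
  flock_by_age <- lapply(uage, flock_state, bird_count = bird_count,
                         mass_floor_kg = cfg$mass_floor_kg)
  age_idx <- match(ages, uage)

  for (i in seq_len(n)) {
    age <- ages[i]
    Td <- Td_by_age[age_idx[i]]
    To <- wx$To_C[i]; RHo <- wx$RHo_pct[i]; hr <- wx$hour[i]
    flock <- flock_by_age[[age_idx[i]]]

    dec <- if (controller == "vrr") {
      decide_vrr(Ti, To, RHo, flock, Td, hr, cfg, prev_pad_state = pad_prev)
    } else {
      decide_baseline(Ti, age, baseline_table, cfg, prev_pad_state = pad_prev)
    }
    pad_prev <- dec$pad_on

    # effective pad drop (duty-weighted over the interval)
    Tc_eff <- 0
    if (dec$pad_duty > 0) {
      Tc_full <- pad_temperature_drop(To, wet_bulb(To, RHo), cfg$pad_efficiency, TRUE)
      Tc_eff <- Tc_full * dec$pad_duty
    }

    heat <- flock_heat(flock, Ti, hr, clamp_negative = TRUE)
    loads <- heat$Qa + heat$Ql + envelope_heat(Ti, To, cfg$envelope)
    sub <- max(1L, as.integer(substeps))
    h <- dt / sub
    for (k in seq_len(sub)) {
      if (k > 1) {
        heat <- flock_heat(flock, Ti, hr, clamp_negative = TRUE)
        loads <- heat$Qa + heat$Ql + envelope_heat(Ti, To, cfg$envelope)
      }
      Ti <- sim_step(Ti, dec$q_m3s, To, Tc_eff, loads, cfg, h)
    }

    eff_fans <- if (dec$stage == 0) dec$n_fans * dec$stage0_duty else dec$n_fans
    fan_sec <- fan_sec + eff_fans * dt
    pad_sec <- pad_sec + dec$pad_duty * dt

    out_Ti[i] <- Ti; out_Td[i] <- Td; out_age[i] <- age
    out_stage[i] <- dec$stage; out_nfans[i] <- dec$n_fans
    out_pad[i] <- dec$pad_duty
    out_vent[i] <- dec$q_m3s * 3600
  }

  log <- data.frame(
    timestamp_s = wx$time_s, Ti_C = out_Ti, To_C = wx$To_C,
    RHo_pct = wx$RHo_pct, Td_C = out_Td, age_days = out_age,
    stage = out_stage, n_fans = out_nfans, pad_on = out_pad,
    actual_vent_m3h = out_vent
  )
  day <- wx$hour >= 11 & wx$hour < 19
  attr(log, "summary") <- list(
    fan_hours = fan_sec / 3600,
    pad_hours = pad_sec / 3600,
    fan_energy_kwh = fan_sec / 3600 * cfg$fan_power_w / 1000,
    pad_energy_kwh = pad_sec / 3600 * cfg$pad_power_w / 1000,
    mean_Ti = mean(out_Ti),
    mean_daytime_Ti = mean(out_Ti[day]),
    step_s = dt
  )
  class(log) <- c("bv_log", "data.frame")
  log
}

#' Episode summary accumulators
#' @param log A `bv_log` from [run_episode()].
#' @return The summary list attached to the log.
#' @export
episode_summary <- function(log) {
  s <- attr(log, "summary")
  if (is.null(s)) stop("episode_summary: log has no summary attribute")
  s
}
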